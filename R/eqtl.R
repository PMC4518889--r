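#' Single-locus expression-genotype regression
#'
#' Ordinary least squares of an expression vector on an additively coded
#' genotype vector, with an intercept. The p-value is two-sided from a t
#' distribution with n - 2 degrees of freedom; for a binary genotype it is
#' identical to the pooled-variance two-sample t-test. Samples with a missing
#' genotype are dropped pairwise.
#'
#' @param y numeric expression values (log2 scale by convention).
#' @param g genotype codes (allele count of the non-reference allele:
#'   0/1 for a backcross, 0/1/2 for a population design); `NA` = missing.
#' @return a one-row tibble with `n`, `slope`, `se`, `tstat`, `p_value`,
#'   `testable` and `degenerate`. Non-testable inputs (fewer than 3 complete
#'   pairs, or a constant genotype) return `testable = FALSE` with `NA`
#'   statistics. A perfect fit with a nonzero slope reports the smallest
#'   positive double as p and `degenerate = TRUE`; a constant `y` reports
#'   slope 0, p 1.
#' @export
#' @examples
#' eqtl_regress(c(1, 2, 3, 4), c(0, 0, 1, 1))  # slope 2, the two-group case
eqtl_regress <- function(y, g) {
  if (length(y) != length(g)) stop_argument("y and g must have equal length")
  ok <- !is.na(y) & !is.na(g)
  y <- as.numeric(y[ok]); g <- as.numeric(g[ok])
  n <- length(y)
  not_testable <- tibble(n = n, slope = NA_real_, se = NA_real_,
                         tstat = NA_real_, p_value = NA_real_,
                         testable = FALSE, degenerate = FALSE)
  if (n < 3L) return(not_testable)
  gc <- g - mean(g)
  sxx <- sum(gc^2)
  if (sxx == 0) return(not_testable)
  yc <- y - mean(y)
  sxy <- sum(yc * gc)
  syy <- sum(yc^2)
  slope <- sxy / sxx
  sse <- max(syy - slope * sxy, 0)
  df <- n - 2L
  if (syy == 0) {
    return(tibble(n = n, slope = 0, se = 0, tstat = 0, p_value = 1,
                  testable = TRUE, degenerate = FALSE))
  }
  if (sse <= syy * .Machine$double.eps * n) {
    return(tibble(n = n, slope = slope, se = 0, tstat = Inf * sign(slope),
                  p_value = .Machine$double.xmin, testable = TRUE,
                  degenerate = TRUE))
  }
  se <- sqrt(sse / df / sxx)
  tstat <- slope / se
  tibble(n = n, slope = slope, se = se, tstat = tstat,
         p_value = max(2 * pt(-abs(tstat), df), .Machine$double.xmin),
         testable = TRUE, degenerate = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: the q-value of the p-value with
#' rank j among m is `min over k >= j of m * p(k) / k`, capped at 1, and
#' returned in the input order.
#'
#' @param pvalues numeric vector with every value in (0, 1].
#' @return q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop_argument("p-values must all lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

# Vectorized OLS of every row of Y (probesets x samples) on one genotype
# vector. Returns slope/p per row; NA row when the locus is untestable.
regress_matrix <- function(Y, g) {
  ok <- !is.na(g)
  n <- sum(ok)
  out <- list(slope = rep(NA_real_, nrow(Y)), p = rep(NA_real_, nrow(Y)), n = n)
  if (n < 3L) return(out)
  gg <- g[ok]
  gc <- gg - mean(gg)
  sxx <- sum(gc^2)
  if (sxx == 0) return(out)
  Ys <- Y[, ok, drop = FALSE]
  Yc <- Ys - rowMeans(Ys)
  sxy <- as.vector(Yc %*% gc)
  syy <- rowSums(Yc^2)
  slope <- sxy / sxx
  sse <- pmax(syy - slope * sxy, 0)
  df <- n - 2L
  p <- rep(NA_real_, nrow(Y))
  const_y <- syy == 0
  degen <- !const_y & sse <= syy * .Machine$double.eps * n
  normal <- !const_y & !degen
  se2 <- sse[normal] / df / sxx
  tstat <- slope[normal] / sqrt(se2)
  p[normal] <- pmax(2 * pt(-abs(tstat), df), .Machine$double.xmin)
  p[const_y] <- 1
  slope[const_y] <- 0
  p[degen] <- .Machine$double.xmin
  out$slope <- slope
  out$p <- p
  out
}

#' Scan probesets for expression QTL
#'
#' For every probeset, regresses expression on genotype at every eligible
#' locus and reports the statistically strongest locus as the candidate eQTL.
#' Ties on p are broken by genomic order (chromosome, position, locus id).
#' In `cis` mode a locus is eligible when it lies on the probeset's TSS
#' chromosome within `cis_window_bp` of the TSS (bounds inclusive); in
#' `genomewide` mode every locus is eligible. Probesets with no testable
#' locus are omitted (a message reports how many). Best-locus p-values are
#' adjusted across probesets with [bh_fdr()].
#'
#' The allele-effect direction `allele_effect_d` is the difference of group
#' means at the best locus, code-0 homozygotes minus carriers (code > 0), in
#' log2 units: a positive value means reference-type homozygotes express the
#' gene more highly.
#'
#' @param expr expression tibble: `probeset_id` column plus one numeric
#'   column per sample (log2 scale).
#' @param geno genotype tibble: `locus_id`, `chrom`, `pos` columns plus one
#'   column per sample holding codes 0/1(/2), `NA` = missing.
#' @param mode `"genomewide"` or `"cis"`.
#' @param cis_window_bp half-width of the cis window around the TSS, in bp
#'   (default 1e6, i.e. one megabase; the boundary locus at exactly this
#'   distance is eligible).
#' @param tss per-probeset anchors for cis mode: a tibble with
#'   `probeset_id`, `tss_chrom`, `tss_pos`, or an [annotation_set()] whose
#'   probesets carry them.
#' @return a tibble of class `eqtl_result`, one row per scanned probeset:
#'   `probeset_id`, `best_locus_id`, `n`, `slope`, `p_value`, `neglog10p`,
#'   `allele_effect_d`, `q_value`.
#' @export
eqtl_scan <- function(expr, geno, mode = c("genomewide", "cis"),
                      cis_window_bp = 1e6, tss = NULL) {
  mode <- match.arg(mode)
  if (!"probeset_id" %in% names(expr)) stop_argument("expr needs a probeset_id column")
  if (anyDuplicated(expr$probeset_id)) stop_argument("expr has duplicate probeset ids")
  need <- c("locus_id", "chrom", "pos")
  if (!all(need %in% names(geno))) {
    stop_argument("geno needs locus_id, chrom, pos columns")
  }
  check_count(cis_window_bp, "cis_window_bp", min = 0L)

  samples <- intersect(setdiff(names(expr), "probeset_id"),
                       setdiff(names(geno), need))
  if (!length(samples)) stop_argument("expr and geno share no sample columns")

  geno <- dplyr::arrange(geno, .data$chrom, .data$pos, .data$locus_id)
  Y <- as.matrix(expr[, samples, drop = FALSE])
  storage.mode(Y) <- "double"
  rownames(Y) <- expr$probeset_id
  if (any(!is.finite(Y))) stop_argument("expression values must be finite")
  G <- as.matrix(geno[, samples, drop = FALSE])
  storage.mode(G) <- "double"

  np <- nrow(Y); nl <- nrow(geno)
  eligible <- matrix(TRUE, np, nl)
  if (mode == "cis") {
    if (is.null(tss)) stop_argument("cis mode requires tss anchors")
    if (inherits(tss, "annotation_set")) tss <- tss$probesets
    anchors <- dplyr::left_join(tibble(probeset_id = expr$probeset_id),
                                tss[, c("probeset_id", "tss_chrom", "tss_pos")],
                                by = "probeset_id")
    for (i in seq_len(np)) {
      eligible[i, ] <- !is.na(anchors$tss_chrom[i]) &
        geno$chrom == anchors$tss_chrom[i] &
        abs(geno$pos - anchors$tss_pos[i]) <= cis_window_bp
    }
  }

  P <- matrix(NA_real_, np, nl)
  S <- matrix(NA_real_, np, nl)
  n_used <- integer(nl)
  for (j in seq_len(nl)) {
    r <- regress_matrix(Y, G[j, ])
    P[, j] <- r$p
    S[, j] <- r$slope
    n_used[j] <- r$n
  }
  P[!eligible] <- NA_real_

  Pm <- P
  Pm[is.na(Pm)] <- Inf
  best_j <- max.col(-Pm, ties.method = "first")  # loci already in genomic order
  has_best <- is.finite(Pm[cbind(seq_len(np), best_j)])
  n_dropped <- sum(!has_best)
  if (n_dropped) {
    inform(sprintf("%d probeset(s) had no testable locus and were omitted", n_dropped))
  }

  idx <- which(has_best)
  bj <- best_j[idx]
  d <- vapply(seq_along(idx), function(k) {
    g <- G[bj[k], ]
    y <- Y[idx[k], ]
    ok <- !is.na(g)
    g0 <- y[ok & g == 0]; g1 <- y[ok & g > 0]
    if (!length(g0) || !length(g1)) return(NA_real_)
    mean(g0) - mean(g1)
  }, double(1))

  p_best <- P[cbind(idx, bj)]
  res <- tibble(
    probeset_id = rownames(Y)[idx],
    best_locus_id = geno$locus_id[bj],
    n = n_used[bj],
    slope = S[cbind(idx, bj)],
    p_value = p_best,
    neglog10p = -log10(p_best),
    allele_effect_d = d,
    q_value = if (length(p_best)) bh_fdr(p_best) else numeric()
  )
  structure(res, class = c("eqtl_result", class(res)))
}

#' @rdname snpmask-tidiers
#' @method glance eqtl_result
#' @export
glance.eqtl_result <- function(x, ...) {
  tibble(
    n_probesets = nrow(x),
    n_fdr05 = sum(x$q_value <= 0.05),
    median_p = stats::median(x$p_value),
    fraction_positive_d = mean(x$allele_effect_d > 0, na.rm = TRUE)
  )
}

#' Allele-effect direction bias diagnostic
#'
#' Under an unbiased platform, the group of samples homozygous for the
#' reference-type allele should show the higher mean expression at about half
#' of all candidate eQTL. This diagnostic counts candidate eQTL with positive
#' versus negative allele effect `allele_effect_d` and tests the split
#' against 0.5 with an exact two-sided binomial test (two-sided by summing
#' all outcomes at most as probable as the one observed). Exact ties
#' (`d == 0`) are excluded from the trials and tallied.
#'
#' @param results an `eqtl_result` from [eqtl_scan()].
#' @param fdr_max optional: restrict to results with `q_value <= fdr_max`.
#' @return an object of class `bias_summary` (see [glance.bias_summary()])
#'   with fields `n_eqtl`, `n_positive_d`, `n_negative_d`, `n_ties_excluded`,
#'   `fraction_positive` (over non-tied results) and `binomial_p`.
#' @export
direction_bias <- function(results, fdr_max = NULL) {
  if (!is.null(fdr_max)) {
    check_fraction(fdr_max, "fdr_max")
    results <- results[!is.na(results$q_value) & results$q_value <= fdr_max, ]
  }
  d <- results$allele_effect_d
  d <- d[!is.na(d)]
  if (!length(d)) stop_argument("no results left to summarize (empty after filtering)")
  n_pos <- sum(d > 0); n_neg <- sum(d < 0); n_tie <- sum(d == 0)
  if (n_pos + n_neg == 0L) {
    stop_argument("all allele effects are exact ties; direction is undefined")
  }
  bt <- binom.test(n_pos, n_pos + n_neg, p = 0.5)
  structure(list(
    n_eqtl = length(d),
    n_positive_d = n_pos,
    n_negative_d = n_neg,
    n_ties_excluded = n_tie,
    fraction_positive = n_pos / (n_pos + n_neg),
    binomial_p = bt$p.value
  ), class = "bias_summary")
}

#' @export
print.bias_summary <- function(x, ...) {
  cat(sprintf(
    "<bias_summary> %d candidate eQTL: %.1f%% with higher expression in code-0 homozygotes (exact binomial P = %.3g; %d ties excluded)\n",
    x$n_eqtl, 100 * x$fraction_positive, x$binomial_p, x$n_ties_excluded))
  invisible(x)
}

#' Tidiers for masking and eQTL result objects
#'
#' `tidy()` returns per-unit rows (per probeset); `glance()` returns a
#' one-row summary.
#'
#' @param x a `mask_report`, `eqtl_result`, `bias_summary` or
#'   `run_comparison` object.
#' @param ... unused.
#' @return a tibble.
#' @name snpmask-tidiers
NULL

#' @rdname snpmask-tidiers
#' @method glance bias_summary
#' @export
glance.bias_summary <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Compare corrected and uncorrected eQTL runs
#'
#' For every probeset present in both runs, computes the change in
#' statistical strength `delta = neglog10p(corrected) -
#' neglog10p(uncorrected)`; negative delta means the result weakened after
#' correction. Summaries: `fraction_decreased` (share of probesets with
#' `delta < 0`; an exact 0 counts as not decreased) and `pearson_r`, the
#' product-moment correlation between the uncorrected strength and the loss
#' of strength `-delta` (a positive value means the strongest uncorrected
#' results lost the most significance).
#'
#' @param uncorrected,corrected `eqtl_result` tibbles from [eqtl_scan()].
#' @return an object of class `run_comparison`: the per-probeset tibble
#'   (`probeset_id`, `neglog10p_uncorrected`, `neglog10p_corrected`,
#'   `delta`) with summary attributes; see [glance.run_comparison()].
#' @export
compare_runs <- function(uncorrected, corrected) {
  shared <- dplyr::inner_join(
    dplyr::select(as_tibble(uncorrected), "probeset_id",
                  neglog10p_uncorrected = "neglog10p"),
    dplyr::select(as_tibble(corrected), "probeset_id",
                  neglog10p_corrected = "neglog10p"),
    by = "probeset_id"
  )
  if (nrow(shared) < 2L) {
    stop_argument("need at least 2 probesets shared between the two runs")
  }
  shared$delta <- shared$neglog10p_corrected - shared$neglog10p_uncorrected

  x <- shared$neglog10p_uncorrected
  y <- -shared$delta
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_; r_p <- NA_real_
  } else {
    r <- cor(x, y)
    r_p <- if (nrow(shared) >= 3L) cor.test(x, y, method = "pearson")$p.value else NA_real_
  }
  structure(shared,
    class = c("run_comparison", class(shared)),
    n_shared = nrow(shared),
    fraction_decreased = mean(shared$delta < 0),
    pearson_r = r,
    pearson_p = r_p
  )
}

#' @export
print.run_comparison <- function(x, ...) {
  cat(sprintf(
    "<run_comparison> %d shared probesets: %.1f%% decreased in significance; Pearson r(uncorrected strength, loss) = %s\n",
    attr(x, "n_shared"), 100 * attr(x, "fraction_decreased"),
    ifelse(is.na(attr(x, "pearson_r")), "not computable (zero variance)",
           sprintf("%.3f", attr(x, "pearson_r")))))
  NextMethod()
}

#' @rdname snpmask-tidiers
#' @method tidy run_comparison
#' @export
tidy.run_comparison <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname snpmask-tidiers
#' @method glance run_comparison
#' @export
glance.run_comparison <- function(x, ...) {
  tibble(
    n_shared = attr(x, "n_shared"),
    fraction_decreased = attr(x, "fraction_decreased"),
    pearson_r = attr(x, "pearson_r"),
    pearson_p = attr(x, "pearson_p")
  )
}
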