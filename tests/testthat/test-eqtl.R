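test_that("regression matches hand OLS and the pooled two-sample t-test", {
  r <- eqtl_regress(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$slope, 2)           # group means 1.5 and 3.5
  expect_equal(r$se, sqrt(0.5))      # sse = 1 on 2 df, sxx = 1
  tt <- t.test(c(3, 4), c(1, 2), var.equal = TRUE)
  expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)

  # random binary fixtures: OLS p == pooled t-test p to 1e-10
  set.seed(51)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    g <- c(0, 0, 1, 1, rbinom(n - 4, 1, 0.5))  # both groups guaranteed
    y <- rnorm(n, mean = g * rnorm(1))
    r <- eqtl_regress(y, g)
    tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-10)
    lm_fit <- summary(lm(y ~ g))$coefficients
    expect_equal(r$slope, lm_fit["g", "Estimate"], tolerance = 1e-10)
    expect_equal(r$p_value, lm_fit["g", "Pr(>|t|)"], tolerance = 1e-10)
  }

  # additive 0/1/2 coding agrees with lm too
  g3 <- c(0, 1, 2, 0, 1, 2, 1, 0)
  y3 <- rnorm(8, g3)
  r3 <- eqtl_regress(y3, g3)
  lm3 <- summary(lm(y3 ~ g3))$coefficients
  expect_equal(r3$p_value, lm3["g3", "Pr(>|t|)"], tolerance = 1e-10)
})

test_that("regression handles degenerate and non-testable inputs", {
  expect_equal(eqtl_regress(c(5, 5, 5, 5), c(0, 1, 0, 1))[, c("slope", "p_value")],
               tibble::tibble(slope = 0, p_value = 1))
  expect_false(eqtl_regress(rnorm(4), c(1, 1, 1, 1))$testable)
  expect_false(eqtl_regress(rnorm(2), c(0, 1))$testable)
  r <- eqtl_regress(c(1, 2, 3, 4, NA), c(0, 0, 1, 1, NA))
  expect_equal(r$n, 4L)
  # perfect fit: degenerate flag, machine-minimum p
  d <- eqtl_regress(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_true(d$degenerate)
  expect_equal(d$p_value, .Machine$double.xmin)
})

test_that("BH q-values match the brute-force step-up and are permutation-stable", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(1.0), 1.0)
  set.seed(61)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    p[p == 0] <- 0.5
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), bh_fdr(p)[perm])
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
  expect_error(bh_fdr(c(0.5, 0)), class = "snpmask_argument_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "snpmask_argument_error")
})

make_scan_fixture <- function() {
  geno <- tibble::tibble(
    locus_id = c("L1", "L2", "L3"),
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(2e6, 3e6, 2e6),
    S1 = c(0L, 0L, 0L), S2 = c(0L, 1L, 0L), S3 = c(1L, 0L, 1L),
    S4 = c(1L, 1L, 1L), S5 = c(0L, 0L, 1L), S6 = c(1L, 1L, 0L)
  )
  set.seed(71)
  expr <- tibble::tibble(
    probeset_id = c("PSA", "PSB"),
    S1 = c(1.0, 5.0), S2 = c(1.2, 5.1), S3 = c(3.0, 4.9),
    S4 = c(3.1, 5.2), S5 = c(1.1, 5.0), S6 = c(2.9, 5.05)
  )
  list(geno = geno, expr = expr)
}

test_that("scan reports the statistically strongest locus with genomic tie-breaks", {
  fx <- make_scan_fixture()
  res <- eqtl_scan(fx$expr, fx$geno, mode = "genomewide")
  expect_s3_class(res, "eqtl_result")
  # PSA tracks L1 perfectly-ish: best locus must be L1
  expect_equal(res$best_locus_id[res$probeset_id == "PSA"], "L1")
  # best-locus p is the minimum over all loci
  for (ps in res$probeset_id) {
    y <- as.numeric(fx$expr[fx$expr$probeset_id == ps, -1])
    all_p <- vapply(seq_len(nrow(fx$geno)), function(j) {
      eqtl_regress(y, as.numeric(fx$geno[j, -(1:3)]))$p_value
    }, double(1))
    expect_equal(res$p_value[res$probeset_id == ps], min(all_p), tolerance = 1e-12)
  }
  expect_equal(res$neglog10p, -log10(res$p_value))
  expect_equal(res$q_value, bh_fdr(res$p_value))

  # exact tie: two identical loci -> the lower genomic coordinate wins
  geno_tie <- fx$geno
  geno_tie[2, -(1:3)] <- geno_tie[1, -(1:3)]
  geno_tie$chrom <- "chr1"
  res_tie <- eqtl_scan(fx$expr, geno_tie, mode = "genomewide")
  expect_equal(res_tie$best_locus_id[res_tie$probeset_id == "PSA"], "L1")

  # allele-effect direction: PSA has higher expression in carriers of L1
  d <- res$allele_effect_d[res$probeset_id == "PSA"]
  y <- as.numeric(fx$expr[1, -1]); g <- as.numeric(fx$geno[1, -(1:3)])
  expect_equal(d, mean(y[g == 0]) - mean(y[g > 0]))
  expect_true(d < 0)
})

test_that("cis mode includes the one-megabase boundary exactly", {
  fx <- make_scan_fixture()
  tss <- tibble::tibble(probeset_id = c("PSA", "PSB"),
                        tss_chrom = "chr1", tss_pos = c(2e6, 2e6))
  # L2 at chr1:3e6 is exactly 1 Mb from the TSS: eligible
  res <- eqtl_scan(fx$expr, fx$geno, mode = "cis", cis_window_bp = 1e6, tss = tss)
  expect_true(all(res$best_locus_id %in% c("L1", "L2")))
  expect_equal(nrow(res), 2L)  # both probesets have eligible loci

  # shift the locus one base beyond the window: no longer eligible
  geno2 <- fx$geno
  geno2$pos[2] <- 3e6 + 1
  res2 <- eqtl_scan(fx$expr, geno2, mode = "cis", cis_window_bp = 1e6, tss = tss)
  expect_true(all(res2$best_locus_id == "L1"))

  # probesets without an anchor on a genotyped chromosome are omitted
  tss_na <- tss
  tss_na$tss_chrom[2] <- "chrX"
  expect_message(
    res3 <- eqtl_scan(fx$expr, fx$geno, mode = "cis", tss = tss_na),
    regexp = "omitted"
  )
  expect_equal(res3$probeset_id, "PSA")
  expect_error(eqtl_scan(fx$expr, fx$geno, mode = "cis"),
               class = "snpmask_argument_error")
})

test_that("scan validates sample alignment and missing genotypes drop pairwise", {
  fx <- make_scan_fixture()
  expr_bad <- dplyr::rename(fx$expr, X1 = S1, X2 = S2, X3 = S3,
                            X4 = S4, X5 = S5, X6 = S6)
  expect_error(eqtl_scan(expr_bad, fx$geno), class = "snpmask_argument_error")

  geno_na <- fx$geno
  geno_na$S1[1] <- NA
  res <- eqtl_scan(fx$expr, geno_na, mode = "genomewide")
  n_l1 <- res$n[res$best_locus_id == "L1"]
  if (length(n_l1)) expect_true(all(n_l1 == 5L))
})

test_that("direction bias counts, fraction and exact binomial match enumeration", {
  mk <- function(d) {
    structure(tibble::tibble(
      probeset_id = sprintf("PS%03d", seq_along(d)),
      best_locus_id = "L1", n = 10L, slope = 1, p_value = 0.5,
      neglog10p = -log10(0.5), allele_effect_d = d,
      q_value = 0.5
    ), class = c("eqtl_result", "tbl_df", "tbl", "data.frame"))
  }
  b3 <- direction_bias(mk(c(1, 2, 3)))
  expect_equal(b3$binomial_p, 0.25)  # 2 * (1/2)^3
  b50 <- direction_bias(mk(c(rep(1, 50), rep(-1, 50))))
  expect_equal(b50$binomial_p, 1.0)
  b76 <- direction_bias(mk(c(rep(1, 76), rep(-1, 24))))
  expect_lt(b76$binomial_p, 0.001)
  expect_equal(b76$fraction_positive, 0.76)

  # exact ties are excluded and tallied
  bt <- direction_bias(mk(c(1, 1, -1, 0, 0)))
  expect_equal(bt$n_ties_excluded, 2L)
  expect_equal(bt$n_eqtl, 5L)
  expect_equal(bt$n_positive_d + bt$n_negative_d + bt$n_ties_excluded, bt$n_eqtl)

  # enumeration oracle for all n <= 20
  for (n in 1:20) {
    for (k in 0:n) {
      d <- c(rep(1, k), rep(-1, n - k))
      expect_equal(direction_bias(mk(d))$binomial_p,
                   oracle_binom_two_sided(k, n), tolerance = 1e-9)
    }
  }

  # FDR filter
  res <- mk(c(1, -1, 1))
  res$q_value <- c(0.01, 0.2, 0.01)
  bf <- direction_bias(res, fdr_max = 0.05)
  expect_equal(bf$n_eqtl, 2L)
  expect_error(direction_bias(res, fdr_max = 1e-6),
               class = "snpmask_argument_error")
})

test_that("run comparison computes deltas, decrease fraction and correlation", {
  mk <- function(ids, p) {
    structure(tibble::tibble(
      probeset_id = ids, best_locus_id = "L", n = 10L, slope = 0,
      p_value = p, neglog10p = -log10(p), allele_effect_d = 0.1,
      q_value = p
    ), class = c("eqtl_result", "tbl_df", "tbl", "data.frame"))
  }
  # one up, one down
  unc <- mk(c("A", "B"), c(1e-4, 0.5))
  cor_ <- mk(c("A", "B"), c(0.5, 1e-4))
  cmp <- compare_runs(unc, cor_)
  expect_equal(attr(cmp, "fraction_decreased"), 0.5)

  # identical runs: all deltas zero, correlation not computable
  same <- mk(c("A", "B", "C"), c(0.01, 0.1, 0.9))
  cmp0 <- compare_runs(same, same)
  expect_equal(attr(cmp0, "fraction_decreased"), 0)
  expect_true(all(cmp0$delta == 0))
  expect_true(is.na(attr(cmp0, "pearson_r")))

  # corrected smaller p everywhere: nothing decreased
  up <- compare_runs(mk(c("A", "B"), c(0.5, 0.2)), mk(c("A", "B"), c(0.05, 0.01)))
  expect_equal(attr(up, "fraction_decreased"), 0)
  expect_true(all(up$delta > 0))

  # restricted to the shared set; < 2 shared errors
  part <- compare_runs(mk(c("A", "B", "C"), rep(0.5, 3)), mk(c("B", "C", "D"), rep(0.5, 3)))
  expect_equal(sort(part$probeset_id), c("B", "C"))
  expect_error(compare_runs(mk("A", 0.5), mk("A", 0.5)),
               class = "snpmask_argument_error")

  # pearson_r follows the product-moment formula on the strength/loss pair
  set.seed(81)
  pu <- runif(30, 1e-6, 1); pc <- runif(30, 1e-6, 1)
  ids <- sprintf("PS%02d", 1:30)
  cmp2 <- compare_runs(mk(ids, pu), mk(ids, pc))
  expect_equal(attr(cmp2, "pearson_r"),
               cor(-log10(pu), -log10(pc / pu) * -1), tolerance = 1e-12)
})

test_that("glance methods summarize result objects as one-row tibbles", {
  fx <- make_scan_fixture()
  res <- eqtl_scan(fx$expr, fx$geno)
  g <- glance(res)
  expect_equal(g$n_probesets, 2L)
  b <- glance(direction_bias(res))
  expect_equal(nrow(b), 1L)
  cmp <- compare_runs(res, res)
  expect_equal(glance(cmp)$n_shared, 2L)
})
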