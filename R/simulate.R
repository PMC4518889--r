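#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' a backcross expression-QTL study at desk scale: 100 animals, 20 genotyped
#' loci, 1000 probesets of 12 probes (25-mer probes, the usual probeset size
#' on IVT-era arrays), probe-level Gaussian noise of 1 log2 unit, and no true
#' genetic effects or hybridization bias unless switched on.
#'
#' @param n_samples number of samples (animals / donors).
#' @param n_loci number of genotyped loci, laid out evenly along the
#'   synthetic chromosomes.
#' @param n_probesets number of probesets.
#' @param probes_per_probeset member probes per probeset (default 12).
#' @param p_probe_hit fraction of all probes that contain one simulated
#'   variant (uniform-random offset within the probe).
#' @param bias_delta log2 attenuation subtracted from a variant-containing
#'   probe in every sample that carries the variant (genotype code > 0);
#'   must be >= 0. This is the hybridization-interference artifact.
#' @param p_true_eqtl fraction of probesets given a genuine cis effect.
#' @param effect_size true slope (log2 units per coded allele) of genuine
#'   effects; the sign is randomized per probeset.
#' @param noise_sd probe-level Gaussian noise sd (log2 units), > 0.
#' @param design `"backcross"` (codes 0/1, each heterozygous with
#'   probability 0.5) or `"population"` (codes 0/1/2 from Hardy-Weinberg
#'   draws at a per-locus minor allele frequency drawn from `maf_range`).
#' @param maf_range length-2 range for population-design MAFs.
#' @param dosage_bias if `TRUE`, attenuation scales with allele dosage
#'   (`bias_delta * code / max_code`) instead of applying in full to any
#'   carrier. Default `FALSE`.
#' @param n_chrom number of synthetic chromosomes.
#' @param chrom_length optional chromosome length in bp; computed from the
#'   probe layout when `NULL`, and an argument error when too short to hold
#'   the probes.
#' @param seed integer seed; every generator output is a deterministic
#'   function of it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100, n_loci = 20, n_probesets = 1000,
                       probes_per_probeset = 12, p_probe_hit = 0,
                       bias_delta = 0, p_true_eqtl = 0, effect_size = 1,
                       noise_sd = 1, design = c("backcross", "population"),
                       maf_range = c(0.05, 0.5), dosage_bias = FALSE,
                       n_chrom = 5, chrom_length = NULL, seed = 1) {
  design <- match.arg(design)
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples", min = 2L),
    n_loci = check_count(n_loci, "n_loci"),
    n_probesets = check_count(n_probesets, "n_probesets"),
    probes_per_probeset = check_count(probes_per_probeset, "probes_per_probeset"),
    p_probe_hit = check_fraction(p_probe_hit, "p_probe_hit"),
    bias_delta = bias_delta,
    p_true_eqtl = check_fraction(p_true_eqtl, "p_true_eqtl"),
    effect_size = effect_size,
    noise_sd = noise_sd,
    design = design,
    maf_range = maf_range,
    dosage_bias = isTRUE(dosage_bias),
    n_chrom = check_count(n_chrom, "n_chrom"),
    chrom_length = chrom_length,
    seed = check_count(seed, "seed", min = 0L)
  )
  if (!is.numeric(bias_delta) || length(bias_delta) != 1L || bias_delta < 0) {
    stop_argument("`bias_delta` must be a single number >= 0")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop_argument("`noise_sd` must be a single number > 0")
  }
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      any(maf_range < 0) || any(maf_range > 0.5) || maf_range[1] > maf_range[2]) {
    stop_argument("`maf_range` must be an increasing pair within [0, 0.5]")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic geometry shared by the platform and genotype generators:
# 25-bp probes on a 100-bp pitch, probesets stacked along n_chrom chromosomes.
sim_layout <- function(cfg) {
  probe_len <- 25L
  pitch <- 100L
  ps_gap <- 800L
  ps_span <- cfg$probes_per_probeset * pitch
  per_chrom <- ceiling(cfg$n_probesets / cfg$n_chrom)
  needed <- 1000L + per_chrom * (ps_span + ps_gap)
  chrom_length <- cfg$chrom_length %||% (needed + 1000L)
  if (chrom_length < needed) {
    stop_argument(sprintf(
      "chrom_length %d cannot hold %d probesets of %d probes per chromosome (need >= %d)",
      chrom_length, per_chrom, cfg$probes_per_probeset, needed))
  }
  list(probe_len = probe_len, pitch = pitch, ps_gap = ps_gap,
       ps_span = ps_span, per_chrom = per_chrom, chrom_length = chrom_length)
}

#' Simulate an array platform with variant-intersecting probes
#'
#' Lays non-overlapping 25-bp probes along synthetic chromosomes, groups them
#' into probesets, and plants exactly `round(p_probe_hit * n_probes)`
#' single-base variants, one per chosen probe at a uniform-random offset.
#' When `dir` is given, the probe BED and variant VCF are also written so
#' they can be re-read through the package's real readers (the emitted files
#' reproduce the in-memory truth table exactly).
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory for `probes.bed` and `variants.vcf`.
#' @return a list: `annotation` ([annotation_set()]), `variants` (variant
#'   tibble), `truth` (tibble `probe_id`, `hit`, `n_variants`), and `paths`
#'   (named character, empty when `dir` is `NULL`).
#' @export
simulate_platform <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  n_probes <- cfg$n_probesets * cfg$probes_per_probeset

  ps_idx <- seq_len(cfg$n_probesets)
  wid_ps <- max(4L, nchar(as.character(cfg$n_probesets)))
  probeset_id <- sprintf("PS%0*d", wid_ps, ps_idx)
  chrom_of_ps <- sprintf("chr%d", ((ps_idx - 1L) %% cfg$n_chrom) + 1L)
  slot <- (ps_idx - 1L) %/% cfg$n_chrom
  ps_start <- 1000L + slot * (lay$ps_span + lay$ps_gap)

  probe_ps <- rep(ps_idx, each = cfg$probes_per_probeset)
  within <- rep(seq_len(cfg$probes_per_probeset), times = cfg$n_probesets) - 1L
  start0 <- ps_start[probe_ps] + within * lay$pitch
  wid_p <- max(6L, nchar(as.character(n_probes)))
  probes <- tibble(
    probe_id = sprintf("P%0*d", wid_p, seq_len(n_probes)),
    probeset_id = probeset_id[probe_ps],
    chrom = chrom_of_ps[probe_ps],
    start0 = start0,
    end0 = start0 + lay$probe_len,
    strand = "+"
  )
  probesets <- tibble(
    probeset_id = probeset_id,
    gene_symbol = sprintf("Gene%d", ps_idx),
    tss_chrom = chrom_of_ps,
    tss_pos = ps_start + 1L
  )
  annotation <- annotation_set(probes, probesets,
                               sprintf("synthetic_%dx%d", cfg$n_probesets,
                                       cfg$probes_per_probeset))

  n_hit <- round(cfg$p_probe_hit * n_probes)
  with_seed(cfg$seed + 1L, {
    hit_rows <- if (n_hit > 0) sort(sample.int(n_probes, n_hit)) else integer()
    offset <- if (n_hit > 0) sample.int(lay$probe_len, n_hit, replace = TRUE) - 1L else integer()
  })
  variants <- tibble(
    chrom = probes$chrom[hit_rows],
    pos = probes$start0[hit_rows] + offset + 1L,
    ref = "A", alt = "G",
    maf = if (cfg$design == "backcross") 0.5 else 0.25,
    population = "synthetic"
  )[order(probes$chrom[hit_rows], probes$start0[hit_rows] + offset), ]

  truth <- tibble(
    probe_id = probes$probe_id,
    hit = seq_len(n_probes) %in% hit_rows,
    n_variants = as.integer(seq_len(n_probes) %in% hit_rows)
  )

  paths <- character()
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(
      probes_bed = file.path(dir, "probes.bed"),
      variants_vcf = file.path(dir, "variants.vcf")
    )
    write_probe_bed(annotation, paths[["probes_bed"]])
    write_variant_vcf(variants, paths[["variants_vcf"]])
  }
  list(annotation = annotation, variants = variants, truth = truth, paths = paths)
}

#' Simulate genotypes
#'
#' Backcross design: each (sample, locus) cell is independently heterozygous
#' (code 1) with probability 0.5, matching the expectation that each locus in
#' a backcross is half heterozygous, half homozygous for the recurrent
#' parent. Population design: per-locus minor allele frequency drawn
#' uniformly from `maf_range`, codes 0/1/2 as Hardy-Weinberg binomial draws.
#' Loci are spread evenly along the same synthetic chromosomes the platform
#' generator uses, so cis relationships are well defined.
#'
#' @param cfg a [sim_config()].
#' @return a genotype tibble: `locus_id`, `chrom`, `pos`, one column per
#'   sample (`S001`, ...).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- sim_layout(cfg)
  li <- seq_len(cfg$n_loci)
  chrom <- sprintf("chr%d", ((li - 1L) %% cfg$n_chrom) + 1L)
  idx_on_chrom <- (li - 1L) %/% cfg$n_chrom
  n_on_chrom <- ceiling(cfg$n_loci / cfg$n_chrom)
  pos <- as.integer(round((idx_on_chrom + 0.5) / n_on_chrom * lay$chrom_length))
  wid <- max(3L, nchar(as.character(cfg$n_loci)))
  locus_id <- sprintf("L%0*d", wid, li)

  codes <- with_seed(cfg$seed + 2L, {
    if (cfg$design == "backcross") {
      matrix(rbinom(cfg$n_loci * cfg$n_samples, 1L, 0.5),
             nrow = cfg$n_loci, ncol = cfg$n_samples)
    } else {
      maf <- runif(cfg$n_loci, cfg$maf_range[1], cfg$maf_range[2])
      matrix(rbinom(cfg$n_loci * cfg$n_samples, 2L, rep(maf, cfg$n_samples)),
             nrow = cfg$n_loci, ncol = cfg$n_samples)
    }
  })
  colnames(codes) <- sprintf("S%03d", seq_len(cfg$n_samples))
  dplyr::bind_cols(
    tibble(locus_id = locus_id, chrom = chrom, pos = pos),
    as_tibble(codes)
  )
}

# Nearest locus on the probeset's TSS chromosome (ties -> lower position);
# NA when that chromosome carries no locus.
causal_locus_map <- function(probesets, geno) {
  vapply(seq_len(nrow(probesets)), function(i) {
    on_chrom <- which(geno$chrom == probesets$tss_chrom[i])
    if (!length(on_chrom)) return(NA_integer_)
    d <- abs(geno$pos[on_chrom] - probesets$tss_pos[i])
    on_chrom[order(d, geno$pos[on_chrom])[1]]
  }, integer(1))
}

#' Simulate probe-level expression with injectable hybridization bias
#'
#' Each probe value is `mu_s + beta_s * g_i * [s is a true eQTL] -
#' bias_delta * [probe contains a variant] * [g_i > 0] + noise`, where `mu_s ~
#' Normal(8, 1)` once per probeset (a typical log2 intensity), `beta_s` is
#' `effect_size` with random sign, `g_i` is the sample's code at the
#' probeset's cis locus (the locus nearest its TSS), and noise is
#' `Normal(0, noise_sd)` per cell. The bias term is the artifact under
#' study: variant-containing probes hybridize less efficiently in samples
#' that carry the variant allele, which mimics a cis-eQTL even when no true
#' effect exists. With `dosage_bias = TRUE` the attenuation scales with
#' allele dosage instead of applying in full to any carrier.
#'
#' @param cfg a [sim_config()].
#' @param genotypes from [simulate_genotypes()].
#' @param annotation from [simulate_platform()].
#' @param truth hit truth table from [simulate_platform()].
#' @return probe-level tibble: `probe_id` plus one column per sample.
#' @export
simulate_probe_expression <- function(cfg, genotypes, annotation, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(annotation, "annotation_set"))
  samples <- setdiff(names(genotypes), c("locus_id", "chrom", "pos"))
  G <- as.matrix(genotypes[, samples, drop = FALSE])
  max_code <- if (cfg$design == "backcross") 1 else 2

  ps <- annotation$probesets
  np <- nrow(ps)
  causal <- causal_locus_map(ps, genotypes)

  with_seed(cfg$seed + 3L, {
    mu <- rnorm(np, mean = 8, sd = 1)
    n_true <- round(cfg$p_true_eqtl * np)
    true_idx <- if (n_true > 0) sample.int(np, n_true) else integer()
    beta <- numeric(np)
    beta[true_idx] <- cfg$effect_size * sample(c(-1, 1), n_true, replace = TRUE)

    probes <- annotation$probes
    hit <- truth$hit[match(probes$probe_id, truth$probe_id)]
    hit[is.na(hit)] <- FALSE
    psi <- match(probes$probeset_id, ps$probeset_id)

    M <- matrix(0, nrow(probes), length(samples))
    for (k in seq_len(np)) {
      rows <- which(psi == k)
      base <- mu[k]
      g <- if (is.na(causal[k])) rep(0, length(samples)) else G[causal[k], ]
      signal <- base + beta[k] * g
      atten <- if (cfg$dosage_bias) cfg$bias_delta * g / max_code
               else cfg$bias_delta * (g > 0)
      for (r in rows) {
        M[r, ] <- signal - if (hit[r]) atten else 0
      }
    }
    M <- M + matrix(rnorm(length(M), 0, cfg$noise_sd), nrow(M))
    colnames(M) <- samples
    dplyr::bind_cols(tibble(probe_id = probes$probe_id), as_tibble(M))
  })
}

#' Summarize probe-level values into probeset expression
#'
#' The probeset value per sample is the arithmetic mean of its member
#' probes' log2 values (the deliberately simple summarizer used for
#' simulation; full normalization pipelines are out of scope). Probesets
#' absent from the annotation — e.g. dropped by [equalize_annotation()] —
#' are absent from the output, and probes whose probeset is unknown are an
#' integrity error.
#'
#' @param probe_expr probe-level tibble (`probe_id` + sample columns).
#' @param annotation an [annotation_set()]; only its member probes are used.
#' @return expression tibble: `probeset_id` + sample columns.
#' @export
summarize_probesets <- function(probe_expr, annotation) {
  stopifnot(inherits(annotation, "annotation_set"))
  membership <- annotation$probes[, c("probe_id", "probeset_id")]
  joined <- dplyr::inner_join(membership, probe_expr, by = "probe_id")
  if (!nrow(joined)) {
    return(tibble(probeset_id = character()))
  }
  # probe rows absent from the annotation (e.g. masked out) do not contribute
  out <- joined |>
    dplyr::select(-"probe_id") |>
    dplyr::group_by(.data$probeset_id) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean), .groups = "drop") |>
    dplyr::arrange(.data$probeset_id)
  out
}

#' Run the full bias-injection experiment
#'
#' End-to-end pipeline on synthetic data: simulate a platform, genotypes and
#' probe-level expression under `cfg`; summarize and scan the uncorrected
#' annotation; intersect probes with the simulated variants (optionally
#' writing and re-reading the BED/VCF through the real readers), mask the hit
#' probes, re-summarize and re-scan; then compute the direction-bias
#' diagnostic for both runs and the corrected-versus-uncorrected comparison.
#'
#' @param cfg a [sim_config()].
#' @param via_files if `TRUE` (default) the simulated BED/VCF are written to
#'   a temporary directory and re-read with [read_probe_bed()] /
#'   [read_vcf_variants()], exercising the full file pipeline.
#' @return a list of class `bias_experiment`: `config`, `mask_report`,
#'   `uncorrected` / `corrected` (`eqtl_result`s), `bias_uncorrected` /
#'   `bias_corrected` (`bias_summary`s, `NULL` when a run is empty) and
#'   `comparison` (`run_comparison`, `NULL` when fewer than 2 shared
#'   probesets).
#' @export
run_bias_experiment <- function(cfg, via_files = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  dir <- if (via_files) file.path(tempdir(), sprintf("snpmask_sim_%d", cfg$seed)) else NULL
  plat <- simulate_platform(cfg, dir = dir)
  geno <- simulate_genotypes(cfg)
  pexpr <- simulate_probe_expression(cfg, geno, plat$annotation, plat$truth)

  if (via_files) {
    probes <- read_probe_bed(plat$paths[["probes_bed"]])
    variants <- read_vcf_variants(plat$paths[["variants_vcf"]], maf_min = 0.05,
                                  population = "synthetic")
  } else {
    probes <- plat$annotation$probes
    variants <- plat$variants
  }
  hits <- probes_hit(probes, build_variant_index(variants))
  eq <- equalize_annotation(plat$annotation, hits)

  expr_unc <- summarize_probesets(pexpr, plat$annotation)
  scan_unc <- eqtl_scan(expr_unc, geno, mode = "genomewide")
  scan_cor <- NULL
  if (nrow(eq$annotation$probes)) {
    expr_cor <- summarize_probesets(pexpr, eq$annotation)
    scan_cor <- eqtl_scan(expr_cor, geno, mode = "genomewide")
  }

  safe_bias <- function(res) {
    if (is.null(res) || !nrow(res)) return(NULL)
    direction_bias(res)
  }
  comparison <- if (!is.null(scan_cor) && nrow(scan_cor) &&
                    length(intersect(scan_unc$probeset_id, scan_cor$probeset_id)) >= 2) {
    compare_runs(scan_unc, scan_cor)
  } else {
    NULL
  }

  structure(list(
    config = cfg,
    mask_report = eq$report,
    uncorrected = scan_unc,
    corrected = scan_cor,
    bias_uncorrected = safe_bias(scan_unc),
    bias_corrected = safe_bias(scan_cor),
    comparison = comparison
  ), class = "bias_experiment")
}

#' @export
print.bias_experiment <- function(x, ...) {
  cat("<bias_experiment>\n")
  t <- attr(x$mask_report, "totals")
  cat(sprintf("  masking: %d / %d probes removed, %d / %d probesets dropped\n",
              t$probes_removed, t$probes_total, t$probesets_dropped, t$probesets_total))
  if (!is.null(x$bias_uncorrected)) {
    cat(sprintf("  uncorrected direction fraction: %.3f (binomial P = %.3g)\n",
                x$bias_uncorrected$fraction_positive, x$bias_uncorrected$binomial_p))
  }
  if (!is.null(x$bias_corrected)) {
    cat(sprintf("  corrected   direction fraction: %.3f (binomial P = %.3g)\n",
                x$bias_corrected$fraction_positive, x$bias_corrected$binomial_p))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  %.1f%% of shared probesets decreased in significance after masking\n",
                100 * attr(x$comparison, "fraction_decreased")))
  }
  invisible(x)
}
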