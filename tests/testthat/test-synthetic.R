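small_cfg <- function(...) {
  sim_config(n_samples = 30, n_loci = 6, n_probesets = 40,
             probes_per_probeset = 4, seed = 7, ...)
}

test_that("generated platforms are deterministic and honor the hit fraction", {
  cfg <- small_cfg(p_probe_hit = 0.25)
  a <- simulate_platform(cfg)
  b <- simulate_platform(cfg)
  expect_equal(a$variants, b$variants)
  expect_equal(a$truth, b$truth)
  expect_annotation_equal(a$annotation, b$annotation)

  n_probes <- nrow(a$annotation$probes)
  expect_equal(sum(a$truth$hit), round(0.25 * n_probes))
  expect_equal(nrow(a$variants), round(0.25 * n_probes))

  # probes are non-overlapping 25-mers
  p <- dplyr::arrange(a$annotation$probes, chrom, start0)
  expect_true(all(p$end0 - p$start0 == 25L))
  same_chrom <- p$chrom[-1] == p$chrom[-nrow(p)]
  expect_true(all(p$start0[-1][same_chrom] >= p$end0[-nrow(p)][same_chrom]))

  # byte-identical files on re-simulation
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_platform(cfg, dir = d1); simulate_platform(cfg, dir = d2)
  for (f in c("probes.bed", "variants.vcf")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("emitted VCF/BED re-read through the real readers reproduce the truth table", {
  cfg <- small_cfg(p_probe_hit = 0.3)
  dir <- withr::local_tempdir()
  plat <- simulate_platform(cfg, dir = dir)
  probes <- read_probe_bed(plat$paths[["probes_bed"]])
  variants <- read_vcf_variants(plat$paths[["variants_vcf"]], maf_min = 0.05)
  hits <- probes_hit(probes, build_variant_index(variants))
  truth_hits <- plat$truth[plat$truth$hit, c("probe_id", "n_variants")]
  expect_equal(as.data.frame(hits),
               as.data.frame(dplyr::arrange(truth_hits, probe_id)))
})

test_that("hit-fraction extremes drive masking to identity or annihilation", {
  none <- simulate_platform(small_cfg(p_probe_hit = 0))
  expect_equal(nrow(none$variants), 0L)
  expect_equal(nrow(probes_hit(none$annotation$probes,
                               build_variant_index(none$variants))), 0L)

  all_hit <- simulate_platform(small_cfg(p_probe_hit = 1))
  hits <- probes_hit(all_hit$annotation$probes,
                     build_variant_index(all_hit$variants))
  eq <- equalize_annotation(all_hit$annotation, hits)
  expect_equal(nrow(eq$annotation$probesets), 0L)
  expect_equal(attr(eq$report, "totals")$probesets_dropped, 40L)
})

test_that("geometry that cannot hold the probes is rejected", {
  cfg <- small_cfg()
  cfg$chrom_length <- 500L
  expect_error(simulate_platform(cfg), class = "snpmask_argument_error")
})

test_that("backcross genotypes are iid Bernoulli(0.5) and reproducible", {
  cfg <- sim_config(n_samples = 1000, n_loci = 1, n_probesets = 1, seed = 3)
  g <- simulate_genotypes(cfg)
  codes <- as.numeric(g[1, -(1:3)])
  expect_true(all(codes %in% c(0, 1)))
  # within 3 binomial sd of 0.5
  expect_lt(abs(mean(codes) - 0.5), 3 * sqrt(0.25 / 1000))
  expect_equal(simulate_genotypes(cfg), g)
})

test_that("population genotypes follow Hardy-Weinberg at the drawn MAF", {
  cfg <- sim_config(n_samples = 3000, n_loci = 2, n_probesets = 1,
                    design = "population", maf_range = c(0.5, 0.5), seed = 5)
  g <- simulate_genotypes(cfg)
  codes <- as.numeric(as.matrix(g[, -(1:3)]))
  freq <- table(factor(codes, levels = 0:2)) / length(codes)
  expect_equal(unname(as.numeric(freq)), c(0.25, 0.5, 0.25), tolerance = 0.05)
})

test_that("probeset summary is the member mean and tracks the annotation", {
  probes <- tibble::tibble(
    probe_id = c("P1", "P2", "P3", "P4"),
    probeset_id = c("PS1", "PS1", "PS1", "PS2"),
    chrom = "chr1", start0 = c(0L, 100L, 200L, 300L),
    end0 = c(25L, 125L, 225L, 325L), strand = "+"
  )
  aset <- annotation_set(probes)
  pexpr <- tibble::tibble(probe_id = c("P1", "P2", "P3", "P4"),
                          S1 = c(1, 2, 3, 7), S2 = c(4, 5, 6, 8))
  expr <- summarize_probesets(pexpr, aset)
  expect_equal(expr$S1, c(2, 7))   # mean{1,2,3}; single-probe probeset passthrough
  expect_equal(expr$S2, c(5, 8))

  # after masking, the summary uses only the survivors
  eq <- equalize_annotation(aset, tibble::tibble(probe_id = c("P1", "P2"),
                                                 n_variants = 1L))
  expr2 <- summarize_probesets(pexpr, eq$annotation)
  expect_equal(expr2$S1[expr2$probeset_id == "PS1"], 3)
  # probesets dropped from the annotation vanish from the summary
  eq_all <- equalize_annotation(aset, tibble::tibble(probe_id = c("P1", "P2", "P3"),
                                                     n_variants = 1L))
  expect_equal(summarize_probesets(pexpr, eq_all$annotation)$probeset_id, "PS2")
})

test_that("probe expression encodes bias against carriers of hit probes", {
  cfg <- sim_config(n_samples = 400, n_loci = 5, n_probesets = 10,
                    probes_per_probeset = 4, p_probe_hit = 0.5,
                    bias_delta = 2, noise_sd = 0.1, seed = 9)
  plat <- simulate_platform(cfg)
  geno <- simulate_genotypes(cfg)
  pexpr <- simulate_probe_expression(cfg, geno, plat$annotation, plat$truth)
  expect_equal(simulate_probe_expression(cfg, geno, plat$annotation, plat$truth),
               pexpr)

  # for a hit probe, carrier samples at the cis locus sit ~bias_delta lower
  samples <- setdiff(names(geno), c("locus_id", "chrom", "pos"))
  probes <- plat$annotation$probes
  hit_probe <- plat$truth$probe_id[plat$truth$hit][1]
  ps <- probes$probeset_id[probes$probe_id == hit_probe]
  tssr <- plat$annotation$probesets[plat$annotation$probesets$probeset_id == ps, ]
  on_chrom <- geno[geno$chrom == tssr$tss_chrom, ]
  cis <- on_chrom[which.min(abs(on_chrom$pos - tssr$tss_pos)), ]
  g <- as.numeric(cis[, samples])
  y <- as.numeric(pexpr[pexpr$probe_id == hit_probe, samples])
  gap <- mean(y[g == 0]) - mean(y[g > 0])
  expect_equal(gap, 2, tolerance = 0.15)

  # an unhit probe of the same probeset shows no such gap
  sibling <- probes$probe_id[probes$probeset_id == ps &
                               !probes$probe_id %in% plat$truth$probe_id[plat$truth$hit]][1]
  y2 <- as.numeric(pexpr[pexpr$probe_id == sibling, samples])
  expect_lt(abs(mean(y2[g == 0]) - mean(y2[g > 0])), 0.15)
})

test_that("true cis effects are recovered without bias on the slope", {
  cfg <- sim_config(n_samples = 100, n_loci = 10, n_probesets = 200,
                    probes_per_probeset = 12, p_true_eqtl = 1,
                    effect_size = 1, bias_delta = 0, noise_sd = 1, seed = 13)
  plat <- simulate_platform(cfg)
  geno <- simulate_genotypes(cfg)
  pexpr <- simulate_probe_expression(cfg, geno, plat$annotation, plat$truth)
  expr <- summarize_probesets(pexpr, plat$annotation)
  res <- eqtl_scan(expr, geno, mode = "genomewide")
  expect_equal(nrow(res), 200L)
  # signs were randomized: compare |slope| at the best locus to |beta| = 1
  expect_lt(abs(mean(abs(res$slope)) - 1), 0.1)
})

test_that("config validation and key=value round-trip work", {
  expect_error(sim_config(p_probe_hit = 1.2), class = "snpmask_argument_error")
  expect_error(sim_config(noise_sd = 0), class = "snpmask_argument_error")
  expect_error(sim_config(n_samples = 1), class = "snpmask_argument_error")
  expect_error(sim_config(maf_range = c(0.5, 0.1)), class = "snpmask_argument_error")

  cfg <- sim_config(n_samples = 12, n_loci = 3, n_probesets = 5,
                    p_probe_hit = 0.5, bias_delta = 1.5, design = "population",
                    maf_range = c(0.1, 0.4), seed = 99)
  path <- tempfile(fileext = ".txt")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back)[names(unclass(cfg))], unclass(cfg))

  writeLines("nonsense_key = 3", path)
  expect_error(read_sim_config(path), class = "snpmask_argument_error")
})
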