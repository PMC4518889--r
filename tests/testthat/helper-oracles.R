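# Independent oracles, deliberately written against the definitions rather
# than via the package's code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All-pairs interval intersection: for every probe, count variants sharing
# >= 1 base on the same chromosome (both sides 0-based half-open).
oracle_hits <- function(probes, variants) {
  if (!all(c("start0", "end0") %in% names(variants))) {
    variants$start0 <- variants$pos - 1L
    variants$end0 <- variants$pos - 1L + nchar(variants$ref)
  }
  counts <- integer(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    counts[i] <- sum(
      variants$chrom == probes$chrom[i] &
        variants$start0 < probes$end0[i] &
        variants$end0 > probes$start0[i]
    )
  }
  tibble::tibble(probe_id = probes$probe_id[counts > 0],
                 n_variants = counts[counts > 0]) |>
    dplyr::arrange(probe_id)
}

# Benjamini-Hochberg step-up from the definition:
# q(rank j) = min over k >= j of m * p(k) / k, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- numeric(m)
  for (j in seq_len(m)) {
    q_sorted[j] <- min(1, min(m * ps[j:m] / (j:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact two-sided binomial test at p = 0.5 by enumeration: sum the
# probabilities of all outcomes no more likely than the observed one.
oracle_binom_two_sided <- function(k, n) {
  probs <- dbinom(0:n, n, 0.5)
  sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
}

# Random valid annotation: n_ps probesets with 1..max_probes probes each,
# 25-bp probes on a few chromosomes. Ids are zero-padded so lexicographic
# and construction order agree.
rand_annotation <- function(n_ps = 8, max_probes = 6, n_chrom = 3, seed = 1) {
  set.seed(seed)
  sizes <- sample.int(max_probes, n_ps, replace = TRUE)
  ps_id <- sprintf("PS%03d", seq_len(n_ps))
  probe_rows <- list()
  k <- 0L
  for (i in seq_len(n_ps)) {
    for (j in seq_len(sizes[i])) {
      k <- k + 1L
      start0 <- (k - 1L) * 60L + sample.int(20L, 1L)
      probe_rows[[k]] <- tibble::tibble(
        probe_id = sprintf("P%04d", k),
        probeset_id = ps_id[i],
        chrom = sprintf("chr%d", ((i - 1L) %% n_chrom) + 1L),
        start0 = start0, end0 = start0 + 25L,
        strand = sample(c("+", "-", "*"), 1L)
      )
    }
  }
  probes <- dplyr::bind_rows(probe_rows)
  probesets <- tibble::tibble(
    probeset_id = ps_id,
    gene_symbol = ifelse(runif(n_ps) < 0.5, sprintf("G%d", seq_len(n_ps)), NA_character_),
    tss_chrom = sprintf("chr%d", ((seq_len(n_ps) - 1L) %% n_chrom) + 1L),
    tss_pos = sample.int(5000L, n_ps)
  )
  # randomly blank some TSS anchors (both fields together)
  drop <- runif(n_ps) < 0.3
  probesets$tss_chrom[drop] <- NA_character_
  probesets$tss_pos[drop] <- NA_integer_
  annotation_set(probes, probesets, sprintf("rand%d", seed))
}

# Random variant footprints (SNPs and short indels) on the same chromosomes.
rand_variants <- function(n = 50, n_chrom = 3, span = 3000L, seed = 1) {
  set.seed(seed)
  ref_len <- sample(c(1L, 1L, 1L, 2L, 3L), n, replace = TRUE)
  tibble::tibble(
    chrom = sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE)),
    pos = sample.int(span, n, replace = TRUE),
    ref = strrep("A", ref_len),
    alt = "G",
    maf = round(runif(n, 0.05, 0.5), 3),
    population = "sim"
  )
}

# Write a VCF text fixture from explicit record lines.
write_vcf_fixture <- function(records, path = tempfile(fileext = ".vcf"),
                              samples = character()) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
            if (length(samples)) c("FORMAT", samples)), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

# Field-for-field annotation equality with canonical ordering.
expect_annotation_equal <- function(a, b) {
  canon <- function(x) {
    list(
      platform_name = x$platform_name,
      probes = dplyr::arrange(x$probes, probeset_id, probe_id),
      probesets = dplyr::arrange(x$probesets, probeset_id)
    )
  }
  ca <- canon(a); cb <- canon(b)
  expect_equal(ca$platform_name, cb$platform_name)
  expect_equal(as.data.frame(ca$probes), as.data.frame(cb$probes))
  expect_equal(as.data.frame(ca$probesets), as.data.frame(cb$probesets))
}
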