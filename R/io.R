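#' Read and write genotype / expression matrices as TSV
#'
#' Genotype TSV: one row per locus with columns `locus_id`, `chrom`, `pos`,
#' then one column per sample holding integer codes (`NA` = missing call).
#' Expression TSV: one row per probeset with `probeset_id` then one numeric
#' column per sample (log2 scale). Column order is preserved and
#' deterministic.
#'
#' @param path file path.
#' @param x the tibble to write.
#' @return a tibble (readers) or `path` invisibly (writers).
#' @name matrix-io
NULL

#' @rdname matrix-io
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("genotype file not found: %s", path))
  g <- readr::read_tsv(path, col_types = readr::cols(
    locus_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), .default = readr::col_integer()
  ), na = "NA", progress = FALSE)
  need <- c("locus_id", "chrom", "pos")
  if (!all(need %in% names(g))) {
    stop_parse(sprintf("%s: genotype TSV needs columns locus_id, chrom, pos", path))
  }
  prob <- readr::problems(g)
  if (nrow(prob)) {
    stop_parse(sprintf("%s line %d: %s", path, prob$row[1] + 1L, prob$expected[1]))
  }
  g
}

#' @rdname matrix-io
#' @export
write_genotype_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname matrix-io
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("expression file not found: %s", path))
  e <- readr::read_tsv(path, col_types = readr::cols(
    probeset_id = readr::col_character(), .default = readr::col_double()
  ), na = "NA", progress = FALSE)
  if (!"probeset_id" %in% names(e)) {
    stop_parse(sprintf("%s: expression TSV needs a probeset_id column", path))
  }
  prob <- readr::problems(e)
  if (nrow(prob)) {
    stop_parse(sprintf("%s line %d: %s", path, prob$row[1] + 1L, prob$expected[1]))
  }
  e
}

#' @rdname matrix-io
#' @export
write_expression_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write eQTL scan results as TSV
#'
#' One row per probeset mirroring the `eqtl_result` columns, in a fixed
#' column order.
#'
#' @param results an `eqtl_result` from [eqtl_scan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eqtl_results <- function(results, path) {
  cols <- c("probeset_id", "best_locus_id", "n", "slope", "p_value",
            "neglog10p", "allele_effect_d", "q_value")
  readr::write_tsv(as_tibble(results)[, cols], path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Write variants as a minimal VCF
#'
#' Emits a VCF 4.2 text file carrying CHROM/POS/REF/ALT with `PASS` filter
#' and the folded allele frequency in `INFO:AF` (omitted when unknown). Used
#' by the simulator so generated variants flow through the same reader as
#' real data.
#'
#' @param variants variant tibble (`chrom`, `pos`, `ref`, `alt`, `maf`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  v <- dplyr::arrange(as_tibble(variants), .data$chrom, .data$pos, .data$ref, .data$alt)
  info <- ifelse(is.na(v$maf), ".", sprintf("AF=%g", v$maf))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", v$chrom, v$pos, v$ref, v$alt, info)
  ), path)
  invisible(path)
}
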