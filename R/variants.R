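#' Read genome variants from a VCF file
#'
#' Reads a VCF 4.x text file (plain or gzip-compressed) into a variant table,
#' keeping records whose minor allele frequency (MAF) passes an inclusive
#' threshold. Only the CHROM, POS, REF, ALT, FILTER, INFO:AF and GT columns
#' are interpreted; everything else is ignored.
#'
#' MAF is resolved in priority order: the `AF` INFO tag (summed over ALT
#' alleles at multi-allelic sites, then folded to the minor allele as
#' `min(AF, 1 - AF)`); failing that, allele counting over the sample GT
#' columns with missing calls excluded; failing both, the record is skipped
#' when `maf_min > 0` and counted in the `skipped_no_maf` tally (when
#' `maf_min == 0` it is kept with `maf = NA`).
#'
#' Multi-allelic records are kept as a single row (any alternate allele makes
#' the site untrusted for probe hybridization); ALT alleles are stored
#' comma-joined in the `alt` column.
#'
#' @param path VCF file path (`.vcf` or `.vcf.gz`).
#' @param maf_min inclusive minor-allele-frequency threshold in \[0, 1\].
#'   The conventional population filter is 0.05.
#' @param population free-text label of the source population or strain,
#'   recorded per variant (e.g. `"SPRET"`, `"EUR"`).
#' @param pass_only if `TRUE` (default) only records whose FILTER column is
#'   `PASS` or `.` are kept; set `FALSE` to accept all records.
#' @param snv_only if `TRUE`, drop records whose REF or any ALT allele is
#'   longer than one base, restricting the footprint set to single-nucleotide
#'   variants. Default `FALSE`: indels are accepted and span their full REF
#'   length.
#' @param chrom_style chromosome-name normalization passed to
#'   [normalize_chrom()].
#' @return a tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`
#'   (comma-joined ALT alleles), `maf` (folded, `NA` when unknown) and
#'   `population`. The attribute `"tally"` records counts of records read,
#'   kept, and skipped by reason (`filtered`, `below_maf`, `no_maf`,
#'   `non_snv`).
#' @export
read_vcf_variants <- function(path, maf_min = 0.05, population = NA_character_,
                              pass_only = TRUE, snv_only = FALSE,
                              chrom_style = "asis") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_input(sprintf("VCF file not found: %s", path))
  }
  check_fraction(maf_min, "maf_min")

  lines <- readr::read_lines(path)
  is_header <- startsWith(lines, "#")
  rec_lines <- which(!is_header & nzchar(lines))
  tally <- c(records = length(rec_lines), kept = 0L, filtered = 0L,
             below_maf = 0L, no_maf = 0L, non_snv = 0L)

  if (!length(rec_lines)) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), maf = double(), population = character())
    attr(out, "tally") <- tally
    return(out)
  }

  fields <- strsplit(lines[rec_lines], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    bad <- rec_lines[which(nf < 8L)[1]]
    stop_parse(sprintf("%s line %d: expected >= 8 tab-separated columns, found %d",
                       path, bad, nf[which(nf < 8L)[1]]))
  }

  col <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- col(1)
  pos <- suppressWarnings(as.integer(col(2)))
  ref <- col(4)
  alt <- col(5)
  filt <- col(7)
  info <- col(8)

  bad <- which(is.na(pos) | pos < 1L | !nzchar(ref) | ref == "." |
                 !nzchar(alt) | alt == ".")
  if (length(bad)) {
    stop_parse(sprintf("%s line %d: malformed record (POS/REF/ALT)",
                       path, rec_lines[bad[1]]))
  }

  keep <- rep(TRUE, length(chrom))
  if (pass_only) {
    ok_filter <- filt == "PASS" | filt == "."
    tally["filtered"] <- sum(!ok_filter)
    keep <- keep & ok_filter
  }
  if (snv_only) {
    is_snv <- nchar(ref) == 1L &
      vapply(strsplit(alt, ",", fixed = TRUE),
             function(a) all(nchar(a) == 1L), logical(1))
    tally["non_snv"] <- sum(keep & !is_snv)
    keep <- keep & is_snv
  }

  af <- vcf_info_af(info)
  need_gt <- is.na(af) & keep
  if (any(need_gt) && length(fields[[1]]) >= 10L) {
    af[need_gt] <- vapply(fields[which(need_gt)], vcf_gt_altfreq, double(1))
  }
  maf <- pmin(af, 1 - af)

  no_maf <- keep & is.na(maf)
  if (maf_min > 0) {
    tally["no_maf"] <- sum(no_maf)
    below <- keep & !is.na(maf) & maf < maf_min
    tally["below_maf"] <- sum(below)
    keep <- keep & !no_maf & !below
  }
  tally["kept"] <- sum(keep)

  out <- tibble(
    chrom = normalize_chrom(chrom[keep], chrom_style),
    pos = pos[keep],
    ref = ref[keep],
    alt = alt[keep],
    maf = maf[keep],
    population = rep(as.character(population), sum(keep))
  )
  attr(out, "tally") <- tally
  out
}

# AF INFO tag, summed over comma-separated per-ALT values; NA when absent.
vcf_info_af <- function(info) {
  vapply(seq_along(info), function(i) {
    hit <- regmatches(info[i], regexpr("(?:^|;)AF=([^;]+)", info[i]))
    if (!length(hit)) return(NA_real_)
    vals <- suppressWarnings(as.numeric(strsplit(sub("^;?AF=", "", hit), ",")[[1]]))
    if (anyNA(vals)) NA_real_ else sum(vals)
  }, double(1))
}

# ALT-allele frequency from GT sample columns of one record (fields vector);
# missing calls ('.') excluded from the denominator.
vcf_gt_altfreq <- function(f) {
  if (length(f) < 10L) return(NA_real_)
  fmt <- strsplit(f[[9]], ":", fixed = TRUE)[[1]]
  gi <- match("GT", fmt)
  if (is.na(gi)) return(NA_real_)
  gts <- vapply(f[10:length(f)], function(s) {
    strsplit(s, ":", fixed = TRUE)[[1]][gi]
  }, character(1))
  alleles <- unlist(strsplit(gts, "[/|]"))
  alleles <- alleles[alleles != "." & nzchar(alleles)]
  if (!length(alleles)) return(NA_real_)
  mean(alleles != "0")
}

#' Genomic footprints of variants
#'
#' Converts 1-based VCF coordinates to 0-based half-open intervals: a variant
#' at POS with REF of length L occupies `[POS - 1, POS - 1 + L)`. SNPs
#' therefore cover exactly one base, deletions span the full REF length, and
#' insertions anchor on their single REF base.
#'
#' @param variants a variant tibble as returned by [read_vcf_variants()].
#' @return the input with `start0` and `end0` columns added.
#' @export
variant_intervals <- function(variants) {
  stopifnot(all(c("chrom", "pos", "ref") %in% names(variants)))
  if (any(variants$pos < 1L)) stop_argument("variant pos must be >= 1")
  if (any(!nzchar(variants$ref))) stop_argument("variant ref must be non-empty")
  dplyr::mutate(variants,
    start0 = .data$pos - 1L,
    end0 = .data$pos - 1L + nchar(.data$ref)
  )
}

#' Merge several variant sources into one set
#'
#' Takes the union of variant tables (e.g. one per strain or population).
#' Records identical in (`chrom`, `pos`, `ref`, `alt`) are emitted once,
#' keeping the first `population` tag seen; the same position with a
#' different allele tuple is kept as a distinct variant.
#'
#' @param sources a list of variant tibbles, or a single tibble.
#' @return one deduplicated variant tibble.
#' @export
merge_variant_sources <- function(sources) {
  if (is.data.frame(sources)) sources <- list(sources)
  if (!is.list(sources) || !length(sources)) {
    stop_argument("`sources` must be a non-empty list of variant tables")
  }
  dplyr::distinct(dplyr::bind_rows(sources),
                  .data$chrom, .data$pos, .data$ref, .data$alt,
                  .keep_all = TRUE)
}
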