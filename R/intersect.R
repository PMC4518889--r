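#' Build a queryable index of variant footprints
#'
#' Converts a variant table into per-chromosome interval ranges ready for
#' overlap queries. Query results are independent of the input order.
#'
#' @param variants variant tibble ([read_vcf_variants()]); footprints are
#'   derived with [variant_intervals()] if `start0`/`end0` are absent.
#' @return an object of class `variant_index`.
#' @export
build_variant_index <- function(variants) {
  if (!all(c("start0", "end0") %in% names(variants))) {
    variants <- variant_intervals(variants)
  }
  v <- dplyr::arrange(as_tibble(variants), .data$chrom, .data$start0, .data$end0)
  ranges <- lapply(split(v, v$chrom), function(d) {
    IRanges::IRanges(start = d$start0 + 1L, end = d$end0)  # 1-based closed internally
  })
  structure(list(variants = v, ranges = ranges, n = nrow(v)),
            class = "variant_index")
}

#' @export
print.variant_index <- function(x, ...) {
  cat(sprintf("<variant_index> %d variant footprints on %d chromosome(s)\n",
              x$n, length(x$ranges)))
  invisible(x)
}

#' Probes intersecting variant footprints
#'
#' A probe is hit when its interval shares at least one base with at least
#' one variant footprint on the same chromosome; both sides are 0-based
#' half-open, so a footprint starting exactly at a probe's `end0` does not
#' touch it. Overlap is strand-agnostic: the criterion is purely positional.
#'
#' @param probes probe tibble ([read_probe_bed()]) or [annotation_set()].
#' @param index a [build_variant_index()] object, or a variant tibble (an
#'   index is built on the fly).
#' @return the hit table: a tibble with `probe_id` and `n_variants`
#'   (count of intersecting footprints, always >= 1; absent probes have zero
#'   hits).
#' @export
probes_hit <- function(probes, index) {
  if (inherits(probes, "annotation_set")) probes <- probes$probes
  if (!inherits(index, "variant_index")) index <- build_variant_index(index)
  if (!nrow(probes) || index$n == 0L) {
    return(tibble(probe_id = character(), n_variants = integer()))
  }
  warn_disjoint_chroms(probes$chrom, index$variants$chrom,
                       "probe BED", "variant set")
  hits <- lapply(split(probes, probes$chrom), function(d) {
    r <- index$ranges[[d$chrom[1]]]
    if (is.null(r)) return(NULL)
    q <- IRanges::IRanges(start = d$start0 + 1L, end = d$end0)
    n <- IRanges::countOverlaps(q, r)
    tibble(probe_id = d$probe_id[n > 0L], n_variants = as.integer(n[n > 0L]))
  })
  out <- dplyr::bind_rows(hits)
  if (!nrow(out)) {
    return(tibble(probe_id = character(), n_variants = integer()))
  }
  dplyr::arrange(out, .data$probe_id)
}

#' Write the hit list as a BED audit trail
#'
#' Emits one 4-column BED line per hit probe (interval plus probe id), sorted
#' by coordinate, so the masking decision can be inspected with standard
#' genome-arithmetic tools.
#'
#' @param probes probe tibble or [annotation_set()] supplying coordinates.
#' @param hits hit table from [probes_hit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(probes, hits, path) {
  if (inherits(probes, "annotation_set")) probes <- probes$probes
  d <- dplyr::semi_join(probes, hits, by = "probe_id")
  d <- dplyr::arrange(d, .data$chrom, .data$start0, .data$probe_id)
  writeLines(sprintf("%s\t%d\t%d\t%s", d$chrom, d$start0, d$end0, d$probe_id), path)
  invisible(path)
}
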