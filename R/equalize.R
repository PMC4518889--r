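#' Remove variant-hit probes from a platform annotation
#'
#' The core masking step: every probe named in the hit table is removed from
#' its probeset; a probeset whose every member probe is removed is itself
#' dropped from the annotation. Surviving probesets keep their surviving
#' members in original order. A probe is removed for any overlap count of at
#' least one — the count is reported but never thresholded.
#'
#' @param aset an [annotation_set()].
#' @param hits hit table from [probes_hit()]; probe ids not present in
#'   `aset` produce a warning and are ignored, so one hit list can serve
#'   annotation subsets.
#' @param min_probes minimum number of surviving probes a probeset needs to
#'   be kept (default 1: only fully-masked probesets are dropped; the
#'   conventional policy keeps even very small survivors).
#' @return a list of class `equalize_result` with elements `annotation`
#'   (the masked [annotation_set()]) and `report` (a `mask_report`, see
#'   [write_mask_report()]).
#' @export
equalize_annotation <- function(aset, hits, min_probes = 1L) {
  stopifnot(inherits(aset, "annotation_set"))
  min_probes <- check_count(min_probes, "min_probes")
  hit_ids <- unique(as.character(hits$probe_id))
  unknown <- setdiff(hit_ids, aset$probes$probe_id)
  if (length(unknown)) {
    warn(sprintf("%d hit probe id(s) not present in the annotation were ignored (e.g. %s)",
                 length(unknown), unknown[1]))
    hit_ids <- setdiff(hit_ids, unknown)
  }

  probes <- aset$probes
  removed <- probes$probe_id %in% hit_ids

  per_ps <- probes |>
    dplyr::mutate(.removed = removed) |>
    dplyr::group_by(.data$probeset_id) |>
    dplyr::summarise(n_probes_before = dplyr::n(),
                     n_probes_removed = sum(.data$.removed),
                     .groups = "drop") |>
    dplyr::mutate(n_probes_after = .data$n_probes_before - .data$n_probes_removed) |>
    dplyr::arrange(.data$probeset_id)

  kept_ps <- per_ps$probeset_id[per_ps$n_probes_after >= min_probes]
  new_probes <- probes[!removed & probes$probeset_id %in% kept_ps, ]
  new_probesets <- aset$probesets[aset$probesets$probeset_id %in% kept_ps, ]

  report <- structure(per_ps, class = c("mask_report", class(per_ps)))
  attr(report, "totals") <- list(
    probes_total = nrow(probes),
    probes_removed = sum(per_ps$n_probes_removed) +
      sum(per_ps$n_probes_after[!per_ps$probeset_id %in% kept_ps]),
    probesets_total = nrow(per_ps),
    probesets_dropped = sum(!per_ps$probeset_id %in% kept_ps)
  )

  out <- annotation_set(new_probes, new_probesets, aset$platform_name)
  structure(list(annotation = out, report = report), class = "equalize_result")
}

#' @export
print.equalize_result <- function(x, ...) {
  t <- attr(x$report, "totals")
  cat(sprintf(
    "<equalize_result> removed %d / %d probes; dropped %d / %d probesets\n",
    t$probes_removed, t$probes_total, t$probesets_dropped, t$probesets_total))
  invisible(x)
}

#' @export
print.mask_report <- function(x, ...) {
  t <- attr(x, "totals")
  cat(sprintf("<mask_report> %d probesets (%d dropped), %d / %d probes removed\n",
              t$probesets_total, t$probesets_dropped, t$probes_removed, t$probes_total))
  NextMethod()
}

#' @rdname snpmask-tidiers
#' @method tidy mask_report
#' @export
tidy.mask_report <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname snpmask-tidiers
#' @method glance mask_report
#' @export
glance.mask_report <- function(x, ...) {
  as_tibble(attr(x, "totals"))
}

#' Write / read the per-probeset masking report
#'
#' One TSV row per probeset (`probeset_id`, `n_probes_before`,
#' `n_probes_removed`, `n_probes_after`), ordered by probeset id, followed by
#' `#TOTAL`-prefixed footer lines carrying the whole-annotation totals.
#'
#' @param report a `mask_report` from [equalize_annotation()].
#' @param path output path.
#' @return `path` (write) or the re-read `mask_report` (read).
#' @export
write_mask_report <- function(report, path) {
  t <- attr(report, "totals")
  lines <- c(
    "probeset_id\tn_probes_before\tn_probes_removed\tn_probes_after",
    sprintf("%s\t%d\t%d\t%d", report$probeset_id, report$n_probes_before,
            report$n_probes_removed, report$n_probes_after),
    sprintf("#TOTAL probes_total\t%d", t$probes_total),
    sprintf("#TOTAL probes_removed\t%d", t$probes_removed),
    sprintf("#TOTAL probesets_total\t%d", t$probesets_total),
    sprintf("#TOTAL probesets_dropped\t%d", t$probesets_dropped)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_mask_report
#' @export
read_mask_report <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("report not found: %s", path))
  lines <- readr::read_lines(path)
  foot <- lines[startsWith(lines, "#TOTAL")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  tab <- readr::read_tsv(I(body), col_types = "ciii", progress = FALSE)
  totals <- as.list(setNames(
    as.integer(sub("^.*\t", "", foot)),
    sub("^#TOTAL ([a-z_]+)\t.*$", "\\1", foot)
  ))
  structure(tab, class = c("mask_report", class(tab)), totals = totals)
}
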