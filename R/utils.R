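#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom stats pt setNames rnorm rbinom runif cor cor.test binom.test p.adjust
#' @importFrom utils head tail packageVersion
NULL

stop_input <- function(msg, ...) abort(msg, class = "snpmask_input_error", ...)
stop_parse <- function(msg, ...) abort(msg, class = "snpmask_parse_error", ...)
stop_integrity <- function(msg, ...) abort(msg, class = "snpmask_integrity_error", ...)
stop_argument <- function(msg, ...) abort(msg, class = "snpmask_argument_error", ...)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_argument(sprintf("`%s` must be a single number in [0, 1], got %s",
                          name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != trunc(x)) {
    stop_argument(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Run `expr` under a deterministic RNG state without disturbing the caller's
# stream; `seed` must stay below 2^31 - 1 (R integer).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Reconcile chromosome naming dialects
#'
#' VCF and BED sources frequently disagree on the `"chr"` prefix. This helper
#' rewrites a vector of chromosome names to a chosen style so the two inputs
#' can be intersected.
#'
#' @param chrom character vector of chromosome names.
#' @param style `"asis"` (no change), `"strip_chr"` (remove a leading `"chr"`),
#'   or `"add_chr"` (prepend `"chr"` where absent).
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_chrom(c("chr1", "2"), "strip_chr")
#' normalize_chrom(c("chr1", "2"), "add_chr")
normalize_chrom <- function(chrom, style = c("asis", "strip_chr", "add_chr")) {
  style <- match.arg(style)
  switch(style,
    asis = chrom,
    strip_chr = sub("^chr", "", chrom),
    add_chr = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

warn_disjoint_chroms <- function(a, b, what_a, what_b) {
  if (length(a) && length(b) && !length(intersect(unique(a), unique(b)))) {
    warn(sprintf(
      "%s and %s share zero chromosome names; check 'chr' prefix conventions (see normalize_chrom())",
      what_a, what_b
    ))
  }
  invisible(NULL)
}

write_manifest <- function(path, command, params, inputs = character()) {
  checksums <- if (length(inputs)) tools::md5sum(inputs[file.exists(inputs)]) else character()
  lines <- c(
    paste0("command\t", command),
    paste0("tool_version\t", as.character(packageVersion("snpmask"))),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(names(params), function(k) {
      paste0("param:", k, "\t", paste(format(params[[k]]), collapse = ","))
    }, character(1)),
    vapply(names(checksums), function(f) {
      paste0("input_md5:", basename(f), "\t", checksums[[f]])
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
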