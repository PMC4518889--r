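#' Construct a platform annotation set
#'
#' An annotation set describes an expression array platform as two linked
#' tables: probes (each a short genomic interval belonging to exactly one
#' probeset) and probesets (each summarized into one expression value from
#' its member probes). Invariants are enforced on construction: probe ids are
#' unique, every probe's probeset exists, every probeset has at least one
#' member probe, and all intervals are valid half-open 0-based ranges.
#'
#' Probe row order within a probeset is the probeset's member order and is
#' preserved by all operations.
#'
#' @param probes tibble with columns `probe_id`, `probeset_id`, `chrom`,
#'   `start0`, `end0`, `strand` (one of `"+"`, `"-"`, `"*"`; `"*"` = unknown).
#' @param probesets tibble with columns `probeset_id` and optionally
#'   `gene_symbol`, `tss_chrom`, `tss_pos` (1-based transcription start, used
#'   to anchor cis-eQTL windows). If `NULL`, derived from `probes`.
#' @param platform_name free-text platform label.
#' @return an object of class `annotation_set`: a list with elements
#'   `platform_name`, `probes`, `probesets`.
#' @export
annotation_set <- function(probes, probesets = NULL, platform_name = "platform") {
  probes <- as_tibble(probes)
  need <- c("probe_id", "probeset_id", "chrom", "start0", "end0")
  miss <- setdiff(need, names(probes))
  if (length(miss)) {
    stop_integrity(paste0("probe table missing columns: ", paste(miss, collapse = ", ")))
  }
  if (!"strand" %in% names(probes)) probes$strand <- "*"
  probes$strand[is.na(probes$strand) | !probes$strand %in% c("+", "-")] <- "*"
  probes <- probes[, c(need, "strand")]

  if (anyDuplicated(probes$probe_id)) {
    dup <- unique(probes$probe_id[duplicated(probes$probe_id)])
    stop_integrity(paste0("duplicate probe ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (any(probes$start0 < 0) || any(probes$end0 <= probes$start0)) {
    stop_integrity("probe intervals must satisfy 0 <= start0 < end0")
  }

  if (is.null(probesets)) {
    probesets <- tibble(probeset_id = unique(probes$probeset_id))
  }
  probesets <- as_tibble(probesets)
  if (!"probeset_id" %in% names(probesets)) {
    stop_integrity("probeset table must have a probeset_id column")
  }
  for (c2 in c("gene_symbol", "tss_chrom")) {
    if (!c2 %in% names(probesets)) probesets[[c2]] <- NA_character_
  }
  if (!"tss_pos" %in% names(probesets)) probesets$tss_pos <- NA_integer_
  probesets$tss_pos <- as.integer(probesets$tss_pos)
  probesets <- probesets[, c("probeset_id", "gene_symbol", "tss_chrom", "tss_pos")]
  if (anyDuplicated(probesets$probeset_id)) {
    stop_integrity("duplicate probeset ids")
  }

  orphan <- setdiff(probes$probeset_id, probesets$probeset_id)
  if (length(orphan)) {
    stop_integrity(paste0("probes reference unknown probesets: ",
                          paste(head(orphan, 5), collapse = ", ")))
  }
  empty <- setdiff(probesets$probeset_id, probes$probeset_id)
  if (length(empty)) {
    stop_integrity(paste0("probesets with no member probes: ",
                          paste(head(empty, 5), collapse = ", ")))
  }

  structure(
    list(platform_name = platform_name, probes = probes, probesets = probesets),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d probesets, %d probes\n",
              x$platform_name, nrow(x$probesets), nrow(x$probes)))
  invisible(x)
}

#' @export
format.annotation_set <- function(x, ...) {
  sprintf("<annotation_set> %s: %d probesets, %d probes",
          x$platform_name, nrow(x$probesets), nrow(x$probes))
}

#' Read probe locations from a BED file
#'
#' Expects BED with at least four columns; coordinates are kept verbatim
#' (BED is 0-based half-open). The name column (4) carries probeset
#' membership as `"probesetID:probeID"`; a bare probe id is resolved against
#' `annotation` when supplied, otherwise it is an integrity error because the
#' probe's owning probeset is unknown. Strand is taken from column 6 when
#' present.
#'
#' @param path BED file path.
#' @param annotation optional [annotation_set()] used to resolve bare probe
#'   ids to their probesets.
#' @param chrom_style chromosome-name normalization, see [normalize_chrom()].
#' @return a probe tibble (`probe_id`, `probeset_id`, `chrom`, `start0`,
#'   `end0`, `strand`).
#' @export
read_probe_bed <- function(path, annotation = NULL, chrom_style = "asis") {
  if (!file.exists(path)) stop_input(sprintf("BED file not found: %s", path))
  lines <- readr::read_lines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#") & !startsWith(lines, "track")
  lineno <- which(keep)
  if (!length(lineno)) {
    return(tibble(probe_id = character(), probeset_id = character(),
                  chrom = character(), start0 = integer(), end0 = integer(),
                  strand = character()))
  }
  fields <- strsplit(lines[lineno], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- which(nf < 4L)[1]
    stop_parse(sprintf("%s line %d: BED needs >= 4 columns", path, lineno[bad]))
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  name <- vapply(fields, `[[`, character(1), 4)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], character(1)), "*")
  strand[!strand %in% c("+", "-")] <- "*"

  bad <- which(is.na(start0) | is.na(end0) | start0 < 0L | start0 >= end0)
  if (length(bad)) {
    stop_parse(sprintf("%s line %d: invalid interval (need 0 <= start < end)",
                       path, lineno[bad[1]]))
  }

  has_sep <- grepl(":", name, fixed = TRUE)
  probeset_id <- ifelse(has_sep, sub(":[^:]*$", "", name), NA_character_)
  probe_id <- ifelse(has_sep, sub("^.*:", "", name), name)

  if (anyDuplicated(probe_id)) {
    dup <- probe_id[duplicated(probe_id)][1]
    stop_integrity(sprintf("%s: duplicate probe id '%s' (line %d)",
                           path, dup, lineno[which(probe_id == dup)[2]]))
  }

  bare <- which(!has_sep)
  if (length(bare)) {
    if (is.null(annotation)) {
      stop_integrity(sprintf(
        "%s line %d: probe '%s' has no probeset (name column is not 'probeset:probe' and no annotation was supplied)",
        path, lineno[bare[1]], probe_id[bare[1]]))
    }
    lut <- setNames(annotation$probes$probeset_id, annotation$probes$probe_id)
    probeset_id[bare] <- lut[probe_id[bare]]
    unresolved <- bare[is.na(probeset_id[bare])]
    if (length(unresolved)) {
      stop_integrity(sprintf("%s line %d: probe '%s' not present in the supplied annotation",
                             path, lineno[unresolved[1]], probe_id[unresolved[1]]))
    }
  }

  tibble(probe_id = probe_id, probeset_id = probeset_id,
         chrom = normalize_chrom(chrom, chrom_style),
         start0 = start0, end0 = end0, strand = strand)
}

#' Write probe locations as BED
#'
#' Inverse of [read_probe_bed()]: emits 6-column BED with the name column
#' `"probesetID:probeID"`, sorted by probeset then probe id.
#'
#' @param probes probe tibble or an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_bed <- function(probes, path) {
  if (inherits(probes, "annotation_set")) probes <- probes$probes
  p <- dplyr::arrange(probes, .data$probeset_id, .data$probe_id)
  lines <- sprintf("%s\t%d\t%d\t%s:%s\t0\t%s",
                   p$chrom, p$start0, p$end0, p$probeset_id, p$probe_id,
                   ifelse(p$strand %in% c("+", "-"), p$strand, "."))
  writeLines(lines, path)
  invisible(path)
}

PLATFORM_HEADER <- "#%platform_name="

read_platform_header <- function(lines, default) {
  hdr <- lines[startsWith(lines, PLATFORM_HEADER)]
  if (length(hdr)) sub(PLATFORM_HEADER, "", hdr[1], fixed = TRUE) else default
}

#' Read a platform annotation
#'
#' Two text dialects are supported. `"tsv"` is a single tab-separated file
#' with header columns `probeset_id, probe_id, chrom, start0, end0, strand,
#' gene_symbol, tss` (the last two optional; `tss` is `"chrom:pos"` with a
#' 1-based position). `"pgf"` is a simplified PGF/CLF text pair: the PGF file
#' carries the probeset-to-probe hierarchy (a probeset line
#' `probeset_id<TAB>gene_symbol<TAB>tss`, followed by one tab-indented line
#' per member probe) and the CLF file carries probe coordinates
#' (`probe_id<TAB>chrom<TAB>start0<TAB>end0<TAB>strand`). Membership and
#' coordinates are cross-checked: a probe present in one file but not the
#' other is an integrity error.
#'
#' @param path annotation file (TSV dialect) or PGF file (PGF dialect).
#' @param dialect `"tsv"` or `"pgf"`.
#' @param clf_path CLF file for the PGF dialect; defaults to `path` with its
#'   extension replaced by `.clf`.
#' @param platform_name override the platform label stored in the file.
#' @return an [annotation_set()].
#' @export
read_annotation <- function(path, dialect = c("tsv", "pgf"), clf_path = NULL,
                            platform_name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_input(sprintf("annotation file not found: %s", path))
  if (dialect == "tsv") read_annotation_tsv(path, platform_name)
  else read_annotation_pgf(path, clf_path, platform_name)
}

read_annotation_tsv <- function(path, platform_name = NULL) {
  lines <- readr::read_lines(path)
  pname <- platform_name %||% read_platform_header(lines, tools::file_path_sans_ext(basename(path)))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) stop_parse(sprintf("%s: no header line", path))
  tab <- readr::read_tsv(I(body), col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  need <- c("probeset_id", "probe_id", "chrom", "start0", "end0", "strand")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_parse(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  probes <- tibble(
    probe_id = tab$probe_id, probeset_id = tab$probeset_id, chrom = tab$chrom,
    start0 = as.integer(tab$start0), end0 = as.integer(tab$end0),
    strand = tab$strand
  )
  ps <- dplyr::distinct(tab, .data$probeset_id, .keep_all = TRUE)
  tss <- parse_tss(if ("tss" %in% names(ps)) ps$tss else rep(NA_character_, nrow(ps)))
  probesets <- tibble(
    probeset_id = ps$probeset_id,
    gene_symbol = if ("gene_symbol" %in% names(ps)) ps$gene_symbol else NA_character_,
    tss_chrom = tss$chrom, tss_pos = tss$pos
  )
  annotation_set(probes, probesets, pname)
}

parse_tss <- function(x) {
  x[is.na(x) | x == "" | x == "."] <- NA_character_
  parts <- strsplit(x, ":", fixed = TRUE)
  list(
    chrom = vapply(parts, function(p) if (length(p) == 2L) p[1] else NA_character_, character(1)),
    pos = vapply(parts, function(p) if (length(p) == 2L) suppressWarnings(as.integer(p[2])) else NA_integer_, integer(1))
  )
}

format_tss <- function(chrom, pos) {
  ifelse(is.na(chrom) | is.na(pos), "", paste0(chrom, ":", pos))
}

read_annotation_pgf <- function(pgf_path, clf_path = NULL, platform_name = NULL) {
  clf_path <- clf_path %||% paste0(tools::file_path_sans_ext(pgf_path), ".clf")
  if (!file.exists(clf_path)) stop_input(sprintf("CLF file not found: %s", clf_path))

  pgf <- readr::read_lines(pgf_path)
  pname <- platform_name %||% read_platform_header(pgf, tools::file_path_sans_ext(basename(pgf_path)))
  pgf <- pgf[!startsWith(pgf, "#") & nzchar(pgf)]

  is_probe <- startsWith(pgf, "\t")
  current_ps <- NA_character_
  membership <- vector("list", length(pgf))
  ps_rows <- list()
  for (i in seq_along(pgf)) {
    if (is_probe[i]) {
      if (is.na(current_ps)) {
        stop_parse(sprintf("%s line %d: probe line before any probeset", pgf_path, i))
      }
      membership[[i]] <- c(current_ps, sub("^\t+", "", pgf[i]))
    } else {
      f <- strsplit(pgf[i], "\t", fixed = TRUE)[[1]]
      current_ps <- f[1]
      ps_rows[[length(ps_rows) + 1L]] <- tibble(
        probeset_id = f[1],
        gene_symbol = if (length(f) >= 2L && nzchar(f[2])) f[2] else NA_character_,
        tss = if (length(f) >= 3L && nzchar(f[3])) f[3] else NA_character_
      )
    }
  }
  membership <- membership[!vapply(membership, is.null, logical(1))]
  hier <- tibble(
    probeset_id = vapply(membership, `[[`, character(1), 1),
    probe_id = vapply(membership, `[[`, character(1), 2)
  )
  psets <- if (length(ps_rows)) dplyr::bind_rows(ps_rows) else {
    tibble(probeset_id = character(), gene_symbol = character(), tss = character())
  }
  tss <- parse_tss(psets$tss)
  probesets <- tibble(probeset_id = psets$probeset_id, gene_symbol = psets$gene_symbol,
                      tss_chrom = tss$chrom, tss_pos = tss$pos)

  clf <- readr::read_lines(clf_path)
  clf <- clf[!startsWith(clf, "#") & nzchar(clf)]
  cf <- strsplit(clf, "\t", fixed = TRUE)
  if (length(cf) && any(lengths(cf) < 4L)) {
    stop_parse(sprintf("%s: CLF lines need probe_id, chrom, start0, end0", clf_path))
  }
  coords <- tibble(
    probe_id = vapply(cf, `[[`, character(1), 1),
    chrom = vapply(cf, `[[`, character(1), 2),
    start0 = as.integer(vapply(cf, `[[`, character(1), 3)),
    end0 = as.integer(vapply(cf, `[[`, character(1), 4)),
    strand = vapply(cf, function(f) if (length(f) >= 5L) f[5] else "*", character(1))
  )

  only_pgf <- setdiff(hier$probe_id, coords$probe_id)
  only_clf <- setdiff(coords$probe_id, hier$probe_id)
  if (length(only_pgf) || length(only_clf)) {
    stop_integrity(paste0(
      "PGF/CLF probe sets disagree; ",
      if (length(only_pgf)) paste0("missing coordinates for: ", paste(head(only_pgf, 5), collapse = ", "), " ") else "",
      if (length(only_clf)) paste0("missing hierarchy for: ", paste(head(only_clf, 5), collapse = ", ")) else ""
    ))
  }

  probes <- dplyr::left_join(hier, coords, by = "probe_id")
  annotation_set(probes, probesets, pname)
}

#' Write a platform annotation
#'
#' Emits the dialect of [read_annotation()]; re-reading the emitted file(s)
#' reproduces the annotation field for field. Output ordering is
#' deterministic (probesets, then probes within probeset, lexicographic by
#' id) so that diffs between an original and a masked annotation are
#' reviewable.
#'
#' @param aset an [annotation_set()].
#' @param path output file (TSV dialect) or PGF file (PGF dialect).
#' @param dialect `"tsv"` or `"pgf"`.
#' @param clf_path CLF output path for the PGF dialect (default: `path` with
#'   extension `.clf`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(aset, path, dialect = c("tsv", "pgf"), clf_path = NULL) {
  stopifnot(inherits(aset, "annotation_set"))
  dialect <- match.arg(dialect)
  ord <- dplyr::arrange(
    dplyr::left_join(aset$probes, aset$probesets, by = "probeset_id"),
    .data$probeset_id, .data$probe_id
  )
  if (dialect == "tsv") {
    lines <- c(
      paste0(PLATFORM_HEADER, aset$platform_name),
      paste(c("probeset_id", "probe_id", "chrom", "start0", "end0", "strand",
              "gene_symbol", "tss"), collapse = "\t"),
      sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s",
              ord$probeset_id, ord$probe_id, ord$chrom, ord$start0, ord$end0,
              ord$strand, ifelse(is.na(ord$gene_symbol), "", ord$gene_symbol),
              format_tss(ord$tss_chrom, ord$tss_pos))
    )
    writeLines(lines, path)
  } else {
    clf_path <- clf_path %||% paste0(tools::file_path_sans_ext(path), ".clf")
    ps <- dplyr::arrange(aset$probesets, .data$probeset_id)
    pgf_lines <- c(paste0(PLATFORM_HEADER, aset$platform_name))
    split_probes <- split(ord$probe_id, ord$probeset_id)
    for (i in seq_len(nrow(ps))) {
      pgf_lines <- c(pgf_lines,
        sprintf("%s\t%s\t%s", ps$probeset_id[i],
                ifelse(is.na(ps$gene_symbol[i]), "", ps$gene_symbol[i]),
                format_tss(ps$tss_chrom[i], ps$tss_pos[i])),
        paste0("\t", split_probes[[ps$probeset_id[i]]])
      )
    }
    writeLines(pgf_lines, path)
    writeLines(c(
      paste0(PLATFORM_HEADER, aset$platform_name),
      sprintf("%s\t%s\t%d\t%d\t%s", ord$probe_id, ord$chrom, ord$start0,
              ord$end0, ord$strand)
    ), clf_path)
  }
  invisible(path)
}
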