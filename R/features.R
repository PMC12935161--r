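# User-supplied functional features: loading/validation, protein-to-genome
# projection, and merging into the augmented annotation.

POSITIONAL_KINDS <- c("domain", "signal_peptide", "nls", "custom")
NP_DTYPES <- c("binary", "categorical", "continuous")

parse_binary <- function(v) {
  lv <- tolower(v)
  ifelse(lv %in% c("true", "1", "yes"), TRUE,
         ifelse(lv %in% c("false", "0", "no"), FALSE, NA))
}

#' Load a feature table
#'
#' One TSV holds both feature families, distinguished by a `row_type` column
#' (`positional` / `nonpositional`). Positional rows use columns `kind`
#' (domain, signal_peptide, nls, custom), `space` (`protein_aa`, 1-based
#' inclusive `start`/`end`; or `transcript_nt`, 0-based half-open) and
#' `label`. Non-positional rows reuse `kind` as the attribute name, `space` as
#' the dtype (binary/categorical/continuous) and `label` as the value.
#' Features on transcripts absent from `models` are collected into a warning
#' report, not dropped fatally.
#'
#' @param path TSV path.
#' @param models optional [tx_models] used to flag unknown transcript ids.
#' @return list with tibbles `positional` (`transcript_id`, `kind`, `space`,
#'   `start`, `end`, `label`), `nonpositional` (`transcript_id`, `name`,
#'   `dtype`, `value`, `value_num`, `value_bool`) and `unknown_ids`.
#' @export
load_features <- function(path, models = NULL) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("row_type", "transcript_id", "kind", "space", "start", "end", "label")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    iso_abort(paste0("feature table missing column(s): ", paste(miss, collapse = ", ")), "schema")
  }
  bad_rt <- which(!d$row_type %in% c("positional", "nonpositional"))
  if (length(bad_rt)) {
    iso_abort(sprintf("feature table row %d: unknown row_type '%s'", bad_rt[1], d$row_type[bad_rt[1]]), "schema")
  }
  pos <- d[d$row_type == "positional", ]
  np <- d[d$row_type == "nonpositional", ]

  pos_rows <- which(d$row_type == "positional")
  bad <- which(!pos$kind %in% POSITIONAL_KINDS)
  if (length(bad)) {
    iso_abort(sprintf("feature table row %d: unknown kind '%s'", pos_rows[bad[1]], pos$kind[bad[1]]), "schema")
  }
  bad <- which(!pos$space %in% c("protein_aa", "transcript_nt"))
  if (length(bad)) {
    iso_abort(sprintf("feature table row %d: unknown space '%s'", pos_rows[bad[1]], pos$space[bad[1]]), "schema")
  }
  start <- suppressWarnings(as.integer(pos$start))
  end <- suppressWarnings(as.integer(pos$end))
  bad <- which(is.na(start) | is.na(end) |
                 (pos$space == "protein_aa" & start > end) |
                 (pos$space == "transcript_nt" & start >= end) |
                 (pos$space == "protein_aa" & start < 1L) |
                 (pos$space == "transcript_nt" & start < 0L))
  if (length(bad)) {
    iso_abort(sprintf("feature table row %d: invalid coordinates", pos_rows[bad[1]]), "schema")
  }
  positional <- tibble::tibble(
    transcript_id = pos$transcript_id, kind = pos$kind, space = pos$space,
    start = start, end = end, label = pos$label
  )

  np_rows <- which(d$row_type == "nonpositional")
  bad <- which(!np$space %in% NP_DTYPES)
  if (length(bad)) {
    iso_abort(sprintf("feature table row %d: unknown dtype '%s'", np_rows[bad[1]], np$space[bad[1]]), "schema")
  }
  value_num <- suppressWarnings(as.numeric(np$label))
  value_bool <- parse_binary(np$label)
  bad <- which((np$space == "continuous" & is.na(value_num)) |
                 (np$space == "binary" & is.na(value_bool)))
  if (length(bad)) {
    iso_abort(sprintf(
      "feature table row %d: value '%s' does not match dtype '%s'",
      np_rows[bad[1]], np$label[bad[1]], np$space[bad[1]]
    ), "schema")
  }
  nonpositional <- tibble::tibble(
    transcript_id = np$transcript_id, name = np$kind, dtype = np$space,
    value = np$label, value_num = value_num, value_bool = value_bool
  )

  unknown <- character()
  if (!is.null(models)) {
    unknown <- setdiff(c(positional$transcript_id, nonpositional$transcript_id), tx_ids(models))
    if (length(unknown)) {
      iso_warn(paste0("features reference unknown transcripts: ", paste(unknown, collapse = ", ")))
    }
  }
  list(positional = positional, nonpositional = nonpositional, unknown_ids = unknown)
}

#' Write a feature table
#'
#' @param features a [load_features()]-shaped list.
#' @param path TSV path.
#' @export
write_features <- function(features, path) {
  pos <- features$positional
  np <- features$nonpositional
  d <- dplyr::bind_rows(
    tibble::tibble(
      row_type = rep("positional", nrow(pos)), transcript_id = pos$transcript_id,
      kind = pos$kind, space = pos$space,
      start = as.character(pos$start), end = as.character(pos$end), label = pos$label
    ),
    tibble::tibble(
      row_type = rep("nonpositional", nrow(np)), transcript_id = np$transcript_id,
      kind = np$name, space = np$dtype,
      start = NA_character_, end = NA_character_, label = np$value
    )
  )
  readr::write_tsv(d, path)
  invisible(path)
}

#' Project a protein-space feature onto the genome
#'
#' Amino-acid interval `[a, b]` (1-based inclusive) maps to the CDS-relative
#' nucleotide interval `[3(a-1), 3b)` and then through the CDS chain to
#' genomic intervals, split at junctions. Features extending beyond the CDS
#' (e.g. on `cds_incomplete` transcripts) are clipped and flagged.
#'
#' @inheritParams coords
#' @param aa_start,aa_end 1-based inclusive amino-acid coordinates.
#' @return tibble of genomic intervals (`start`, `end`) with attribute
#'   `clipped`.
#' @export
project_protein_feature <- function(models, transcript_id, aa_start, aa_end) {
  cd <- tx_cds(models, transcript_id)
  if (!nrow(cd)) {
    iso_abort(paste0("protein-space feature on transcript without CDS: ", transcript_id), "domain")
  }
  cds_len <- sum(cd$end - cd$start)
  nt_start <- 3L * (aa_start - 1L)
  nt_end <- 3L * aa_end
  clipped <- nt_end > cds_len
  nt_end <- min(nt_end, cds_len)
  if (nt_start >= nt_end) iso_abort("feature lies beyond the CDS", "domain")

  # project within the CDS chain (transcript-ordered)
  strand <- tx_strand(models, transcript_id)
  ord <- if (strand == "+") order(cd$start) else order(-cd$start)
  lens <- (cd$end - cd$start)[ord]
  cum <- cumsum(c(0L, lens))
  out <- list()
  for (i in seq_along(lens)) {
    a <- max(nt_start, cum[i])
    b <- min(nt_end, cum[i + 1L])
    if (a < b) {
      piece <- cd[ord[i], ]
      if (strand == "+") {
        out[[length(out) + 1L]] <- c(piece$start + (a - cum[i]), piece$start + (b - cum[i]))
      } else {
        out[[length(out) + 1L]] <- c(piece$end - (b - cum[i]), piece$end - (a - cum[i]))
      }
    }
  }
  m <- do.call(rbind, out)
  res <- tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  res <- res[order(res$start), ]
  attr(res, "clipped") <- clipped
  res
}

#' Merge features into the annotation
#'
#' Positional features are lifted to genomic coordinates and stored as extra
#' GTF records (feature type = kind, attributes `feature_label` /
#' `feature_source`); non-positional features become transcript-level
#' attributes `np_<name>`. A [parse_gtf()] of the written augmented GTF
#' recovers every feature. Merging an empty feature set is the identity.
#'
#' @param models a [tx_models] object.
#' @param features a [load_features()]-shaped list.
#' @param source value recorded in `feature_source`.
#' @return the augmented [tx_models].
#' @export
merge_into_annotation <- function(models, features, source = "user") {
  pos <- features$positional
  rows <- list()
  for (i in seq_len(nrow(pos))) {
    tid <- pos$transcript_id[i]
    if (!tid %in% tx_ids(models)) next
    iv <- if (pos$space[i] == "protein_aa") {
      project_protein_feature(models, tid, pos$start[i], pos$end[i])
    } else {
      project_interval(models, tid, pos$start[i], pos$end[i])
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      transcript_id = tid, type = pos$kind[i],
      start = iv$start, end = iv$end,
      label = pos$label[i], source = source
    )
  }
  if (length(rows)) {
    models$features <- dplyr::bind_rows(models$features, dplyr::bind_rows(rows))
  }
  np <- features$nonpositional
  for (i in seq_len(nrow(np))) {
    j <- match(np$transcript_id[i], models$transcripts$transcript_id)
    if (is.na(j)) next
    at <- models$transcripts$attributes[[j]]
    at[[paste0("np_", np$name[i])]] <- np$value[i]
    models$transcripts$attributes[[j]] <- at
  }
  models
}

#' Extract non-positional features stored as transcript attributes
#'
#' Inverse of the non-positional half of [merge_into_annotation()]: collects
#' `np_<name>` attributes back into a tidy table (dtype inferred from the
#' value).
#'
#' @param models a [tx_models] object.
#' @export
nonpositional_from_models <- function(models) {
  rows <- list()
  for (i in seq_len(nrow(models$transcripts))) {
    at <- models$transcripts$attributes[[i]]
    keys <- grep("^np_", names(at), value = TRUE)
    for (k in keys) {
      v <- at[[k]]
      vb <- parse_binary(v)
      vn <- suppressWarnings(as.numeric(v))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        transcript_id = models$transcripts$transcript_id[i],
        name = sub("^np_", "", k),
        dtype = if (!is.na(vb)) "binary" else if (!is.na(vn)) "continuous" else "categorical",
        value = v, value_num = vn, value_bool = vb
      )
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(
      transcript_id = character(), name = character(), dtype = character(),
      value = character(), value_num = numeric(), value_bool = logical()
    ))
  }
  dplyr::bind_rows(rows)
}
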