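#' Transcript model container
#'
#' `tx_models` holds a set of gene models: transcripts with their exon chains,
#' optional CDS chains, attached positional features and arbitrary GTF
#' attributes. All internal coordinates are 0-based half-open on the genome;
#' conversion to the 1-based inclusive GTF convention happens only in
#' [parse_gtf()] / [write_gtf()].
#'
#' @param transcripts tibble with columns `transcript_id`, `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `cds_incomplete` and a list-column
#'   `attributes` of named character vectors.
#' @param exons,cds tibbles with columns `transcript_id`, `start`, `end`
#'   (0-based half-open genomic coordinates).
#' @param features tibble of positional features already lifted to genomic
#'   coordinates: `transcript_id`, `type`, `start`, `end`, `label`, `source`.
#' @param extra tibble of pass-through GTF records of unknown feature type.
#' @return An object of class `tx_models`.
#' @export
tx_models <- function(transcripts, exons, cds = NULL, features = NULL, extra = NULL) {
  empty_iv <- tibble::tibble(transcript_id = character(), start = integer(), end = integer())
  as_int_coords <- function(d) {
    d <- tibble::as_tibble(d)
    d$start <- as.integer(d$start)
    d$end <- as.integer(d$end)
    d
  }
  exons <- as_int_coords(exons)
  if (!is.null(cds)) cds <- as_int_coords(cds)
  if (!is.null(features)) features <- as_int_coords(features)
  x <- structure(
    list(
      transcripts = tibble::as_tibble(transcripts),
      exons = tibble::as_tibble(exons),
      cds = if (is.null(cds)) empty_iv else tibble::as_tibble(cds),
      features = if (is.null(features)) {
        tibble::tibble(
          transcript_id = character(), type = character(),
          start = integer(), end = integer(),
          label = character(), source = character()
        )
      } else {
        tibble::as_tibble(features)
      },
      extra = if (is.null(extra)) {
        tibble::tibble(
          chrom = character(), source = character(), type = character(),
          start = integer(), end = integer(), score = character(),
          strand = character(), frame = character(), attr_str = character()
        )
      } else {
        tibble::as_tibble(extra)
      }
    ),
    class = "tx_models"
  )
  validate_tx_models(x)
}

validate_tx_models <- function(x) {
  tr <- x$transcripts
  if (anyDuplicated(tr$transcript_id)) {
    iso_abort("duplicate transcript ids in model", "validation")
  }
  if (!all(tr$strand %in% c("+", "-"))) {
    iso_abort("strand must be '+' or '-'", "validation")
  }
  ex <- x$exons
  if (!all(ex$transcript_id %in% tr$transcript_id)) {
    iso_abort("exon records reference unknown transcripts", "validation")
  }
  if (any(ex$start < 0L) || any(ex$end <= ex$start)) {
    iso_abort("exon intervals must satisfy 0 <= start < end", "validation")
  }
  # per-transcript: >=1 exon, sorted, pairwise disjoint
  split_ex <- split(ex, ex$transcript_id)
  missing_ex <- setdiff(tr$transcript_id, names(split_ex))
  if (length(missing_ex)) {
    iso_abort(paste0("transcripts without exons: ", paste(missing_ex, collapse = ", ")), "validation")
  }
  for (tid in names(split_ex)) {
    e <- split_ex[[tid]]
    o <- order(e$start)
    if (any(e$end[o][-nrow(e)] > e$start[o][-1L])) {
      iso_abort(paste0("overlapping exons in transcript ", tid), "validation")
    }
  }
  # CDS contained in exons
  if (nrow(x$cds)) {
    for (i in seq_len(nrow(x$cds))) {
      tid <- x$cds$transcript_id[i]
      e <- split_ex[[tid]]
      if (is.null(e) || !any(e$start <= x$cds$start[i] & e$end >= x$cds$end[i])) {
        iso_abort(paste0("CDS interval outside exons in transcript ", tid), "validation")
      }
    }
  }
  # genes live on one chromosome
  per_gene <- tapply(tr$chrom, tr$gene_id, function(ch) length(unique(ch)))
  if (any(per_gene > 1L)) {
    iso_abort("gene with transcripts on multiple chromosomes", "validation")
  }
  x
}

#' @export
print.tx_models <- function(x, ...) {
  cat(sprintf(
    "<tx_models> %d transcripts, %d genes, %d exon records, %d CDS records, %d features\n",
    nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
    nrow(x$exons), nrow(x$cds), nrow(x$features)
  ))
  invisible(x)
}

#' Accessors for transcript models
#'
#' @param models a [tx_models] object.
#' @param transcript_id a single transcript id.
#' @name tx-accessors
NULL

#' @rdname tx-accessors
#' @export
tx_ids <- function(models) models$transcripts$transcript_id

#' @rdname tx-accessors
#' @export
gene_ids <- function(models) unique(models$transcripts$gene_id)

tx_row <- function(models, transcript_id) {
  i <- match(transcript_id, models$transcripts$transcript_id)
  if (is.na(i)) iso_abort(paste0("unknown transcript id: ", transcript_id), "lookup")
  models$transcripts[i, ]
}

#' @rdname tx-accessors
#' @export
tx_exons <- function(models, transcript_id) {
  tx_row(models, transcript_id) # id check
  e <- models$exons[models$exons$transcript_id == transcript_id, ]
  e[order(e$start), ]
}

#' @rdname tx-accessors
#' @export
tx_cds <- function(models, transcript_id) {
  tx_row(models, transcript_id)
  e <- models$cds[models$cds$transcript_id == transcript_id, ]
  e[order(e$start), ]
}

#' @rdname tx-accessors
#' @export
tx_strand <- function(models, transcript_id) tx_row(models, transcript_id)$strand

#' @rdname tx-accessors
#' @export
spliced_length <- function(models, transcript_id) {
  e <- tx_exons(models, transcript_id)
  sum(e$end - e$start)
}

#' Subset a model set to one gene
#'
#' @inheritParams tx-accessors
#' @param gene_id a single gene id.
#' @return a `tx_models` with that gene's transcripts only.
#' @export
filter_gene <- function(models, gene_id) {
  keep <- models$transcripts$gene_id == gene_id
  if (!any(keep)) iso_abort(paste0("unknown gene id: ", gene_id), "lookup")
  ids <- models$transcripts$transcript_id[keep]
  tx_models(
    models$transcripts[keep, ],
    models$exons[models$exons$transcript_id %in% ids, ],
    models$cds[models$cds$transcript_id %in% ids, ],
    models$features[models$features$transcript_id %in% ids, ],
    models$extra[0, ]
  )
}

# --- GTF I/O ---------------------------------------------------------------

STRUCT_TYPES <- c("gene", "transcript", "exon", "CDS")
FEATURE_TYPES <- c("domain", "signal_peptide", "nls")

parse_gtf_attributes <- function(s) {
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_.]*)\\s+(("([^"]*)")|([^;\\s]+))\\s*;', s, perl = TRUE)
  hits <- regmatches(s, m)[[1]]
  keys <- sub('^([A-Za-z_][A-Za-z0-9_.]*)\\s+.*$', "\\1", hits)
  vals <- sub('^[A-Za-z_][A-Za-z0-9_.]*\\s+', "", hits)
  vals <- sub(";\\s*$", "", vals)
  vals <- gsub('^"|"$', "", vals)
  stats::setNames(vals, keys)
}

#' Read a GENCODE-dialect GTF into transcript models
#'
#' Exon and CDS records are aggregated per `transcript_id`; positional feature
#' records of type `domain`, `signal_peptide` or `nls` are attached to their
#' transcript; records of any other unknown type are preserved verbatim and
#' re-emitted by [write_gtf()]. On-disk coordinates are 1-based inclusive and
#' converted to the internal 0-based half-open convention.
#'
#' @param path path to a GTF file.
#' @return a [tx_models] object.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) iso_abort(paste0("no such file: ", path), "io")
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    iso_abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields", idx[bad[1]]), "parse")
  }
  if (!length(fields)) {
    return(tx_models(
      tibble::tibble(
        transcript_id = character(), gene_id = character(), gene_name = character(),
        chrom = character(), strand = character(), cds_incomplete = logical(),
        attributes = list()
      ),
      tibble::tibble(transcript_id = character(), start = integer(), end = integer())
    ))
  }
  rec <- tibble::tibble(
    line = idx,
    chrom = vapply(fields, `[[`, "", 1L),
    source = vapply(fields, `[[`, "", 2L),
    type = vapply(fields, `[[`, "", 3L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))) - 1L,
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    score = vapply(fields, `[[`, "", 6L),
    strand = vapply(fields, `[[`, "", 7L),
    frame = vapply(fields, `[[`, "", 8L),
    attr_str = vapply(fields, `[[`, "", 9L)
  )
  if (anyNA(rec$start) || anyNA(rec$end)) {
    bad <- rec$line[which(is.na(rec$start) | is.na(rec$end))[1]]
    iso_abort(sprintf("malformed GTF line %d: non-integer coordinates", bad), "parse")
  }
  attrs <- lapply(rec$attr_str, parse_gtf_attributes)
  need <- rec$type %in% c("exon", "CDS", "transcript", FEATURE_TYPES)
  gid <- vapply(attrs, function(a) a["gene_id"] %||% NA_character_, "")
  tid <- vapply(attrs, function(a) a["transcript_id"] %||% NA_character_, "")
  missing_ids <- need & (is.na(gid) | is.na(tid))
  if (any(missing_ids)) {
    iso_abort(sprintf(
      "malformed GTF line %d: gene_id/transcript_id attribute missing", rec$line[which(missing_ids)[1]]
    ), "parse")
  }

  is_exon <- rec$type == "exon"
  is_cds <- rec$type == "CDS"
  is_txline <- rec$type == "transcript"
  is_feat <- rec$type %in% FEATURE_TYPES
  is_extra <- !(rec$type %in% c(STRUCT_TYPES, FEATURE_TYPES))

  tids <- unique(tid[is_exon])
  if (!length(tids)) iso_abort("GTF contains no exon records", "parse")

  # consistency of strand/chrom within a transcript
  for (flag in list(is_exon, is_cds)) {
    if (!any(flag)) next
    st <- tapply(rec$strand[flag], tid[flag], function(s) length(unique(s)))
    ch <- tapply(rec$chrom[flag], tid[flag], function(s) length(unique(s)))
    if (any(st > 1L) || any(ch > 1L)) {
      off <- names(which(st > 1L | ch > 1L))[1]
      iso_abort(paste0("inconsistent strand/chromosome within transcript ", off), "validation")
    }
  }
  exon_idx <- which(is_exon)
  ref <- exon_idx[!duplicated(tid[exon_idx])]
  tx_meta <- tibble::tibble(
    transcript_id = tid[ref], gene_id = gid[ref],
    chrom = rec$chrom[ref], strand = rec$strand[ref]
  )
  cds_strand <- rec$strand[is_cds][match(tx_meta$transcript_id, tid[is_cds])]
  mism <- !is.na(cds_strand) & cds_strand != tx_meta$strand
  if (any(mism)) {
    iso_abort(paste0(
      "CDS strand differs from exon strand in transcript ",
      tx_meta$transcript_id[which(mism)[1]]
    ), "validation")
  }

  # transcript-level attributes: from the transcript line when present,
  # otherwise from the first exon line; structural keys held separately.
  drop_keys <- c("gene_id", "transcript_id", "gene_name")
  attr_of <- function(tt) {
    j <- which(is_txline & tid == tt)
    if (!length(j)) j <- which(is_exon & tid == tt)[1]
    a <- attrs[[j]]
    a[setdiff(names(a), drop_keys)]
  }
  gname_of <- function(tt) {
    j <- c(which(is_txline & tid == tt), which(is_exon & tid == tt))
    for (jj in j) {
      a <- attrs[[jj]]
      if ("gene_name" %in% names(a)) return(a[["gene_name"]])
    }
    NA_character_
  }
  tx_meta$gene_name <- unname(vapply(tx_meta$transcript_id, gname_of, ""))
  tx_meta$attributes <- lapply(tx_meta$transcript_id, attr_of)

  exons <- tibble::tibble(transcript_id = tid[is_exon], start = rec$start[is_exon], end = rec$end[is_exon])
  cds <- tibble::tibble(transcript_id = tid[is_cds], start = rec$start[is_cds], end = rec$end[is_cds])
  cds_len <- tapply(cds$end - cds$start, cds$transcript_id, sum)
  tx_meta$cds_incomplete <- vapply(seq_len(nrow(tx_meta)), function(i) {
    flagged <- identical(unname(tx_meta$attributes[[i]]["cds_incomplete"]), "true")
    len <- cds_len[tx_meta$transcript_id[i]]
    flagged || (!is.na(len) && len %% 3L != 0L)
  }, TRUE)
  feats <- tibble::tibble(
    transcript_id = tid[is_feat], type = rec$type[is_feat],
    start = rec$start[is_feat], end = rec$end[is_feat],
    label = vapply(attrs[is_feat], attr_get, "", key = "feature_label"),
    source = vapply(attrs[is_feat], attr_get, "", key = "feature_source")
  )
  extra <- rec[is_extra, c("chrom", "source", "type", "start", "end", "score", "strand", "frame", "attr_str")]
  tx_models(tx_meta, exons, cds, feats, extra)
}

format_gtf_attributes <- function(gene_id, transcript_id, gene_name = NA, extra = NULL) {
  parts <- c(
    sprintf('gene_id "%s";', gene_id),
    sprintf('transcript_id "%s";', transcript_id)
  )
  if (!is.na(gene_name)) parts <- c(parts, sprintf('gene_name "%s";', gene_name))
  if (length(extra)) {
    keys <- sort(names(extra))
    parts <- c(parts, sprintf('%s "%s";', keys, unname(extra[keys])))
  }
  paste(parts, collapse = " ")
}

cds_phases <- function(cds_sorted, strand) {
  # GTF frame column: bases to skip to reach the next full codon, accumulated
  # in transcript (5'->3') order.
  lens <- cds_sorted$end - cds_sorted$start
  ord <- if (strand == "+") seq_along(lens) else rev(seq_along(lens))
  before <- cumsum(c(0L, lens[ord]))[seq_along(lens)]
  phase <- (3L - before %% 3L) %% 3L
  out <- integer(length(lens))
  out[ord] <- phase
  out
}

#' Write transcript models as GENCODE-dialect GTF
#'
#' Output is deterministic (ordered by gene id, transcript id, genomic start;
#' attribute keys sorted) so repeated writes are byte-identical. The stop codon
#' is assumed to be excluded from stored CDS records.
#'
#' @param models a [tx_models] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- c("##provider: isoscope", "##format: gtf")
  tr <- models$transcripts[order(models$transcripts$gene_id, models$transcripts$transcript_id), ]
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    ex <- tx_exons(models, t$transcript_id)
    cd <- tx_cds(models, t$transcript_id)
    at <- t$attributes[[1]]
    if (isTRUE(t$cds_incomplete)) at[["cds_incomplete"]] <- "true"
    attr_str <- format_gtf_attributes(t$gene_id, t$transcript_id, t$gene_name, at)
    mk <- function(type, s, e, frame = ".") {
      sprintf(
        "%s\tisoscope\t%s\t%d\t%d\t.\t%s\t%s\t%s",
        t$chrom, type, s + 1L, e, t$strand, frame, attr_str
      )
    }
    lines <- c(lines, mk("transcript", min(ex$start), max(ex$end)))
    for (j in seq_len(nrow(ex))) lines <- c(lines, mk("exon", ex$start[j], ex$end[j]))
    if (nrow(cd)) {
      ph <- cds_phases(cd, t$strand)
      for (j in seq_len(nrow(cd))) lines <- c(lines, mk("CDS", cd$start[j], cd$end[j], as.character(ph[j])))
    }
    fe <- models$features[models$features$transcript_id == t$transcript_id, ]
    fe <- fe[order(fe$start, fe$type, fe$label), ]
    for (j in seq_len(nrow(fe))) {
      fat <- c(
        if (!is.na(fe$label[j])) c(feature_label = fe$label[j]),
        if (!is.na(fe$source[j])) c(feature_source = fe$source[j])
      )
      lines <- c(lines, sprintf(
        "%s\tisoscope\t%s\t%d\t%d\t.\t%s\t.\t%s",
        t$chrom, fe$type[j], fe$start[j] + 1L, fe$end[j], t$strand,
        format_gtf_attributes(t$gene_id, t$transcript_id, t$gene_name, fat)
      ))
    }
  }
  if (nrow(models$extra)) {
    xo <- models$extra[order(models$extra$chrom, models$extra$start, models$extra$type), ]
    lines <- c(lines, sprintf(
      "%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
      xo$chrom, xo$source, xo$type, xo$start + 1L, xo$end, xo$score, xo$strand, xo$frame, xo$attr_str
    ))
  }
  tryCatch(
    readr::write_lines(lines, path),
    error = function(e) iso_abort(paste0("cannot write GTF: ", conditionMessage(e)), "io")
  )
  invisible(path)
}
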