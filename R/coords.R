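#' Coordinate transforms between genome and spliced transcript space
#'
#' Transcript coordinates are 0-based offsets along the spliced transcript in
#' 5'->3' orientation; on the minus strand the largest genomic exonic
#' coordinate maps to offset 0. Genomic coordinates are 0-based half-open.
#'
#' @param models a [tx_models] object.
#' @param transcript_id transcript to operate on.
#' @param gpos genomic position(s), 0-based.
#' @param tpos transcript position(s), 0-based.
#' @name coords
NULL

# plus-orientation offset of an exonic genomic position (vectorized)
plus_offset <- function(ex, gpos) {
  starts <- ex$start
  ends <- ex$end
  cum_before <- cumsum(c(0L, ends - starts))[seq_along(starts)]
  i <- findInterval(gpos, starts)
  ok <- i >= 1L & gpos < ends[pmax(i, 1L)]
  if (!all(ok)) iso_abort("position not inside an exon", "domain")
  cum_before[i] + (gpos - starts[i])
}

#' @rdname coords
#' @export
genome_to_transcript <- function(models, transcript_id, gpos) {
  ex <- tx_exons(models, transcript_id)
  off <- plus_offset(ex, gpos)
  if (tx_strand(models, transcript_id) == "+") {
    off
  } else {
    sum(ex$end - ex$start) - 1L - off
  }
}

#' @rdname coords
#' @export
transcript_to_genome <- function(models, transcript_id, tpos) {
  ex <- tx_exons(models, transcript_id)
  total <- sum(ex$end - ex$start)
  if (any(tpos < 0L) || any(tpos >= total)) {
    iso_abort("transcript position out of range", "domain")
  }
  off <- if (tx_strand(models, transcript_id) == "+") tpos else total - 1L - tpos
  cum_before <- cumsum(c(0L, ex$end - ex$start))
  i <- findInterval(off, cum_before, rightmost.closed = FALSE)
  ex$start[i] + (off - cum_before[i])
}

#' Project a transcript-space interval onto the genome
#'
#' Splits a half-open interval of spliced-transcript coordinates at exon
#' junctions and returns the corresponding genomic intervals, ordered by
#' genomic start. The union of the result has total length `t_end - t_start`.
#'
#' @inheritParams coords
#' @param t_start,t_end half-open transcript-space interval.
#' @return tibble with columns `start`, `end` (0-based half-open genomic).
#' @export
project_interval <- function(models, transcript_id, t_start, t_end) {
  ex <- tx_exons(models, transcript_id)
  total <- sum(ex$end - ex$start)
  if (!(t_start >= 0 && t_start < t_end && t_end <= total)) {
    iso_abort("invalid transcript interval", "domain")
  }
  # convert to plus-orientation offsets
  if (tx_strand(models, transcript_id) == "+") {
    lo <- t_start
    hi <- t_end
  } else {
    lo <- total - t_end
    hi <- total - t_start
  }
  cum <- cumsum(c(0L, ex$end - ex$start))
  out <- list()
  for (i in seq_len(nrow(ex))) {
    a <- max(lo, cum[i])
    b <- min(hi, cum[i + 1L])
    if (a < b) {
      out[[length(out) + 1L]] <- c(ex$start[i] + (a - cum[i]), ex$start[i] + (b - cum[i]))
    }
  }
  m <- do.call(rbind, out)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

#' Transcription start site
#'
#' Genomic coordinate of the transcript 5' end: minimum exon start on the plus
#' strand, maximum exon end minus one on the minus strand.
#'
#' @inheritParams coords
#' @export
tss <- function(models, transcript_id) {
  ex <- tx_exons(models, transcript_id)
  if (tx_strand(models, transcript_id) == "+") min(ex$start) else max(ex$end) - 1L
}

# --- display map (intron compression) -------------------------------------

union_intervals <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  us <- starts[1]
  ue <- ends[1]
  out <- list()
  for (i in seq_along(starts)[-1]) {
    if (starts[i] > ue) {
      out[[length(out) + 1L]] <- c(us, ue)
      us <- starts[i]
      ue <- ends[i]
    } else {
      ue <- max(ue, ends[i])
    }
  }
  out[[length(out) + 1L]] <- c(us, ue)
  m <- do.call(rbind, out)
  tibble::tibble(start = m[, 1], end = m[, 2])
}

#' Build an intron-compressed display map for a locus
#'
#' The map is computed on the union of exons across all transcripts of the
#' locus so that shared intronic gaps align across isoforms. Exonic bases map
#' with slope one (length preserving); each maximal gap in the exon union is
#' rendered as exactly `intron_display_length` display units.
#'
#' @param models a [tx_models] object restricted (or restrictable) to one gene.
#' @param gene_id the locus to map.
#' @param intron_display_length display units per compressed intron.
#' @return an object of class `display_map` with a `segments` tibble
#'   (`g_start`, `g_end`, `d_start`, `d_end`, `type`) and a total `span`.
#' @export
build_display_map <- function(models, gene_id, intron_display_length = 100) {
  ids <- models$transcripts$transcript_id[models$transcripts$gene_id == gene_id]
  if (!length(ids)) iso_abort(paste0("unknown gene id: ", gene_id), "lookup")
  ex <- models$exons[models$exons$transcript_id %in% ids, ]
  u <- union_intervals(ex$start, ex$end)
  segs <- list()
  d <- 0
  for (i in seq_len(nrow(u))) {
    if (i > 1L) {
      segs[[length(segs) + 1L]] <- tibble::tibble(
        g_start = u$end[i - 1L], g_end = u$start[i],
        d_start = d, d_end = d + intron_display_length, type = "intron"
      )
      d <- d + intron_display_length
    }
    len <- u$end[i] - u$start[i]
    segs[[length(segs) + 1L]] <- tibble::tibble(
      g_start = u$start[i], g_end = u$end[i],
      d_start = d, d_end = d + len, type = "exon"
    )
    d <- d + len
  }
  structure(
    list(
      segments = dplyr::bind_rows(segs),
      span = d,
      intron_display_length = intron_display_length,
      gene_id = gene_id
    ),
    class = "display_map"
  )
}

#' Map genomic positions to display coordinates
#'
#' @param dmap a [build_display_map()] result.
#' @param gpos genomic positions within the locus extent.
#' @return numeric display coordinates (strictly monotone in `gpos`).
#' @export
display_pos <- function(dmap, gpos) {
  s <- dmap$segments
  if (any(gpos < s$g_start[1]) || any(gpos > s$g_end[nrow(s)])) {
    iso_abort("position outside the locus extent", "domain")
  }
  i <- pmin(findInterval(gpos, s$g_start), nrow(s))
  frac <- (gpos - s$g_start[i]) / (s$g_end[i] - s$g_start[i])
  s$d_start[i] + frac * (s$d_end[i] - s$d_start[i])
}

#' @export
print.display_map <- function(x, ...) {
  cat(sprintf(
    "<display_map> locus %s: %d segments, span %g (introns -> %g units)\n",
    x$gene_id, nrow(x$segments), x$span, x$intron_display_length
  ))
  invisible(x)
}
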