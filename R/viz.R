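# Structured drawing model and panel renderers. Every figure is first built
# as a tibble of typed primitives (rect / segment / text with coordinates and
# roles) that tests can read back; SVG serialization and ggplot2 display are
# thin views of that model.

ROW_H <- 30
LANE_THIN <- 4.5
LANE_THICK <- 10.5
LABEL_W <- 180
PANEL_GAP <- 40
MID_W <- 170
RIGHT_W <- 230

ISO_PALETTE <- c(
  exon_utr = "#7ea6c9", exon_cds = "#2b5d8c", intron = "#666666",
  tss_guide = "#c0392b", text = "#222222",
  control = "#8da0cb", case = "#fc8d62",
  domain = "#66c2a5", signal_peptide = "#e78ac3", nls = "#a6d854",
  custom = "#ffd92f", bar = "#4d4d4d"
)

pal <- function(key) {
  if (key %in% names(ISO_PALETTE)) ISO_PALETTE[[key]] else ISO_PALETTE[["custom"]]
}

drawing_row <- function(element, role, panel, x0, x1, y0, y1,
                        transcript_id = NA, group = NA, key = NA,
                        value = NA, label = NA, fill = NA, anchor = "start") {
  tibble::tibble(
    element = element, role = role, panel = panel,
    transcript_id = as.character(transcript_id), group = as.character(group),
    key = as.character(key),
    x0 = as.numeric(x0), x1 = as.numeric(x1),
    y0 = as.numeric(y0), y1 = as.numeric(y1),
    value = as.numeric(value), label = as.character(label),
    fill = as.character(fill), anchor = anchor
  )
}

new_drawing <- function(rows, width, height, xmin = -LABEL_W, scales = list()) {
  structure(
    dplyr::bind_rows(rows),
    class = c("iso_drawing", class(tibble::tibble())),
    width = width, height = height, xmin = xmin, scales = scales
  )
}

lane_order <- function(models, gene_id, sort_order = NULL) {
  tr <- models$transcripts[models$transcripts$gene_id == gene_id, ]
  if (!is.null(sort_order)) {
    miss <- setdiff(tr$transcript_id, sort_order)
    if (length(miss)) iso_abort("sort order does not cover all transcripts", "validation")
    return(intersect(sort_order, tr$transcript_id))
  }
  novel <- vapply(tr$attributes, function(a) identical(attr_get(a, "orf_source"), "predicted"), TRUE)
  tr$transcript_id[order(novel, tr$transcript_id)]
}

#' Build the shared locus track
#'
#' One horizontal lane per transcript: exons as boxes (thick over the CDS,
#' thin over untranslated regions), introns as connector lines of compressed
#' display width, positional features as styled sub-boxes, and one vertical
#' auxiliary guide line per distinct transcription start site spanning all
#' lanes. Lane order defaults to annotated-before-novel, then transcript id.
#'
#' @param models a [tx_models] object.
#' @param gene_id locus to draw.
#' @param dmap optional [build_display_map()] result for this locus.
#' @param highlight_cds draw CDS segments as thick boxes.
#' @param with_features draw attached positional features.
#' @param sort_order optional explicit lane order of transcript ids.
#' @return an `iso_drawing` tibble.
#' @export
build_locus_track <- function(models, gene_id, dmap = NULL, highlight_cds = TRUE,
                              with_features = TRUE, sort_order = NULL) {
  dmap <- dmap %||% build_display_map(models, gene_id)
  ids <- lane_order(models, gene_id, sort_order)
  rows <- list()
  tss_d <- numeric()
  for (i in seq_along(ids)) {
    tid <- ids[i]
    yc <- i * ROW_H
    ex <- tx_exons(models, tid)
    d0 <- display_pos(dmap, ex$start)
    d1 <- display_pos(dmap, ex$end)
    rows[[length(rows) + 1L]] <- drawing_row(
      "text", "tx_label", "locus", -10, -10, yc, yc,
      transcript_id = tid, label = tid, fill = ISO_PALETTE[["text"]], anchor = "end"
    )
    for (j in seq_len(nrow(ex))) {
      rows[[length(rows) + 1L]] <- drawing_row(
        "rect", "exon", "locus", d0[j], d1[j], yc - LANE_THIN, yc + LANE_THIN,
        transcript_id = tid, key = sprintf("exon_%d", j),
        value = ex$end[j] - ex$start[j], fill = ISO_PALETTE[["exon_utr"]]
      )
      if (j > 1L) {
        rows[[length(rows) + 1L]] <- drawing_row(
          "segment", "intron", "locus", d1[j - 1L], d0[j], yc, yc,
          transcript_id = tid, fill = ISO_PALETTE[["intron"]]
        )
      }
    }
    if (highlight_cds) {
      cd <- tx_cds(models, tid)
      for (j in seq_len(nrow(cd))) {
        rows[[length(rows) + 1L]] <- drawing_row(
          "rect", "cds", "locus",
          display_pos(dmap, cd$start[j]), display_pos(dmap, cd$end[j]),
          yc - LANE_THICK, yc + LANE_THICK,
          transcript_id = tid, key = sprintf("cds_%d", j),
          value = cd$end[j] - cd$start[j], fill = ISO_PALETTE[["exon_cds"]]
        )
      }
    }
    if (with_features) {
      fe <- models$features[models$features$transcript_id == tid, ]
      fe <- fe[order(fe$start, fe$type, fe$label), ]
      for (j in seq_len(nrow(fe))) {
        rows[[length(rows) + 1L]] <- drawing_row(
          "rect", "feature", "locus",
          display_pos(dmap, fe$start[j]), display_pos(dmap, fe$end[j]),
          yc + LANE_THICK + 1, yc + LANE_THICK + 6,
          transcript_id = tid, group = fe$type[j], key = fe$label[j],
          value = fe$end[j] - fe$start[j],
          fill = pal(fe$type[j])
        )
      }
    }
    tss_d <- c(tss_d, display_pos(dmap, tss(models, tid)))
  }
  n <- length(ids)
  for (d in sort(unique(round(tss_d, 6)))) {
    rows[[length(rows) + 1L]] <- drawing_row(
      "segment", "tss_guide", "locus", d, d, ROW_H / 2, n * ROW_H + ROW_H / 2,
      fill = ISO_PALETTE[["tss_guide"]]
    )
  }
  new_drawing(rows, width = LABEL_W + dmap$span + 20, height = (n + 1.5) * ROW_H,
              scales = list(span = dmap$span, n_lanes = n, lane_ids = ids))
}

box_stats <- function(x) {
  q <- unname(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7))
  list(lo = q[1], q1 = q[2], med = q[3], q3 = q[4], hi = q[5])
}

panel_scale <- function(values, x_off, width) {
  lo <- min(values)
  hi <- max(values)
  if (hi - lo < 1e-9) {
    lo <- lo - 1
    hi <- hi + 1
  }
  list(lo = lo, hi = hi, x = function(v) x_off + (v - lo) / (hi - lo) * width)
}

#' Differential-expression panel
#'
#' Left: the shared locus track. Middle: per-isoform box plots of log2 CPM in
#' the control and case groups. Right: the q-value and log2 fold change per
#' isoform, with a `*` significance mark when `q < alpha`; transcripts absent
#' from the DE table render as `n/a`.
#'
#' @inheritParams build_locus_track
#' @param de_table DE results ([de_test()] `$table` or [load_de_table()]).
#' @param log2cpm wide tibble of log2 CPM values ([cpm()] with `log = TRUE`).
#' @param design a [sample_design()].
#' @param alpha significance threshold on q.
#' @return an `iso_drawing`.
#' @export
build_de_panel <- function(models, gene_id, de_table, log2cpm, design,
                           alpha = 0.05, sort_order = NULL) {
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  loc <- build_locus_track(models, gene_id, with_features = FALSE, sort_order = sort_order)
  sc <- attr(loc, "scales")
  ids <- sc$lane_ids
  x_off <- sc$span + PANEL_GAP
  cm <- counts_like_matrix(log2cpm)
  grp <- design_groups(design, colnames(cm))
  present <- ids[ids %in% rownames(cm)]
  vals <- if (length(present)) as.vector(cm[present, , drop = FALSE]) else c(0, 1)
  pscale <- panel_scale(vals, x_off, MID_W)
  rows <- list(loc)
  for (i in seq_along(ids)) {
    tid <- ids[i]
    yc <- i * ROW_H
    if (tid %in% rownames(cm)) {
      for (g in c("control", "case")) {
        xrow <- cm[tid, grp[[g]]]
        st <- box_stats(xrow)
        yb <- yc + if (g == "control") -7 else 7
        rows[[length(rows) + 1L]] <- drawing_row(
          "segment", "de_whisker", "middle", pscale$x(st$lo), pscale$x(st$hi), yb, yb,
          transcript_id = tid, group = g, fill = ISO_PALETTE[[g]]
        )
        rows[[length(rows) + 1L]] <- drawing_row(
          "rect", "de_box", "middle", pscale$x(st$q1), pscale$x(st$q3), yb - 5, yb + 5,
          transcript_id = tid, group = g, value = st$med, fill = ISO_PALETTE[[g]]
        )
        rows[[length(rows) + 1L]] <- drawing_row(
          "segment", "de_median", "middle", pscale$x(st$med), pscale$x(st$med), yb - 5, yb + 5,
          transcript_id = tid, group = g, value = st$med, fill = ISO_PALETTE[["text"]]
        )
      }
    } else {
      rows[[length(rows) + 1L]] <- drawing_row(
        "text", "de_missing", "middle", x_off, x_off, yc, yc,
        transcript_id = tid, label = "n/a", fill = ISO_PALETTE[["text"]]
      )
    }
    j <- match(tid, de_table$transcript_id)
    lab <- if (is.na(j)) {
      "n/a"
    } else {
      sprintf(
        "q=%.2g log2FC=%+.2f%s", de_table$q[j], de_table$log2fc[j],
        if (de_table$q[j] < alpha) " *" else ""
      )
    }
    rows[[length(rows) + 1L]] <- drawing_row(
      "text", "de_label", "right", x_off + MID_W + PANEL_GAP, x_off + MID_W + PANEL_GAP, yc, yc,
      transcript_id = tid, value = if (is.na(j)) NA else de_table$q[j],
      label = lab, fill = ISO_PALETTE[["text"]]
    )
  }
  rows[[length(rows) + 1L]] <- drawing_row(
    "text", "axis_label", "middle", x_off, x_off, (length(ids) + 1) * ROW_H,
    (length(ids) + 1) * ROW_H, label = "log2 CPM", fill = ISO_PALETTE[["text"]]
  )
  new_drawing(rows,
    width = LABEL_W + x_off + MID_W + PANEL_GAP + RIGHT_W,
    height = attr(loc, "height"),
    scales = c(sc, list(de_scale = pscale[c("lo", "hi")], x_off = x_off))
  )
}

counts_like_matrix <- function(wide) {
  wide <- tibble::as_tibble(wide)
  m <- as.matrix(wide[setdiff(names(wide), "transcript_id")])
  rownames(m) <- wide$transcript_id
  m
}

#' Differential-usage panel
#'
#' Left: the shared locus track. Middle: per-isoform mean-usage bars for the
#' two groups on a fixed 0-1 scale. Right: signed usage-difference bars
#' annotated with the transcript p-value and the usage change in percentage
#' points; confirmed transcripts carry a `*` mark.
#'
#' @inheritParams build_de_panel
#' @param diu_table DIU results for this gene ([write_diu_table()] schema).
#' @return an `iso_drawing`.
#' @export
build_diu_panel <- function(models, gene_id, diu_table, sort_order = NULL) {
  loc <- build_locus_track(models, gene_id, with_features = FALSE, sort_order = sort_order)
  sc <- attr(loc, "scales")
  ids <- sc$lane_ids
  d <- diu_table[diu_table$transcript_id %in% ids, ]
  if (!nrow(d)) {
    iso_abort(paste0("gene has no usage results (skipped or unknown): ", gene_id), "lookup")
  }
  x_off <- sc$span + PANEL_GAP
  rows <- list(loc)
  dx_off <- x_off + MID_W + PANEL_GAP
  half <- RIGHT_W / 3
  zero_x <- dx_off + half
  for (i in seq_along(ids)) {
    tid <- ids[i]
    yc <- i * ROW_H
    j <- match(tid, d$transcript_id)
    if (is.na(j)) next
    for (g in c("control", "case")) {
      u <- if (g == "control") d$usage_control[j] else d$usage_case[j]
      yb <- yc + if (g == "control") -7 else 2
      rows[[length(rows) + 1L]] <- drawing_row(
        "rect", "usage_bar", "middle", x_off, x_off + u * MID_W, yb, yb + 5,
        transcript_id = tid, group = g, value = u, fill = ISO_PALETTE[[g]]
      )
    }
    du <- d$delta_usage[j]
    rows[[length(rows) + 1L]] <- drawing_row(
      "rect", "delta_bar", "right", zero_x, zero_x + du * half, yc - 5, yc + 5,
      transcript_id = tid, value = du,
      fill = if (du >= 0) ISO_PALETTE[["case"]] else ISO_PALETTE[["control"]]
    )
    rows[[length(rows) + 1L]] <- drawing_row(
      "text", "diu_label", "right", zero_x + half + 12, zero_x + half + 12, yc, yc,
      transcript_id = tid, value = d$tx_p[j],
      label = sprintf(
        "p=%.2g Δ=%+.1fpp%s", d$tx_p[j], 100 * du,
        if (isTRUE(d$confirmed[j])) " *" else ""
      ),
      fill = ISO_PALETTE[["text"]]
    )
  }
  rows[[length(rows) + 1L]] <- drawing_row(
    "segment", "delta_zero", "right", zero_x, zero_x,
    ROW_H / 2, length(ids) * ROW_H + ROW_H / 2, fill = ISO_PALETTE[["intron"]]
  )
  rows[[length(rows) + 1L]] <- drawing_row(
    "text", "axis_label", "middle", x_off, x_off, (length(ids) + 1) * ROW_H,
    (length(ids) + 1) * ROW_H, label = "mean usage (0-1)", fill = ISO_PALETTE[["text"]]
  )
  new_drawing(rows,
    width = LABEL_W + dx_off + RIGHT_W + PANEL_GAP,
    height = attr(loc, "height"),
    scales = c(sc, list(x_off = x_off, zero_x = zero_x))
  )
}

#' Functional-feature panel
#'
#' Left: the locus track with positional features drawn as styled sub-boxes at
#' their projected display coordinates. Right: one column per non-positional
#' attribute - binary values as presence glyphs (false renders nothing),
#' categorical values as text tags, continuous values as horizontal bars
#' scaled to the column maximum.
#'
#' @inheritParams build_locus_track
#' @param nonpositional optional tidy non-positional table
#'   ([load_features()]`$nonpositional`); defaults to the `np_*` attributes
#'   stored in `models`.
#' @return an `iso_drawing`.
#' @export
build_ff_panel <- function(models, gene_id, nonpositional = NULL, sort_order = NULL) {
  loc <- build_locus_track(models, gene_id, with_features = TRUE, sort_order = sort_order)
  sc <- attr(loc, "scales")
  ids <- sc$lane_ids
  np <- nonpositional %||% nonpositional_from_models(models)
  np <- np[np$transcript_id %in% ids, ]
  cols <- unique(np$name)
  col_w <- if (length(cols)) RIGHT_W / length(cols) else RIGHT_W
  x_off <- sc$span + PANEL_GAP
  rows <- list(loc)
  for (ci in seq_along(cols)) {
    cx <- x_off + (ci - 1) * col_w
    sub <- np[np$name == cols[ci], ]
    rows[[length(rows) + 1L]] <- drawing_row(
      "text", "ff_header", "right", cx, cx, ROW_H / 2, ROW_H / 2,
      key = cols[ci], label = cols[ci], fill = ISO_PALETTE[["text"]]
    )
    col_max <- if (any(sub$dtype == "continuous")) max(sub$value_num, na.rm = TRUE) else NA
    for (i in seq_along(ids)) {
      j <- which(sub$transcript_id == ids[i])
      if (!length(j)) next
      j <- j[1]
      yc <- i * ROW_H
      if (sub$dtype[j] == "binary") {
        if (isTRUE(sub$value_bool[j])) {
          rows[[length(rows) + 1L]] <- drawing_row(
            "rect", "ff_binary", "right", cx, cx + 10, yc - 5, yc + 5,
            transcript_id = ids[i], key = cols[ci], value = 1,
            fill = ISO_PALETTE[["exon_cds"]]
          )
        }
      } else if (sub$dtype[j] == "categorical") {
        rows[[length(rows) + 1L]] <- drawing_row(
          "text", "ff_tag", "right", cx, cx, yc, yc,
          transcript_id = ids[i], key = cols[ci], label = sub$value[j],
          fill = ISO_PALETTE[["text"]]
        )
      } else {
        frac <- if (col_max > 0) sub$value_num[j] / col_max else 0
        rows[[length(rows) + 1L]] <- drawing_row(
          "rect", "ff_bar", "right", cx, cx + frac * (col_w - 15), yc - 5, yc + 5,
          transcript_id = ids[i], key = cols[ci], value = sub$value_num[j],
          fill = ISO_PALETTE[["bar"]]
        )
      }
    }
  }
  new_drawing(rows,
    width = LABEL_W + x_off + RIGHT_W + PANEL_GAP,
    height = attr(loc, "height"),
    scales = c(sc, list(x_off = x_off))
  )
}

# --- output ---------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_fmt <- function(x) sprintf("%.2f", x)

#' Serialize a drawing to deterministic SVG
#'
#' Identical drawings produce byte-identical files: numbers are formatted with
#' fixed precision, fonts are referenced by family name only, and no
#' timestamps or ids are embedded.
#'
#' @param drawing an `iso_drawing`.
#' @param path output path.
#' @export
svg_write <- function(drawing, path) {
  w <- attr(drawing, "width")
  h <- attr(drawing, "height")
  xmin <- attr(drawing, "xmin")
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="%s 0 %s %s">',
      svg_fmt(w), svg_fmt(h), svg_fmt(xmin), svg_fmt(w), svg_fmt(h)
    )
  )
  for (i in seq_len(nrow(drawing))) {
    r <- drawing[i, ]
    if (r$element == "rect") {
      out <- c(out, sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
        svg_fmt(min(r$x0, r$x1)), svg_fmt(min(r$y0, r$y1)),
        svg_fmt(abs(r$x1 - r$x0)), svg_fmt(abs(r$y1 - r$y0)), r$fill
      ))
    } else if (r$element == "segment") {
      out <- c(out, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1.5"/>',
        svg_fmt(r$x0), svg_fmt(r$y0), svg_fmt(r$x1), svg_fmt(r$y1), r$fill
      ))
    } else if (r$element == "text") {
      out <- c(out, sprintf(
        '<text x="%s" y="%s" font-family="monospace" font-size="11" text-anchor="%s" fill="%s">%s</text>',
        svg_fmt(r$x0), svg_fmt(r$y0 + 4), r$anchor, r$fill, xml_escape(r$label)
      ))
    }
  }
  out <- c(out, "</svg>")
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' Plot a drawing with ggplot2
#'
#' @param object an `iso_drawing`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.iso_drawing <- function(object, ...) {
  d <- tibble::as_tibble(object)
  rects <- d[d$element == "rect", ]
  segs <- d[d$element == "segment", ]
  txts <- d[d$element == "text", ]
  txts$hjust <- ifelse(txts$anchor == "end", 1, ifelse(txts$anchor == "middle", 0.5, 0))
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = pmin(.data$x0, .data$x1), xmax = pmax(.data$x0, .data$x1),
                   ymin = pmin(.data$y0, .data$y1), ymax = pmax(.data$y0, .data$y1),
                   fill = .data$fill)
    ) +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$x0, xend = .data$x1, y = .data$y0, yend = .data$y1,
                   colour = .data$fill)
    ) +
    ggplot2::geom_text(
      data = txts,
      ggplot2::aes(x = .data$x0, y = .data$y0, label = .data$label, hjust = .data$hjust),
      size = 3, family = "mono"
    ) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_colour_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_void()
}

#' Render a figure to disk
#'
#' `svg` uses the deterministic serializer ([svg_write()]); `png` and `pdf`
#' render through ggplot2 devices.
#'
#' @param drawing an `iso_drawing`.
#' @param path output path.
#' @param format one of `svg`, `png`, `pdf`.
#' @export
save_figure <- function(drawing, path, format = c("svg", "png", "pdf")) {
  format <- match.arg(format)
  if (format == "svg") return(svg_write(drawing, path))
  p <- autoplot(drawing)
  w_in <- attr(drawing, "width") / 72
  h_in <- attr(drawing, "height") / 72
  ggplot2::ggsave(path, p, width = w_in, height = h_in, units = "in",
                  device = format, dpi = 150, limitsize = FALSE)
  invisible(path)
}

#' Tidy export of a drawing
#'
#' @param x an `iso_drawing`.
#' @param path TSV path.
#' @export
write_drawing <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
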