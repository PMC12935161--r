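toy_panels <- function() {
  toy <- make_toy_locus()
  models <- merge_into_annotation(toy$models, toy$features)
  fac <- tmm_factors(toy$counts)
  lc <- cpm(toy$counts, fac, log = TRUE)
  de <- de_test(toy$counts, toy$design)
  diu <- diu_test(toy$counts, toy$design, toy$models)
  list(toy = toy, models = models, lc = lc, de = de, diu = diu)
}

test_that("locus track geometry reads back exon widths and deduped TSS guides", {
  p <- toy_panels()
  loc <- build_locus_track(p$models, "TOYG1")
  exons <- loc[loc$role == "exon", ]
  expect_equal(exons$x1 - exons$x0, exons$value) # display width == genomic length
  # TOYT01/02/04 share the TSS at 1000; TOYT03 starts at 6300 -> 2 guides
  expect_equal(sum(loc$role == "tss_guide"), 2L)
  guides <- loc[loc$role == "tss_guide", ]
  dmap <- build_display_map(p$models, "TOYG1")
  expect_setequal(round(guides$x0, 6), round(display_pos(dmap, c(1000, 6300)), 6))
  # every intron in the display map occupies exactly 100 units
  segs <- dmap$segments[dmap$segments$type == "intron", ]
  expect_true(all(abs((segs$d_end - segs$d_start) - 100) < 1e-9))
  # transcripts without CDS render all-thin
  no_cds <- tx_models(p$toy$models$transcripts, p$toy$models$exons)
  loc2 <- build_locus_track(no_cds, "TOYG1")
  expect_equal(sum(loc2$role == "cds"), 0L)
  expect_gt(sum(loc2$role == "exon"), 0L)
})

test_that("DE panel box plots match brute-force medians and mark significance", {
  p <- toy_panels()
  drawing <- build_de_panel(p$models, "TOYG1", tidy(p$de), p$lc, p$toy$design)
  med <- drawing[drawing$role == "de_median", ]
  lcm <- as.matrix(p$lc[, -1])
  rownames(lcm) <- p$lc$transcript_id
  for (i in seq_len(nrow(med))) {
    cols <- if (med$group[i] == "control") 1:6 else 7:12
    expect_equal(med$value[i], median(lcm[med$transcript_id[i], cols]), tolerance = 1e-12)
  }
  labs <- drawing[drawing$role == "de_label", ]
  starred <- grepl("\\*", labs$label)
  q <- tidy(p$de)$q[match(labs$transcript_id, tidy(p$de)$transcript_id)]
  expect_equal(unname(starred), unname(q < 0.05))

  # q above threshold must not be starred even when present
  fake <- tidy(p$de)
  fake$q[] <- 0.2
  d2 <- build_de_panel(p$models, "TOYG1", fake, p$lc, p$toy$design)
  expect_false(any(grepl("\\*", d2[d2$role == "de_label", ]$label)))

  # missing expression renders n/a, not an error
  lc_missing <- p$lc[p$lc$transcript_id != "TOYT03", ]
  d3 <- build_de_panel(p$models, "TOYG1", tidy(p$de), lc_missing, p$toy$design)
  expect_true(any(d3$role == "de_missing" & d3$transcript_id == "TOYT03"))
})

test_that("usage panel bars sum to one per group and annotate confirmation", {
  p <- toy_panels()
  drawing <- build_diu_panel(p$models, "TOYG1", tidy(p$diu))
  bars <- drawing[drawing$role == "usage_bar", ]
  sums <- tapply(bars$value, bars$group, sum)
  expect_equal(unname(sums[["control"]]), 1, tolerance = 1e-9)
  expect_equal(unname(sums[["case"]]), 1, tolerance = 1e-9)
  delta <- drawing[drawing$role == "delta_bar", ]
  m <- match(c("TOYT01", "TOYT04"), delta$transcript_id)
  expect_equal(delta$value[m], c(-0.3, 0.3), tolerance = 1e-9)
  labs <- drawing[drawing$role == "diu_label", ]
  conf <- tidy(p$diu)
  starred <- grepl("\\*", labs$label)
  expect_equal(starred, conf$confirmed[match(labs$transcript_id, conf$transcript_id)])
  expect_error(build_diu_panel(p$models, "TOYG1", conf[0, ]), class = "isoscope_lookup")
})

test_that("feature panel encodes binary, categorical and continuous columns", {
  p <- toy_panels()
  drawing <- build_ff_panel(p$models, "TOYG1")
  # positional features appear as locus sub-boxes aligned to projections
  featrows <- drawing[drawing$role == "feature", ]
  expect_equal(nrow(featrows), 7L)
  doma <- featrows[featrows$key == "DOM_A" & featrows$transcript_id == "TOYT01", ]
  expect_equal(nrow(doma), 2L) # junction-spanning domain drawn in 2 segments
  expect_equal(sum(doma$value), 3 * 51)
  # binary false -> empty cell; true -> one glyph
  bin <- drawing[drawing$role == "ff_binary", ]
  expect_equal(bin$transcript_id, "TOYT03")
  # continuous bars max-normalize to the column maximum
  bars <- drawing[drawing$role == "ff_bar", ]
  top <- bars[which.max(bars$value), ]
  expect_equal(top$transcript_id, "TOYT01")
  widths <- bars$x1 - bars$x0
  expect_equal(widths / max(widths), bars$value / max(bars$value), tolerance = 1e-9)
  # categorical tags as text
  expect_equal(sum(drawing$role == "ff_tag"), 4L)

  # single-transcript continuous column -> full-width bar
  one <- p$models
  np1 <- tibble::tibble(
    transcript_id = "TOYT02", name = "score", dtype = "continuous",
    value = "7.5", value_num = 7.5, value_bool = NA
  )
  d1 <- build_ff_panel(one, "TOYG1", nonpositional = np1)
  b1 <- d1[d1$role == "ff_bar", ]
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$value / max(b1$value), 1)
})

test_that("rendering is deterministic and matches the golden SVG", {
  p <- toy_panels()
  drawing <- build_de_panel(p$models, "TOYG1", tidy(p$de), p$lc, p$toy$design)
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  svg_write(drawing, f1)
  svg_write(build_de_panel(p$models, "TOYG1", tidy(p$de), p$lc, p$toy$design), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)), readBin(f2, "raw", file.size(f2)))
  golden <- test_path("golden", "toy-de-panel.svg")
  expect_identical(readLines(f1), readLines(golden))
})

test_that("drawings export to ggplot and tidy TSV", {
  p <- toy_panels()
  drawing <- build_ff_panel(p$models, "TOYG1")
  gg <- autoplot(drawing)
  expect_s3_class(gg, "ggplot")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_drawing(drawing, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(drawing))
})
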