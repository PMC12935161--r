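toy_usage_models <- function() {
  tx_models(
    tibble::tibble(
      transcript_id = c("A1", "A2", "B1", "C1", "C2"),
      gene_id = c("GA", "GA", "GB", "GC", "GC"),
      gene_name = NA_character_, chrom = "chr1", strand = "+",
      cds_incomplete = FALSE,
      attributes = rep(list(character()), 5)
    ),
    tibble::tibble(
      transcript_id = c("A1", "A2", "B1", "C1", "C2"),
      start = c(0L, 0L, 100L, 200L, 200L), end = c(50L, 50L, 150L, 250L, 250L)
    )
  )
}

test_that("usage tables carry proportions and exclusion reasons", {
  m <- rbind(
    A1 = c(30L, 40L), A2 = c(70L, 60L),
    B1 = c(50L, 50L), # single-transcript gene -> excluded
    C1 = c(1L, 2L), C2 = c(2L, 1L) # low total -> excluded
  )
  tabs <- build_usage_tables(wide_counts(m, rownames(m)), toy_usage_models(), min_gene_count = 10)
  expect_equal(tabs$gene_id, "GA")
  Y <- tabs$counts[[1]]
  expect_equal(unname(Y[1, ] / sum(Y[1, ])), c(0.3, 0.7))
  exc <- attr(tabs, "excluded")
  expect_setequal(exc$gene_id, c("GB", "GC"))
  expect_equal(exc$reason[exc$gene_id == "GB"], "fewer_than_two_expressed_transcripts")
  expect_equal(exc$reason[exc$gene_id == "GC"], "low_gene_count")
  expect_error(
    build_usage_tables(wide_counts(m, c(rownames(m)[-5], "ZZ")), toy_usage_models()),
    "ZZ", class = "isoscope_validation"
  )
})

test_that("the DM fit is symmetric, matches the log-gamma pmf, and recovers truth", {
  f <- fit_dm(rbind(c(5, 5)))
  expect_equal(f$proportions, c(0.5, 0.5), tolerance = 1e-6)

  Yt <- rbind(c(2, 1), c(0, 3))
  a <- c(1.2, 0.8)
  expect_equal(isoscope:::dm_loglik(Yt, a), oracle_dm_loglik(Yt, a), tolerance = 1e-12)
  expect_error(fit_dm(matrix(1:4, 4, 1)), class = "isoscope_domain")

  set.seed(51)
  truth <- c(0.7, 0.2, 0.1)
  Y <- t(sapply(1:40, function(i) rmultinom(1, 200, rdirichlet_one(50 * truth))))
  f2 <- fit_dm(Y)
  expect_true(all(abs(f2$proportions - truth) < 0.05))
  expect_equal(sum(f2$proportions), 1, tolerance = 1e-9)
  g <- glance(f2)
  expect_true(g$precision > 10 && g$precision < 250)
})

test_that("the DM likelihood approaches the multinomial limit at high precision", {
  set.seed(52)
  Y <- t(sapply(1:5, function(i) rmultinom(1, 100, c(0.5, 0.3, 0.2))))
  p <- c(0.5, 0.3, 0.2)
  ll_dm <- isoscope:::dm_loglik(Y, 1e6 * p)
  ll_mn <- sum(apply(Y, 1, function(y) stats::dmultinom(y, prob = p, log = TRUE)))
  expect_lt(abs(ll_dm - ll_mn) / nrow(Y), 1e-3)
})

test_that("gene LRT is null-centered for identical groups and label-symmetric", {
  Y <- rbind(c(10, 20), c(12, 18), c(9, 21), c(11, 19))
  Y2 <- rbind(Y, Y)
  r <- gene_lrt(Y2, list(control = 1:4, case = 5:8))
  expect_lt(r$statistic, 1e-4)
  expect_gt(r$p, 0.99)
  set.seed(53)
  Yr <- t(sapply(1:12, function(i) rmultinom(1, 150, rdirichlet_one(c(4, 3, 2)))))
  r1 <- gene_lrt(Yr, list(control = 1:6, case = 7:12))
  r2 <- gene_lrt(Yr, list(control = 7:12, case = 1:6))
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-6)
  expect_equal(r$df, 1L)
  expect_error(gene_lrt(Y, list(control = 1L, case = 2:4)), class = "isoscope_domain")
})

test_that("transcript-level p-values are complementary for two-isoform genes", {
  set.seed(54)
  Y <- t(sapply(1:10, function(i) rmultinom(1, 100, c(0.4, 0.6))))
  gi <- list(control = 1:5, case = 6:10)
  p1 <- transcript_test(Y, gi, 1)$p
  p2 <- transcript_test(Y, gi, 2)$p
  # the two collapses are mirrored optimization problems; agreement is limited
  # by the quasi-Newton tolerance
  expect_equal(p1, p2, tolerance = 1e-3)
})

test_that("a planted usage shift is detected with high power", {
  set.seed(55)
  hits <- replicate(40, {
    p <- c(0.5, 0.3, 0.2)
    q <- c(0.2, 0.6, 0.2)
    Y <- t(sapply(1:40, function(i) {
      rmultinom(1, 300, rdirichlet_one(50 * (if (i <= 20) p else q)))
    }))
    transcript_test(Y, list(control = 1:20, case = 21:40), 1)$p < 0.05
  })
  expect_gt(mean(hits), 0.8)
})

test_that("stage-wise correction gatekeeps confirmation behind screening", {
  # no gene passes screening -> nothing confirmed
  g <- tibble::tibble(gene_id = c("g1", "g2"), p = c(0.6, 0.9))
  t <- tibble::tibble(gene_id = c("g1", "g1", "g2"), transcript_id = c("a", "b", "c"),
                      p = c(0.001, 0.5, 0.01))
  sw <- stagewise_correct(g, t, alpha = 0.05)
  expect_false(any(sw$transcripts$confirmed))
  expect_true(all(is.na(sw$transcripts$p_adjusted)))

  # one gene, one transcript, p = 0.001 -> confirmed at alpha 0.05
  sw2 <- stagewise_correct(
    tibble::tibble(gene_id = "g1", p = 0.001),
    tibble::tibble(gene_id = "g1", transcript_id = "a", p = 0.001),
    alpha = 0.05
  )
  expect_true(sw2$genes$screened)
  expect_true(sw2$transcripts$confirmed)
  expect_equal(sw2$transcripts$p_adjusted, 0.001)

  expect_error(
    stagewise_correct(g, tibble::tibble(gene_id = "gX", transcript_id = "z", p = 0.5)),
    class = "isoscope_validation"
  )
})

test_that("delta usage is a difference of per-group mean proportions", {
  Y <- rbind(c(30, 70), c(30, 70), c(60, 40), c(60, 40))
  gi <- list(control = 1:2, case = 3:4)
  du <- delta_usage(Y, gi)
  expect_equal(du$delta_usage, c(0.3, -0.3))
  expect_equal(sum(du$usage_control), 1, tolerance = 1e-9)
  expect_equal(sum(du$usage_case), 1, tolerance = 1e-9)
  du0 <- delta_usage(rbind(Y[1:2, ], Y[1:2, ]), gi)
  expect_equal(du0$delta_usage, c(0, 0))
  set.seed(56)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    Yr <- matrix(rpois(8 * k, 30) + 1L, 8, k)
    dur <- delta_usage(Yr, list(control = 1:4, case = 5:8))
    expect_equal(sum(dur$delta_usage), 0, tolerance = 1e-9)
  }
})

test_that("the full usage pipeline confirms the toy switch and round-trips", {
  toy <- make_toy_locus()
  diu <- diu_test(toy$counts, toy$design, toy$models)
  td <- tidy(diu)
  m <- match(toy$expected$transcript_ids, td$transcript_id)
  expect_equal(td$delta_usage[m], toy$expected$delta_usage, tolerance = 1e-9)
  expect_equal(td$usage_control[m], toy$expected$usage_control, tolerance = 1e-9)
  # confirmed implies screened
  expect_true(all(!td$confirmed | td$screened))
  expect_true(td$confirmed[m][1] && td$confirmed[m][4])

  path <- withr::local_tempfile(fileext = ".tsv")
  write_diu_table(diu, path)
  back <- load_diu_table(path)
  expect_equal(nrow(back), 4L)
  expect_equal(sort(back$delta_usage), sort(td$delta_usage), tolerance = 1e-9)
  g <- glance(diu)
  expect_equal(g$n_genes, 1L)
})
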