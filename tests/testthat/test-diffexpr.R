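test_that("TMM factors are one for composition-identical samples", {
  set.seed(41)
  base <- rnbinom(500, mu = 200, size = 5) + 1L
  m <- cbind(base, base * 2L, base, base)
  f <- tmm_factors(wide_counts(m))
  expect_equal(f$norm_factor, rep(1, 4), tolerance = 1e-12)
  expect_equal(f$lib_size, unname(colSums(m)))
  m2 <- cbind(base, base, base)
  expect_equal(tmm_factors(wide_counts(m2))$norm_factor, rep(1, 3))
  expect_error(tmm_factors(wide_counts(cbind(base, base * 0L))), class = "isoscope_validation")
})

test_that("TMM matches the direct trimmed weighted-mean formula and edgeR", {
  set.seed(42)
  for (rep in 1:50) {
    m <- matrix(rnbinom(200 * 4, mu = rexp(200, 1 / 150), size = 3), 200, 4)
    m[cbind(sample(200, 4), 1:4)] <- 0 # sprinkle zeros
    if (any(colSums(m) == 0)) next
    f <- tmm_factors(wide_counts(m))$norm_factor
    expect_equal(f, oracle_tmm(m), tolerance = 1e-8)
  }
  skip_if_not_installed("edgeR")
  set.seed(43)
  for (rep in 1:5) {
    m <- matrix(rnbinom(1000 * 6, mu = rexp(1000, 1 / 200), size = 5), 1000, 6)
    expect_equal(
      tmm_factors(wide_counts(m))$norm_factor,
      unname(edgeR::calcNormFactors(m, method = "TMM")),
      tolerance = 1e-10
    )
  }
  # geometric mean is one and factors are permutation-equivariant
  set.seed(44)
  m <- matrix(rnbinom(800 * 5, mu = 150, size = 2), 800, 5)
  f <- tmm_factors(wide_counts(m))$norm_factor
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  perm <- c(3, 1, 5, 2, 4)
  fp <- tmm_factors(wide_counts(m[, perm]))$norm_factor
  expect_equal(fp, f[perm], tolerance = 1e-12)
})

test_that("cpm applies the prior/effective-library formula", {
  m <- matrix(c(100L, 0L), 1, 2, dimnames = list(NULL, c("a", "b")))
  fac <- tibble::tibble(sample_id = c("a", "b"), lib_size = c(1e6, 1e6), norm_factor = c(1, 1))
  out <- cpm(wide_counts(m), fac, prior = 0.5)
  expect_equal(out$a, 100.5)
  expect_equal(out$b, 0.5)
  expect_true(all(as.matrix(out[, -1]) > 0))
  # row reordering commutes with the column operation
  set.seed(45)
  mm <- matrix(rpois(50 * 3, 20), 50, 3)
  w <- wide_counts(mm)
  o <- sample(50)
  expect_equal(cpm(w[o, ])[, -1], cpm(w)[o, -1])
})

test_that("dispersion estimation recovers simulated values and trends", {
  set.seed(46)
  n <- 20L
  G <- 2000L
  mu <- rexp(G, 1 / 150) + 20
  m <- matrix(rnbinom(G * 2L * n, mu = rep(mu, 2L * n), size = 1 / 0.1), G, 2L * n)
  cts <- wide_counts(m)
  des <- two_group_design(n)
  fac <- tmm_factors(cts)
  d <- estimate_dispersions(cts, des, fac)
  expect_gt(median(d$dispersion), 0.05)
  expect_lt(median(d$dispersion), 0.2)

  mp <- matrix(rpois(1000L * 2L * n, rep(mu[1:1000], 2L * n)), 1000L, 2L * n)
  dp <- estimate_dispersions(wide_counts(mp), des, tmm_factors(wide_counts(mp)))
  expect_lt(median(dp$dispersion), 0.05)

  # constant counts: no overdispersion evidence -> raw estimate at grid floor
  mc <- matrix(50L, 10, 2L * n)
  dc <- estimate_dispersions(wide_counts(mc), des, tmm_factors(wide_counts(mc)))
  expect_equal(unique(dc$dispersion_raw), 1e-3, tolerance = 1e-9)
})

test_that("identical groups give near-null DE results", {
  set.seed(47)
  base <- rnbinom(300, mu = 200, size = 5) + 5L
  m <- matrix(rep(base, 8), ncol = 8)
  de <- de_test(wide_counts(m), two_group_design(4))
  expect_equal(de$table$log2fc, rep(0, nrow(de$table)), tolerance = 1e-9)
  expect_true(all(de$table$p > 0.9))
  expect_false(any(de$table$significant))
})

test_that("label swap negates log2fc and preserves p-values", {
  set.seed(48)
  cfg <- sim_config(seed = 48, n_genes = 60, n_samples = 5, frac_de = 0.2, frac_diu = 0)
  sim <- simulate_annotation(cfg)
  cts <- simulate_counts(sim$models, cfg)
  fac <- tmm_factors(cts$counts)
  de1 <- de_test(cts$counts, cts$design)
  swapped <- sample_design(tibble::as_tibble(cts$design), control = "case")
  de2 <- de_test(cts$counts, swapped)
  m <- match(de1$table$transcript_id, de2$table$transcript_id)
  expect_equal(de2$table$log2fc[m], -de1$table$log2fc, tolerance = 1e-9)
  expect_equal(de2$table$p[m], de1$table$p, tolerance = 1e-9)
})

test_that("a four-fold shift is recovered as log2fc near two", {
  set.seed(49)
  n <- 8L
  G <- 600L
  mu <- rexp(G, 1 / 200) + 30
  mcase <- matrix(rnbinom(G * n, mu = rep(mu * 4, n), size = 10), G, n)
  mctrl <- matrix(rnbinom(G * n, mu = rep(mu, n), size = 10), G, n)
  m <- cbind(mctrl, mcase)
  des <- two_group_design(n)
  # equal library compositions here, so use unit factors to isolate the effect
  fac <- tibble::tibble(
    sample_id = des$sample_id,
    lib_size = rep(mean(colSums(m)), 2L * n), norm_factor = 1
  )
  de <- de_test(wide_counts(m), des, factors = fac)
  expect_lt(abs(median(de$table$log2fc) - 2), 0.3)
  expect_gt(mean(de$table$significant), 0.9)
})

test_that("bh_adjust equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(50)
  for (rep in 1:20) {
    p <- runif(sample(3:50, 1))
    a <- bh_adjust(p)
    expect_equal(a, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(a >= p - 1e-12) && all(a <= 1))
    expect_true(all(diff(a[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 0)), class = "isoscope_domain")
})

test_that("DE tables round trip and enforce the q >= p invariant", {
  d <- tibble::tibble(
    transcript_id = c("t1", "t2"), log2fc = c(1.5, -0.2),
    p = c(0.001, 0.2), q = c(0.002, 0.2), mean_expr = c(5, 2),
    significant = c(TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_de_table(d, path)
  back <- load_de_table(path)
  expect_equal(back$log2fc, d$log2fc)
  expect_equal(back$mean_expr, d$mean_expr) # extra columns preserved

  bad <- d
  bad$q[1] <- 1e-5
  path2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(bad, path2)
  expect_error(load_de_table(path2), "q >= p", class = "isoscope_validation")
  readr::write_tsv(d[, c("transcript_id", "p", "q")], path2)
  expect_error(load_de_table(path2), "log2fc", class = "isoscope_schema")
})
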