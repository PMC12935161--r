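# Two-group transcript-level differential expression: TMM normalization,
# grid-based NB dispersion estimation with trend shrinkage, and a moderated
# quasi-likelihood F test.

counts_to_matrix <- function(counts) {
  counts <- tibble::as_tibble(counts)
  if (!"transcript_id" %in% names(counts)) {
    iso_abort("counts must have a transcript_id column", "schema")
  }
  if (anyDuplicated(counts$transcript_id)) iso_abort("duplicate transcript ids in counts", "validation")
  m <- as.matrix(counts[setdiff(names(counts), "transcript_id")])
  if (anyDuplicated(colnames(m))) iso_abort("duplicate sample ids in counts", "validation")
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m != floor(m))) {
    iso_abort("counts must be non-negative integers", "validation")
  }
  rownames(m) <- counts$transcript_id
  m
}

#' Two-group sample design
#'
#' @param design data frame with columns `sample_id` and `group` (exactly two
#'   distinct labels, at least two samples each).
#' @param control the reference group label; defaults to the group of the
#'   first row (the group named first in a design file).
#' @return a validated tibble of class `sample_design` with attributes
#'   `control` and `case`.
#' @export
sample_design <- function(design, control = NULL) {
  design <- tibble::as_tibble(design)[, c("sample_id", "group")]
  if (anyDuplicated(design$sample_id)) iso_abort("duplicate sample ids in design", "validation")
  lv <- unique(design$group)
  if (length(lv) != 2L) iso_abort("design must have exactly two group labels", "validation")
  if (min(table(design$group)) < 2L) iso_abort("each group needs at least two samples", "validation")
  control <- control %||% design$group[1]
  if (!control %in% lv) iso_abort(paste0("control label not in design: ", control), "validation")
  structure(design, class = c("sample_design", class(design)),
            control = control, case = setdiff(lv, control))
}

design_groups <- function(design, sample_ids) {
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  i <- match(sample_ids, design$sample_id)
  if (anyNA(i)) {
    iso_abort(paste0("samples missing from design: ",
                     paste(sample_ids[is.na(i)], collapse = ", ")), "validation")
  }
  list(
    control = which(design$group[i] == attr(design, "control")),
    case = which(design$group[i] == attr(design, "case")),
    control_label = attr(design, "control"), case_label = attr(design, "case")
  )
}

# --- TMM -------------------------------------------------------------------

tmm_pair_factor <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]
  ref <- ref[keep]
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abs_trim) + 1
  hiS <- n + 1 - loS
  keep <- (rank(logR) >= loL & rank(logR) <= hiL) & (rank(absE) >= loS & rank(absE) <= hiS)
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' TMM normalization factors
#'
#' Trimmed mean of M values: the reference sample is the one whose
#' upper-quartile CPM is closest to the mean upper-quartile; per sample the
#' factor is `2^` the weighted (inverse asymptotic variance) mean of gene-wise
#' log2 ratios after trimming the extremes of M (`logratio_trim` each tail)
#' and of average abundance A (`abs_trim` each tail); transcripts with a zero
#' in either sample are excluded. Factors are rescaled to geometric mean 1.
#'
#' @param counts wide count table (column `transcript_id` + one column per
#'   sample, raw non-negative integers).
#' @param logratio_trim,abs_trim two-sided trim fractions for M and A.
#' @return tibble with columns `sample_id`, `lib_size`, `norm_factor`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  m <- counts_to_matrix(counts)
  lib <- colSums(m)
  if (any(lib <= 0)) iso_abort("all-zero sample in counts", "validation")
  m <- m[rowSums(m) > 0, , drop = FALSE] # all-zero transcripts carry no ratio information
  uq <- vapply(seq_len(ncol(m)), function(j) stats::quantile(m[, j], 0.75) / lib[j], 0)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(j) {
    if (j == ref) 1 else tmm_pair_factor(m[, j], m[, ref], lib[j], lib[ref], logratio_trim, abs_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  tibble::tibble(sample_id = colnames(m), lib_size = unname(lib), norm_factor = unname(f))
}

#' Counts per million
#'
#' `(count + prior) / (lib_size * norm_factor) * 1e6`, optionally on the log2
#' scale.
#'
#' @inheritParams tmm_factors
#' @param factors a [tmm_factors()] tibble; defaults to factors of 1.
#' @param prior prior count added before scaling.
#' @param log return log2 values.
#' @return tibble in the same wide shape as `counts`.
#' @export
cpm <- function(counts, factors = NULL, prior = 0.5, log = FALSE) {
  m <- counts_to_matrix(counts)
  lib <- colSums(m)
  nf <- rep(1, ncol(m))
  if (!is.null(factors)) {
    i <- match(colnames(m), factors$sample_id)
    if (anyNA(i)) iso_abort("factors missing samples present in counts", "validation")
    nf <- factors$norm_factor[i]
    lib <- factors$lib_size[i]
  }
  eff <- lib * nf
  out <- sweep(m + prior, 2, eff, "/") * 1e6
  if (log) out <- log2(out)
  dplyr::bind_cols(
    tibble::tibble(transcript_id = rownames(m)),
    tibble::as_tibble(out)
  )
}

# --- NB GLM machinery ------------------------------------------------------

# Vectorized per-transcript Newton fit of a common log-mean across columns
# `cols` with per-sample effective library sizes `eff` and per-transcript
# dispersion `phi`. Returns list(beta, mu) where mu is G x length(cols).
nb_fit_mean <- function(Y, eff, phi, cols, maxit = 50L, tol = 1e-10) {
  Ys <- Y[, cols, drop = FALSE]
  s <- eff[cols]
  beta <- log((rowSums(Ys) + 0.5) / sum(s))
  for (it in seq_len(maxit)) {
    mu <- exp(beta) %o% s
    denom <- 1 + phi * mu
    U <- rowSums((Ys - mu) / denom)
    I <- rowSums(mu / denom)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -3), 3)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  mu <- exp(beta) %o% s
  list(beta = beta, mu = mu)
}

nb_loglik <- function(Y, mu, phi) {
  r <- 1 / phi
  rowSums(lgamma(Y + r) - lgamma(r) - lfactorial(Y) +
            r * log(r / (r + mu)) + Y * log(pmax(mu, 1e-300) / (r + mu)))
}

nb_deviance <- function(Y, mu, phi) {
  r <- 1 / phi
  t1 <- ifelse(Y > 0, Y * log(Y / mu), 0)
  t2 <- (Y + r) * log((Y + r) / (mu + r))
  2 * rowSums(t1 - t2)
}

#' Estimate per-transcript NB dispersions
#'
#' Cox-Reid-style adjusted profile likelihood maximized over a fixed log-grid
#' (0.001-5, 41 points) with group-wise mean fits, then shrunk on the log
#' scale (weight 0.5) toward the mean trend in 20 abundance bins. Transcripts
#' with all-zero counts are excluded and reported as filtered upstream.
#'
#' @inheritParams tmm_factors
#' @param design a [sample_design()] (or coercible data frame).
#' @param factors a [tmm_factors()] tibble.
#' @return tibble: `transcript_id`, `dispersion`, `dispersion_raw`,
#'   `ave_log2_cpm`.
#' @export
estimate_dispersions <- function(counts, design, factors) {
  Y <- counts_to_matrix(counts)
  grp <- design_groups(design, colnames(Y))
  i <- match(colnames(Y), factors$sample_id)
  eff <- factors$lib_size[i] * factors$norm_factor[i]
  if (any(rowSums(Y) == 0)) iso_abort("all-zero transcripts must be filtered before dispersion estimation", "validation")
  grid <- exp(seq(log(1e-3), log(5), length.out = 41L))
  apl <- matrix(-Inf, nrow(Y), length(grid))
  for (g in seq_along(grid)) {
    phi <- rep(grid[g], nrow(Y))
    f1 <- nb_fit_mean(Y, eff, phi, grp$control)
    f2 <- nb_fit_mean(Y, eff, phi, grp$case)
    mu <- cbind(f1$mu, f2$mu)[, order(c(grp$control, grp$case))]
    ll <- nb_loglik(Y, mu, phi)
    w1 <- rowSums(f1$mu / (1 + grid[g] * f1$mu))
    w2 <- rowSums(f2$mu / (1 + grid[g] * f2$mu))
    apl[, g] <- ll - 0.5 * (log(pmax(w1, 1e-12)) + log(pmax(w2, 1e-12)))
  }
  raw <- grid[max.col(apl, ties.method = "first")]
  ave <- rowMeans(log2(sweep(Y + 0.5, 2, eff, "/") * 1e6))
  bins <- cut(rank(ave, ties.method = "first"), breaks = 20L, labels = FALSE)
  trend <- tapply(log(raw), bins, mean)
  shrunk <- as.numeric(exp(0.5 * log(raw) + 0.5 * trend[as.character(bins)]))
  tibble::tibble(
    transcript_id = rownames(Y),
    dispersion = shrunk,
    dispersion_raw = raw,
    ave_log2_cpm = ave
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement (delegates to
#' [stats::p.adjust()]).
#'
#' @param pvalues numeric vector in (0, 1].
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    iso_abort("p-values must lie in (0, 1]", "domain")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Low-expression filter
#'
#' Transcripts kept when their unadjusted CPM exceeds 1 in at least
#' `min(group sizes)` samples; all-zero transcripts always fail.
#'
#' @inheritParams estimate_dispersions
#' @return logical vector along the rows of `counts`.
#' @export
expression_filter <- function(counts, design, factors) {
  Y <- counts_to_matrix(counts)
  grp <- design_groups(design, colnames(Y))
  i <- match(colnames(Y), factors$sample_id)
  eff <- factors$lib_size[i] * factors$norm_factor[i]
  cpm0 <- sweep(Y, 2, eff, "/") * 1e6
  k <- min(length(grp$control), length(grp$case))
  rowSums(cpm0 > 1) >= k
}

#' Two-group quasi-likelihood differential expression test
#'
#' Per transcript, an NB GLM with a group effect and `log(lib_size *
#' norm_factor)` offsets is fit at the estimated dispersion; the deviance
#' difference between the full and intercept-only fit is converted to a
#' quasi-likelihood F statistic with an empirical-Bayes moderated residual
#' variance ([limma::squeezeVar()] with an abundance covariate). Low-expression
#' transcripts are excluded before testing and reported separately.
#'
#' @inheritParams estimate_dispersions
#' @param alpha significance threshold on BH-adjusted values.
#' @return an object of class `iso_de`; its `$table` is a tibble with
#'   `transcript_id`, `log2fc` (case vs control), `p`, `q`, `mean_expr`,
#'   `significant`, and `$filtered` lists excluded transcripts.
#' @export
de_test <- function(counts, design, factors = NULL, dispersions = NULL, alpha = 0.05) {
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  factors <- factors %||% tmm_factors(counts)
  keep <- expression_filter(counts, design, factors)
  counts <- tibble::as_tibble(counts)
  filtered <- counts$transcript_id[!keep]
  counts_kept <- counts[keep, ]
  if (!nrow(counts_kept)) iso_abort("no transcripts pass the expression filter", "validation")
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts_kept, design, factors)
  }
  Y <- counts_to_matrix(counts_kept)
  grp <- design_groups(design, colnames(Y))
  i <- match(colnames(Y), factors$sample_id)
  eff <- factors$lib_size[i] * factors$norm_factor[i]
  di <- match(rownames(Y), dispersions$transcript_id)
  if (anyNA(di)) iso_abort("dispersions missing for some tested transcripts", "validation")
  phi <- dispersions$dispersion[di]

  fit_c <- nb_fit_mean(Y, eff, phi, grp$control)
  fit_t <- nb_fit_mean(Y, eff, phi, grp$case)
  mu_full <- matrix(0, nrow(Y), ncol(Y))
  mu_full[, grp$control] <- fit_c$mu
  mu_full[, grp$case] <- fit_t$mu
  fit_0 <- nb_fit_mean(Y, eff, phi, seq_len(ncol(Y)))

  dev_full <- nb_deviance(Y, mu_full, phi)
  dev_null <- nb_deviance(Y, fit_0$mu, phi)
  df_res <- ncol(Y) - 2L
  s2 <- pmax(dev_full / df_res, 1e-8)
  ave <- dispersions$ave_log2_cpm[di]
  sq <- tryCatch(
    limma::squeezeVar(s2, df = df_res, covariate = ave),
    error = function(e) limma::squeezeVar(s2, df = df_res)
  )
  df_prior <- sq$df.prior
  if (length(df_prior) == 1L) df_prior <- rep(df_prior, length(s2))
  df_total <- pmin(df_res + df_prior, nrow(Y) * df_res)
  Fstat <- pmax(dev_null - dev_full, 0) / pmax(sq$var.post, 1e-12)
  p <- stats::pf(Fstat, 1, df_total, lower.tail = FALSE)
  p <- pmin(pmax(p, 1e-300), 1)
  q <- bh_adjust(p)
  tab <- tibble::tibble(
    transcript_id = rownames(Y),
    log2fc = unname((fit_t$beta - fit_c$beta) / log(2)),
    p = unname(p), q = unname(q), mean_expr = unname(ave),
    significant = unname(q < alpha)
  )
  structure(
    list(
      table = tab,
      filtered = filtered,
      alpha = alpha,
      design = design,
      factors = factors,
      dispersions = dispersions,
      groups = c(control = grp$control_label, case = grp$case_label)
    ),
    class = "iso_de"
  )
}

#' @export
print.iso_de <- function(x, ...) {
  cat(sprintf(
    "<iso_de> %d transcripts tested (%d filtered), %d significant at q < %g (case '%s' vs control '%s')\n",
    nrow(x$table), length(x$filtered), sum(x$table$significant), x$alpha,
    x$groups[["case"]], x$groups[["control"]]
  ))
  invisible(x)
}

# --- tool-agnostic DE result I/O ------------------------------------------

validate_de_table <- function(d) {
  need <- c("transcript_id", "log2fc", "p", "q")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    iso_abort(paste0("DE table missing required column(s): ", paste(miss, collapse = ", ")), "schema")
  }
  if (any(d$p <= 0 | d$p > 1, na.rm = TRUE) || any(d$q <= 0 | d$q > 1, na.rm = TRUE)) {
    iso_abort("DE table p/q values must lie in (0, 1]", "validation")
  }
  bad <- which(d$q < d$p - 1e-12)
  if (length(bad)) {
    iso_abort(sprintf("DE table row %d violates q >= p", bad[1]), "validation")
  }
  d
}

#' Read / write DE result tables (tool-agnostic TSV)
#'
#' Required columns: `transcript_id`, `log2fc`, `p`, `q`; extra columns are
#' preserved for display.
#'
#' @param path TSV path.
#' @export
load_de_table <- function(path) {
  validate_de_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname load_de_table
#' @param de an `iso_de` object or a data frame with the required columns.
#' @export
write_de_table <- function(de, path) {
  d <- if (inherits(de, "iso_de")) de$table else validate_de_table(tibble::as_tibble(de))
  readr::write_tsv(d, path)
  invisible(path)
}
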