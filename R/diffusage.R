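# Differential isoform usage: Dirichlet-multinomial likelihood-ratio tests
# within genes and a two-stage (screening/confirmation) FDR procedure.

#' Build per-gene usage tables
#'
#' One table per gene with at least two expressed transcripts. Genes whose
#' total count is below `min_gene_count` in more than half the samples are
#' excluded and reported; samples with a zero gene total are flagged per gene
#' and excluded from fitting.
#'
#' @inheritParams tmm_factors
#' @param models a [tx_models] object supplying the transcript-to-gene map.
#' @param min_gene_count minimum per-sample gene total.
#' @return an object of class `usage_tables`: a tibble with columns `gene_id`,
#'   `transcript_ids` (list), `counts` (list of samples x transcripts
#'   matrices), `samples` (list of retained sample ids); excluded genes in
#'   `attr(, "excluded")`.
#' @export
build_usage_tables <- function(counts, models, min_gene_count = 10) {
  Y <- counts_to_matrix(counts)
  gene_of <- models$transcripts$gene_id[match(rownames(Y), models$transcripts$transcript_id)]
  if (anyNA(gene_of)) {
    iso_abort(paste0(
      "transcripts in counts absent from models: ",
      paste(rownames(Y)[is.na(gene_of)], collapse = ", ")
    ), "validation")
  }
  excluded <- list()
  rows <- list()
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    expressed <- idx[rowSums(Y[idx, , drop = FALSE]) > 0]
    if (length(expressed) < 2L) {
      excluded[[g]] <- tibble::tibble(gene_id = g, reason = "fewer_than_two_expressed_transcripts")
      next
    }
    sub <- t(Y[expressed, , drop = FALSE]) # samples x transcripts
    tot <- rowSums(sub)
    if (sum(tot < min_gene_count) > ncol(Y) / 2) {
      excluded[[g]] <- tibble::tibble(gene_id = g, reason = "low_gene_count")
      next
    }
    keep <- tot > 0
    rows[[g]] <- tibble::tibble(
      gene_id = g,
      transcript_ids = list(rownames(Y)[expressed]),
      counts = list(sub[keep, , drop = FALSE]),
      samples = list(colnames(Y)[keep]),
      dropped_samples = list(colnames(Y)[!keep])
    )
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("usage_tables", class(out)),
            excluded = dplyr::bind_rows(excluded))
}

# --- Dirichlet-multinomial likelihood -------------------------------------

# log DM pmf summed over rows of Y (samples x k) at alpha (length k, > 0),
# including the multinomial coefficient.
dm_loglik <- function(Y, alpha) {
  A <- sum(alpha)
  n <- rowSums(Y)
  sum(lgamma(n + 1) - rowSums(lgamma(Y + 1)) +
        lgamma(A) - lgamma(n + A) +
        rowSums(lgamma(sweep(Y, 2, alpha, "+"))) - sum(lgamma(alpha)))
}

# gradient of dm_loglik wrt alpha
dm_grad_alpha <- function(Y, alpha) {
  A <- sum(alpha)
  n <- rowSums(Y)
  nr <- nrow(Y)
  colSums(digamma(sweep(Y, 2, alpha, "+"))) - nr * digamma(alpha) +
    nr * digamma(A) - sum(digamma(n + A))
}

softmax_k <- function(z) {
  # z has length k-1; category k is the reference
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

# Fit a DM model by bounded quasi-Newton on (logit proportions, log precision).
# groups: list of row-index vectors sharing a proportion vector; the precision
# is shared across groups. Deterministic start: pooled proportions, precision
# `start_precision`.
dm_optimize <- function(Y, groups, start_precision = 10) {
  k <- ncol(Y)
  p0 <- (colSums(Y) + 0.5) / sum(colSums(Y) + 0.5)
  z0 <- log(p0[-k] / p0[k])
  par0 <- c(rep(z0, length(groups)), log(start_precision))
  nll <- function(par) {
    phi <- exp(par[length(par)])
    val <- 0
    for (gi in seq_along(groups)) {
      z <- par[((gi - 1) * (k - 1) + 1):(gi * (k - 1))]
      p <- softmax_k(z)
      val <- val + dm_loglik(Y[groups[[gi]], , drop = FALSE], phi * p)
    }
    -val
  }
  gr <- function(par) {
    phi <- exp(par[length(par)])
    gz <- numeric(length(par) - 1)
    gphi <- 0
    for (gi in seq_along(groups)) {
      z <- par[((gi - 1) * (k - 1) + 1):(gi * (k - 1))]
      p <- softmax_k(z)
      ga <- dm_grad_alpha(Y[groups[[gi]], , drop = FALSE], phi * p)
      gphi <- gphi + sum(ga * p) * phi
      gbar <- sum(ga * p)
      gz[((gi - 1) * (k - 1) + 1):(gi * (k - 1))] <- phi * p[-k] * (ga[-k] - gbar)
    }
    -c(gz, gphi)
  }
  lower <- c(rep(-30, length(par0) - 1), log(1e-3))
  upper <- c(rep(30, length(par0) - 1), log(1e8))
  fit <- stats::optim(par0, nll, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, pgtol = 1e-8, factr = 1e4))
  phi <- exp(fit$par[length(fit$par)])
  props <- lapply(seq_along(groups), function(gi) {
    softmax_k(fit$par[((gi - 1) * (k - 1) + 1):(gi * (k - 1))])
  })
  list(proportions = props, precision = phi, loglik = -fit$value, convergence = fit$convergence)
}

#' Maximum-likelihood Dirichlet-multinomial fit
#'
#' Fits proportions and a precision (concentration) parameter to counts over
#' `k >= 2` transcripts across samples by bounded quasi-Newton on
#' logit-transformed proportions and log precision (deterministic start:
#' pooled proportions, precision 10; tolerance 1e-8).
#'
#' @param Y samples x transcripts count matrix (rows with zero totals must be
#'   removed beforehand).
#' @return an object of class `dm_fit` with `proportions`, `precision`,
#'   `loglik`.
#' @export
fit_dm <- function(Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) < 2L) iso_abort("DM fit requires at least two transcripts", "domain")
  if (!nrow(Y) || any(rowSums(Y) <= 0)) {
    iso_abort("DM fit requires samples with positive totals", "domain")
  }
  f <- dm_optimize(Y, list(seq_len(nrow(Y))))
  structure(
    list(
      proportions = f$proportions[[1]], precision = f$precision,
      loglik = f$loglik, n_samples = nrow(Y), k = ncol(Y)
    ),
    class = "dm_fit"
  )
}

#' @export
print.dm_fit <- function(x, ...) {
  cat(sprintf(
    "<dm_fit> k=%d, n=%d, precision=%.3g, loglik=%.4f\n",
    x$k, x$n_samples, x$precision, x$loglik
  ))
  cat("proportions:", paste(sprintf("%.3f", x$proportions), collapse = " "), "\n")
  invisible(x)
}

#' Gene-level usage likelihood-ratio test
#'
#' Null: one proportion vector shared by both groups; full: separate
#' proportion vectors per group; the precision is shared under both
#' hypotheses. The statistic `2 * (loglik_full - loglik_null)` is referred to
#' a chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param Y samples x transcripts counts (positive row totals).
#' @param group_idx list with elements `control` and `case`: row indices of Y.
#' @return list: `statistic`, `df`, `p`, plus the two fits.
#' @export
gene_lrt <- function(Y, group_idx) {
  Y <- as.matrix(Y)
  if (length(group_idx$control) < 2L || length(group_idx$case) < 2L) {
    iso_abort("need at least two usable samples per group", "domain")
  }
  null_fit <- dm_optimize(Y, list(seq_len(nrow(Y))))
  full_fit <- dm_optimize(Y, list(group_idx$control, group_idx$case))
  stat <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  df <- ncol(Y) - 1L
  list(
    statistic = stat, df = df,
    p = stats::pchisq(stat, df, lower.tail = FALSE),
    null = null_fit, full = full_fit
  )
}

#' Transcript-level usage test (one-vs-rest collapse)
#'
#' Collapses the gene to two categories (the transcript of interest vs the sum
#' of the others) and applies the same shared-precision DM LRT with one degree
#' of freedom.
#'
#' @inheritParams gene_lrt
#' @param tx_col column index of the transcript within `Y`.
#' @export
transcript_test <- function(Y, group_idx, tx_col) {
  Y <- as.matrix(Y)
  Y2 <- cbind(Y[, tx_col], rowSums(Y[, -tx_col, drop = FALSE]))
  gene_lrt(Y2, group_idx)
}

#' Per-transcript usage difference
#'
#' Mean per-sample proportion in the case group minus the control group.
#'
#' @inheritParams gene_lrt
#' @return list with `usage_control`, `usage_case`, `delta_usage` (each along
#'   the columns of `Y`).
#' @export
delta_usage <- function(Y, group_idx) {
  Y <- as.matrix(Y)
  if (!length(group_idx$control) || !length(group_idx$case)) {
    iso_abort("both groups need at least one usable sample", "domain")
  }
  P <- Y / rowSums(Y)
  uc <- colMeans(P[group_idx$control, , drop = FALSE])
  ut <- colMeans(P[group_idx$case, , drop = FALSE])
  list(usage_control = uc, usage_case = ut, delta_usage = ut - uc)
}

#' Two-stage (screening / confirmation) FDR control
#'
#' Screening: BH across gene-level p-values at `alpha`; genes with adjusted
#' value at or below `alpha` pass. Confirmation: within each screened gene the
#' transcript p-values undergo a Holm-Sidak adjustment tested against the
#' adjusted level `alpha * n_screened / n_genes`. Transcripts of unscreened
#' genes are never confirmed (their adjusted values are `NA`).
#'
#' @param gene_p tibble with columns `gene_id`, `p`.
#' @param tx_p tibble with columns `gene_id`, `transcript_id`, `p`.
#' @param alpha overall target FDR.
#' @return list of tibbles `genes` (`gene_id`, `p`, `q`, `screened`) and
#'   `transcripts` (`gene_id`, `transcript_id`, `p`, `p_adjusted`,
#'   `confirmed`).
#' @export
stagewise_correct <- function(gene_p, tx_p, alpha = 0.05) {
  if (!all(tx_p$gene_id %in% gene_p$gene_id)) {
    iso_abort("transcript p-value without a matching gene p-value", "validation")
  }
  genes <- tibble::tibble(gene_id = gene_p$gene_id, p = gene_p$p)
  genes$q <- bh_adjust(genes$p)
  genes$screened <- genes$q <= alpha
  n_genes <- nrow(genes)
  n_screened <- sum(genes$screened)
  out_tx <- tx_p
  out_tx$p_adjusted <- NA_real_
  out_tx$confirmed <- FALSE
  if (n_screened > 0) {
    for (g in genes$gene_id[genes$screened]) {
      rows <- which(out_tx$gene_id == g)
      pv <- out_tx$p[rows]
      k <- length(pv)
      o <- order(pv)
      hs <- 1 - (1 - pv[o])^(k - seq_len(k) + 1) # Holm-Sidak within gene
      hs <- cummax(hs)
      adj <- pmin(1, hs * n_genes / n_screened)
      out_tx$p_adjusted[rows[o]] <- adj
      out_tx$confirmed[rows[o]] <- adj <= alpha
    }
  }
  list(genes = genes, transcripts = out_tx)
}

#' Differential isoform usage analysis
#'
#' Runs the full within-gene usage pipeline: per-gene usage tables, the
#' gene-level shared-precision DM likelihood-ratio test, one-vs-rest
#' transcript tests, two-stage FDR control and per-transcript usage
#' differences.
#'
#' @inheritParams build_usage_tables
#' @param design a [sample_design()] (or coercible data frame).
#' @param alpha overall target FDR.
#' @return an object of class `iso_diu` with tibbles `$genes` (`gene_id`,
#'   `statistic`, `df`, `gene_p`, `gene_q`, `screened`) and `$transcripts`
#'   (`gene_id`, `transcript_id`, `usage_control`, `usage_case`,
#'   `delta_usage`, `tx_p`, `tx_p_adjusted`, `confirmed`); skipped genes in
#'   `$skipped`.
#' @export
diu_test <- function(counts, design, models, min_gene_count = 10, alpha = 0.05) {
  design <- if (inherits(design, "sample_design")) design else sample_design(design)
  tables <- build_usage_tables(counts, models, min_gene_count)
  skipped <- attr(tables, "excluded")
  gene_rows <- list()
  tx_rows <- list()
  for (i in seq_len(nrow(tables))) {
    g <- tables$gene_id[i]
    Y <- tables$counts[[i]]
    txs <- tables$transcript_ids[[i]]
    grp <- design_groups(design, tables$samples[[i]])
    if (length(grp$control) < 2L || length(grp$case) < 2L) {
      skipped <- dplyr::bind_rows(skipped, tibble::tibble(gene_id = g, reason = "too_few_usable_samples"))
      next
    }
    lrt <- gene_lrt(Y, grp)
    du <- delta_usage(Y, grp)
    txp <- vapply(seq_along(txs), function(j) transcript_test(Y, grp, j)$p, 0)
    gene_rows[[g]] <- tibble::tibble(
      gene_id = g, statistic = lrt$statistic, df = lrt$df, gene_p = lrt$p
    )
    tx_rows[[g]] <- tibble::tibble(
      gene_id = g, transcript_id = txs,
      usage_control = unname(du$usage_control),
      usage_case = unname(du$usage_case),
      delta_usage = unname(du$delta_usage),
      tx_p = txp
    )
  }
  genes <- dplyr::bind_rows(gene_rows)
  txs <- dplyr::bind_rows(tx_rows)
  if (!nrow(genes)) iso_abort("no testable genes for usage analysis", "validation")
  sw <- stagewise_correct(
    tibble::tibble(gene_id = genes$gene_id, p = genes$gene_p),
    tibble::tibble(gene_id = txs$gene_id, transcript_id = txs$transcript_id, p = txs$tx_p),
    alpha
  )
  genes$gene_q <- sw$genes$q
  genes$screened <- sw$genes$screened
  key <- paste(sw$transcripts$gene_id, sw$transcripts$transcript_id)
  m <- match(paste(txs$gene_id, txs$transcript_id), key)
  txs$tx_p_adjusted <- sw$transcripts$p_adjusted[m]
  txs$confirmed <- sw$transcripts$confirmed[m]
  structure(
    list(genes = genes, transcripts = txs, skipped = skipped, alpha = alpha,
         tables = tables, design = design),
    class = "iso_diu"
  )
}

#' @export
print.iso_diu <- function(x, ...) {
  cat(sprintf(
    "<iso_diu> %d genes tested (%d skipped), %d screened, %d transcripts confirmed at alpha %g\n",
    nrow(x$genes), nrow(x$skipped), sum(x$genes$screened), sum(x$transcripts$confirmed), x$alpha
  ))
  invisible(x)
}

# --- tool-agnostic DIU result I/O -----------------------------------------

DIU_COLUMNS <- c(
  "gene_id", "transcript_id", "usage_control", "usage_case", "delta_usage",
  "gene_p", "gene_q", "tx_p", "tx_p_adjusted", "confirmed"
)

#' Read / write DIU result tables (tool-agnostic TSV)
#'
#' @param path TSV path with the documented DIU schema.
#' @export
load_diu_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  miss <- setdiff(DIU_COLUMNS, names(d))
  if (length(miss)) {
    iso_abort(paste0("DIU table missing required column(s): ", paste(miss, collapse = ", ")), "schema")
  }
  if (any(abs(d$delta_usage) > 1 + 1e-9, na.rm = TRUE)) {
    iso_abort("delta_usage outside [-1, 1]", "validation")
  }
  d
}

#' @rdname load_diu_table
#' @param diu an `iso_diu` object or a data frame with the documented columns.
#' @export
write_diu_table <- function(diu, path) {
  d <- if (inherits(diu, "iso_diu")) {
    dplyr::select(
      dplyr::left_join(diu$transcripts, diu$genes[, c("gene_id", "gene_p", "gene_q")], by = "gene_id"),
      dplyr::all_of(DIU_COLUMNS)
    )
  } else {
    tibble::as_tibble(diu)
  }
  readr::write_tsv(d, path)
  invisible(path)
}
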