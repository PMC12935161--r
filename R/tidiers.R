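# broom-style tidiers for fitted objects and result containers.

#' @describeIn de_test tidy method: the per-transcript result table.
#' @param x an `iso_de` object.
#' @param ... unused.
#' @export
tidy.iso_de <- function(x, ...) x$table

#' @describeIn de_test glance method: one-row test summary.
#' @export
glance.iso_de <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$table),
    n_filtered = length(x$filtered),
    n_significant = sum(x$table$significant),
    alpha = x$alpha,
    control = x$groups[["control"]],
    case = x$groups[["case"]]
  )
}

#' @describeIn diu_test tidy method: per-transcript usage results joined with
#'   gene-level p/q values.
#' @param x an `iso_diu` object.
#' @param ... unused.
#' @export
tidy.iso_diu <- function(x, ...) {
  dplyr::left_join(
    x$transcripts,
    x$genes[, c("gene_id", "gene_p", "gene_q", "screened")],
    by = "gene_id"
  )
}

#' @describeIn diu_test glance method: one-row analysis summary.
#' @export
glance.iso_diu <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$genes),
    n_skipped = nrow(x$skipped),
    n_screened = sum(x$genes$screened),
    n_confirmed = sum(x$transcripts$confirmed),
    alpha = x$alpha
  )
}

#' @describeIn fit_dm tidy method: per-category estimated proportions.
#' @param x a `dm_fit` object.
#' @param ... unused.
#' @export
tidy.dm_fit <- function(x, ...) {
  tibble::tibble(
    category = seq_along(x$proportions),
    proportion = x$proportions
  )
}

#' @describeIn fit_dm glance method: precision and log-likelihood.
#' @export
glance.dm_fit <- function(x, ...) {
  tibble::tibble(
    precision = x$precision, loglik = x$loglik,
    n_samples = x$n_samples, k = x$k
  )
}

#' @describeIn fit_coding_model tidy method: model coefficients.
#' @param x a `coding_model` object.
#' @param ... unused.
#' @export
tidy.coding_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @describeIn fit_coding_model glance method: fit summary.
#' @export
glance.coding_model <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy, ridge = x$ridge)
}
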