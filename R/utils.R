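# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

iso_abort <- function(msg, class = "error", ...) {
  rlang::abort(msg, class = c(paste0("isoscope_", class), "isoscope_error"), ...)
}

iso_warn <- function(msg, class = "warning") {
  rlang::warn(msg, class = c(paste0("isoscope_", class), "isoscope_warning"))
}

# safe lookup in a named character vector of GTF attributes
attr_get <- function(a, key, default = NA_character_) {
  if (!is.null(a) && key %in% names(a)) unname(a[[key]]) else default
}

# scalar integer check used by validators
is_count <- function(x, positive = TRUE) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && (!positive || x > 0)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
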