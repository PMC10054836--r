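#' @importFrom rlang .data abort warn :=
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @keywords internal
"_PACKAGE"

abort_invalid <- function(msg, ...) {
  rlang::abort(msg, class = "episens_invalid_input", ...)
}

abort_parse <- function(msg, ...) {
  rlang::abort(msg, class = "episens_parse_error", ...)
}

abort_convergence <- function(msg, ...) {
  rlang::abort(msg, class = "episens_convergence_error", ...)
}

# Evaluate `expr` under a reproducible RNG state when `seed` is non-NULL,
# otherwise use (and advance) the session RNG stream.
with_noise_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
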