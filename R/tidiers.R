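#' Tidy a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`m`, `s`, `lapse`).
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("m", "s", "lapse"),
    estimate = c(x$m, x$s, x$lapse)
  )
}

#' One-row summary of a psychometric fit
#'
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @return A one-row tibble: threshold, CI, log-likelihood, trial counts and
#'   flags.
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, ci_lo = x$ci[1], ci_hi = x$ci[2],
    logLik = x$loglik, n_levels = nrow(x$data), n_trials = sum(x$data$n_trials),
    boundary = x$boundary, converged = x$converged
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
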