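#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ESS result
#'
#' @param x An `ess_result` from [pseudo_ess()] or [approximate_ess()].
#' @param ... Unused.
#' @return A one-row tibble with `method`, `metric`, `value`, `ci_low`,
#'   `ci_high`, `is_upper_bound`, `N`, `flags`.
#' @method tidy ess_result
#' @export
tidy.ess_result <- function(x, ...) tidy_ess(x)

#' @rdname tidy.ess_result
#' @method glance ess_result
#' @export
glance.ess_result <- function(x, ...) tidy_ess(x)

#' Tidy an ESS comparison
#'
#' @param x An `ess_comparison` from [compare_ess()].
#' @param ... Unused.
#' @return A two-row tibble, one row per estimator.
#' @method tidy ess_comparison
#' @export
tidy.ess_comparison <- function(x, ...) x$report

#' @rdname tidy.ess_comparison
#' @method glance ess_comparison
#' @export
glance.ess_comparison <- function(x, ...) {
  tibble::tibble(
    pseudo = x$pseudo$value,
    approximate = x$approximate$value,
    approx_within_ci = x$approx_within_ci,
    N = x$pseudo$N
  )
}

#' Tidy a semivariogram fit
#'
#' @param x A `semivariogram_fit` from [fit_semivariogram()].
#' @param ... Unused.
#' @return A tibble with one row per model parameter (`D`, `a`) plus the
#'   derived autocorrelation time `m`.
#' @method tidy semivariogram_fit
#' @export
tidy.semivariogram_fit <- function(x, ...) {
  tibble::tibble(
    term = c("D", "a", "m"),
    estimate = c(x$D, x$a, as.numeric(x$m))
  )
}

#' @rdname tidy.semivariogram_fit
#' @method glance semivariogram_fit
#' @export
glance.semivariogram_fit <- function(x, ...) {
  tibble::tibble(
    D = x$D, a = x$a, m = x$m,
    asymptote_reached = x$asymptote_reached,
    residual_norm = x$residual_norm,
    status = x$status
  )
}
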