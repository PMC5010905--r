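#' Effective sample size of a univariate trace
#'
#' The standard MCMC estimator: `ESS = N * var / S(0)`, with the spectral
#' density at frequency zero `S(0)` estimated from an autoregressive model
#' whose order is chosen by AIC (via `coda::effectiveSize()`). A constant
#' trace carries no autocorrelation information; it returns `N` with a
#' `flat = TRUE` attribute and a warning, since a flat topology trace can be
#' a false negative rather than evidence of perfect mixing.
#'
#' @param values Numeric vector of at least 20 values.
#' @return A positive number; attribute `flat` is `TRUE` for a constant
#'   input.
#' @export
univariate_ess <- function(values) {
  if (!is.numeric(values) || length(values) < 20L) {
    stop("univariate_ess: need a numeric vector of at least 20 values",
         call. = FALSE)
  }
  if (anyNA(values)) stop("univariate_ess: values contain NA", call. = FALSE)
  n <- length(values)
  if (stats::sd(values) <= 1e-12 * max(1, abs(mean(values)))) {
    warning("univariate_ess: flat trace; returning N (possible false negative)",
            call. = FALSE)
    return(structure(as.numeric(n), flat = TRUE))
  }
  ess <- as.numeric(coda::effectiveSize(values))
  max(ess, 1)
}

#' Pseudo-ESS of tree topologies
#'
#' Converts the topology sample into univariate traces — the distance of
#' every tree to a randomly chosen focal tree — and applies the standard ESS
#' estimator to each. Because the focal tree is arbitrary (and no single
#' focal tree is guaranteed to give the smallest ESS, hence "pseudo"), the
#' calculation is replicated with `n_replicates` randomly drawn focal trees
#' and summarised by the median and the 2.5%/97.5% percentiles.
#'
#' @param sample A [tree_sample] with at least 20 trees.
#' @param metric A [distance_metric()].
#' @param n_replicates Number of focal-tree replicates (default 100). Focal
#'   trees are drawn without replacement, so `n_replicates <= N`.
#' @param seed Integer seed making the focal draws reproducible.
#' @return An `ess_result` with `method = "pseudo"`: `value` (median across
#'   replicates), `ci_low`/`ci_high` (95% percentile interval), and a
#'   `replicates` tibble (`replicate`, `focal_index`, `ess`, `flat`).
#'   Pseudo-ESS values are not clamped to `N`; values above `N` are flagged
#'   in `flags`.
#' @export
pseudo_ess <- function(sample, metric = distance_metric("path_difference"),
                       n_replicates = 100L, seed = NULL) {
  metric <- as_metric(metric)
  check_tree_sample(sample, min_n = 20L, caller = "pseudo_ess")
  N <- sample$N
  if (n_replicates < 1L) {
    stop("pseudo_ess: n_replicates must be at least 1", call. = FALSE)
  }
  if (n_replicates > N) {
    stop("pseudo_ess: n_replicates (", n_replicates, ") exceeds the sample size (",
         N, "); focal trees are drawn without replacement", call. = FALSE)
  }
  focal_idx <- if (is.null(seed)) {
    sample.int(N, n_replicates)
  } else {
    withr::with_seed(seed, sample.int(N, n_replicates))
  }
  rep <- sample_rep(sample, metric)
  ess <- numeric(n_replicates)
  flat <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    d2 <- pair_sqdist(rep, seq_len(N), base::rep(focal_idx[r], N))
    vals <- if (metric$squared) d2 else sqrt(d2)
    e <- withCallingHandlers(
      univariate_ess(vals),
      warning = function(w) invokeRestart("muffleWarning")
    )
    flat[r] <- isTRUE(attr(e, "flat"))
    ess[r] <- as.numeric(e)
  }
  value <- stats::median(ess)
  ci <- stats::quantile(ess, c(0.025, 0.975), names = FALSE)
  flags <- character(0)
  if (all(flat)) flags <- c(flags, "flat_sample")
  if (value > N) flags <- c(flags, "exceeds_N")
  new_ess_result(
    method = "pseudo", metric = metric, value = value,
    ci_low = ci[1L], ci_high = ci[2L],
    replicates = tibble::tibble(replicate = seq_len(n_replicates),
                                focal_index = focal_idx, ess = ess, flat = flat),
    is_upper_bound = FALSE, N = N, flags = flags
  )
}

#' Approximate-ESS of tree topologies
#'
#' Equates the expected squared pairwise topological distance of the chain
#' with that of a hypothetical sample of `M` independent draws and solves
#' for `M`. Writing `D` for the expected squared distance between two
#' independent topologies and `f(k)` for the expected squared distance at
#' sampling interval `k`, the defining equation is
#'
#' \deqn{\frac{M(M-1)}{4M^2} D =
#'   \frac{\sum_{k=1}^{m-1} (N-k) f(k) +
#'         \frac{(N-m+1)(N-m)}{2} D}{2N^2}}
#'
#' where `m` is the autocorrelation time (smallest lag at which samples are
#' independent): every pair of samples contributes its expected squared
#' distance once — `f(k)` at lag `k < m`, `D` at lag `>= m`. `m` is located
#' by fitting an exponential semivariogram to the jump profile of mean
#' squared distances ([fit_semivariogram()]); the `f(k)` entering the sum
#' are the *empirical* lag means for `k < m`, and `D` is the pooled
#' empirical mean squared distance over all profiled lags `>= m`. Solving
#' gives `M = 1 / (1 - 4r)` with `r` the right-hand side divided by `D`:
#' an i.i.d. chain (`m = 1`) has `r = (N-1)/(4N)` and hence `M = N`
#' exactly, noisier-than-independent profiles push `r` above `1/4` and are
#' clamped to `N`, and `M` is never below 1. Writing `rho_k = 1 - f(k)/D`
#' for the implied autocorrelation, the equation reduces to the classical
#' `M = N / (1 + 2 sum rho_k)`. If the fitted asymptote lies beyond the
#' largest profiled lag the result is only an upper bound: `D` is then
#' taken as the largest observed mean squared distance and
#' `is_upper_bound` is set.
#'
#' @param sample A [tree_sample] with at least 20 trees.
#' @param metric A [distance_metric()]; distances are used in squared form
#'   regardless of the `squared` flag.
#' @param asymptote_threshold Passed to [fit_semivariogram()].
#' @return An `ess_result` with `method = "approximate"`, `value` in
#'   `[1, N]`, `is_upper_bound`, and a `details` list (`m`, `D`, `r`,
#'   semivariogram fit).
#' @export
approximate_ess <- function(sample, metric = distance_metric("path_difference"),
                            asymptote_threshold = 0.95) {
  metric <- as_metric(metric)
  check_tree_sample(sample, min_n = 20L, caller = "approximate_ess")
  N <- sample$N
  rep <- sample_rep(sample, metric)
  intervals <- sampling_intervals(N)
  profile <- profile_from_rep(rep, intervals, metric)
  fit <- fit_semivariogram(profile, asymptote_threshold = asymptote_threshold)
  if (fit$status == "flat") {
    return(new_ess_result(
      method = "approximate", metric = metric, value = as.numeric(N),
      is_upper_bound = FALSE, N = N, flags = "flat_sample",
      details = list(m = 1L, D = 0, r = NA_real_, fit = fit)
    ))
  }
  max_lag <- max(intervals)
  is_upper_bound <- FALSE
  if (fit$asymptote_reached) {
    m <- fit$m
    tail_lags <- intervals[intervals >= m]
    D <- pooled_msd(profile, tail_lags)
  } else {
    # asymptote beyond the profile: smallest m consistent with that, and the
    # largest observed mean squared distance as a lower bound on D, giving an
    # upper bound on the ESS
    m <- max_lag + 1L
    D <- max(profile$mean_squared_distance)
    is_upper_bound <- TRUE
  }
  if (D <= 0) {
    D <- max(profile$mean_squared_distance)
    if (D <= 0) {
      return(new_ess_result(
        method = "approximate", metric = metric, value = as.numeric(N),
        is_upper_bound = FALSE, N = N, flags = "flat_sample",
        details = list(m = m, D = 0, r = NA_real_, fit = fit)
      ))
    }
  }
  fk <- empirical_f(rep, profile, m)
  r <- approx_ess_r(fk, D, m, N)
  value <- approx_ess_from_r(r, N)
  new_ess_result(
    method = "approximate", metric = metric, value = value,
    is_upper_bound = is_upper_bound, N = N,
    flags = if (is_upper_bound) "upper_bound" else character(0),
    details = list(m = m, D = D, r = r, fit = fit)
  )
}

# Pair-count-weighted mean squared distance pooled over the given lags.
pooled_msd <- function(profile, lags) {
  rows <- profile$interval %in% lags
  if (!any(rows)) return(0)
  sum(profile$mean_squared_distance[rows] * profile$n_pairs[rows]) /
    sum(profile$n_pairs[rows])
}

# Empirical f(k) for k = 1..m-1, filling lags missing from a subsampled
# profile on demand.
empirical_f <- function(rep, profile, m) {
  if (m <= 1L) return(numeric(0))
  ks <- seq_len(m - 1L)
  fk <- profile$mean_squared_distance[match(ks, profile$interval)]
  for (i in which(is.na(fk))) {
    fk[i] <- lag_summary(rep, ks[i])[["mean_squared_distance"]]
  }
  fk
}

# r = RHS / D of the defining equation: the expected total squared distance
# over all N(N-1)/2 sample pairs, with each pair at lag k contributing f(k)
# for k < m and D for k >= m, normalised by 2 N^2 D. In closed form:
#   r = [ sum_{k<m} (N-k) f(k) + (N-m+1)(N-m)/2 * D ] / (2 N^2 D).
# Each pair is counted exactly once. The equation can also be read with the
# inner sum running to min(m, N-i), which counts lag-m pairs both there and
# in the tail term; that reading (double_count_lag_m = TRUE) inflates the
# ESS by ~2x at moderate mixing and is kept only for comparison.
approx_ess_r <- function(fk, D, m, N, double_count_lag_m = FALSE) {
  stopifnot(length(fk) == m - 1L)
  ks <- seq_len(m - 1L)
  total <- sum((N - ks) * fk) + (N - m + 1) * (N - m) / 2 * D
  if (double_count_lag_m) total <- total + (N - m) * D
  total / (2 * N^2 * D)
}

# Solve (M - 1) / (4M) = r for M, clamped to [1, N].
approx_ess_from_r <- function(r, N) {
  if (!is.finite(r) || r < 0) {
    stop("approx_ess_from_r: invalid r", call. = FALSE)
  }
  if (r >= 0.25) return(as.numeric(N))
  min(max(1 / (1 - 4 * r), 1), N)
}

#' Run both ESS estimators on one chain and compare them
#'
#' @param sample A [tree_sample].
#' @param metric A [distance_metric()].
#' @param n_replicates,seed,asymptote_threshold Passed to the estimators.
#' @return An `ess_comparison`: list with both `ess_result`s, a combined
#'   tidy `report` tibble, and `approx_within_ci` — whether the approximate
#'   value lies inside the pseudo 95% replicate interval.
#' @export
compare_ess <- function(sample, metric = distance_metric("path_difference"),
                        n_replicates = 100L, seed = NULL,
                        asymptote_threshold = 0.95) {
  metric <- as_metric(metric)
  ps <- pseudo_ess(sample, metric, n_replicates = n_replicates, seed = seed)
  ap <- approximate_ess(sample, metric, asymptote_threshold = asymptote_threshold)
  report <- dplyr::bind_rows(tidy_ess(ps), tidy_ess(ap))
  structure(
    list(pseudo = ps, approximate = ap, report = report,
         approx_within_ci = ap$value >= ps$ci_low && ap$value <= ps$ci_high),
    class = "ess_comparison"
  )
}

#' @export
print.ess_comparison <- function(x, ...) {
  cat("<ess_comparison>\n")
  print(x$report)
  cat(if (x$approx_within_ci) {
    "approximate-ESS lies inside the pseudo-ESS 95% interval\n"
  } else {
    "approximate-ESS lies OUTSIDE the pseudo-ESS 95% interval\n"
  })
  invisible(x)
}

new_ess_result <- function(method, metric, value, ci_low = NA_real_,
                           ci_high = NA_real_, replicates = NULL,
                           is_upper_bound = FALSE, N, flags = character(0),
                           details = list()) {
  structure(
    list(method = method, metric = metric, value = value, ci_low = ci_low,
         ci_high = ci_high, replicates = replicates,
         is_upper_bound = is_upper_bound, N = N, flags = flags,
         details = details),
    class = "ess_result"
  )
}

#' @export
print.ess_result <- function(x, ...) {
  cat("<ess_result> ", x$method, "-ESS (", x$metric$name, ")\n", sep = "")
  cat(sprintf("  value: %.1f%s  (N = %d)\n", x$value,
              if (x$is_upper_bound) " [upper bound]" else "", x$N))
  if (!is.na(x$ci_low)) {
    cat(sprintf("  95%% replicate interval: [%.1f, %.1f]\n", x$ci_low, x$ci_high))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

tidy_ess <- function(x) {
  tibble::tibble(
    method = x$method,
    metric = x$metric$name,
    value = x$value,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    is_upper_bound = x$is_upper_bound,
    N = x$N,
    flags = paste(x$flags, collapse = ";")
  )
}
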