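#' Sampling intervals for a jump distance profile
#'
#' Intervals (lags) run from 1 to `floor(N/10)`. When more than 100 such
#' lags exist, a deterministic, approximately even subsample of exactly 100
#' distinct integers is returned, always including 1 and `floor(N/10)`; this
#' keeps profiles readable and bounds the computation on long chains.
#'
#' @param N Chain length; at least 20, so that at least two lags exist.
#' @return An ascending integer vector of distinct lags.
#' @export
sampling_intervals <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 20) {
    stop("sampling_intervals: need N >= 20 samples for a jump profile",
         call. = FALSE)
  }
  max_lag <- floor(N / 10)
  if (max_lag <= 100L) return(seq_len(max_lag))
  ks <- unique(round(seq(1, max_lag, length.out = 100L)))
  ks[1L] <- 1L
  ks[length(ks)] <- max_lag
  # rounding can merge neighbours; top up from unused lags to keep exactly 100
  while (length(ks) < 100L) {
    pool <- setdiff(seq_len(max_lag), ks)
    ks <- sort(c(ks, pool[seq_len(100L - length(ks))]))
  }
  as.integer(ks)
}

#' Overlapping index pairs at a sampling interval
#'
#' All pairs of chain positions `(i, i + k)` for `i = 1, ..., N - k`. With
#' `N = 5` and `k = 2` the first three pairs are (1, 3), (2, 4) and (3, 5).
#'
#' @param N Chain length.
#' @param k Lag, `1 <= k < N`.
#' @return A two-column integer matrix, one row per pair, in order.
#' @export
pairs_at_lag <- function(N, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != floor(k)) {
    stop("pairs_at_lag: k must be a positive integer", call. = FALSE)
  }
  if (k >= N) {
    stop("pairs_at_lag: lag k must be smaller than the chain length N",
         call. = FALSE)
  }
  i <- seq_len(N - k)
  cbind(first = as.integer(i), second = as.integer(i + k))
}

#' Topology trace: distance of every sampled tree to one focal tree
#'
#' The topology trace is the tree analogue of a parameter trace: the
#' distance from each sampled topology to a fixed focal topology, plotted
#' against generation. A well-mixed chain shows a stationary band; slow
#' drifts or two-level switching indicate autocorrelation or multimodality.
#' Note the trace can be flat yet the chain unmixed if distinct topologies
#' happen to be equidistant from the focal tree (a rare false negative), so
#' traces with several different focal trees are worth inspecting.
#'
#' @param sample A [tree_sample].
#' @param focal Either an index into the sample, an external `phylo` on the
#'   same leaf set, or `NULL` (default) to draw a uniformly random sample
#'   member (use `seed` for reproducibility). The first tree is a common
#'   choice but shows a start-tree artefact: early distances climb away from
#'   it even in a stationary chain.
#' @param metric A [distance_metric()].
#' @param seed Optional integer seed used only when `focal` is `NULL`.
#' @param chain Chain identifier stored in the output (useful when
#'   overlaying replicate chains against one shared focal tree).
#' @return A tibble of class `topology_trace` with columns `chain`,
#'   `generation`, `distance`, and attributes `focal_index` (NA for an
#'   external focal tree) and `metric`.
#' @export
topology_trace <- function(sample, focal = NULL,
                           metric = distance_metric("path_difference"),
                           seed = NULL, chain = "chain1") {
  metric <- as_metric(metric)
  check_tree_sample(sample, min_n = 1L, caller = "topology_trace")
  rep <- sample_rep(sample, metric)
  trace_from_rep(rep, sample, focal, metric, seed, chain)
}

# Shared worker so multi-chain overlays can reuse a cache.
trace_from_rep <- function(rep, sample, focal, metric, seed = NULL,
                           chain = "chain1") {
  N <- sample$N
  focal_index <- NA_integer_
  if (is.null(focal)) {
    focal_index <- if (is.null(seed)) {
      sample.int(N, 1L)
    } else {
      withr::with_seed(seed, sample.int(N, 1L))
    }
    d2 <- pair_sqdist(rep, seq_len(N), base::rep(focal_index, N))
  } else if (is.numeric(focal) && length(focal) == 1L) {
    focal_index <- as.integer(focal)
    if (focal_index < 1L || focal_index > N) {
      stop("topology_trace: focal index out of range", call. = FALSE)
    }
    d2 <- pair_sqdist(rep, seq_len(N), base::rep(focal_index, N))
  } else if (inherits(focal, "phylo")) {
    lf <- sort_labels(focal$tip.label)
    if (!identical(lf, sample$labels)) {
      stop("topology_trace: focal tree leaf set differs from the sample",
           call. = FALSE)
    }
    d2 <- external_focal_sqdist(rep, focal)
  } else {
    stop("topology_trace: focal must be NULL, an index, or a 'phylo'",
         call. = FALSE)
  }
  values <- if (metric$squared) d2 else sqrt(d2)
  out <- tibble::tibble(chain = chain, generation = seq_len(N),
                        distance = values)
  structure(out, focal_index = focal_index, metric = metric,
            class = c("topology_trace", class(out)))
}

external_focal_sqdist <- function(rep, focal) {
  focal <- normalize_topology(focal)
  if (!is.null(rep$X)) {
    v <- path_vector(focal, rep$labels)
    d <- sweep(rep$X, 2L, v)
    return(rowSums(d * d)[rep$uid])
  }
  sf <- tree_splits(focal, rep$labels)
  if (is.null(rep$splits)) stop("internal: missing split representation", call. = FALSE)
  u <- vapply(seq_len(rep$nu), function(i) {
    rf_from_splits(rep$splits[[i]], sf)^2
  }, numeric(1))
  u[rep$uid]
}

#' Jump distance profile of a chain
#'
#' For each sampling interval (lag) `k`, the mean and mean squared
#' topological distance over all overlapping pairs of trees `k` samples
#' apart. Uncorrelated samples give a flat profile; autocorrelated chains
#' give a rising profile that (for a well-mixed chain) saturates at the lag
#' where samples become effectively independent.
#'
#' @param sample A [tree_sample] with at least 20 trees.
#' @param metric A [distance_metric()].
#' @param intervals Optional integer vector of lags; defaults to
#'   [sampling_intervals()] of the chain length.
#' @return A tibble of class `jump_profile` with columns `interval`,
#'   `n_pairs`, `mean_distance`, `mean_squared_distance`; attributes `metric`
#'   and `N`.
#' @export
jump_profile <- function(sample, metric = distance_metric("path_difference"),
                         intervals = NULL) {
  metric <- as_metric(metric)
  check_tree_sample(sample, min_n = 20L, caller = "jump_profile")
  if (is.null(intervals)) intervals <- sampling_intervals(sample$N)
  intervals <- as.integer(sort(unique(intervals)))
  if (any(intervals < 1L | intervals >= sample$N)) {
    stop("jump_profile: intervals must lie in [1, N - 1]", call. = FALSE)
  }
  rep <- sample_rep(sample, metric)
  profile_from_rep(rep, intervals, metric)
}

profile_from_rep <- function(rep, intervals, metric) {
  stats <- vapply(intervals, function(k) lag_summary(rep, k), numeric(3))
  out <- tibble::tibble(
    interval = intervals,
    n_pairs = as.integer(stats["n_pairs", ]),
    mean_distance = stats["mean_distance", ],
    mean_squared_distance = stats["mean_squared_distance", ]
  )
  structure(out, metric = metric, N = rep$N,
            class = c("jump_profile", class(out)))
}

#' Fit an exponential semivariogram to a jump profile
#'
#' Models the mean squared distance at lag `k` as `f(k) = D (1 - e^(-k/a))`:
#' `D` is the asymptotic squared distance between effectively independent
#' samples and `a` sets how fast the asymptote is approached. The fit is
#' least squares via `optim()` from a deterministic scale-aware start
#' (`D0 =` largest observed mean squared distance; `a0 =` smallest lag whose
#' value exceeds `(1 - e^-1) D0`), refined by a profiled line search over
#' `a` (the model is linear in `D` given `a`). The autocorrelation time `m`
#' is the smallest integer lag at which the fitted curve reaches
#' `asymptote_threshold * D`, i.e. `m = ceiling(-a * log(1 - threshold))`;
#' if `m` exceeds the largest profiled lag the asymptote was not reached
#' within the chain and `asymptote_reached` is `FALSE`.
#'
#' @param profile A [jump_profile()].
#' @param asymptote_threshold Fraction of the sill treated as "reached";
#'   default 0.95.
#' @return An object of class `semivariogram_fit` with elements `D`, `a`,
#'   `m`, `asymptote_reached`, `residual_norm`, `status` (`"ok"` or
#'   `"flat"`), `threshold`, `max_interval`. A flat (all-zero) profile
#'   returns `status = "flat"` with `m = 1` and no model parameters.
#' @export
fit_semivariogram <- function(profile, asymptote_threshold = 0.95) {
  if (!inherits(profile, "jump_profile")) {
    stop("fit_semivariogram: expected a jump_profile", call. = FALSE)
  }
  ok <- profile$n_pairs > 0L
  k <- as.numeric(profile$interval[ok])
  y <- profile$mean_squared_distance[ok]
  if (length(k) < 2L) {
    stop("fit_semivariogram: need at least 2 profiled intervals", call. = FALSE)
  }
  if (asymptote_threshold <= 0 || asymptote_threshold >= 1) {
    stop("fit_semivariogram: asymptote_threshold must be in (0, 1)", call. = FALSE)
  }
  max_interval <- max(k)
  if (max(y) <= 1e-12) {
    return(new_semivariogram_fit(D = 0, a = NA_real_, m = 1L,
                                 asymptote_reached = TRUE, residual_norm = 0,
                                 status = "flat",
                                 threshold = asymptote_threshold,
                                 max_interval = max_interval))
  }
  obj <- function(par) sum((y - par[1L] * (1 - exp(-k / par[2L])))^2)
  D0 <- max(y)
  above <- k[y > (1 - exp(-1)) * D0]
  a0 <- if (length(above)) min(above) else 1
  fit <- tryCatch(
    stats::optim(c(D0, a0), obj, method = "L-BFGS-B",
                 lower = c(1e-12, 1e-8),
                 control = list(factr = 1e4, maxit = 500L)),
    error = function(e) NULL
  )
  # profiled refinement: for fixed a the optimal D is closed form
  prof <- profile_search_a(k, y, a_hint = if (is.null(fit)) a0 else fit$par[2L])
  best <- prof
  if (!is.null(fit) && fit$value < prof$value) {
    best <- list(D = fit$par[1L], a = fit$par[2L], value = fit$value)
  }
  if (!is.finite(best$value) || best$D <= 0 || best$a <= 0) {
    # optimiser failure: signal not-reached so consumers use the bound rule
    return(new_semivariogram_fit(D = D0, a = NA_real_,
                                 m = as.integer(max_interval) + 1L,
                                 asymptote_reached = FALSE,
                                 residual_norm = NA_real_, status = "ok",
                                 threshold = asymptote_threshold,
                                 max_interval = max_interval))
  }
  m <- max(1L, as.integer(ceiling(-best$a * log(1 - asymptote_threshold) - 1e-9)))
  new_semivariogram_fit(D = best$D, a = best$a, m = m,
                        asymptote_reached = m <= max_interval,
                        residual_norm = sqrt(best$value), status = "ok",
                        threshold = asymptote_threshold,
                        max_interval = max_interval)
}

# Deterministic 1-D search over a with D profiled out analytically.
profile_search_a <- function(k, y, a_hint = 1) {
  d_of_a <- function(a) {
    g <- 1 - exp(-k / a)
    sum(y * g) / sum(g * g)
  }
  f <- function(loga) {
    a <- exp(loga)
    D <- d_of_a(a)
    if (!is.finite(D) || D <= 0) return(sum(y^2))
    sum((y - D * (1 - exp(-k / a)))^2)
  }
  lo <- log(min(k) / 50)
  hi <- log(max(k) * 50)
  grid <- seq(lo, hi, length.out = 200L)
  grid <- sort(unique(c(grid, log(max(a_hint, exp(lo))))))
  vals <- vapply(grid, f, numeric(1))
  centre <- grid[which.min(vals)]
  o <- stats::optimize(f, interval = c(centre - 0.25, centre + 0.25),
                       tol = 1e-10)
  a <- exp(o$minimum)
  list(D = d_of_a(a), a = a, value = o$objective)
}

new_semivariogram_fit <- function(D, a, m, asymptote_reached, residual_norm,
                                  status, threshold, max_interval) {
  structure(list(D = D, a = a, m = m, asymptote_reached = asymptote_reached,
                 residual_norm = residual_norm, status = status,
                 threshold = threshold, max_interval = max_interval),
            class = "semivariogram_fit")
}

#' @export
print.semivariogram_fit <- function(x, ...) {
  cat("<semivariogram_fit>\n")
  if (x$status == "flat") {
    cat("  flat profile (all squared distances ~ 0); m = 1\n")
    return(invisible(x))
  }
  cat(sprintf("  D (sill):       %.4g\n", x$D))
  cat(sprintf("  a (range):      %.4g\n", x$a))
  cat(sprintf("  m (autocorrelation time): %d%s\n", x$m,
              if (x$asymptote_reached) "" else " (beyond profiled lags)"))
  cat(sprintf("  residual norm:  %.4g\n", x$residual_norm))
  invisible(x)
}

#' Plot-ready table for a topology trace
#'
#' @param trace A [topology_trace()].
#' @return A plain tibble with columns `chain`, `generation`, `distance`.
#' @export
trace_plot_data <- function(trace) {
  if (!inherits(trace, "topology_trace")) {
    stop("trace_plot_data: expected a topology_trace", call. = FALSE)
  }
  tibble::tibble(chain = trace$chain, generation = trace$generation,
                 distance = trace$distance)
}

#' Plot-ready table for a jump profile
#'
#' @param profile A [jump_profile()].
#' @return A plain tibble with columns `interval`, `mean_distance`.
#' @export
jump_plot_data <- function(profile) {
  if (!inherits(profile, "jump_profile")) {
    stop("jump_plot_data: expected a jump_profile", call. = FALSE)
  }
  tibble::tibble(interval = profile$interval,
                 mean_distance = profile$mean_distance)
}
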