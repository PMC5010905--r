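test_that("sampling intervals span 1..floor(N/10) with at most 100 lags", {
  expect_identical(sampling_intervals(50), 1:5)
  expect_identical(sampling_intervals(20), 1:2)
  ks <- sampling_intervals(1000)
  expect_length(ks, 100L)
  expect_equal(max(ks), 100L)
  expect_equal(min(ks), 1L)
  # subsampled case: exactly 100 distinct lags, endpoints forced
  ks2 <- sampling_intervals(4321)
  expect_length(ks2, 100L)
  expect_equal(ks2[1], 1L)
  expect_equal(ks2[100], 432L)
  expect_false(is.unsorted(ks2, strictly = TRUE))
  expect_error(sampling_intervals(19), ">= 20")
})

test_that("pairs at a lag are the overlapping (i, i+k) pairs in order", {
  p <- pairs_at_lag(5, 2)
  expect_equal(p[1:3, ], cbind(first = 1:3, second = 3:5))
  expect_equal(nrow(p), 3L)
  expect_equal(pairs_at_lag(5, 4), cbind(first = 1L, second = 5L))
  expect_equal(nrow(pairs_at_lag(1000, 1)), 999L)
  expect_error(pairs_at_lag(5, 5), "smaller than")
})

test_that("topology traces measure distance to the focal tree", {
  trees <- list(q_ab_cd(), q_ab_cd(), q_ac_bd())
  ts <- tree_sample(trees, source = "toy")
  tr <- topology_trace(ts, focal = 1, metric = distance_metric("rf"))
  expect_equal(tr$distance, c(0, 0, 2))
  expect_equal(nrow(tr), 3L)
  expect_equal(attr(tr, "focal_index"), 1L)

  # identical trees -> all-zero trace regardless of focal
  same <- tree_sample(rep(list(q_ab_cd()), 5))
  tr0 <- topology_trace(same, focal = 3)
  expect_true(all(tr0$distance == 0))

  # external focal tree on the same leaf set
  tre <- topology_trace(ts, focal = q_ad_bc(), metric = distance_metric("rf"))
  expect_equal(tre$distance, c(2, 2, 2))
  expect_true(is.na(attr(tre, "focal_index")))

  # mismatched focal leaf set
  expect_error(
    topology_trace(ts, focal = ape::read.tree(text = "((A,B),(C,E));")),
    "leaf set")

  # seeded random focal is reproducible
  t1 <- topology_trace(ts, seed = 9)
  t2 <- topology_trace(ts, seed = 9)
  expect_identical(attr(t1, "focal_index"), attr(t2, "focal_index"))
})

test_that("jump profiles summarise lag pairs and basic inequalities hold", {
  same <- tree_sample(rep(list(q_ab_cd()), 30))
  jp0 <- jump_profile(same)
  expect_true(all(jp0$mean_distance == 0))
  expect_equal(jp0$n_pairs, 30L - jp0$interval)

  ts <- simulate_unimodal(n_taxa = 10, n_samples = 60, sprs_per_step = 1,
                          seed = 21)
  jp <- jump_profile(ts)
  expect_equal(jp$interval, 1:6)
  expect_equal(jp$n_pairs, 60L - 1:6)
  # Jensen: mean of squares >= square of mean, per lag
  expect_true(all(jp$mean_squared_distance >= jp$mean_distance^2 - 1e-9))
  # lag means agree with direct pairwise computation
  for (k in c(1L, 4L)) {
    expect_equal(jp$mean_squared_distance[k], bf_lag_msd(ts, k),
                 tolerance = 1e-12)
  }
})

test_that("jump profile is invariant under time reversal", {
  ts <- simulate_unimodal(n_taxa = 8, n_samples = 40, sprs_per_step = 1,
                          seed = 13)
  rev_ts <- tree_sample(rev(unclass(ts$trees)), source = "reversed")
  expect_equal(as.data.frame(jump_profile(ts)),
               as.data.frame(jump_profile(rev_ts)))
})

test_that("an i.i.d. shuffle of a chain has a statistically flat profile", {
  ts <- simulate_unimodal(n_taxa = 10, n_samples = 200, sprs_per_step = 1,
                          seed = 31)
  slopes <- vapply(1:8, function(s) {
    shuffled <- withr::with_seed(s, tree_sample(
      unclass(ts$trees)[sample(ts$N)], source = "shuffle"))
    jp <- jump_profile(shuffled)
    unname(stats::coef(stats::lm(mean_distance ~ interval, data = jp))[2])
  }, numeric(1))
  scale <- mean(jump_profile(ts)$mean_distance)
  # slope per lag should be a tiny fraction of the typical distance
  expect_lt(abs(mean(slopes)), 0.02 * scale)
})

test_that("a poorly mixing chain has a rising profile", {
  ts <- simulate_unimodal(n_taxa = 50, n_samples = 300, sprs_per_step = 1,
                          seed = 41)
  jp <- jump_profile(ts)
  fit <- stats::coef(stats::lm(mean_distance ~ interval, data = jp))
  expect_gt(fit[2], 0)
  # early lags tend upward
  expect_gt(jp$mean_distance[nrow(jp)], jp$mean_distance[1])
})

test_that("semivariogram fits recover noiseless parameters within 1%", {
  for (D in c(10, 250, 1e4)) {
    for (a in c(0.5, 5, 50)) {
      k <- 1:100
      y <- D * (1 - exp(-k / a))
      prof <- structure(
        tibble::tibble(interval = k, n_pairs = 1000L - k,
                       mean_distance = sqrt(y), mean_squared_distance = y),
        metric = distance_metric("pd"), N = 1000L,
        class = c("jump_profile", "tbl_df", "tbl", "data.frame"))
      fit <- fit_semivariogram(prof)
      expect_equal(fit$D, D, tolerance = 0.01)
      expect_equal(fit$a, a, tolerance = 0.01)
      expect_equal(fit$m, max(1L, ceiling(a * log(20))))
    }
  }
})

test_that("flat and saturated profiles are classified correctly", {
  same <- tree_sample(rep(list(q_ab_cd()), 40))
  fit0 <- fit_semivariogram(jump_profile(same))
  expect_equal(fit0$status, "flat")
  expect_equal(fit0$m, 1L)
  expect_true(fit0$asymptote_reached)

  # i.i.d. sample: flat but nonzero -> m = 1, asymptote reached
  set.seed(61)
  pool <- lapply(1:12, function(i) random_topology(12))
  iid <- tree_sample(pool[sample.int(12, 300, replace = TRUE)], "iid")
  fit1 <- fit_semivariogram(jump_profile(iid))
  expect_equal(fit1$status, "ok")
  expect_equal(fit1$m, 1L)
  expect_true(fit1$asymptote_reached)

  # still-rising profile: fitted m beyond the largest interval
  k <- 1:10
  y <- 500 * (1 - exp(-k / 200))
  prof <- structure(
    tibble::tibble(interval = k, n_pairs = 100L - k,
                   mean_distance = sqrt(y), mean_squared_distance = y),
    metric = distance_metric("pd"), N = 100L,
    class = c("jump_profile", "tbl_df", "tbl", "data.frame"))
  fit2 <- fit_semivariogram(prof)
  expect_false(fit2$asymptote_reached)
  expect_gt(fit2$m, 10L)
})

test_that("plot data tables have the documented shape", {
  ts <- simulate_unimodal(n_taxa = 8, n_samples = 30, sprs_per_step = 1,
                          seed = 3)
  tr <- topology_trace(ts, focal = 1)
  td <- trace_plot_data(tr)
  expect_named(td, c("chain", "generation", "distance"))
  expect_equal(nrow(td), 30L)

  jp <- jump_profile(ts)
  jd <- jump_plot_data(jp)
  expect_named(jd, c("interval", "mean_distance"))
  expect_equal(nrow(jd), nrow(jp))

  # multi-chain overlay with one shared focal tree
  ts2 <- simulate_unimodal(n_taxa = 8, n_samples = 30, sprs_per_step = 1,
                           seed = 4)
  focal <- ts$trees[[1]]
  both <- dplyr::bind_rows(
    trace_plot_data(topology_trace(ts, focal = focal, chain = "chain1")),
    trace_plot_data(topology_trace(ts2, focal = focal, chain = "chain2")))
  expect_equal(nrow(both), 60L)
  expect_setequal(unique(both$chain), c("chain1", "chain2"))
})

test_that("autoplot methods return ggplot objects", {
  ts <- simulate_unimodal(n_taxa = 8, n_samples = 30, sprs_per_step = 1,
                          seed = 3)
  expect_s3_class(ggplot2::autoplot(topology_trace(ts, focal = 1)), "ggplot")
  expect_s3_class(ggplot2::autoplot(jump_profile(ts)), "ggplot")
})
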