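test_that("windowed MSD equals the brute-force double-loop oracle", {
  set.seed(42)
  for (i in 1:10) {
    d <- random_detections(n_rows = 150, t_max = 25)
    for (w in c(0, 3, 7)) {
      m <- compute_msd(d, window = w)
      expect_equal(m$msd, msd_oracle(d, m$t, w), tolerance = 1e-12)
    }
  }
})

test_that("MSD matches hand-computed values and pooling is count-weighted", {
  d <- make_detections(t = c(1, 1, 1), s = c(-10, 0, 10))
  m <- compute_msd(d, window = 0)
  expect_equal(m$msd[1], 200 / 3)

  expect_equal(compute_msd(make_detections(1:5, rep(0, 5)), window = 2)$msd,
               rep(0, 5))

  # two replicates with equal MSD but detection counts 10 and 30
  d2 <- dplyr::bind_rows(
    make_detections(rep(1, 10), rep(4, 10), replicate = 1),
    make_detections(rep(1, 30), rep(c(-4, 4), 15), replicate = 2)
  )
  expect_equal(compute_msd(d2, window = 0)$msd[1], 16)

  # empty windows give NA, not zero
  d3 <- make_detections(c(1, 10), c(5, 5))
  expect_true(is.na(compute_msd(d3, window = 2)$msd[5]))
})

test_that("population quantiles follow the order-statistic convention", {
  d <- make_detections(rep(1, 100), sample(c(-1, 1), 100, TRUE) * (1:100))
  q <- compute_quantiles(d, p = c(50, 90), window = 0, times = 1)
  expect_equal(q$q[q$p == 90], stats::quantile(1:100, 0.9, names = FALSE))
  expect_equal(q$q[q$p == 50], stats::quantile(1:100, 0.5, names = FALSE))

  # constant distance: every quantile equals it; symmetric pair median
  dc <- make_detections(rep(1, 20), rep(c(-7, 7), 10))
  qc <- compute_quantiles(dc, p = c(50, 75, 99), window = 0, times = 1)
  expect_equal(qc$q, rep(7, 3))

  # monotone in p at fixed t
  set.seed(1)
  dr <- random_detections(500, t_max = 10)
  qr <- compute_quantiles(dr, p = c(50, 75, 90, 95, 98, 99), window = 7)
  wide <- tidyr::pivot_wider(qr, id_cols = "t", names_from = "p",
                             values_from = "q")
  mat <- as.matrix(wide[, -1])
  expect_true(all(apply(mat, 1, function(r) all(diff(r) >= -1e-12))))
})

test_that("diffusion fits recover exact and noisy slopes", {
  s <- tibble::tibble(t = 1:480, msd = 4 * (1:480))
  fit <- fit_diffusion(s)
  expect_equal(fit$D, 4)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$D_m2h, 0.024)
  expect_equal(fit$window[1], 30)

  expect_equal(fit_diffusion(tibble::tibble(t = 1:100, msd = 5))$D, 0)

  set.seed(2)
  sn <- tibble::tibble(t = 31:480, msd = 4 * (31:480) + rnorm(450))
  fitn <- fit_diffusion(sn)
  expect_equal(fitn$D, 4, tolerance = 3 * fitn$se_D / 4)

  expect_error(fit_diffusion(tibble::tibble(t = 1:5, msd = 1:5), t_min = 30),
               "fewer than 2")
})

test_that("piecewise fit recovers a noiseless changepoint exactly", {
  s <- two_slope_series(5.73, 3.09, bp = 246)
  fit <- fit_piecewise(s, B = 19)
  expect_equal(fit$breakpoint, 246)
  expect_equal(fit$D_before, 5.73, tolerance = 1e-8)
  expect_equal(fit$D_after, 3.09, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-12)
  expect_true(fit$reliable)
})

test_that("piecewise fit on truly linear data is not significant", {
  set.seed(5)
  s <- tibble::tibble(t = 30:480, msd = 2 * (30:480) + rnorm(451, 0, 20))
  fit <- fit_piecewise(s, B = 99, grid_by = 4)
  expect_gt(fit$p_piecewise, 0.05)
  # RSS improvement is marginal relative to the linear fit
  expect_lt((fit$rss_linear - fit$rss) / fit$rss_linear, 0.05)
})

test_that("breakpoint estimate agrees with the segmented package", {
  skip_if_not_installed("segmented")
  set.seed(8)
  s <- two_slope_series(6, 2, bp = 200, noise_sd = 25)
  fit <- fit_piecewise(s, B = 19)
  seg <- segmented::segmented(stats::lm(msd ~ t, data = s),
                              seg.Z = ~t, psi = 150)
  expect_equal(fit$breakpoint, seg$psi[, "Est."], tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("replicate bootstrap CIs behave correctly", {
  # identical replicates collapse the CI to a point
  d <- dplyr::bind_rows(lapply(1:4, function(r)
    make_detections(rep(1, 10), 1:10, replicate = r)))
  ci <- bootstrap_replicates(d, function(x) mean(x$s), B = 50)
  expect_equal(ci$ci_low, ci$ci_high)
  expect_equal(ci$ci_low, 5.5)

  # CI of a mean over replicate means stays inside the replicate range
  d2 <- dplyr::bind_rows(lapply(1:3, function(r)
    make_detections(rep(1, 5), rep(r, 5), replicate = r)))
  ci2 <- bootstrap_replicates(
    d2, function(x) mean(tapply(x$s, x$replicate, mean)), B = 400)
  expect_gte(ci2$ci_low, 1)
  expect_lte(ci2$ci_high, 3)
})

test_that("bootstrap CI coverage is near nominal for a replicate-mean", {
  set.seed(9)
  hits <- 0L
  n_trial <- 60
  for (i in seq_len(n_trial)) {
    mu <- 5
    d <- dplyr::bind_rows(lapply(1:12, function(r)
      make_detections(rep(1, 8), rnorm(8, mu + rnorm(1), 1), replicate = r)))
    ci <- bootstrap_replicates(
      d, function(x) mean(tapply(x$s, x$replicate, mean)), B = 199)
    if (ci$ci_low <= mu && mu <= ci$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / n_trial, 0.85)
})

test_that("treatment comparisons use rank tests with BH adjustment", {
  d <- tibble::tibble(treatment = rep(c("a", "b"), each = 10),
                      value = rep(1:10, 2))
  res <- compare_treatments(d, value)
  expect_equal(res$p_adjusted, 1, tolerance = 1e-9)

  # one pair: BH leaves the p-value unchanged
  set.seed(3)
  d2 <- tibble::tibble(treatment = rep(c("a", "b"), each = 12),
                       value = c(rnorm(12), rnorm(12, 3)))
  res2 <- compare_treatments(d2, value)
  expect_equal(res2$p_value, res2$p_adjusted)
  expect_lt(res2$p_adjusted, 0.05)

  # power at a 2 SD shift, n = 20 per group
  set.seed(4)
  sig <- vapply(1:20, function(i) {
    dd <- tibble::tibble(treatment = rep(c("a", "b"), each = 20),
                         value = c(rnorm(20), rnorm(20, 2)))
    compare_treatments(dd, value)$p_adjusted < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.95)

  # small groups flagged
  d3 <- tibble::tibble(treatment = c("a", "a", "b", "b", "b"),
                       value = c(1, 2, 5, 6, 7))
  expect_equal(compare_treatments(d3, value)$flag, "small_n")
})
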