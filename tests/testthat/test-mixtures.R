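test_that("centred Gaussian MLE has the closed form sqrt(sum(x^2)/n)", {
  fit <- fit_centred_mixture(c(-10, 0, 10, -10, 0, 10, -10, 0, 10, 0), K = 1)
  expect_equal(fit$scales, sqrt(sum(c(-10, 0, 10)^2 * 3) / 10))
  fit3 <- fit_centred_mixture(rep(c(-10, 0, 10), 4), K = 1)
  expect_equal(fit3$scales, sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(fit3$aic, 2 - 2 * fit3$loglik)
})

test_that("EM recovers a well-separated two-scale mixture", {
  set.seed(10)
  x <- c(rnorm(2000, 0, 5), rnorm(2000, 0, 50))
  fit <- fit_centred_mixture(x, K = 2)
  expect_true(fit$converged)
  expect_false(fit$degenerate)
  expect_equal(fit$weights[1], 0.5, tolerance = 0.05)
  expect_equal(fit$scales[1], 5, tolerance = 0.1 * 5)
  expect_equal(fit$scales[2], 50, tolerance = 0.1 * 50)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(diff(fit$scales) > 0))
  # mixture loglik dominates the nested single Gaussian
  expect_gte(fit$loglik, fit_centred_mixture(x, K = 1)$loglik)
  # fitted density integrates to one
  dens <- function(z) fit$weights[1] * dnorm(z, 0, fit$scales[1]) +
    fit$weights[2] * dnorm(z, 0, fit$scales[2])
  expect_equal(stats::integrate(dens, -Inf, Inf)$value, 1, tolerance = 1e-6)
})

test_that("scale-collapsed data are flagged effectively unimodal", {
  x <- rep(c(-3, 3), 50)
  fit <- fit_centred_mixture(x, K = 2)
  expect_true(fit$unimodal)
  expect_equal(fit$scales[1], 3, tolerance = 0.01)
})

test_that("centred Student fit recovers df and hits the Gaussian cap", {
  set.seed(11)
  g <- rnorm(4000, 0, 10)
  fg <- fit_centred_student(g)
  # likelihood is flat near the Gaussian limit: df large, loglik Gaussian
  expect_gt(fg$df, 100)
  gauss_ll <- fit_centred_mixture(g, K = 1)$loglik
  expect_equal(fg$loglik, gauss_ll, tolerance = 1e-3)

  x3 <- 10 * rt(4000, df = 3)
  f3 <- fit_centred_student(x3)
  expect_gt(f3$df, 2.5)
  expect_lt(f3$df, 3.6)

  # heavy outliers pull the tail index down
  fo <- fit_centred_student(c(g, rnorm(200, 0, 120)))
  expect_lt(fo$df, fg$df)
})

test_that("AIC selects the generating model", {
  set.seed(12)
  sel_g <- select_model(rnorm(1000, 0, 10))
  expect_equal(sel_g$winner, "gaussian")

  x <- c(rnorm(2000, 0, 5), rnorm(2000, 0, 50))
  sel_m <- select_model(x)
  expect_equal(sel_m$winner, "gmix2")

  sel_t <- select_model(8 * rt(4000, df = 3))
  tab <- sel_t$table
  expect_lt(tab$aic[tab$model == "student"],
            tab$aic[tab$model == "gaussian"])
})

test_that("excess kurtosis diagnostics match closed forms", {
  set.seed(13)
  g <- gaussianity_diagnostics(rnorm(20000, 0, 10))
  expect_equal(g$excess_kurtosis, 0, tolerance = 0.1)
  expect_lt(max(abs(g$qq$deviation)) / 10, 0.05)

  # scale mixture of variances 25 and 2500: kurtosis 3 E[v^2]/E[v]^2 - 3
  v <- c(25, 2500)
  kurt_true <- 3 * mean(v^2) / mean(v)^2 - 3
  x <- ifelse(runif(20000) < 0.5, rnorm(20000, 0, 5), rnorm(20000, 0, 50))
  gm <- gaussianity_diagnostics(x)
  expect_equal(gm$excess_kurtosis, kurt_true, tolerance = 0.2)
})

test_that("per-replicate normalisation separates mixture from replicate heterogeneity", {
  set.seed(14)
  # replicate-level variance heterogeneity only: Gaussian within replicate
  het <- dplyr::bind_rows(lapply(1:10, function(r)
    make_detections(rep(1, 500), rnorm(500, 0, sample(c(5, 50), 1)),
                    replicate = r)))
  raw <- gaussianity_diagnostics(het)
  norm <- gaussianity_diagnostics(het, per_replicate_normalize = TRUE)
  expect_gt(raw$excess_kurtosis, 1)
  expect_lt(abs(norm$excess_kurtosis), 0.3)

  # a true within-replicate mixture stays leptokurtic after normalisation
  mix <- dplyr::bind_rows(lapply(1:10, function(r)
    make_detections(rep(1, 500),
                    ifelse(runif(500) < 0.5, rnorm(500, 0, 5),
                           rnorm(500, 0, 50)),
                    replicate = r)))
  norm_mix <- gaussianity_diagnostics(mix, per_replicate_normalize = TRUE)
  expect_gt(norm_mix$excess_kurtosis, 1)
})

test_that("component tracking recovers frozen 50/50 modes", {
  sims <- lapply(1:8, function(i)
    simulate_replicate(
      sim_config(n_agents = 80, duration = 240, sigma_resident = 1,
                 sigma_explorer = 8, initial_explorer_frac = 0.5,
                 switch_re_base = 0, switch_re_density_coef = 0,
                 switch_re_host_boost = 0, switch_er_hazard = 0,
                 seed = 500 + i),
      replicate_id = i)$detections)
  det <- dplyr::bind_rows(sims)
  traj <- track_components(det, B = 0)
  late <- traj[traj$reliable, ]
  expect_equal(mean(late$pi_explorer), 0.5, tolerance = 0.07)
  # explorer-component MSD tracks sigma_e^2 * t
  fit <- fit_diffusion(late, msd_col = "msd_explorer")
  expect_equal(fit$D, 64, tolerance = 0.15 * 64)
})

test_that("one-way switching gives a non-decreasing explorer proportion", {
  sims <- lapply(1:6, function(i)
    simulate_replicate(
      sim_config(n_agents = 80, duration = 300, sigma_resident = 1,
                 sigma_explorer = 8, switch_re_base = 5e-3,
                 switch_re_density_coef = 0, switch_er_hazard = 0,
                 latency = 0, seed = 700 + i),
      replicate_id = i)$detections)
  det <- dplyr::bind_rows(sims)
  traj <- track_components(det, B = 0)
  late <- traj[traj$t >= 45, ]
  # monotone trend within estimation noise: strong positive rank correlation
  expect_gt(stats::cor(late$t, late$pi_explorer, method = "spearman"), 0.7)
  # and all-resident data yield a degenerate (effectively unimodal) fit
  res <- simulate_replicate(
    sim_config(n_agents = 80, duration = 120, switch_re_base = 0,
               switch_re_density_coef = 0, switch_re_host_boost = 0,
               seed = 909))$detections
  traj0 <- track_components(res, B = 0, min_detections = 40)
  expect_true(mean(traj0$degenerate) > 0.5 ||
                mean(traj0$pi_explorer[traj0$reliable]) < 0.2)
})

test_that("bootstrap CIs from component tracking cover the truth", {
  sims <- lapply(1:6, function(i)
    simulate_replicate(
      sim_config(n_agents = 80, duration = 90, sigma_resident = 1,
                 sigma_explorer = 8, initial_explorer_frac = 0.5,
                 switch_re_base = 0, switch_re_density_coef = 0,
                 switch_re_host_boost = 0, switch_er_hazard = 0,
                 seed = 800 + i),
      replicate_id = i)$detections)
  det <- dplyr::bind_rows(sims)
  traj <- track_components(det, B = 60, t_reliable = 60)
  late <- traj[traj$reliable, ]
  expect_true(all(late$pi_lo <= 0.5 + 0.1 & late$pi_hi >= 0.5 - 0.1))
  expect_true(all(late$pi_lo <= late$pi_hi))
})

test_that("component diffusion prefers piecewise only under a slope change", {
  lin <- tibble::tibble(t = seq(15, 480, by = 15),
                        msd_explorer = 30 * seq(15, 480, by = 15),
                        reliable = TRUE)
  set.seed(15)
  lin$msd_explorer <- lin$msd_explorer + rnorm(nrow(lin), 0, 100)
  cd <- component_diffusion(lin, B = 99)
  expect_equal(cd$preferred, "linear")
  expect_equal(cd$linear$D, 30, tolerance = 0.05)

  brk <- tibble::tibble(t = seq(15, 480, by = 15), reliable = TRUE)
  brk$msd_explorer <- ifelse(brk$t <= 240, 40 * brk$t,
                             40 * 240 + 8 * (brk$t - 240)) +
    rnorm(nrow(brk), 0, 100)
  cd2 <- component_diffusion(brk, B = 99)
  expect_equal(cd2$preferred, "piecewise")
  expect_equal(cd2$piecewise$breakpoint, 240, tolerance = 0.15 * 240)
})
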