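test_that("dispersal sigma is the RMS distance of parasitised hosts", {
  h <- make_hosts(c(-80, 80, 150), parasitized = c(TRUE, TRUE, FALSE),
                  first_discovery = c(10L, 20L, NA), total_visit = c(5, 5, 0))
  k <- dispersal_kernel(h)
  expect_equal(k$sigma_dispersal, 80)
  expect_equal(k$n_parasitized, 2)
  # sign-flip invariance
  h2 <- h; h2$s <- -h2$s
  expect_equal(dispersal_kernel(h2)$sigma_dispersal, 80)
})

test_that("kernel bins partition hosts and a flat kernel is flagged", {
  set.seed(20)
  s <- seq(-290, 290, by = 5)
  par <- runif(length(s)) < exp(-s^2 / (2 * 90^2))
  h <- make_hosts(s, parasitized = par,
                  first_discovery = ifelse(par, 5L, NA),
                  total_visit = ifelse(par, 10, 0))
  k <- dispersal_kernel(h, bin = 30)
  expect_equal(sum(k$bins$n_hosts), length(s))
  expect_equal(sum(k$bins$n_parasitized), sum(par))
  expect_true(all(k$bins$fraction >= 0 & k$bins$fraction <= 1))

  flat <- make_hosts(s, parasitized = TRUE,
                     first_discovery = 5L, total_visit = 10)
  kf <- dispersal_kernel(flat)
  expect_true("flat_kernel" %in% kf$flags)

  none <- make_hosts(s, parasitized = FALSE)
  expect_true("no_parasitism" %in% dispersal_kernel(none)$flags)
  expect_true(is.na(dispersal_kernel(none)$sigma_dispersal))
})

test_that("kernel Gaussian fit recovers a known dispersal scale", {
  set.seed(21)
  # parasitism probability Gaussian in position, many hosts
  s <- rep(seq(-297.5, 297.5, by = 5), 12)
  par <- runif(length(s)) < 0.9 * exp(-s^2 / (2 * 80^2))
  h <- make_hosts(s, parasitized = par,
                  first_discovery = ifelse(par, 5L, NA),
                  total_visit = ifelse(par, 10, 0))
  expect_gte(sum(par), 300)
  k <- dispersal_kernel(h)
  expect_equal(k$sigma_dispersal, 80, tolerance = 0.15)
  expect_equal(k$gaussian_fit$sigma, 80, tolerance = 0.15)
  expect_gt(k$gaussian_fit$r_squared, 0.8)
})

test_that("on-host fractions use truth or proximity consistently", {
  lay <- make_host_layout("diffuse")
  # all detections exactly on eggs
  d <- make_detections(rep(10, 6), rep(c(-2.5, 2.5, 7.5), 2))
  d$on_host <- 1L
  f_truth <- on_host_fraction(d, lay, times = 10, rule = "truth")
  expect_true(all(f_truth$fraction == 1))
  f_prox <- on_host_fraction(d, lay, times = 10, rule = "proximity")
  expect_true(all(f_prox$fraction == 1))
  # detections far from any host
  d2 <- make_detections(rep(10, 4), c(-4.6, 0, 4.9, 5.4))
  f2 <- on_host_fraction(d2, lay, times = 10, rule = "proximity")
  expect_true(all(f2$fraction == 0))
  expect_error(on_host_fraction(d, make_host_layout("none"), times = 10),
               "no hosts")
})

test_that("discovery times exclude undiscovered hosts and grow with distance", {
  sims <- lapply(1:6, function(i)
    simulate_replicate(
      sim_config(n_agents = 80, duration = 300, sigma_resident = 5,
                 sigma_explorer = 5, host_layout = make_host_layout("diffuse"),
                 host_refractory = 5, seed = 40 + i),
      replicate_id = i)$hosts)
  h <- dplyr::bind_rows(sims)
  dt <- discovery_times(h)
  expect_equal(nrow(dt), sum(!is.na(h$first_discovery)))
  # first-passage times increase with distance from the release point
  near <- dt$first_discovery[dt$distance < 50]
  far <- dt$first_discovery[dt$distance > 120]
  expect_gt(length(far), 10)
  expect_gt(median(far), median(near))
  expect_gt(cor(dt$distance, dt$first_discovery, method = "spearman"), 0.4)
})

test_that("discoverer posterior follows the two-component density ratio", {
  traj <- tibble::tibble(
    t = seq(15, 300, by = 15), pi_explorer = 0.5,
    sigma_resident = 2, sigma_explorer = 20,
    msd_explorer = 400, n_detections = 1000, reliable = TRUE,
    degenerate = FALSE
  )
  h <- make_hosts(c(0, 1, -150, 150), parasitized = TRUE,
                  first_discovery = c(100L, 100L, 100L, 100L),
                  total_visit = 10)
  asg <- assign_discoverer(h, traj)
  expect_equal(asg$label[1], "resident")  # centre: narrow component wins
  expect_equal(asg$label[3], "explorer")  # tail: broad component wins
  expect_equal(asg$label[4], "explorer")
  # monotone non-decreasing posterior in |s| when sigma_e > sigma_r
  grid <- make_hosts(seq(0, 100, by = 5), parasitized = TRUE,
                     first_discovery = 100L, total_visit = 10)
  p <- assign_discoverer(grid, traj)$p_explorer
  expect_true(all(diff(p) >= -1e-12))
  # discoveries before the reliability window are unassigned
  early <- make_hosts(50, parasitized = TRUE, first_discovery = 20L,
                      total_visit = 10)
  expect_equal(assign_discoverer(early, traj)$label, "unassigned")
})

test_that("gain curve estimates saturating parasitism probability", {
  set.seed(22)
  T_vis <- c(rep(0, 100), runif(500, 1, 300))
  par <- runif(length(T_vis)) < 1 - exp(-T_vis / 60)
  h <- make_hosts(seq_along(T_vis), parasitized = par,
                  first_discovery = ifelse(T_vis > 0, 5L, NA),
                  total_visit = T_vis)
  g <- gain_curve(h)
  expect_equal(g$bins$fraction[g$bins$T_mid < 15][1], 0, tolerance = 0.02)
  expect_equal(g$fit$tau, 60, tolerance = 0.25)
  expect_gte(g$fit$asymptote, 0.9)
  # fitted curve is non-decreasing and the binned trend rises overall
  expect_true(all(diff(g$predict(seq(0, 300, 10))) >= 0))
  expect_gt(cor(g$bins$T_mid, g$bins$fraction, method = "spearman"), 0.6)
})

test_that("replicate metrics and rank correlations behave", {
  # deterministic monotone relation: rho^2 = 1
  d <- tibble::tibble(replicate = 1:8, front = 1:8,
                      total_parasitism = (1:8)^2 / 100,
                      sigma_dispersal = 2 * (1:8))
  cr <- correlate_metrics(d)
  expect_equal(cr$rho2, rep(1, 3))
  # constant metric flagged
  d2 <- d; d2$front <- 5
  expect_equal(correlate_metrics(d2)$flag[1], "constant_input")
  # independent metrics: small rho2
  set.seed(23)
  d3 <- tibble::tibble(replicate = 1:40, front = rnorm(40),
                       total_parasitism = rnorm(40),
                       sigma_dispersal = rnorm(40))
  expect_true(all(correlate_metrics(d3)$rho2 < 0.2))
  expect_error(correlate_metrics(d[1:3, ]), "at least 5")
})

test_that("replicate_metrics summarises movement and parasitism per replicate", {
  det <- dplyr::bind_rows(
    make_detections(rep(466:480, each = 4), rep(c(-20, -5, 5, 20), 15),
                    replicate = 1),
    make_detections(rep(466:480, each = 4), rep(c(-60, -15, 15, 60), 15),
                    replicate = 2)
  )
  hosts <- dplyr::bind_rows(
    make_hosts(c(-30, 30), parasitized = c(TRUE, TRUE),
               first_discovery = 5L, total_visit = 10, replicate = 1),
    make_hosts(c(-90, 90), parasitized = c(TRUE, FALSE),
               first_discovery = c(5L, NA), total_visit = c(10, 0),
               replicate = 2)
  )
  m <- replicate_metrics(det, hosts, p = 98)
  expect_equal(nrow(m), 2)
  expect_gt(m$front[2], m$front[1])
  expect_equal(m$total_parasitism, c(1, 0.5))
  expect_equal(m$sigma_dispersal[1], 30)
  expect_true(is.na(m$sigma_dispersal[2]))  # single parasitised host
})
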