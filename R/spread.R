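# Population-spread statistics: MSD, quantile fronts, diffusion and
# changepoint fits, replicate bootstrap CIs, treatment comparisons.

check_detections <- function(data) {
  miss <- setdiff(c("t", "s"), names(data))
  if (length(miss))
    stop("detection table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  data
}

#' Mean squared displacement over time
#'
#' At every minute `t`, the MSD is the mean of squared signed distances from
#' the release point, \eqn{MSD_t = \sum_i x_{it}^2 / N_t}, pooling all
#' detections within a moving window of `± window` minutes across replicates.
#' Pooling weights each replicate by its number of detections. Windows with
#' no detections yield `NA`, never zero.
#'
#' @param data Detection tibble with columns `t`, `s` and optionally
#'   `replicate`.
#' @param window Half-width of the moving window in minutes (default 7).
#' @param times Integer minutes at which to evaluate (default all minutes
#'   from 1 to `max(t)`).
#' @param ci If `TRUE`, add a replicate-level bootstrap percentile CI.
#' @param B Bootstrap resamples for the CI (default 2000).
#'
#' @return A tibble of class `msd_series`: `t`, `msd` (cm²), `n_detections`,
#'   plus `ci_low`/`ci_high` when `ci = TRUE`.
#' @export
compute_msd <- function(data, window = 7, times = NULL, ci = FALSE, B = 2000) {
  data <- check_detections(data)
  stopifnot(window >= 0, nrow(data) > 0)
  if (is.null(times)) times <- seq_len(max(data$t))
  out <- pooled_window_stat(data, times, window,
                            function(x) sum(x^2) / length(x))
  names(out)[names(out) == "value"] <- "msd"
  if (ci) {
    cis <- bootstrap_replicates(
      data,
      function(d) pooled_window_stat(d, times, window,
                                     function(x) sum(x^2) / length(x))$value,
      B = B
    )
    out$ci_low <- cis$ci_low
    out$ci_high <- cis$ci_high
  }
  class(out) <- c("msd_series", class(out))
  out
}

# evaluate stat(|pool of s|) over moving windows; returns tibble
pooled_window_stat <- function(data, times, window, stat, use_abs = FALSE) {
  by_min <- split(data$s, factor(data$t, levels = seq_len(max(data$t, times))))
  value <- numeric(length(times))
  n_det <- integer(length(times))
  Tmax <- length(by_min)
  for (i in seq_along(times)) {
    t0 <- times[i]
    lo <- max(1, t0 - window); hi <- min(Tmax, t0 + window)
    x <- unlist(by_min[lo:hi], use.names = FALSE)
    n_det[i] <- length(x)
    if (use_abs) x <- abs(x)
    value[i] <- if (length(x)) stat(x) else NA_real_
  }
  tibble::tibble(t = times, value = value, n_detections = n_det)
}

#' Population quantiles (front positions) over time
#'
#' The `p`% quantile is the distance from the release point within which
#' `p`% of detected individuals are found, i.e. the empirical `p`-th
#' percentile of `|s|` pooled over the moving window (linear-interpolation
#' convention).
#'
#' @inheritParams compute_msd
#' @param p Percentages in (0, 100); default `c(50, 75, 90, 95, 98, 99)`.
#'
#' @return A tibble of class `quantile_series`: `p`, `t`, `q` (cm),
#'   `n_detections`, plus CI columns when `ci = TRUE`.
#' @export
compute_quantiles <- function(data, p = c(50, 75, 90, 95, 98, 99), window = 7,
                              times = NULL, ci = FALSE, B = 2000) {
  data <- check_detections(data)
  stopifnot(all(p > 0), all(p < 100))
  if (is.null(times)) times <- seq_len(max(data$t))
  one_p <- function(pp, d) {
    res <- pooled_window_stat(d, times, window,
                              function(x) stats::quantile(x, pp / 100,
                                                          names = FALSE),
                              use_abs = TRUE)
    res$p <- pp
    res
  }
  out <- dplyr::bind_rows(lapply(p, one_p, d = data))
  names(out)[names(out) == "value"] <- "q"
  out <- out[, c("p", "t", "q", "n_detections")]
  if (ci) {
    out$ci_low <- NA_real_
    out$ci_high <- NA_real_
    for (pp in p) {
      cis <- bootstrap_replicates(
        data,
        function(d) one_p(pp, d)$value,
        B = B
      )
      out$ci_low[out$p == pp] <- cis$ci_low
      out$ci_high[out$p == pp] <- cis$ci_high
    }
  }
  class(out) <- c("quantile_series", class(out))
  out
}

#' Diffusion coefficient from an MSD series
#'
#' Regresses MSD on time by ordinary least squares over `t >= t_min`
#' (the first 30 minutes are excluded by default to avoid initial-condition
#' and latency effects). The diffusion coefficient `D` is the raw slope in
#' cm² min⁻¹; `D_m2h` converts to m² h⁻¹ (× 0.006).
#'
#' @param series An [compute_msd()] tibble, or any tibble with columns `t`
#'   and `msd` (a `value` column named via `msd_col`).
#' @param t_min Minutes excluded at the start (default 30).
#' @param msd_col Name of the response column (default `"msd"`).
#'
#' @return An object of class `diffusion_fit` with elements `D`, `D_m2h`,
#'   `intercept`, `window` (fitted time range), `n`, `rss`, `sigma`,
#'   `se_D`, `breakpoint = NA` (see [fit_piecewise()] for changepoint fits).
#' @export
fit_diffusion <- function(series, t_min = 30, msd_col = "msd") {
  d <- series[!is.na(series[[msd_col]]) & series$t >= t_min, ]
  if (nrow(d) < 2) stop("fewer than 2 time points after exclusion",
                        call. = FALSE)
  fit <- stats::lm(d[[msd_col]] ~ d$t)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      D = unname(cf[2]), D_m2h = unname(cf[2]) * 0.006,
      intercept = unname(cf[1]),
      window = range(d$t), n = nrow(d),
      rss = sum(stats::resid(fit)^2),
      sigma = sm$sigma,
      se_D = sm$coefficients[2, 2],
      breakpoint = NA_real_, D_before = NA_real_, D_after = NA_real_,
      p_piecewise = NA_real_, reliable = TRUE
    ),
    class = "diffusion_fit"
  )
}

# per-replicate windowed sums of x^2 and detection counts at given times;
# lets the replicate bootstrap recompute pooled MSD series by summing rows
replicate_window_sums <- function(data, times, window) {
  reps <- sort(unique(data$replicate))
  Tmax <- max(data$t, times)
  S2 <- matrix(0, length(reps), length(times))
  N <- matrix(0, length(reps), length(times))
  for (i in seq_along(reps)) {
    d <- data[data$replicate == reps[i], ]
    s2_min <- rep(0, Tmax)
    n_min <- rep(0, Tmax)
    agg_s2 <- tapply(d$s^2, d$t, sum)
    agg_n <- tapply(d$s, d$t, length)
    s2_min[as.integer(names(agg_s2))] <- agg_s2
    n_min[as.integer(names(agg_n))] <- agg_n
    cs2 <- cumsum(c(0, s2_min))
    cn <- cumsum(c(0, n_min))
    lo <- pmax(1, times - window)
    hi <- pmin(Tmax, times + window)
    S2[i, ] <- cs2[hi + 1] - cs2[lo]
    N[i, ] <- cn[hi + 1] - cn[lo]
  }
  list(S2 = S2, N = N)
}

# closed-form OLS for the continuous two-segment model at breakpoint bp
piecewise_rss <- function(t, y, bp) {
  X <- cbind(1, t, pmax(t - bp, 0))
  fit <- stats::.lm.fit(X, y)
  sum(fit$residuals^2)
}

piecewise_best <- function(t, y, grid) {
  rss <- vapply(grid, function(bp) piecewise_rss(t, y, bp), numeric(1))
  k <- which.min(rss)
  list(bp = grid[k], rss = rss[k])
}

#' Piecewise (changepoint) linear fit of an MSD series
#'
#' Fits a continuous two-segment linear model to MSD vs time, with the
#' breakpoint found by grid search over interior times minimising the
#' residual sum of squares. Two bootstrap significance tests against the
#' single-line null are available:
#'
#' * residual bootstrap (`data = NULL`): surrogate series are built from the
#'   single-line fit plus resampled residuals and the p-value is the
#'   fraction of surrogate relative RSS improvements at least as large as
#'   the observed one. Appropriate for a plain series with roughly
#'   independent noise.
#' * replicate bootstrap (`data` given): whole replicates are resampled with
#'   replacement, the windowed MSD series and the piecewise fit are
#'   recomputed, and the p-value is the two-sided percentile test of zero
#'   slope change (`D_after - D_before`). This is the right test for pooled
#'   multi-replicate series, whose moving-window noise is strongly
#'   autocorrelated.
#'
#' @inheritParams fit_diffusion
#' @param B Bootstrap resamples for the significance test (default 200).
#' @param grid_by Spacing in minutes of the breakpoint search grid
#'   (default 1).
#' @param edge_frac Fraction of the fitted window at each end excluded from
#'   the breakpoint grid; a best breakpoint on the grid edge is flagged
#'   `reliable = FALSE` (default 0.05).
#' @param data Optional detection tibble (with `replicate`) from which
#'   `series` was computed; switches the significance test to the replicate
#'   bootstrap.
#' @param window Moving-window half-width used to recompute the MSD series
#'   in the replicate bootstrap (default 7; match the value used for
#'   `series`).
#'
#' @return A `diffusion_fit` object with `breakpoint`, `D_before`,
#'   `D_after`, `p_piecewise`, `rss` (piecewise), `rss_linear` and
#'   `reliable` filled in; `D` is the overall single-line slope for
#'   reference.
#' @export
fit_piecewise <- function(series, t_min = 30, msd_col = "msd", B = 200,
                          grid_by = 1, edge_frac = 0.05, data = NULL,
                          window = 7) {
  d <- series[!is.na(series[[msd_col]]) & series$t >= t_min, ]
  if (nrow(d) < 10) stop("piecewise fit needs at least 10 points",
                         call. = FALSE)
  stopifnot(B >= 1)
  t <- d$t; y <- d[[msd_col]]
  rng <- range(t)
  margin <- max(edge_frac * diff(rng), 2 * grid_by)
  # candidate breakpoints are observed interior times, thinned by grid_by
  grid <- sort(unique(t[t >= rng[1] + margin & t <= rng[2] - margin]))
  if (grid_by > 1) grid <- grid[seq(1, length(grid), by = grid_by)]
  if (length(grid) < 2) stop("time window too short for breakpoint search",
                             call. = FALSE)

  lin <- stats::lm(y ~ t)
  rss1 <- sum(stats::resid(lin)^2)
  best <- piecewise_best(t, y, grid)
  stat_obs <- (rss1 - best$rss) / best$rss

  cf <- stats::coef(stats::lm(y ~ t + pmax(t - best$bp, 0)))
  D_before <- unname(cf[2]); D_after <- unname(cf[2] + cf[3])

  if (is.null(data)) {
    # surrogate series under the single-line null (residual bootstrap)
    fitted1 <- stats::fitted(lin)
    res1 <- stats::resid(lin)
    stat_null <- numeric(B)
    for (b in seq_len(B)) {
      yb <- fitted1 + sample(res1, replace = TRUE)
      rss1b <- sum(stats::.lm.fit(cbind(1, t), yb)$residuals^2)
      bb <- piecewise_best(t, yb, grid)
      stat_null[b] <- (rss1b - bb$rss) / bb$rss
    }
    p <- (1 + sum(stat_null >= stat_obs)) / (B + 1)
  } else {
    # replicate bootstrap: percentile test of zero slope change
    data <- check_detections(data)
    sums <- replicate_window_sums(data, t, window)
    reps <- nrow(sums$S2)
    delta <- numeric(B)
    for (b in seq_len(B)) {
      take <- sample.int(reps, replace = TRUE)
      S2 <- colSums(sums$S2[take, , drop = FALSE])
      N <- colSums(sums$N[take, , drop = FALSE])
      ok <- N > 0
      if (sum(ok) < 10) { delta[b] <- NA; next }
      bb <- piecewise_best(t[ok], S2[ok] / N[ok], grid)
      cfb <- stats::.lm.fit(cbind(1, t[ok], pmax(t[ok] - bb$bp, 0)),
                            S2[ok] / N[ok])$coefficients
      delta[b] <- cfb[3]
    }
    delta <- delta[!is.na(delta)]
    p_lo <- (1 + sum(delta >= 0)) / (length(delta) + 1)
    p_hi <- (1 + sum(delta <= 0)) / (length(delta) + 1)
    p <- min(1, 2 * min(p_lo, p_hi))
  }

  structure(
    list(
      D = unname(stats::coef(lin)[2]),
      D_m2h = unname(stats::coef(lin)[2]) * 0.006,
      intercept = unname(cf[1]),
      window = rng, n = length(t),
      rss = best$rss, rss_linear = rss1,
      sigma = sqrt(best$rss / (length(t) - 3)),
      se_D = suppressWarnings(summary(lin))$coefficients[2, 2],
      breakpoint = best$bp,
      D_before = D_before, D_after = D_after,
      D_before_m2h = D_before * 0.006, D_after_m2h = D_after * 0.006,
      p_piecewise = p,
      reliable = best$bp > min(grid) && best$bp < max(grid)
    ),
    class = "diffusion_fit"
  )
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("<diffusion_fit> over t in [", x$window[1], ", ", x$window[2],
      "] min, n = ", x$n, "\n", sep = "")
  if (is.na(x$breakpoint)) {
    cat("  D = ", signif(x$D, 4), " cm2/min (",
        signif(x$D_m2h, 4), " m2/h)\n", sep = "")
  } else {
    cat("  breakpoint at t = ", x$breakpoint, " min (p = ",
        signif(x$p_piecewise, 3), ")\n", sep = "")
    cat("  D before = ", signif(x$D_before, 4), ", after = ",
        signif(x$D_after, 4), " cm2/min\n", sep = "")
    if (!x$reliable) cat("  note: breakpoint on grid edge, unreliable\n")
  }
  invisible(x)
}

#' Replicate-level bootstrap percentile confidence interval
#'
#' Resamples whole replicates with replacement (never individual detections,
#' which are autocorrelated within a replicate) and returns the 2.5% and
#' 97.5% percentiles of the recomputed statistic.
#'
#' @param data Detection tibble with a `replicate` column.
#' @param statistic Function taking a detection tibble and returning a
#'   numeric scalar or vector (of fixed length).
#' @param B Number of resamples (default 2000).
#' @param probs CI percentiles (default `c(0.025, 0.975)`).
#'
#' @return A tibble with columns `ci_low` and `ci_high`, one row per element
#'   of the statistic.
#' @export
bootstrap_replicates <- function(data, statistic, B = 2000,
                                 probs = c(0.025, 0.975)) {
  stopifnot(B >= 1)
  data <- check_detections(data)
  reps <- unique(data$replicate)
  if (length(reps) < 2)
    warning("fewer than 2 replicates: bootstrap CI is degenerate",
            call. = FALSE)
  by_rep <- split(seq_len(nrow(data)), data$replicate)
  draws <- matrix(NA_real_, nrow = B, ncol = length(statistic(data)))
  for (b in seq_len(B)) {
    take <- sample(reps, replace = TRUE)
    rows <- unlist(by_rep[as.character(take)], use.names = FALSE)
    d <- data[rows, ]
    # resampled copies of the same replicate must stay distinct
    d$replicate <- rep(seq_along(take),
                       times = lengths(by_rep[as.character(take)]))
    draws[b, ] <- statistic(d)
  }
  qs <- apply(draws, 2, stats::quantile, probs = probs, na.rm = TRUE,
              names = FALSE)
  tibble::tibble(ci_low = qs[1, ], ci_high = qs[2, ])
}

#' Pairwise treatment comparisons with FDR correction
#'
#' Compares a per-replicate statistic between treatments with pairwise
#' Wilcoxon rank tests and adjusts the family of p-values with the
#' Benjamini–Hochberg procedure. Treatments are unpaired replicate sets, so
#' the rank-sum (Mann–Whitney) form is used.
#'
#' @param data Tibble with one row per replicate.
#' @param value Column with the per-replicate statistic (tidy-eval).
#' @param group Grouping column (default `treatment`).
#'
#' @return A tibble: `group1`, `group2`, `statistic`, `p_value`,
#'   `p_adjusted`, `n1`, `n2`, `flag` (`"small_n"` when a group has fewer
#'   than 3 replicates).
#' @export
compare_treatments <- function(data, value, group = treatment) {
  value <- rlang::enquo(value); group <- rlang::enquo(group)
  v <- rlang::eval_tidy(value, data)
  g <- as.character(rlang::eval_tidy(group, data))
  lev <- unique(g)
  if (length(lev) < 2) stop("need at least 2 groups", call. = FALSE)
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    x <- v[g == g1]; y <- v[g == g2]
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    tibble::tibble(
      group1 = g1, group2 = g2,
      statistic = unname(wt$statistic), p_value = wt$p.value,
      n1 = length(x), n2 = length(y),
      flag = ifelse(length(x) < 3 || length(y) < 3, "small_n", NA_character_)
    )
  })
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res[, c("group1", "group2", "statistic", "p_value", "p_adjusted",
          "n1", "n2", "flag")]
}
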