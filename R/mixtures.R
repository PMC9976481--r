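# Centred distribution fits: zero-mean Gaussian mixtures by EM, Student
# fits, AIC model selection, time-resolved resident/explorer decomposition
# and Gaussianity diagnostics.

#' Fit a zero-mean Gaussian mixture by EM
#'
#' Maximum-likelihood fit of a K-component Gaussian mixture in which every
#' component mean is fixed at zero (the release point), so only the weights
#' \eqn{\pi_k} and scales \eqn{\sigma_k} are estimated. The EM update keeps
#' the component means at zero; scales are initialised at
#' \eqn{\{0.5, 2\} \times} the sample SD (with seeded jitter across
#' multi-starts) and components are returned sorted by increasing
#' \eqn{\sigma}. For `K = 1` the closed-form centred MLE
#' \eqn{\hat\sigma^2 = \sum x_i^2 / n} is used. The number of free
#' parameters is \eqn{2K - 1}, so `AIC = 2(2K - 1) - 2 logLik`.
#'
#' In the two-component case the narrow component is interpreted as the
#' "resident" and the broad component as the "explorer" movement mode. Fits
#' with \eqn{\sigma_K / \sigma_1 < 1.1} are flagged effectively unimodal
#' (weights are then barely identifiable).
#'
#' @param x Numeric vector of signed positions (cm).
#' @param K Number of components (1, 2 or 3 are typical).
#' @param n_starts Number of EM multi-starts (default 5).
#' @param max_iter Maximum EM iterations per start (default 500).
#' @param tol Stop when the log-likelihood gain drops below this
#'   (default 1e-8).
#'
#' @return An object of class `mixture_fit`: `K`, `weights`, `scales`
#'   (increasing), `loglik`, `aic`, `n`, `converged`, `degenerate`,
#'   `unimodal`, `iterations`.
#' @export
fit_centred_mixture <- function(x, K = 2, n_starts = 5, max_iter = 500,
                                tol = 1e-8) {
  x <- x[is.finite(x)]
  n <- length(x)
  stopifnot(K >= 1, n >= 10 * K)
  sd0 <- sqrt(mean(x^2))
  if (sd0 == 0) stop("all positions are zero: scales are degenerate",
                     call. = FALSE)

  if (K == 1) {
    ll <- sum(stats::dnorm(x, 0, sd0, log = TRUE))
    return(new_mixture_fit(1L, 1, sd0, ll, n, TRUE, FALSE, FALSE, 0L))
  }

  base_scales <- sd0 * exp(seq(log(0.5), log(2), length.out = K))
  best <- NULL
  for (st in seq_len(n_starts)) {
    jit <- if (st == 1) rep(1, K) else exp(stats::rnorm(K, 0, 0.4))
    fit <- em_centred(x, sort(base_scales * jit), rep(1 / K, K),
                      max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  o <- order(best$scales)
  w <- best$weights[o]; s <- best$scales[o]
  degen <- any(s < 1e-8 * sd0) || any(w < 1e-6)
  unimodal <- s[K] / s[1] < 1.1
  new_mixture_fit(as.integer(K), w, s, best$loglik, n, best$converged,
                  degen, unimodal, best$iterations)
}

new_mixture_fit <- function(K, weights, scales, loglik, n, converged,
                            degenerate, unimodal, iterations) {
  structure(
    list(K = K, weights = weights, scales = scales, loglik = loglik,
         aic = 2 * (2 * K - 1) - 2 * loglik, n = n, converged = converged,
         degenerate = degenerate, unimodal = unimodal,
         iterations = iterations),
    class = "mixture_fit"
  )
}

# EM for a zero-mean Gaussian mixture; returns unsorted components
em_centred <- function(x, scales, weights, max_iter, tol) {
  n <- length(x)
  K <- length(scales)
  x2 <- x^2
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  const <- -0.5 * log(2 * pi)
  for (iter in seq_len(max_iter)) {
    # log(pi_k) + log N(x; 0, sigma_k) as an n x K matrix, built by sweeps
    logd <- tcrossprod(x2, -1 / (2 * scales^2))
    logd <- sweep(logd, 2, log(weights) - log(scales) + const, "+")
    m <- logd[max.col(logd) * n - n + seq_len(n)]
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    wsum <- colSums(resp)
    weights <- wsum / n
    scales <- sqrt(colSums(resp * x2) / pmax(wsum, 1e-300))
    scales <- pmax(scales, 1e-12)
    if (ll - ll_old < tol && iter > 1) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(weights = weights, scales = scales, loglik = ll,
       converged = converged, iterations = iter)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> K = ", x$K, ", n = ", x$n, "\n", sep = "")
  for (k in seq_len(x$K))
    cat(sprintf("  component %d: weight %.3f, sigma %.3f cm\n",
                k, x$weights[k], x$scales[k]))
  cat("  logLik ", round(x$loglik, 2), ", AIC ", round(x$aic, 2), "\n",
      sep = "")
  if (!x$converged) cat("  warning: EM did not converge\n")
  if (x$degenerate) cat("  warning: degenerate component\n")
  if (x$unimodal) cat("  note: scales within 10%, effectively unimodal\n")
  invisible(x)
}

#' Fit a centred Student t distribution
#'
#' Maximum-likelihood fit of a zero-location Student t with free scale and
#' degrees of freedom, the limit of a Gaussian scale mixture with many
#' heterogeneous variances. \eqn{\nu} is capped at 1000 (the Gaussian
#' limit); `AIC = 2·2 - 2 logLik`.
#'
#' @param x Numeric vector of signed positions.
#' @param nu_max Upper bound on the degrees of freedom (default 1000).
#'
#' @return An object of class `student_fit`: `scale`, `df`, `loglik`,
#'   `aic`, `n`, `converged`, `at_cap`.
#' @export
fit_centred_student <- function(x, nu_max = 1000) {
  x <- x[is.finite(x)]
  n <- length(x)
  stopifnot(n >= 10)
  negll <- function(p) {
    s <- exp(p[1]); nu <- exp(p[2])
    -sum(stats::dt(x / s, df = nu, log = TRUE) - log(s))
  }
  s0 <- stats::sd(x)
  opt <- stats::optim(c(log(s0), log(10)), negll, method = "L-BFGS-B",
                      lower = c(log(s0) - 15, log(0.1)),
                      upper = c(log(s0) + 15, log(nu_max)))
  structure(
    list(scale = exp(opt$par[1]), df = exp(opt$par[2]),
         loglik = -opt$value, aic = 2 * 2 + 2 * opt$value, n = n,
         converged = opt$convergence == 0,
         at_cap = exp(opt$par[2]) > nu_max * 0.999),
    class = "student_fit"
  )
}

#' @export
print.student_fit <- function(x, ...) {
  cat("<student_fit> scale ", signif(x$scale, 4), " cm, df ",
      signif(x$df, 4), if (x$at_cap) " (at cap: Gaussian limit)" else "",
      "\n  logLik ", round(x$loglik, 2), ", AIC ", round(x$aic, 2), "\n",
      sep = "")
  invisible(x)
}

#' Model selection among centred position distributions
#'
#' Fits the centred Gaussian, 2- and 3-component zero-mean Gaussian mixtures
#' and the centred Student t to the same positions and ranks them by AIC.
#' For time-resolved data, fit unpooled per-minute positions (no moving
#' window) to avoid pseudoreplication.
#'
#' @inheritParams fit_centred_mixture
#' @return An object of class `model_selection`: `table` (tibble with
#'   `model`, `k_params`, `loglik`, `aic`, `delta_aic`, ranked), `winner`,
#'   and `fits` (named list of the four fit objects).
#' @export
select_model <- function(x, n_starts = 5) {
  x <- x[is.finite(x)]
  stopifnot(length(x) >= 30)
  fits <- list(
    gaussian = fit_centred_mixture(x, 1),
    gmix2 = fit_centred_mixture(x, 2, n_starts = n_starts),
    gmix3 = fit_centred_mixture(x, 3, n_starts = n_starts),
    student = fit_centred_student(x)
  )
  tab <- tibble::tibble(
    model = c("gaussian", "gmix2", "gmix3", "student"),
    k_params = c(1L, 3L, 5L, 2L),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1))
  )
  tab$delta_aic <- tab$aic - min(tab$aic)
  tab <- tab[order(tab$aic), ]
  structure(
    list(table = tab, winner = tab$model[1], fits = fits, n = length(x)),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("<model_selection> n = ", x$n, ", winner: ", x$winner, "\n", sep = "")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' Time-resolved resident/explorer decomposition
#'
#' Fits the two-component zero-mean Gaussian mixture to positions pooled in
#' short windows on a regular time grid (every 15 min over 10-min windows by
#' default) and tracks the explorer proportion and the component scales over
#' time. The component MSD of the explorer mode is \eqn{\sigma_e^2(t)}.
#' Confidence intervals come from a replicate-level bootstrap; estimates
#' before `t_reliable` (default 60 min) are flagged, the distribution being
#' still close to Gaussian early on.
#'
#' @param data Detection tibble with `t`, `s` and optionally `replicate`.
#' @param grid_by Grid spacing in minutes (default 15).
#' @param window Total window width in minutes pooled around each grid time
#'   (default 10, i.e. ± 5).
#' @param B Bootstrap resamples (default 600); `0` skips CIs. Bootstrap
#'   refits are warm-started at the point estimate with a single EM start.
#' @param min_detections Minimum pooled detections per window; sparser grid
#'   times are skipped with a warning (default 50).
#' @param t_reliable Grid times earlier than this are flagged unreliable
#'   (default 60).
#'
#' @return A tibble of class `component_trajectory`: `t`, `pi_explorer`,
#'   `sigma_resident`, `sigma_explorer`, `msd_explorer`, `n_detections`,
#'   `reliable`, `degenerate`, plus bootstrap CI columns (`pi_lo`, `pi_hi`,
#'   `sigma_explorer_lo`, `sigma_explorer_hi`, `msd_explorer_lo`,
#'   `msd_explorer_hi`) when `B > 0`.
#' @export
track_components <- function(data, grid_by = 15, window = 10, B = 600,
                             min_detections = 50, t_reliable = 60) {
  data <- check_detections(data)
  half <- window / 2
  grid <- seq(grid_by, max(data$t), by = grid_by)
  rows <- purrr::map(grid, function(t0) {
    sel <- data[abs(data$t - t0) <= half, ]
    if (nrow(sel) < min_detections) {
      warning("skipping t = ", t0, ": only ", nrow(sel), " detections",
              call. = FALSE)
      return(NULL)
    }
    fit <- fit_centred_mixture(sel$s, 2)
    out <- tibble::tibble(
      t = t0, pi_explorer = fit$weights[2],
      sigma_resident = fit$scales[1], sigma_explorer = fit$scales[2],
      msd_explorer = fit$scales[2]^2,
      n_detections = nrow(sel), reliable = t0 >= t_reliable,
      degenerate = fit$degenerate || fit$unimodal || !fit$converged
    )
    if (B > 0) {
      boot <- bootstrap_replicates(sel, function(d) {
        f <- em_centred(d$s, fit$scales, fit$weights, 200, 1e-8)
        o <- order(f$scales)
        c(f$weights[o][2], f$scales[o][2], f$scales[o][2]^2)
      }, B = B)
      out$pi_lo <- boot$ci_low[1]; out$pi_hi <- boot$ci_high[1]
      out$sigma_explorer_lo <- boot$ci_low[2]
      out$sigma_explorer_hi <- boot$ci_high[2]
      out$msd_explorer_lo <- boot$ci_low[3]
      out$msd_explorer_hi <- boot$ci_high[3]
    }
    out
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("component_trajectory", class(out))
  out
}

#' Diffusion fit of the explorer-component MSD
#'
#' Applies [fit_diffusion()] and [fit_piecewise()] to the explorer-component
#' MSD series \eqn{\sigma_e^2(t)} from [track_components()] and reports the
#' better-supported model (piecewise when its bootstrap p-value is below
#' `alpha`).
#'
#' @param traj A [track_components()] tibble.
#' @param t_min Minutes excluded at the start (default 30).
#' @param B Bootstrap resamples for the piecewise significance (default 200).
#' @param alpha Significance level for preferring the piecewise model
#'   (default 0.05).
#' @param reliable_only Drop grid times flagged unreliable (default `TRUE`).
#'
#' @return A list with `linear` and `piecewise` (`diffusion_fit` objects)
#'   and `preferred` (`"linear"` or `"piecewise"`).
#' @export
component_diffusion <- function(traj, t_min = 30, B = 200, alpha = 0.05,
                                reliable_only = TRUE) {
  d <- traj
  if (reliable_only && "reliable" %in% names(d)) d <- d[d$reliable, ]
  if (nrow(d) < 10) stop("need at least 10 grid points", call. = FALSE)
  lin <- fit_diffusion(d, t_min = t_min, msd_col = "msd_explorer")
  pw <- fit_piecewise(d, t_min = t_min, msd_col = "msd_explorer", B = B,
                      grid_by = max(1, diff(range(d$t)) / 100))
  list(linear = lin, piecewise = pw,
       preferred = if (!is.na(pw$p_piecewise) && pw$p_piecewise < alpha &&
                       pw$reliable) "piecewise" else "linear")
}

#' Gaussianity diagnostics for position distributions
#'
#' Excess kurtosis and decile deviations from the fitted centred Gaussian.
#' Because the distributions are centred on the release point, moments are
#' taken about zero: kurtosis is \eqn{m_4 / m_2^2 - 3} with
#' \eqn{m_j = \sum x^j / n}. Positive excess kurtosis (leptokurtic
#' distribution) is the signature of a scale mixture of Gaussians. With
#' `per_replicate_normalize = TRUE` each replicate is first scaled to unit
#' variance, separating within-replicate heterogeneity from inter-replicate
#' variance differences: pure inter-replicate heterogeneity then yields
#' kurtosis near zero whereas a true within-replicate mixture stays
#' leptokurtic.
#'
#' @param data Detection tibble (`s`, optionally `replicate`) or a numeric
#'   vector of positions.
#' @param per_replicate_normalize Scale each replicate to unit variance
#'   before pooling (default `FALSE`).
#'
#' @return A list with `excess_kurtosis`, `n`, and `qq`: a tibble of decile
#'   probabilities with empirical and fitted-Gaussian quantiles and their
#'   deviation.
#' @export
gaussianity_diagnostics <- function(data, per_replicate_normalize = FALSE) {
  if (is.numeric(data)) data <- tibble::tibble(t = 1L, s = data)
  data <- check_detections(data)
  x <- data$s
  stopifnot(length(x) >= 30)
  if (per_replicate_normalize) {
    x <- unlist(lapply(split(data$s, data$replicate), function(v) {
      s <- sqrt(mean(v^2))
      if (s > 0) v / s else v
    }), use.names = FALSE)
  }
  m2 <- mean(x^2); m4 <- mean(x^4)
  probs <- seq(0.1, 0.9, by = 0.1)
  emp <- stats::quantile(x, probs, names = FALSE)
  theo <- stats::qnorm(probs, 0, sqrt(m2))
  list(
    excess_kurtosis = m4 / m2^2 - 3,
    n = length(x),
    qq = tibble::tibble(p = probs, empirical = emp, gaussian = theo,
                        deviation = emp - theo)
  )
}
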