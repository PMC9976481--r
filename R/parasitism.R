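# Dispersal-kernel estimation and the movement-to-parasitism linkage:
# on-host fractions, discovery times, discoverer-type assignment, gain
# function and cross-replicate correlations.

check_hosts <- function(hosts) {
  miss <- setdiff(c("s", "parasitized"), names(hosts))
  if (length(miss))
    stop("host table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  hosts
}

#' Dispersal kernel from parasitism data
#'
#' Bins hosts by signed position (default 30-cm bins, the spacing between
#' consecutive patches in the clumped layout) and computes the fraction
#' parasitised per bin. The dispersal distance `sigma_dispersal` is the
#' standard deviation of the signed distances from the release point to
#' parasitised hosts, taken about the release point (the kernel's centre),
#' i.e. \eqn{\sqrt{\mathrm{mean}(s^2)}} — the dispersal coefficient
#' \eqn{\sigma} in the usual population-biology sense. A centred Gaussian
#' \eqn{f(s) = A e^{-s^2 / 2\sigma^2}} is fitted to the binned fractions by
#' least squares.
#'
#' @param hosts Host tibble with columns `s` and `parasitized` (pool
#'   replicates for the population kernel).
#' @param bin Bin width in cm (default 30).
#'
#' @return An object of class `kernel_fit`: `bins` (tibble `bin_centre`,
#'   `n_hosts`, `n_parasitized`, `fraction`), `sigma_dispersal` (`NA` with a
#'   flag when nothing is parasitised), `gaussian_fit` (`amplitude`,
#'   `sigma`, `rss`, `r_squared`), `n_hosts`, `n_parasitized`, `flags`.
#' @export
dispersal_kernel <- function(hosts, bin = 30) {
  hosts <- check_hosts(hosts)
  stopifnot(nrow(hosts) >= 1, bin > 0)
  edges <- seq(-ceiling(max(abs(hosts$s)) / bin) * bin,
               ceiling(max(abs(hosts$s)) / bin) * bin, by = bin)
  idx <- cut(hosts$s, edges, include.lowest = TRUE)
  bins <- tibble::tibble(
    bin_centre = (edges[-length(edges)] + edges[-1]) / 2,
    n_hosts = as.integer(table(idx)),
    n_parasitized = as.integer(tapply(hosts$parasitized, idx, sum,
                                      default = 0))
  )
  bins <- bins[bins$n_hosts > 0, ]
  bins$fraction <- bins$n_parasitized / bins$n_hosts

  par_s <- hosts$s[hosts$parasitized]
  flags <- character()
  sigma_disp <- NA_real_
  if (length(par_s) == 0) {
    flags <- c(flags, "no_parasitism")
  } else {
    sigma_disp <- sqrt(mean(par_s^2))
  }
  if (nrow(bins) > 1 && stats::sd(bins$fraction) == 0)
    flags <- c(flags, "flat_kernel", "poor_gaussian_fit")

  gfit <- list(amplitude = NA_real_, sigma = NA_real_, rss = NA_real_,
               r_squared = NA_real_)
  if (sum(bins$fraction > 0) >= 3) {
    obj <- function(p) {
      A <- exp(p[1]); sg <- exp(p[2])
      sum((bins$fraction - A * exp(-bins$bin_centre^2 / (2 * sg^2)))^2)
    }
    start <- c(log(max(bins$fraction)),
               log(max(stats::sd(rep(bins$bin_centre, bins$n_parasitized)),
                       bin)))
    opt <- stats::optim(start, obj, method = "Nelder-Mead")
    A <- exp(opt$par[1]); sg <- exp(opt$par[2])
    tss <- sum((bins$fraction - mean(bins$fraction))^2)
    r2 <- if (tss > 0) 1 - opt$value / tss else NA_real_
    gfit <- list(amplitude = A, sigma = sg, rss = opt$value, r_squared = r2)
    if (!is.na(r2) && r2 < 0.5) flags <- c(flags, "poor_gaussian_fit")
  } else {
    flags <- c(flags, "too_few_nonzero_bins")
  }

  structure(
    list(bins = bins, sigma_dispersal = sigma_disp, gaussian_fit = gfit,
         n_hosts = nrow(hosts), n_parasitized = length(par_s),
         flags = flags),
    class = "kernel_fit"
  )
}

#' @export
print.kernel_fit <- function(x, ...) {
  cat("<kernel_fit> ", x$n_parasitized, "/", x$n_hosts,
      " hosts parasitised\n", sep = "")
  cat("  sigma_dispersal = ", signif(x$sigma_dispersal, 4), " cm\n",
      sep = "")
  if (!is.na(x$gaussian_fit$sigma))
    cat("  Gaussian fit: amplitude ", signif(x$gaussian_fit$amplitude, 3),
        ", sigma ", signif(x$gaussian_fit$sigma, 4), " cm, R2 ",
        signif(x$gaussian_fit$r_squared, 3), "\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of individuals in immediate host proximity
#'
#' For each focal time and 10-cm position bin, the fraction of detections
#' within the reactive distance of some host, with a loess-smoothed spatial
#' trend per focal time. Ground-truth tables can use the `on_host` column
#' directly via `rule = "truth"`; otherwise proximity along the linear
#' coordinate is used.
#'
#' @param data Detection tibble (`t`, `s`, optionally `on_host`).
#' @param layout Host layout or host tibble with column `s`.
#' @param times Focal times in minutes (default `c(15, 180, 380)`).
#' @param window Half-window in minutes pooled around each focal time
#'   (default 5).
#' @param bin Position bin width in cm (default 10).
#' @param reactive_distance Proximity radius in cm (default 0.4).
#' @param rule `"proximity"` (distance to nearest host) or `"truth"` (use
#'   the simulator's `on_host` ground-truth column).
#' @param span Loess span for the smoothed trend (default 0.5).
#'
#' @return A tibble: `time`, `bin_centre`, `n`, `n_on_host`, `fraction`,
#'   `smooth` (loess trend over occupied bins; `NA` when a focal time has
#'   too few bins).
#' @export
on_host_fraction <- function(data, layout, times = c(15, 180, 380),
                             window = 5, bin = 10, reactive_distance = 0.4,
                             rule = c("proximity", "truth"), span = 0.5) {
  rule <- match.arg(rule)
  data <- check_detections(data)
  if (nrow(layout) == 0) stop("no hosts in layout", call. = FALSE)
  if (rule == "truth" && !"on_host" %in% names(data))
    stop("rule = \"truth\" needs an on_host column", call. = FALSE)
  purrr::map_dfr(times, function(t0) {
    sel <- data[abs(data$t - t0) <= window, ]
    if (nrow(sel) == 0) return(NULL)
    on <- if (rule == "truth") {
      !is.na(sel$on_host)
    } else {
      d <- abs(outer(sel$s, layout$s, "-"))
      apply(d, 1, min) <= reactive_distance
    }
    ctr <- round(sel$s / bin) * bin
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(bin_centre = ctr, on = on), bin_centre),
      n = dplyr::n(), n_on_host = sum(on), .groups = "drop"
    )
    agg$fraction <- agg$n_on_host / agg$n
    agg$time <- t0
    agg$smooth <- NA_real_
    if (nrow(agg) >= 8) {
      lo <- stats::loess(fraction ~ bin_centre, data = agg, span = span,
                         degree = 2)
      agg$smooth <- stats::predict(lo, agg$bin_centre)
    }
    agg[, c("time", "bin_centre", "n", "n_on_host", "fraction", "smooth")]
  })
}

#' Host discovery times versus position
#'
#' Returns first-discovery records for discovered hosts as a function of
#' distance from the release point, with a loess-smoothed trend.
#'
#' @param hosts Host tibble with `s` and `first_discovery` (`NA` when never
#'   discovered).
#' @param span Loess span (default 0.75).
#'
#' @return A tibble: `host_id` (if present), `s`, `distance = |s|`,
#'   `first_discovery`, `smooth` (trend of discovery time vs distance).
#' @export
discovery_times <- function(hosts, span = 0.75) {
  stopifnot("first_discovery" %in% names(hosts))
  d <- hosts[!is.na(hosts$first_discovery), ]
  if (nrow(d) == 0) stop("no discovered hosts", call. = FALSE)
  out <- tibble::tibble(
    s = d$s, distance = abs(d$s),
    first_discovery = as.numeric(d$first_discovery)
  )
  if ("host_id" %in% names(d)) out <- dplyr::bind_cols(
    tibble::tibble(host_id = d$host_id), out)
  out$smooth <- NA_real_
  if (nrow(out) >= 10) {
    lo <- stats::loess(first_discovery ~ distance, data = out, span = span,
                       degree = 1)
    out$smooth <- stats::predict(lo, out$distance)
  }
  out
}

#' Assign the likely discoverer type of each parasitised host
#'
#' Uses the time-resolved two-component decomposition to compute, for each
#' discovered host, the posterior probability that its discoverer was an
#' explorer given the host's position and discovery time:
#' \deqn{p_e(s, t) = \frac{\pi_e(t)\,\phi(s; \sigma_e(t))}
#'   {\pi_e(t)\,\phi(s; \sigma_e(t)) + (1 - \pi_e(t))\,\phi(s; \sigma_r(t))}}
#' with \eqn{\phi} the centred Gaussian density. Component parameters are
#' linearly interpolated between grid times. Hosts discovered before the
#' reliability time (or while the fit is degenerate) are left unassigned.
#'
#' @param hosts Host tibble with `s` and `first_discovery`.
#' @param traj A [track_components()] tibble.
#' @param threshold Posterior threshold for the explorer label
#'   (default 0.5).
#' @param t_reliable Discoveries before this time are unassigned
#'   (default 60).
#'
#' @return A tibble: host columns plus `p_explorer` and
#'   `label` (`"explorer"`, `"resident"` or `"unassigned"`).
#' @export
assign_discoverer <- function(hosts, traj, threshold = 0.5,
                              t_reliable = 60) {
  stopifnot(all(c("s", "first_discovery") %in% names(hosts)),
            nrow(traj) >= 2)
  d <- hosts[!is.na(hosts$first_discovery), ]
  ok_traj <- traj[!traj$degenerate, ]
  if (nrow(ok_traj) < 2) stop("component trajectory is degenerate",
                              call. = FALSE)
  ap <- function(col, t) stats::approx(ok_traj$t, ok_traj[[col]], xout = t,
                                       rule = 2)$y
  t <- as.numeric(d$first_discovery)
  pi_e <- ap("pi_explorer", t)
  sig_e <- ap("sigma_explorer", t)
  sig_r <- ap("sigma_resident", t)
  num <- pi_e * stats::dnorm(d$s, 0, sig_e)
  den <- num + (1 - pi_e) * stats::dnorm(d$s, 0, sig_r)
  p_exp <- ifelse(den > 0, num / den, NA_real_)
  covered <- t >= min(ok_traj$t) & t <= max(ok_traj$t) + 15
  assignable <- t >= t_reliable & !is.na(p_exp) & covered
  out <- tibble::as_tibble(d)
  out$p_explorer <- p_exp
  out$label <- dplyr::case_when(
    !assignable ~ "unassigned",
    p_exp > threshold ~ "explorer",
    TRUE ~ "resident"
  )
  out
}

#' Parasitism gain function
#'
#' Estimates the probability that a host is parasitised as a function of the
#' total visit time it received (cumulated over individuals), as binned
#' empirical proportions plus a fitted saturating curve
#' \eqn{p(T) = a\,(1 - e^{-T/\tau})}. Under the constant-hazard model the
#' asymptote is \eqn{a = 1} and the curve is concave, saturating near 1
#' after a few multiples of \eqn{\tau}.
#'
#' @param hosts Host tibble with `total_visit` and `parasitized`.
#' @param breaks Bin breaks for total visit time in minutes, or a single bin
#'   width (default 15).
#'
#' @return An object of class `gain_curve`: `bins` (tibble `T_mid`, `n`,
#'   `n_parasitized`, `fraction`, binomial `ci_low`/`ci_high`), `fit`
#'   (`asymptote`, `tau`, `converged`), `predict` (function of T), `n_hosts`.
#' @export
gain_curve <- function(hosts, breaks = 15) {
  stopifnot(all(c("total_visit", "parasitized") %in% names(hosts)))
  h <- hosts[!is.na(hosts$total_visit), ]
  if (nrow(h) == 0) stop("no hosts with visit records", call. = FALSE)
  if (length(breaks) == 1)
    breaks <- seq(0, max(h$total_visit) + breaks, by = breaks)
  idx <- cut(h$total_visit, breaks, include.lowest = TRUE, right = FALSE)
  bins <- tibble::tibble(
    T_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    n = as.integer(table(idx)),
    n_parasitized = as.integer(tapply(h$parasitized, idx, sum, default = 0))
  )
  bins <- bins[bins$n > 0, ]
  bins$fraction <- bins$n_parasitized / bins$n
  ci <- t(mapply(function(k, n) stats::binom.test(k, n)$conf.int,
                 bins$n_parasitized, bins$n))
  bins$ci_low <- ci[, 1]; bins$ci_high <- ci[, 2]

  # saturating fit on per-host data (binomial log-likelihood)
  negll <- function(p) {
    a <- stats::plogis(p[1]); tau <- exp(p[2])
    pr <- pmin(pmax(a * (1 - exp(-h$total_visit / tau)), 1e-12), 1 - 1e-12)
    -sum(ifelse(h$parasitized, log(pr), log(1 - pr)))
  }
  opt <- tryCatch(
    stats::optim(c(stats::qlogis(0.95), log(30)), negll,
                 method = "Nelder-Mead"),
    error = function(e) NULL
  )
  fit <- if (!is.null(opt)) {
    list(asymptote = stats::plogis(opt$par[1]), tau = exp(opt$par[2]),
         converged = opt$convergence == 0)
  } else {
    list(asymptote = NA_real_, tau = NA_real_, converged = FALSE)
  }
  pred <- function(T) fit$asymptote * (1 - exp(-T / fit$tau))
  structure(
    list(bins = bins, fit = fit, predict = pred, n_hosts = nrow(h)),
    class = "gain_curve"
  )
}

#' @export
print.gain_curve <- function(x, ...) {
  cat("<gain_curve> ", x$n_hosts, " hosts\n", sep = "")
  cat("  fitted asymptote ", signif(x$fit$asymptote, 3), ", tau ",
      signif(x$fit$tau, 4), " min\n", sep = "")
  invisible(x)
}

#' Per-replicate movement and parasitism metrics
#'
#' Computes, for each replicate, the end-of-experiment population front (the
#' `p`% quantile of `|s|` over the last `end_window` minutes), the fraction
#' of hosts parasitised and the dispersal distance (SD of parasitised-host
#' positions), plus the end-of-run MSD as an alternative movement predictor.
#'
#' @param detections Detection tibble with `replicate`, `t`, `s`.
#' @param hosts Host tibble with `replicate`, `s`, `parasitized`.
#' @param p Front quantile percentage (default 98).
#' @param end_window Minutes at the end of the run to pool (default 15).
#'
#' @return A tibble with one row per replicate: `replicate`, `front`,
#'   `msd_end`, `total_parasitism`, `sigma_dispersal`.
#' @export
replicate_metrics <- function(detections, hosts, p = 98, end_window = 15) {
  detections <- check_detections(detections)
  t_end <- max(detections$t)
  late <- detections[detections$t > t_end - end_window, ]
  mv <- dplyr::summarise(
    dplyr::group_by(late, replicate),
    front = stats::quantile(abs(s), p / 100, names = FALSE),
    msd_end = mean(s^2), .groups = "drop"
  )
  pr <- dplyr::summarise(
    dplyr::group_by(hosts, replicate),
    total_parasitism = mean(parasitized),
    sigma_dispersal = ifelse(sum(parasitized) >= 2,
                             sqrt(mean(s[parasitized]^2)), NA_real_),
    .groups = "drop"
  )
  dplyr::left_join(mv, pr, by = "replicate")
}

#' Spearman correlations between replicate-level metrics
#'
#' Pairwise Spearman rank correlations (and their squares) between the
#' chosen per-replicate metrics, typically the 98% population front, total
#' parasitism and the dispersal distance.
#'
#' @param data Tibble with one row per replicate (see
#'   [replicate_metrics()]).
#' @param metrics Character vector of column names to correlate (default
#'   `c("front", "total_parasitism", "sigma_dispersal")`).
#'
#' @return A tibble: `metric1`, `metric2`, `rho`, `rho2`, `p_value`, `n`,
#'   `flag` (`"constant_input"` when a metric has no variance).
#' @export
correlate_metrics <- function(data,
                              metrics = c("front", "total_parasitism",
                                          "sigma_dispersal")) {
  stopifnot(all(metrics %in% names(data)))
  if (nrow(data) < 5) stop("need at least 5 replicates", call. = FALSE)
  pairs <- utils::combn(metrics, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    m1 <- pairs[1, k]; m2 <- pairs[2, k]
    ok <- stats::complete.cases(data[[m1]], data[[m2]])
    x <- data[[m1]][ok]; y <- data[[m2]][ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(metric1 = m1, metric2 = m2, rho = NA_real_,
                            rho2 = NA_real_, p_value = NA_real_,
                            n = sum(ok), flag = "constant_input"))
    }
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    tibble::tibble(metric1 = m1, metric2 = m2,
                   rho = unname(ct$estimate), rho2 = unname(ct$estimate)^2,
                   p_value = ct$p.value, n = sum(ok), flag = NA_character_)
  })
}
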