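# broom-style tidy() / glance() methods for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a zero-mean mixture fit
#'
#' @param x A [fit_centred_mixture()] object.
#' @param ... Unused.
#' @return One row per component: `component`, `role` (resident/explorer
#'   labelling for two-component fits), `weight`, `sigma`.
#' @export
tidy.mixture_fit <- function(x, ...) {
  role <- if (x$K == 2) c("resident", "explorer") else
    paste0("component", seq_len(x$K))
  tibble::tibble(component = seq_len(x$K), role = role,
                 weight = x$weights, sigma = x$scales)
}

#' @rdname tidy.mixture_fit
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(K = x$K, loglik = x$loglik, aic = x$aic, n = x$n,
                 converged = x$converged, degenerate = x$degenerate,
                 unimodal = x$unimodal)
}

#' Tidy a centred Student fit
#'
#' @param x A [fit_centred_student()] object.
#' @param ... Unused.
#' @return A one-row tibble with `scale` and `df`.
#' @export
tidy.student_fit <- function(x, ...) {
  tibble::tibble(scale = x$scale, df = x$df)
}

#' @rdname tidy.student_fit
#' @export
glance.student_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, aic = x$aic, n = x$n,
                 converged = x$converged, at_cap = x$at_cap)
}

#' Tidy a diffusion / changepoint fit
#'
#' @param x A [fit_diffusion()] or [fit_piecewise()] object.
#' @param ... Unused.
#' @return For a single-line fit, one row (`term = "D"`); for a piecewise
#'   fit, rows for the slopes before and after the breakpoint. Slopes are in
#'   cm² min⁻¹ with the m² h⁻¹ conversion alongside.
#' @export
tidy.diffusion_fit <- function(x, ...) {
  if (is.na(x$breakpoint)) {
    tibble::tibble(term = "D", estimate = x$D, estimate_m2h = x$D_m2h,
                   std_error = x$se_D)
  } else {
    tibble::tibble(
      term = c("D_before", "D_after"),
      estimate = c(x$D_before, x$D_after),
      estimate_m2h = c(x$D_before, x$D_after) * 0.006,
      std_error = NA_real_
    )
  }
}

#' @rdname tidy.diffusion_fit
#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(
    D = x$D, D_m2h = x$D_m2h, intercept = x$intercept,
    breakpoint = x$breakpoint, p_piecewise = x$p_piecewise,
    t_min = x$window[1], t_max = x$window[2], n = x$n, rss = x$rss,
    reliable = x$reliable
  )
}

#' Tidy an AIC model-selection table
#'
#' @param x A [select_model()] object.
#' @param ... Unused.
#' @return The ranked AIC table as a tibble.
#' @export
tidy.model_selection <- function(x, ...) x$table

#' @rdname tidy.model_selection
#' @export
glance.model_selection <- function(x, ...) {
  tibble::tibble(winner = x$winner, n = x$n,
                 delta_next = x$table$delta_aic[2])
}

#' Tidy a dispersal-kernel fit
#'
#' @param x A [dispersal_kernel()] object.
#' @param ... Unused.
#' @return The binned kernel as a tibble.
#' @export
tidy.kernel_fit <- function(x, ...) x$bins

#' @rdname tidy.kernel_fit
#' @export
glance.kernel_fit <- function(x, ...) {
  tibble::tibble(
    sigma_dispersal = x$sigma_dispersal,
    gaussian_sigma = x$gaussian_fit$sigma,
    gaussian_amplitude = x$gaussian_fit$amplitude,
    gaussian_r2 = x$gaussian_fit$r_squared,
    n_hosts = x$n_hosts, n_parasitized = x$n_parasitized,
    flags = paste(x$flags, collapse = ";")
  )
}

#' Tidy a gain-curve fit
#'
#' @param x A [gain_curve()] object.
#' @param ... Unused.
#' @return The binned empirical proportions as a tibble.
#' @export
tidy.gain_curve <- function(x, ...) x$bins

#' @rdname tidy.gain_curve
#' @export
glance.gain_curve <- function(x, ...) {
  tibble::tibble(asymptote = x$fit$asymptote, tau = x$fit$tau,
                 converged = x$fit$converged, n_hosts = x$n_hosts)
}
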