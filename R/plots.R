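# ggplot2 autoplot() methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an MSD series
#'
#' @param object A [compute_msd()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.msd_series <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data$msd))
  if (all(c("ci_low", "ci_high") %in% names(object)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80")
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = expression(MSD ~ (cm^2)))
}

#' Plot population-quantile series
#'
#' @param object A [compute_quantiles()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.quantile_series <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$t, y = .data$q,
                               colour = factor(.data$p))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "distance from centre (cm)",
                  colour = "quantile (%)")
}

#' Plot a mixture fit over a position histogram
#'
#' @param object A [fit_centred_mixture()] object.
#' @param x Positions the fit was computed on.
#' @param ... Unused.
#' @return A ggplot with the mixture density and its components.
#' @export
autoplot.mixture_fit <- function(object, x, ...) {
  grid <- seq(-max(abs(x)), max(abs(x)), length.out = 400)
  dens <- purrr::map_dfr(seq_len(object$K), function(k) {
    tibble::tibble(s = grid, component = factor(k),
                   density = object$weights[k] *
                     stats::dnorm(grid, 0, object$scales[k]))
  })
  total <- dplyr::summarise(dplyr::group_by(dens, .data$s),
                            density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot(tibble::tibble(s = x), ggplot2::aes(x = .data$s)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component),
                       linetype = "dashed") +
    ggplot2::geom_line(data = total, ggplot2::aes(y = .data$density)) +
    ggplot2::labs(x = "position (cm)", y = "density")
}

#' Plot a component trajectory
#'
#' @param object A [track_components()] tibble.
#' @param what `"pi"` (explorer proportion) or `"msd"` (explorer MSD).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.component_trajectory <- function(object, what = c("pi", "msd"),
                                          ...) {
  what <- match.arg(what)
  ycol <- if (what == "pi") "pi_explorer" else "msd_explorer"
  lo <- paste0(if (what == "pi") "pi" else "msd_explorer", "_lo")
  hi <- paste0(if (what == "pi") "pi" else "msd_explorer", "_hi")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t, y = .data[[ycol]]))
  if (all(c(lo, hi) %in% names(object)))
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[lo]], ymax = .data[[hi]]), fill = "grey80")
  p + ggplot2::geom_point(ggplot2::aes(alpha = .data$reliable)) +
    ggplot2::geom_line() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "time (min)",
                  y = if (what == "pi") "explorer proportion"
                      else expression(MSD[explorer] ~ (cm^2)))
}

#' Plot a dispersal kernel
#'
#' @param object A [dispersal_kernel()] object.
#' @param ... Unused.
#' @return A ggplot of binned parasitised fractions with the fitted
#'   Gaussian.
#' @export
autoplot.kernel_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$bins,
                       ggplot2::aes(x = .data$bin_centre,
                                    y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey80", colour = "grey60") +
    ggplot2::labs(x = "position (cm)", y = "fraction of hosts parasitised")
  if (!is.na(object$gaussian_fit$sigma)) {
    grid <- seq(min(object$bins$bin_centre), max(object$bins$bin_centre),
                length.out = 200)
    fit <- tibble::tibble(
      bin_centre = grid,
      fraction = object$gaussian_fit$amplitude *
        exp(-grid^2 / (2 * object$gaussian_fit$sigma^2))
    )
    p <- p + ggplot2::geom_line(data = fit, colour = "blue")
  }
  p
}

#' Plot a gain curve
#'
#' @param object A [gain_curve()] object.
#' @param ... Unused.
#' @return A ggplot of the binned probability of parasitism against total
#'   visit time with the fitted saturating curve.
#' @export
autoplot.gain_curve <- function(object, ...) {
  grid <- seq(0, max(object$bins$T_mid), length.out = 200)
  fit <- tibble::tibble(T_mid = grid, fraction = object$predict(grid))
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$T_mid, y = .data$fraction)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_line(data = fit, colour = "red") +
    ggplot2::labs(x = "total visit time (min)", y = "P(parasitised)")
}

#' Plot a spiral skeleton
#'
#' @param object A [build_spiral()] object.
#' @param layout Optional host layout to overlay (projected to plate
#'   coordinates by nearest arclength).
#' @param ... Unused.
#' @return A ggplot of the arena centerline.
#' @export
autoplot.spiral_skeleton <- function(object, layout = NULL, ...) {
  v <- object$vertices
  p <- ggplot2::ggplot(v, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(colour = "grey40") +
    ggplot2::geom_point(data = v[object$centre_index, ], colour = "red",
                        size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)")
  if (!is.null(layout) && nrow(layout) > 0) {
    k <- vapply(layout$s, function(si) which.min(abs(v$s - si)), integer(1))
    p <- p + ggplot2::geom_point(data = v[k, ], colour = "blue", size = 1)
  }
  p
}

#' @importFrom rlang .data
NULL
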