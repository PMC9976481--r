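# Arena geometry: double-spiral skeleton, projection to the linear
# coordinate, host layouts and distance metrics.

#' Build a double-spiral tunnel skeleton
#'
#' Constructs the centerline ("skeleton") of a long linear tunnel folded into
#' an interleaved double Archimedean spiral, so that a tunnel of several
#' metres fits inside a small rectangular plate. The two arms start at the
#' release point in the centre of the spiral and wind outwards, one arm being
#' the point reflection of the other. Positions along the tunnel are expressed
#' as signed arclength from the release point: negative on the left arm,
#' positive on the right arm.
#'
#' The spiral arm follows \eqn{r = b\theta} with \eqn{b} chosen so that
#' successive windings of the same arm are separated by
#' \eqn{2(\mathrm{channel} + \mathrm{wall})}; adjacent channels in the plate
#' alternate between the two arms, so the physical centre-to-centre channel
#' spacing is \eqn{\mathrm{channel} + \mathrm{wall}}.
#'
#' @param total_length Total tunnel length in cm (default 630).
#' @param box Numeric length-2, the rectangular plate (width, height) in cm
#'   that must contain the spiral (default `c(60, 40)`).
#' @param channel_width Tunnel width in cm (default 1).
#' @param chirality `"levogyrous"` (left-turning) or `"dextrogyrous"`; the two
#'   are mirror images with identical arclength structure.
#' @param wall_thickness Wall between adjacent channels in cm (default 0.85).
#' @param resolution Arclength spacing of polyline vertices in cm
#'   (default 0.1); also the grid used for projection.
#'
#' @return An object of class `spiral_skeleton`: a list with
#'   * `vertices`: tibble with columns `x`, `y` (plate coordinates, cm) and
#'     `s` (signed arclength from the release point, cm), ordered from the
#'     left tip (`s = -total_length/2`) to the right tip;
#'   * `centre_index`: row index of the release point (`s = 0`);
#'   * `total_length`, `channel_width`, `chirality`, `resolution`;
#'   * `bounding_box`: (width, height) of the polyline extent plus channel.
#'
#' @examples
#' sk <- build_spiral()
#' sk$total_length
#' @export
build_spiral <- function(total_length = 630, box = c(60, 40), channel_width = 1,
                         chirality = c("levogyrous", "dextrogyrous"),
                         wall_thickness = 0.85, resolution = 0.1) {
  chirality <- match.arg(chirality)
  stopifnot(total_length > 0, channel_width > 0, wall_thickness >= 0,
            resolution > 0, length(box) == 2, all(box > 0))

  arm_length <- total_length / 2
  arm_pitch <- 2 * (channel_width + wall_thickness)  # same-arm winding spacing
  b <- arm_pitch / (2 * pi)

  # Arclength of r = b*theta from 0 to theta: (b/2)(theta*sqrt(1+theta^2) + asinh(theta))
  arc <- function(theta) (b / 2) * (theta * sqrt(1 + theta^2) + asinh(theta))
  theta_max <- sqrt(2 * arm_length / b) + 2      # generous upper bracket
  inv_arc <- function(s_target) {
    vapply(s_target, function(s1) {
      if (s1 <= 0) return(0)
      stats::uniroot(function(th) arc(th) - s1, c(0, theta_max),
                     tol = 1e-10)$root
    }, numeric(1))
  }

  s_target <- seq(0, arm_length, by = resolution)
  if (s_target[length(s_target)] < arm_length)
    s_target <- c(s_target, arm_length)
  theta <- inv_arc(s_target)
  r <- b * theta
  x <- r * cos(theta)
  y <- r * sin(theta)
  if (chirality == "dextrogyrous") y <- -y
  # store the polyline's own cumulative chord length so that arclength
  # differences match Euclidean segment lengths exactly
  s_arm <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))

  # Left arm is the point reflection of the right arm through the centre,
  # giving a continuous smooth tunnel through the release point.
  vertices <- tibble::tibble(
    x = c(rev(-x[-1]), x),
    y = c(rev(-y[-1]), y),
    s = c(rev(-s_arm[-1]), s_arm)
  )

  extent <- c(diff(range(vertices$x)), diff(range(vertices$y))) + channel_width
  if (extent[1] > box[1] + 1e-6 || extent[2] > box[2] + 1e-6) {
    stop("infeasible geometry: a ", total_length, " cm tunnel at pitch ",
         arm_pitch / 2, " cm needs ", round(extent[1], 1), " x ",
         round(extent[2], 1), " cm, larger than the ",
         box[1], " x ", box[2], " cm plate", call. = FALSE)
  }

  structure(
    list(
      vertices = vertices,
      centre_index = length(s_arm),  # s = 0 row
      total_length = 2 * s_arm[length(s_arm)],
      channel_width = channel_width,
      chirality = chirality,
      resolution = resolution,
      bounding_box = extent
    ),
    class = "spiral_skeleton"
  )
}

#' @export
print.spiral_skeleton <- function(x, ...) {
  cat("<spiral_skeleton>\n")
  cat("  total length: ", round(x$total_length, 2), " cm (",
      x$chirality, ")\n", sep = "")
  cat("  bounding box: ", round(x$bounding_box[1], 1), " x ",
      round(x$bounding_box[2], 1), " cm; channel ",
      x$channel_width, " cm\n", sep = "")
  cat("  ", nrow(x$vertices), " vertices at ", x$resolution,
      " cm resolution\n", sep = "")
  invisible(x)
}

#' Project plate coordinates onto the tunnel skeleton
#'
#' Each 2-D point is projected orthogonally onto the nearest skeleton vertex
#' and assigned the signed linear coordinate `s` of that vertex (negative on
#' the left arm) together with the perpendicular offset. Ties between the two
#' arms are broken by smaller offset, then smaller `|s|`.
#'
#' @param data Data frame with columns `x` and `y` (cm, plate coordinates).
#' @param skeleton A [build_spiral()] object.
#' @param warn_offset Warn when an offset exceeds half the channel width plus
#'   `tolerance` (such detections lie outside the tunnel). Default `TRUE`.
#' @param tolerance Offset slack in cm added to the half channel width before
#'   warning (default 0.1).
#'
#' @return The input tibble with columns `s` (signed arclength, cm) and
#'   `offset` (perpendicular distance to the skeleton, cm) appended.
#' @examples
#' sk <- build_spiral(100)
#' project_to_skeleton(data.frame(x = 0, y = 0), sk)
#' @export
project_to_skeleton <- function(data, skeleton, warn_offset = TRUE,
                                tolerance = 0.1) {
  stopifnot(inherits(skeleton, "spiral_skeleton"),
            all(c("x", "y") %in% names(data)))
  v <- skeleton$vertices
  n <- nrow(data)
  s_out <- numeric(n)
  off_out <- numeric(n)
  # chunked nearest-vertex search keeps the distance matrix small
  chunk <- max(1L, floor(4e6 / nrow(v)))
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    d2 <- outer(data$x[idx], v$x, "-")^2 + outer(data$y[idx], v$y, "-")^2
    for (j in seq_along(idx)) {
      dj <- d2[j, ]
      best <- which(dj <= min(dj) + 1e-12)
      if (length(best) > 1L) best <- best[which.min(abs(v$s[best]))]
      s_out[idx[j]] <- v$s[best]
      off_out[idx[j]] <- sqrt(dj[best])
    }
  }
  if (warn_offset) {
    n_out <- sum(off_out > skeleton$channel_width / 2 + tolerance)
    if (n_out > 0)
      warning(n_out, " point(s) lie farther than half the channel width ",
              "from the skeleton", call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$s <- s_out
  out$offset <- off_out
  out
}

#' Generate a host egg layout along the tunnel
#'
#' Host eggs are laid out symmetrically about the release point in one of two
#' modalities of equal mean density: `"diffuse"` (one egg every 5 cm, the
#' first 2.5 cm on each side of the centre) or `"clumped"` (one patch of six
#' co-located eggs every 30 cm, the first 15 cm on each side). With the
#' default 300 cm placement cutoff both modalities contain exactly 120 eggs.
#'
#' @param modality `"diffuse"`, `"clumped"` or `"none"`.
#' @param tunnel_half_length Half tunnel length in cm (default 315).
#' @param cutoff Maximum `|s|` at which eggs are placed, cm (default 300).
#'
#' @return A tibble of class `host_layout` with columns `host_id`, `patch_id`
#'   and `s` (signed cm); zero rows for `"none"`. Diffuse eggs are singleton
#'   patches.
#' @examples
#' nrow(make_host_layout("diffuse"))   # 120
#' nrow(make_host_layout("clumped"))   # 120
#' @export
make_host_layout <- function(modality = c("none", "diffuse", "clumped"),
                             tunnel_half_length = 315, cutoff = 300) {
  modality <- match.arg(modality)
  stopifnot(cutoff <= tunnel_half_length)
  if (modality == "none") {
    out <- tibble::tibble(host_id = integer(), patch_id = integer(),
                          s = numeric())
  } else if (modality == "diffuse") {
    half <- seq(2.5, cutoff, by = 5)
    s <- sort(c(-half, half))
    out <- tibble::tibble(host_id = seq_along(s), patch_id = seq_along(s),
                          s = s)
  } else {
    centres <- seq(15, cutoff, by = 30)
    centres <- sort(c(-centres, centres))
    out <- tibble::tibble(
      host_id = seq_len(6L * length(centres)),
      patch_id = rep(seq_along(centres), each = 6L),
      s = rep(centres, each = 6L)
    )
  }
  attr(out, "modality") <- modality
  class(out) <- c("host_layout", class(out))
  out
}

#' Distances to the nearest host and between individuals
#'
#' Computes, along the linear tunnel coordinate, each individual's distance
#' to the closest host egg and all pairwise distances between individuals.
#'
#' @param positions Numeric vector of signed linear positions (cm).
#' @param layout A [make_host_layout()] tibble (may have zero rows).
#'
#' @return A list with `nearest_host`: tibble (`s`, `nearest_host_distance`,
#'   `nearest_host_id`) — distance is `Inf` with `NA` id when no hosts — and
#'   `pairwise`: tibble (`i`, `j`, `distance`) for all unordered pairs.
#' @export
distance_metrics <- function(positions, layout) {
  if (nrow(layout) > 0) {
    d <- abs(outer(positions, layout$s, "-"))
    k <- max.col(-d, ties.method = "first")
    nh <- tibble::tibble(
      s = positions,
      nearest_host_distance = d[cbind(seq_along(positions), k)],
      nearest_host_id = layout$host_id[k]
    )
  } else {
    nh <- tibble::tibble(
      s = positions,
      nearest_host_distance = rep(Inf, length(positions)),
      nearest_host_id = rep(NA_integer_, length(positions))
    )
  }
  pw <- if (length(positions) >= 2) {
    cmb <- utils::combn(seq_along(positions), 2)
    tibble::tibble(i = cmb[1, ], j = cmb[2, ],
                   distance = abs(positions[cmb[1, ]] - positions[cmb[2, ]]))
  } else {
    tibble::tibble(i = integer(), j = integer(), distance = numeric())
  }
  list(nearest_host = nh, pairwise = pw)
}

#' Write / read a skeleton as JSON
#'
#' @param skeleton A `spiral_skeleton`.
#' @param path File path.
#' @return `read_skeleton()` returns the `spiral_skeleton`;
#'   `write_skeleton()` returns `path` invisibly.
#' @export
write_skeleton <- function(skeleton, path) {
  stopifnot(inherits(skeleton, "spiral_skeleton"))
  obj <- list(
    polyline = unname(as.matrix(skeleton$vertices[, c("x", "y")])),
    s = skeleton$vertices$s,
    centre_index = skeleton$centre_index,
    total_length = skeleton$total_length,
    channel_width = skeleton$channel_width,
    chirality = skeleton$chirality,
    resolution = skeleton$resolution,
    bounding_box = skeleton$bounding_box
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_skeleton
#' @export
read_skeleton <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      vertices = tibble::tibble(x = obj$polyline[, 1], y = obj$polyline[, 2],
                                s = obj$s),
      centre_index = obj$centre_index,
      total_length = obj$total_length,
      channel_width = obj$channel_width,
      chirality = obj$chirality,
      resolution = obj$resolution,
      bounding_box = obj$bounding_box
    ),
    class = "spiral_skeleton"
  )
}
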