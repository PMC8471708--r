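#' Fit helix parameters to an ordered point cloud
#'
#' Estimates the axis, radius and pitch of the helix traced by an ordered set
#' of points (typically the dipole origins, i.e. molecular centers of mass,
#' along a nanotube coil). The axis is chosen among the principal directions
#' of the centered cloud as the one about which the radial distances are most
#' nearly constant; the radius is the mean distance from that axis; the pitch
#' is the mean per-point rise along the axis multiplied by the points per
#' turn inferred from the mean azimuthal step.
#'
#' @param points Ordered matrix or data frame of point coordinates
#'   (columns x, y, z in Angstrom; origin columns `ox`, `oy`, `oz` are also
#'   accepted), at least 4 points.
#' @return A list of class `helix_fit`: `pitch` and `radius` (Angstrom),
#'   `axis_direction` (unit vector, oriented along increasing traversal),
#'   `points_per_turn`, `n_points`, `center`, `degenerate` (TRUE when the
#'   rise is indistinguishable from zero, e.g. points on a flat circle), and
#'   `residuals` (standard deviations of radius, rise and azimuthal step).
#' @examples
#' ros <- make_dipole_rosette(n = 6, turns = 2, radius = 8.15,
#'                            rise_per_turn = 5.456)
#' fit_helix_params(ros[, c("ox", "oy", "oz")])
#' @export
fit_helix_params <- function(points) {
  pts <- if (is.matrix(points)) points else as.matrix(as_tibble(points))
  if (!is.null(colnames(pts)) && all(c("ox", "oy", "oz") %in% colnames(pts))) {
    pts <- pts[, c("ox", "oy", "oz")]
  }
  if (ncol(pts) != 3) {
    stop_helichir("points must have three coordinate columns.",
                  "invalid_input")
  }
  if (nrow(pts) < 4) {
    stop_helichir(
      sprintf("helix fit needs at least 4 points; got %d.", nrow(pts)),
      "insufficient_points"
    )
  }
  check_finite(pts, "helix points")
  center <- colMeans(pts)
  centered <- sweep(pts, 2, center)
  pc <- prcomp(centered, center = FALSE)
  if (pc$sdev[2] < 1e-8 * max(pc$sdev[1], 1)) {
    stop_helichir("points are collinear; helix radius is undefined.",
                  "degenerate_fit")
  }
  # candidate axes: the principal direction about which radial distances
  # vary least, then refined (direction + in-plane offset) by minimizing
  # the radial-distance variance, which vanishes on an exact helix
  score <- vapply(1:3, function(k) {
    ax <- pc$rotation[, k]
    radial <- sqrt(rowSums((centered - (centered %*% ax) %*% t(ax))^2))
    stats::var(radial)
  }, numeric(1))
  axis0 <- pc$rotation[, which.min(score)]
  par0 <- c(acos(max(-1, min(1, axis0[3]))), atan2(axis0[2], axis0[1]), 0, 0)
  radial_about <- function(par) {
    ax <- c(sin(par[1]) * cos(par[2]), sin(par[1]) * sin(par[2]),
            cos(par[1]))
    fr <- axis_frame(ax)
    rel <- sweep(centered, 2, par[3] * fr$e1 + par[4] * fr$e2)
    list(axis = ax, frame = fr, offset = par[3] * fr$e1 + par[4] * fr$e2,
         radial = sqrt(rowSums((rel - (rel %*% ax) %*% t(ax))^2)))
  }
  fit <- stats::optim(par0, function(par) stats::var(radial_about(par)$radial),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  sol <- radial_about(fit$par)
  axis <- sol$axis
  center <- center + sol$offset
  centered <- sweep(pts, 2, center)
  radial <- sqrt(rowSums((centered - (centered %*% axis) %*% t(axis))^2))
  if (mean(radial) < 1e-8) {
    stop_helichir("points are collinear; helix radius is undefined.",
                  "degenerate_fit")
  }
  axial <- drop(centered %*% axis)
  rises <- diff(axial)
  # orient the axis along the dominant traversal direction
  if (sum(rises) < 0) {
    axis <- -axis
    axial <- -axial
    rises <- -rises
  }
  frame <- axis_frame(axis)
  phi <- atan2(drop(centered %*% frame$e2), drop(centered %*% frame$e1))
  dphi <- diff(phi)
  dphi <- ((dphi + pi) %% (2 * pi)) - pi  # wrap steps to (-pi, pi]
  mean_step <- mean(abs(dphi))
  rise <- mean(rises)
  rise_noise <- 2 * sd(rises) / sqrt(length(rises))
  degenerate <- mean_step < 1e-9 ||
    abs(rise) < max(1e-4 * mean(radial), rise_noise)
  points_per_turn <- if (mean_step > 1e-9) 2 * pi / mean_step else NA_real_
  pitch <- if (is.na(points_per_turn)) NA_real_ else abs(rise) * points_per_turn
  structure(
    list(
      pitch = pitch,
      radius = mean(radial),
      axis_direction = axis,
      axis = axis,
      points_per_turn = points_per_turn,
      n_points = nrow(pts),
      center = center,
      degenerate = degenerate,
      residuals = list(radius_sd = sd(radial), rise_sd = sd(rises),
                       step_sd = sd(abs(dphi)))
    ),
    class = "helix_fit"
  )
}

# an orthonormal frame (e1, e2) perpendicular to a unit axis
axis_frame <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  seed <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- seed - sum(seed * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' @export
print.helix_fit <- function(x, ...) {
  cat("Helix fit\n")
  cat(sprintf("  n points:        %d\n", x$n_points))
  cat(sprintf("  radius:          %.3f Angstrom (sd %.3g)\n", x$radius,
              x$residuals$radius_sd))
  cat(sprintf("  pitch:           %s Angstrom\n",
              if (is.na(x$pitch)) "NA" else sprintf("%.3f", x$pitch)))
  cat(sprintf("  points per turn: %s\n",
              if (is.na(x$points_per_turn)) "NA"
              else sprintf("%.2f", x$points_per_turn)))
  if (x$degenerate) cat("  (degenerate: rise indistinguishable from zero)\n")
  invisible(x)
}

#' @rdname fit_helix_params
#' @param x A `helix_fit` object.
#' @param ... Unused.
#' @method glance helix_fit
#' @export
glance.helix_fit <- function(x, ...) {
  tibble(
    pitch = x$pitch, radius = x$radius,
    points_per_turn = x$points_per_turn, n_points = x$n_points,
    degenerate = x$degenerate,
    radius_sd = x$residuals$radius_sd, rise_sd = x$residuals$rise_sd,
    step_sd = x$residuals$step_sd
  )
}
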