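#' Plot a dipole coil as arrows in the xy plane
#'
#' Projects each dipole onto the plane normal to the helix axis (the xy
#' plane), drawing one arrow per molecule from its origin (when origins are
#' present) or from a unit circle layout otherwise. The rotating in-plane
#' components that generate the chirality signal are immediately visible.
#'
#' @param object A [coil_dipoles].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coil_dipoles
#' @export
autoplot.coil_dipoles <- function(object, ...) {
  df <- as_tibble(object)
  if (!all(c("ox", "oy") %in% names(df))) {
    phi <- 2 * pi * (df$i - 1) / nrow(df)
    df$ox <- cos(phi)
    df$oy <- sin(phi)
  }
  scale <- max(df$di) / max(sqrt(df$ox^2 + df$oy^2), 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ox, y = .data$oy)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$ox + .data$dx / scale,
                   yend = .data$oy + .data$dy / scale,
                   colour = factor(.data$i)),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      linewidth = 0.8
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$i), nudge_y = 0.4,
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Angstrom)", y = "y (Angstrom)",
                  colour = "molecule",
                  title = attr(object, "label") %||% "dipole coil (xy projection)") +
    ggplot2::theme_minimal()
}

#' Plot the per-triple contributions of a chirality result
#'
#' Bar chart of the signed scalar triple products whose sum is `c_total`;
#' a structure of consistent handedness shows all bars on one side of zero.
#'
#' @param object A `chirality_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot chirality_result
#' @export
autoplot.chirality_result <- function(object, ...) {
  unit <- if (object$mode == "dipole") "Debye^3" else "Angstrom^3"
  ggplot2::ggplot(object$terms,
                  ggplot2::aes(x = factor(.data$i), y = .data$triple,
                               fill = .data$triple > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac",
                                          `FALSE` = "#b2182b")) +
    ggplot2::labs(
      x = "triple (starting index i)",
      y = sprintf("([v_i, v_i+1], v_i+2)  (%s)", unit),
      title = sprintf("c_total = %.2f %s (%s, symbol %s)", object$c_total,
                      unit, object$handedness, object$symbol)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an alpha-carbon trace
#'
#' xy projection of the trace colored by height along z; a helix appears as
#' a circle (or arc) whose color cycles with each turn.
#'
#' @param object A [calpha_trace].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot calpha_trace
#' @export
autoplot.calpha_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, colour = .data$z)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (Angstrom)", y = "y (Angstrom)",
                  colour = "z (Angstrom)",
                  title = "Calpha trace (xy projection)") +
    ggplot2::theme_minimal()
}
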