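#' Scalar triple product of three vectors
#'
#' The scalar triple product ([a,b], c) is the determinant of the 3x3 matrix
#' with rows `a`, `b`, `c`. It is a pseudoscalar: proper rotations leave it
#' unchanged and any reflection flips its sign, which makes it the natural
#' building block of a signed chirality measure. Units are the cube of the
#' input unit (Debye^3 for dipoles, Angstrom^3 for backbone vectors).
#'
#' @param a,b,c Numeric vectors of length 3, all in the same unit.
#' @return The signed triple product, a length-1 numeric.
#' @examples
#' triple_product(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)) # +1, right-handed basis
#' @export
triple_product <- function(a, b, c) {
  if (length(a) != 3 || length(b) != 3 || length(c) != 3) {
    stop_helichir("triple_product expects three vectors of length 3.",
                  "invalid_input")
  }
  check_finite(c(a, b, c), "triple_product arguments")
  det(rbind(a, b, c))
}

# triple products of all consecutive row triples of an n x 3 matrix
consecutive_triples <- function(m) {
  n <- nrow(m)
  vapply(seq_len(n - 2), function(i) {
    det(m[i:(i + 2), , drop = FALSE])
  }, numeric(1))
}

#' Dipole-moment magnitude
#'
#' Euclidean norm of a dipole's Cartesian components, in Debye.
#'
#' @param components Numeric vector of length 3 (Dx, Dy, Dz in Debye).
#' @return Non-negative magnitude in Debye.
#' @examples
#' dipole_magnitude(c(11.645, 1.115, 0.899)) # 11.733 D, an L-FF molecule
#' @export
dipole_magnitude <- function(components) {
  if (length(components) != 3) {
    stop_helichir("dipole components must have length 3.", "invalid_input")
  }
  check_finite(components, "dipole components")
  sqrt(sum(components^2))
}

#' Total chirality of a dipole coil
#'
#' Sums the scalar triple products of all consecutive dipole triples
#' (D_i, D_{i+1}, D_{i+2}) for i = 1..n-2, in the traversal order supplied.
#' There is no wrap-around: the triple closing the loop back to D_1 is not
#' included. The sign encodes handedness (positive = right-handed).
#'
#' @param coil A [coil_dipoles] object or data frame acceptable to it,
#'   with at least 3 records in helix traversal order.
#' @return Total chirality in Debye^3.
#' @examples
#' rosette <- make_dipole_rosette(n = 6, seed = 1)
#' c_total_dipoles(rosette)
#' @export
c_total_dipoles <- function(coil) {
  coil <- as_coil(coil)
  if (nrow(coil) < 3) {
    stop_helichir(
      sprintf("chirality sum needs at least 3 dipoles; got %d.", nrow(coil)),
      "insufficient_vectors"
    )
  }
  sum(consecutive_triples(coil_matrix(coil)))
}

as_coil <- function(x) {
  if (inherits(x, "coil_dipoles")) x else coil_dipoles(x)
}

#' Mean dipole magnitude of a coil
#'
#' Arithmetic mean of the per-molecule dipole magnitudes |D_i| — not the
#' magnitude of the mean vector. This is the normalization scale of the
#' dimensionless chirality measure.
#'
#' @inheritParams c_total_dipoles
#' @return Mean magnitude in Debye.
#' @export
d_av <- function(coil) {
  coil <- as_coil(coil)
  mean(coil$di)
}

#' Normalized chirality
#'
#' Divides the total chirality by the cube of the mean dipole magnitude,
#' yielding a dimensionless measure comparable across computation methods
#' and systems.
#'
#' @param c_total Total chirality (Debye^3).
#' @param d_av Mean dipole magnitude (Debye), strictly positive.
#' @return Dimensionless normalized chirality.
#' @examples
#' c_norm(16034.82, 22.728) # ~1.37, a right-handed peptide nanotube
#' @export
c_norm <- function(c_total, d_av) {
  check_finite(c(c_total, d_av), "normalization inputs")
  if (d_av <= 0) {
    stop_helichir("normalization requires a positive mean dipole magnitude.",
                  "degenerate_normalization")
  }
  c_total / d_av^3
}

#' Aggregate dipole summary of a coil
#'
#' Componentwise sum vector of the coil (the coil's total dipole moment),
#' its magnitude, the mean of the per-molecule magnitudes, and the
#' componentwise means. For a helix-like arrangement the in-plane components
#' largely cancel around a turn, so the total dipole points mainly along the
#' helix axis.
#'
#' @inheritParams c_total_dipoles
#' @return One-row tibble with columns `n`, `d_coil`, `d_coil_x`, `d_coil_y`,
#'   `d_coil_z`, `d_av`, `d_mean_x`, `d_mean_y`, `d_mean_z` (all Debye).
#' @export
coil_summary <- function(coil) {
  coil <- as_coil(coil)
  sums <- colSums(coil_matrix(coil))
  tibble(
    n = nrow(coil),
    d_coil = sqrt(sum(sums^2)),
    d_coil_x = sums[["dx"]], d_coil_y = sums[["dy"]], d_coil_z = sums[["dz"]],
    d_av = mean(coil$di),
    d_mean_x = sums[["dx"]] / nrow(coil),
    d_mean_y = sums[["dy"]] / nrow(coil),
    d_mean_z = sums[["dz"]] / nrow(coil)
  )
}

#' Classify handedness from a signed chirality value
#'
#' Positive total chirality means a right-handed structure (symbol D),
#' negative means left-handed (symbol L). Exactly zero is indeterminate:
#' the sign convention is undefined there, so no symbol is assigned.
#'
#' @param c_value Finite signed chirality value (any of the measures).
#' @return One-row tibble with columns `handedness`
#'   (`"right"`/`"left"`/`"indeterminate"`) and `symbol` (`"D"`/`"L"`/`"none"`).
#' @examples
#' classify_handedness(-14497.03) # left-handed, symbol L
#' @export
classify_handedness <- function(c_value) {
  check_finite(c_value, "chirality value")
  if (c_value > 0) {
    tibble(handedness = "right", symbol = "D")
  } else if (c_value < 0) {
    tibble(handedness = "left", symbol = "L")
  } else {
    tibble(handedness = "indeterminate", symbol = "none")
  }
}

new_chirality_result <- function(mode, c_total, n_vectors, n_terms, terms,
                                 d_av = NULL, c_norm = NULL, summary = NULL,
                                 label = NULL, method = NULL) {
  cls <- classify_handedness(c_total)
  structure(
    list(
      mode = mode,
      c_total = c_total,
      d_av = d_av,
      c_norm = c_norm,
      n_vectors = n_vectors,
      n_terms = n_terms,
      handedness = cls$handedness,
      symbol = cls$symbol,
      terms = terms,
      summary = summary,
      label = label,
      method = method
    ),
    class = "chirality_result"
  )
}

#' Full chirality analysis of a dipole coil
#'
#' Composes the whole dipole-mode pipeline: total chirality, mean dipole
#' magnitude, normalized chirality, handedness classification, and the coil's
#' aggregate dipole summary.
#'
#' @inheritParams c_total_dipoles
#' @return A `chirality_result` object; see [tidy.chirality_result()] for the
#'   per-triple terms and [glance.chirality_result()] for the one-row summary.
#' @examples
#' coil <- read_dipole_table(helichir_fixture("lff_pm3.tsv"))
#' full_dipole_analysis(coil)
#' @export
full_dipole_analysis <- function(coil) {
  coil <- as_coil(coil)
  ct <- c_total_dipoles(coil)
  dav <- d_av(coil)
  terms <- tibble(
    i = seq_len(nrow(coil) - 2L),
    triple = consecutive_triples(coil_matrix(coil))
  )
  new_chirality_result(
    mode = "dipole", c_total = ct, d_av = dav, c_norm = c_norm(ct, dav),
    n_vectors = nrow(coil), n_terms = nrow(coil) - 2L, terms = terms,
    summary = coil_summary(coil),
    label = attr(coil, "label"), method = attr(coil, "method")
  )
}

#' Backbone chirality of an alpha-carbon trace
#'
#' Builds the n-1 difference vectors between consecutive Calpha positions and
#' sums the scalar triple products of all n-3 consecutive vector triples.
#' Positive values indicate a right-handed helix, negative left-handed.
#'
#' @param trace A [calpha_trace] (or data frame with `x`, `y`, `z`) of at
#'   least 4 points in chain order.
#' @return A `chirality_result` with `c_total` in Angstrom^3; the dipole-mode
#'   fields `d_av` and `c_norm` are absent in backbone mode.
#' @examples
#' helix <- make_calpha_helix(n_residues = 10, handedness = "right")
#' chi_total_backbone(helix)
#' @export
chi_total_backbone <- function(trace) {
  if (!inherits(trace, "calpha_trace")) trace <- calpha_trace(trace)
  n_res <- nrow(trace)
  if (n_res < 4) {
    stop_helichir(
      sprintf("backbone chirality needs at least 4 Calpha points; got %d.",
              n_res),
      "insufficient_points"
    )
  }
  pts <- trace_matrix(trace)
  v <- pts[-1, , drop = FALSE] - pts[-n_res, , drop = FALSE]
  triples <- consecutive_triples(v)
  new_chirality_result(
    mode = "backbone", c_total = sum(triples),
    n_vectors = n_res - 1L, n_terms = n_res - 3L,
    terms = tibble(i = seq_along(triples), triple = triples),
    label = attr(trace, "chain")
  )
}

#' @export
print.chirality_result <- function(x, digits = 2, ...) {
  unit <- if (x$mode == "dipole") "Debye^3" else "Angstrom^3"
  hdr <- if (x$mode == "dipole") "dipole coil" else "Calpha backbone"
  cat(sprintf("Chirality analysis (%s)\n", hdr))
  if (!is.null(x$label)) cat(sprintf("  label:      %s\n", x$label))
  if (!is.null(x$method)) cat(sprintf("  method:     %s\n", x$method))
  cat(sprintf("  c_total:    %s %s over %d triples\n",
              format(round(x$c_total, digits), big.mark = ","), unit,
              x$n_terms))
  if (!is.null(x$d_av)) {
    cat(sprintf("  D_av:       %.3f Debye\n", x$d_av))
    cat(sprintf("  c_norm:     %.*f\n", digits, x$c_norm))
  }
  cat(sprintf("  handedness: %s (symbol %s)\n", x$handedness, x$symbol))
  invisible(x)
}

#' @export
as.list.chirality_result <- function(x, ...) {
  out <- list(
    mode = x$mode, c_total = x$c_total, n_vectors = x$n_vectors,
    n_terms = x$n_terms, handedness = x$handedness, symbol = x$symbol
  )
  if (!is.null(x$d_av)) {
    out$d_av <- x$d_av
    out$c_norm <- x$c_norm
  }
  if (!is.null(x$label)) out$label <- x$label
  if (!is.null(x$method)) out$method <- x$method
  out
}

#' Tidy the per-triple terms of a chirality result
#'
#' @param x A `chirality_result`.
#' @param ... Unused.
#' @return Tibble with one row per consecutive vector triple: starting index
#'   `i` and the signed `triple` product contributing to `c_total`.
#' @method tidy chirality_result
#' @export
tidy.chirality_result <- function(x, ...) {
  x$terms
}

#' One-row summary of a chirality result
#'
#' @param x A `chirality_result`.
#' @param ... Unused.
#' @return One-row tibble with `mode`, `label`, `method`, `c_total`, `d_av`,
#'   `c_norm` (NA in backbone mode), `n_vectors`, `n_terms`, `handedness`,
#'   `symbol`.
#' @method glance chirality_result
#' @export
glance.chirality_result <- function(x, ...) {
  tibble(
    mode = x$mode,
    label = x$label %||% NA_character_,
    method = x$method %||% NA_character_,
    c_total = x$c_total,
    d_av = x$d_av %||% NA_real_,
    c_norm = x$c_norm %||% NA_real_,
    n_vectors = x$n_vectors,
    n_terms = x$n_terms,
    handedness = x$handedness,
    symbol = x$symbol
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
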