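#' Construct an ordered set of per-molecule dipole moments
#'
#' A `coil_dipoles` object holds the dipole-moment vectors of the molecules
#' forming one turn (or several turns) of a helix-like assembly, in helix
#' traversal order. Order is semantic: reversing it flips the sign of the
#' chirality measure, so the constructor never re-sorts rows.
#'
#' Magnitudes are always recomputed from the components; a supplied `di`
#' column is kept as `di_printed` for reference only (printed tables are
#' rounded, and rounded magnitudes can disagree with their own components).
#'
#' @param data Data frame with columns `dx`, `dy`, `dz` (Debye; case
#'   insensitive, `Dx` etc. also accepted), optionally `i` (1-based molecule
#'   index along the helix), `di` (advisory magnitude) and `ox`, `oy`, `oz`
#'   (dipole origin, i.e. the molecule's center of mass, in Angstrom).
#' @param method Free-form provenance tag for how the dipoles were obtained
#'   (e.g. `"PM3-RHF"`, `"Amber"`, `"point-charge"`).
#' @param label Free-form label for the assembly (e.g. `"L-FF"`).
#' @return A tibble of class `coil_dipoles` with columns `i`, `dx`, `dy`,
#'   `dz`, `di` (recomputed) and, when present, `di_printed`, `ox`, `oy`,
#'   `oz`; attributes `method`, `label` and `unit = "debye"`.
#' @examples
#' coil_dipoles(data.frame(dx = c(1, 0, -1), dy = c(0, 1, 0), dz = -1))
#' @export
coil_dipoles <- function(data, method = NULL, label = NULL) {
  df <- as_tibble(data)
  names(df) <- tolower(names(df))
  for (col in c("dx", "dy", "dz")) {
    if (!col %in% names(df)) {
      stop_helichir(sprintf("dipole table lacks required column '%s'.", col),
                    "invalid_input")
    }
  }
  if (nrow(df) < 1) stop_helichir("dipole set is empty.", "insufficient_vectors")
  check_finite(c(df$dx, df$dy, df$dz), "dipole components")
  if (!"i" %in% names(df)) df$i <- seq_len(nrow(df))
  if (anyDuplicated(df$i)) {
    stop_helichir(
      sprintf("duplicate molecule index: %s.",
              paste(unique(df$i[duplicated(df$i)]), collapse = ", ")),
      "duplicate_index"
    )
  }
  if (!identical(as.integer(df$i), seq_len(nrow(df)))) {
    stop_helichir("molecule indices must be consecutive starting at 1.",
                  "invalid_input")
  }
  di_printed <- if ("di" %in% names(df)) df$di else NULL
  df$di <- sqrt(df$dx^2 + df$dy^2 + df$dz^2)
  out <- tibble(
    i = as.integer(df$i),
    dx = as.numeric(df$dx), dy = as.numeric(df$dy), dz = as.numeric(df$dz),
    di = df$di
  )
  if (!is.null(di_printed)) out$di_printed <- as.numeric(di_printed)
  if (all(c("ox", "oy", "oz") %in% names(df))) {
    check_finite(c(df$ox, df$oy, df$oz), "dipole origins")
    out$ox <- as.numeric(df$ox)
    out$oy <- as.numeric(df$oy)
    out$oz <- as.numeric(df$oz)
  }
  new_coil_dipoles(out, method = method, label = label)
}

new_coil_dipoles <- function(df, method = NULL, label = NULL) {
  structure(df,
            method = method, label = label, unit = "debye",
            class = c("coil_dipoles", class(tibble())))
}

#' @export
print.coil_dipoles <- function(x, ...) {
  lab <- attr(x, "label")
  met <- attr(x, "method")
  cat(sprintf("<coil_dipoles> %d dipoles%s%s [Debye]\n", nrow(x),
              if (!is.null(lab)) paste0(", label=", lab) else "",
              if (!is.null(met)) paste0(", method=", met) else ""))
  print(as_tibble(x), ...)
  invisible(x)
}

coil_matrix <- function(coil) {
  as.matrix(as_tibble(coil)[, c("dx", "dy", "dz")])
}

#' Construct an ordered alpha-carbon trace
#'
#' Holds the Calpha coordinates of one polypeptide chain, ordered N- to
#' C-terminus, from which consecutive difference vectors are built for the
#' backbone chirality sum.
#'
#' @param data Data frame with columns `x`, `y`, `z` (Angstrom) and
#'   optionally `residue` (residue numbers, used for ordering provenance).
#' @param chain Chain identifier, kept as metadata.
#' @return A tibble of class `calpha_trace` with columns `residue`, `x`,
#'   `y`, `z` and attributes `chain` and `unit = "angstrom"`.
#' @examples
#' calpha_trace(data.frame(x = 0:4, y = c(0, 1, 0, -1, 0), z = 0:4 / 2))
#' @export
calpha_trace <- function(data, chain = NA_character_) {
  df <- as_tibble(data)
  names(df) <- tolower(names(df))
  for (col in c("x", "y", "z")) {
    if (!col %in% names(df)) {
      stop_helichir(sprintf("trace lacks required coordinate column '%s'.", col),
                    "invalid_input")
    }
  }
  check_finite(c(df$x, df$y, df$z), "Calpha coordinates")
  if (!"residue" %in% names(df)) df$residue <- seq_len(nrow(df))
  pts <- as.matrix(df[, c("x", "y", "z")])
  if (nrow(pts) > 1) {
    steps <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
    if (any(steps == 0)) {
      stop_helichir("consecutive Calpha coordinates must be distinct points.",
                    "invalid_input")
    }
  }
  structure(
    tibble(residue = as.integer(df$residue),
           x = as.numeric(df$x), y = as.numeric(df$y), z = as.numeric(df$z)),
    chain = chain, unit = "angstrom",
    class = c("calpha_trace", class(tibble()))
  )
}

#' @export
print.calpha_trace <- function(x, ...) {
  cat(sprintf("<calpha_trace> %d residues, chain %s [Angstrom]\n",
              nrow(x), attr(x, "chain")))
  print(as_tibble(x), ...)
  invisible(x)
}

trace_matrix <- function(trace) {
  as.matrix(as_tibble(trace)[, c("x", "y", "z")])
}
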