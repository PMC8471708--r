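#' Generate an ideal (or noisy) dipole rosette
#'
#' Emulates the dipole arrangement of a helix-like nanotube coil: the
#' in-plane part of each successive dipole is rotated by a fixed step (about
#' 60 degrees for a 6-molecule coil) while the axial component stays
#' constant, and the dipole origins lie on a helix. `handedness` names the
#' geometric helix sense (right = azimuth increases counterclockwise, viewed
#' from +z, as z increases). The emitted traversal order descends the helix
#' — azimuth decreasing for a right-handed rosette — matching the
#' arrangement observed in right-handed diphenylalanine nanotubes, whose
#' downward-pointing dipoles then give a positive total chirality.
#'
#' @param n Molecules per turn (>= 3).
#' @param step_angle Azimuthal step in degrees between successive dipoles;
#'   defaults to 360/n.
#' @param in_plane_magnitude In-plane dipole component magnitude, Debye.
#' @param z_component Axial dipole component, Debye (negative in the
#'   nanotube geometry this mirrors).
#' @param handedness `"right"` or `"left"` (mirror images of one another).
#' @param turns Number of full turns to generate.
#' @param radius Helix radius of the dipole origins, Angstrom.
#' @param rise_per_turn Helix pitch of the origins, Angstrom.
#' @param noise_sigma Standard deviation of seeded Gaussian noise added to
#'   every dipole component (Debye) and origin coordinate (Angstrom).
#' @param seed Integer seed; the same spec and seed give identical output.
#' @param label Optional label attached to the coil.
#' @return A [coil_dipoles] of `n * turns` dipoles with origins; the
#'   generating parameters are kept in the `spec` attribute.
#' @examples
#' make_dipole_rosette(n = 6, z_component = -12, handedness = "right")
#' @export
make_dipole_rosette <- function(n = 6, step_angle = 360 / n,
                                in_plane_magnitude = 19, z_component = -12,
                                handedness = c("right", "left"), turns = 1,
                                radius = 8.15, rise_per_turn = 5.456,
                                noise_sigma = 0, seed = NULL, label = NULL) {
  handedness <- match.arg(handedness)
  if (!is.numeric(n) || n < 3) {
    stop_helichir("a rosette needs at least 3 molecules per turn.",
                  "invalid_input")
  }
  check_finite(c(step_angle, in_plane_magnitude, z_component, turns,
                 radius, rise_per_turn, noise_sigma), "rosette parameters")
  n_pts <- as.integer(round(n * turns))
  k <- seq_len(n_pts) - 1
  # descending traversal: azimuth decreases for a right-handed helix
  az <- -k * step_angle * pi / 180
  z0 <- turns * rise_per_turn - k * rise_per_turn / n
  if (handedness == "left") az <- -az  # mirror through the xz plane
  df <- tibble(
    i = seq_len(n_pts),
    dx = in_plane_magnitude * cos(az),
    dy = in_plane_magnitude * sin(az),
    dz = rep(z_component, n_pts),
    ox = radius * cos(az),
    oy = radius * sin(az),
    oz = z0
  )
  if (noise_sigma > 0) {
    noise <- with_seed(seed, matrix(rnorm(6 * n_pts, sd = noise_sigma),
                                    ncol = 6))
    df[c("dx", "dy", "dz", "ox", "oy", "oz")] <-
      df[c("dx", "dy", "dz", "ox", "oy", "oz")] + noise
  }
  coil <- coil_dipoles(df, method = "synthetic-rosette", label = label)
  attr(coil, "spec") <- list(
    n = n, step_angle = step_angle, in_plane_magnitude = in_plane_magnitude,
    z_component = z_component, handedness = handedness, turns = turns,
    radius = radius, rise_per_turn = rise_per_turn,
    noise_sigma = noise_sigma, seed = seed
  )
  coil
}

#' Generate an ideal (or noisy) alpha-carbon helix
#'
#' Points on a circular helix with alpha-helix-like defaults. A right-handed
#' helix has azimuth increasing counterclockwise (viewed from +z) as z
#' increases; traversed N- to C-terminus upward it yields a positive
#' backbone chirality.
#'
#' @param n_residues Number of Calpha points (>= 4).
#' @param radius Helix radius, Angstrom.
#' @param rise_per_residue Rise along the axis per residue, Angstrom.
#' @param residues_per_turn Residues per full turn.
#' @param handedness `"right"` or `"left"`.
#' @param noise_sigma Seeded Gaussian noise per coordinate, Angstrom.
#' @param seed Integer seed.
#' @param pdb_path Optional path; when given, the trace is also written as a
#'   minimal PDB file (poly-alanine CA records).
#' @return A [calpha_trace]; the generating parameters are in the `spec`
#'   attribute.
#' @examples
#' make_calpha_helix(n_residues = 10, handedness = "right")
#' @export
make_calpha_helix <- function(n_residues = 10, radius = 2.3,
                              rise_per_residue = 1.5, residues_per_turn = 3.6,
                              handedness = c("right", "left"),
                              noise_sigma = 0, seed = NULL, pdb_path = NULL) {
  handedness <- match.arg(handedness)
  if (!is.numeric(n_residues) || n_residues < 4) {
    stop_helichir("a backbone helix needs at least 4 residues.",
                  "invalid_input")
  }
  check_finite(c(radius, rise_per_residue, residues_per_turn, noise_sigma),
               "helix parameters")
  if (radius <= 0 || rise_per_residue <= 0 || residues_per_turn <= 0) {
    stop_helichir("helix geometry parameters must be positive.",
                  "invalid_input")
  }
  k <- seq_len(n_residues) - 1
  alpha <- 2 * pi / residues_per_turn
  sgn <- if (handedness == "right") 1 else -1
  df <- tibble(
    residue = seq_len(n_residues),
    x = radius * cos(k * alpha),
    y = sgn * radius * sin(k * alpha),
    z = k * rise_per_residue
  )
  if (noise_sigma > 0) {
    noise <- with_seed(seed, matrix(rnorm(3 * n_residues, sd = noise_sigma),
                                    ncol = 3))
    df[c("x", "y", "z")] <- df[c("x", "y", "z")] + noise
  }
  trace <- calpha_trace(df, chain = "A")
  attr(trace, "spec") <- list(
    n_residues = n_residues, radius = radius,
    rise_per_residue = rise_per_residue,
    residues_per_turn = residues_per_turn, handedness = handedness,
    noise_sigma = noise_sigma, seed = seed
  )
  if (!is.null(pdb_path)) write_calpha_pdb(trace, pdb_path)
  trace
}

#' Write an alpha-carbon trace as a minimal PDB file
#'
#' One poly-alanine CA ATOM record per residue; enough for round-tripping
#' through standard PDB readers.
#'
#' @param trace A [calpha_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calpha_pdb <- function(trace, path) {
  if (!inherits(trace, "calpha_trace")) trace <- calpha_trace(trace)
  chain <- attr(trace, "chain")
  if (is.na(chain) || is.null(chain)) chain <- "A"
  recs <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(trace)), chain, trace$residue, trace$x, trace$y, trace$z
  )
  writeLines(c(recs, "END"), path)
  invisible(path)
}

#' Generate a synthetic supramolecular coil of pseudo-molecules
#'
#' Builds `n_molecules` compact pseudo-molecules (bonded random walks,
#' rescaled to a bounded blob) whose centers sit on a helix, as a stand-in
#' assembly for partitioning, center-of-mass and point-charge-dipole tests.
#' Each molecule is its own chain with its own residue block, atoms get
#' random light elements, and (optionally) net-neutral random charges.
#'
#' @param n_molecules Number of molecules on the helix.
#' @param atoms_per_molecule Atoms in each molecule.
#' @param radius,rise_per_turn,points_per_turn Helix geometry of the
#'   molecular centers, Angstrom / Angstrom / count.
#' @param charges Add a net-neutral random `charge` column.
#' @param seed Integer seed.
#' @param pdb_path Optional path to also write the assembly as a PDB file.
#' @return Atom tibble in the layout of [read_structure()] (plus `charge`
#'   when requested), one chain per molecule.
#' @export
make_supramolecular_coil <- function(n_molecules = 6, atoms_per_molecule = 43,
                                     radius = 8.15, rise_per_turn = 5.456,
                                     points_per_turn = 6, charges = TRUE,
                                     seed = NULL, pdb_path = NULL) {
  with_seed(seed, {
    centers <- tibble(
      phi = (seq_len(n_molecules) - 1) * 2 * pi / points_per_turn,
      cx = radius * cos(.data$phi),
      cy = radius * sin(.data$phi),
      cz = (seq_len(n_molecules) - 1) * rise_per_turn / points_per_turn
    )
    elements <- c("C", "N", "O", "H", "S")
    mols <- purrr::map(seq_len(n_molecules), function(m) {
      steps <- matrix(rnorm(3 * atoms_per_molecule), ncol = 3)
      steps <- 1.4 * steps / sqrt(rowSums(steps^2))
      pos <- apply(steps, 2, cumsum)
      pos <- sweep(pos, 2, colMeans(pos))
      extent <- max(sqrt(rowSums(pos^2)))
      if (extent > 2.8) pos <- pos * (2.8 / extent)  # keep neighbors apart
      el <- sample(elements, atoms_per_molecule, replace = TRUE,
                   prob = c(0.5, 0.15, 0.15, 0.18, 0.02))
      tibble(
        atom_name = paste0(el, seq_len(atoms_per_molecule)),
        residue = "UNK",
        resno = 0L,
        chain = LETTERS[m],
        x = pos[, 1] + centers$cx[m],
        y = pos[, 2] + centers$cy[m],
        z = pos[, 3] + centers$cz[m],
        element = el
      )
    })
    atoms <- bind_rows(mols)
    # two residues per molecule, separated blocks between molecules
    within_mol <- rep(1:2, each = ceiling(atoms_per_molecule / 2))
    atoms$resno <- rep(seq_len(n_molecules) * 10, each = atoms_per_molecule) +
      rep(within_mol[seq_len(atoms_per_molecule)], n_molecules)
    atoms <- atoms |>
      mutate(eleno = row_number(), mass = element_mass(.data$element)) |>
      select("eleno", "atom_name", "residue", "resno", "chain",
             "x", "y", "z", "element", "mass")
    if (charges) {
      q <- rnorm(nrow(atoms), sd = 0.3)
      q <- q - stats::ave(q, rep(seq_len(n_molecules),
                                 each = atoms_per_molecule))
      atoms$charge <- q  # net-neutral within every molecule
    }
    if (!is.null(pdb_path)) write_atoms_pdb(atoms, pdb_path)
    atoms
  })
}

write_atoms_pdb <- function(atoms, path) {
  # short atom names start in column 14, 4-character names in column 13
  name4 <- ifelse(nchar(atoms$atom_name) >= 4,
                  substr(atoms$atom_name, 1, 4),
                  sprintf(" %-3s", atoms$atom_name))
  recs <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    atoms$eleno, name4, substr(atoms$residue, 1, 3),
    substr(atoms$chain, 1, 1), atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$element
  )
  writeLines(c(recs, "END"), path)
  invisible(path)
}

#' Mirror vectors or points through a coordinate plane
#'
#' Negates the coordinate normal to the named plane on every element.
#' Applying the same mirror twice is the identity. Chirality measures are
#' pseudoscalars: mirroring a coil or trace exactly negates them, while
#' magnitudes (and hence the normalization scale) are unchanged.
#'
#' @param x A [coil_dipoles], [calpha_trace], matrix or data frame of
#'   3-vectors, or a numeric length-3 vector.
#' @param plane `"xy"` (negate z), `"xz"` (negate y) or `"yz"` (negate x).
#' @return An object of the same type as `x`.
#' @export
mirror <- function(x, plane = c("xy", "xz", "yz")) {
  UseMethod("mirror")
}

mirror_axis <- function(plane) {
  switch(match.arg(plane, c("xy", "xz", "yz")), xy = 3L, xz = 2L, yz = 1L)
}

#' @export
mirror.coil_dipoles <- function(x, plane = c("xy", "xz", "yz")) {
  ax <- mirror_axis(plane)
  comp <- c("dx", "dy", "dz")[ax]
  x[[comp]] <- -x[[comp]]
  orig <- c("ox", "oy", "oz")[ax]
  if (orig %in% names(x)) x[[orig]] <- -x[[orig]]
  x$di <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  x
}

#' @export
mirror.calpha_trace <- function(x, plane = c("xy", "xz", "yz")) {
  comp <- c("x", "y", "z")[mirror_axis(plane)]
  x[[comp]] <- -x[[comp]]
  x
}

#' @export
mirror.matrix <- function(x, plane = c("xy", "xz", "yz")) {
  x[, mirror_axis(plane)] <- -x[, mirror_axis(plane)]
  x
}

#' @export
mirror.data.frame <- function(x, plane = c("xy", "xz", "yz")) {
  j <- mirror_axis(plane)
  x[[j]] <- -x[[j]]
  x
}

#' @export
mirror.numeric <- function(x, plane = c("xy", "xz", "yz")) {
  j <- mirror_axis(plane)
  x[j] <- -x[j]
  x
}

#' Draw a uniformly random proper rotation
#'
#' Haar-uniform rotation matrix (determinant +1), reproducible by seed; used
#' to test rotation invariance of the chirality measures.
#'
#' @param seed Integer seed (optional).
#' @return A 3x3 orthogonal matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  with_seed(seed, {
    qr_dec <- qr(matrix(rnorm(9), 3, 3))
    q <- qr.Q(qr_dec)
    q <- q %*% diag(sign(diag(qr.R(qr_dec))))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}

#' Rotate a coil or trace by a rotation matrix
#'
#' Applies one rotation to every dipole vector (and origin) of a coil, or to
#' every point of a trace. Proper rotations leave the chirality measures
#' unchanged; improper ones (determinant -1) negate them.
#'
#' @param x A [coil_dipoles] or [calpha_trace].
#' @param rotation A 3x3 rotation matrix.
#' @return An object of the same type as `x`.
#' @export
rotate <- function(x, rotation) {
  UseMethod("rotate")
}

#' @export
rotate.coil_dipoles <- function(x, rotation) {
  d <- coil_matrix(x) %*% t(rotation)
  x$dx <- d[, 1]; x$dy <- d[, 2]; x$dz <- d[, 3]
  if (all(c("ox", "oy", "oz") %in% names(x))) {
    o <- as.matrix(as_tibble(x)[, c("ox", "oy", "oz")]) %*% t(rotation)
    x$ox <- o[, 1]; x$oy <- o[, 2]; x$oz <- o[, 3]
  }
  x$di <- sqrt(x$dx^2 + x$dy^2 + x$dz^2)
  x
}

#' @export
rotate.calpha_trace <- function(x, rotation) {
  p <- trace_matrix(x) %*% t(rotation)
  x$x <- p[, 1]; x$y <- p[, 2]; x$z <- p[, 3]
  x
}
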