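#' Read an atomic structure into an atom table
#'
#' Parses a PDB or mmCIF file (via bio3d) into a tidy atom table. Element
#' symbols are taken from the file when present, otherwise derived from atom
#' names; each element is resolved to its standard atomic weight.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (from the file extension).
#' @return Tibble with one row per atom: `eleno`, `atom_name`, `residue`,
#'   `resno`, `chain`, `x`, `y`, `z` (Angstrom), `element`, `mass` (u).
#' @examples
#' pdb <- helichir_fixture("helix4.pdb")
#' read_structure(pdb)
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop_helichir(sprintf("structure file '%s' does not exist.", path), "io")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) {
      stop_helichir(
        sprintf("cannot parse '%s' as %s: %s", path, format,
                conditionMessage(e)),
        "format"
      )
    }
  )
  at <- parsed$atom
  element <- trimws(as.character(at$elesy))
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- vapply(at$elety[missing_el],
                                  function(e) bio3d::atom2ele(e),
                                  character(1))
  }
  tibble(
    eleno = as.integer(at$eleno),
    atom_name = trimws(as.character(at$elety)),
    residue = as.character(at$resid),
    resno = as.integer(at$resno),
    chain = as.character(at$chain),
    x = as.numeric(at$x), y = as.numeric(at$y), z = as.numeric(at$z),
    element = element,
    mass = element_mass(element)
  )
}

# standard atomic weights from bio3d's element table; unknown or dummy
# symbols (mass 0) are rejected
.helichir_cache <- new.env(parent = emptyenv())

element_mass <- function(element) {
  if (is.null(.helichir_cache$elements)) {
    env <- new.env()
    utils::data("elements", package = "bio3d", envir = env)
    .helichir_cache$elements <- env$elements
  }
  tab <- .helichir_cache$elements
  idx <- match(toupper(element), toupper(as.character(tab$symb)))
  mass <- tab$mass[idx]
  bad <- is.na(mass) | mass <= 0
  if (any(bad)) {
    stop_helichir(
      sprintf("cannot resolve atomic mass for element symbol(s): %s.",
              paste(unique(element[bad]), collapse = ", ")),
      "mass_lookup"
    )
  }
  as.numeric(mass)
}

#' Extract the alpha-carbon trace of one chain
#'
#' @param atoms Atom table from [read_structure()].
#' @param chain_id Chain to extract; `NULL` uses the only chain present and
#'   errors if the structure has several.
#' @return A [calpha_trace] ordered by ascending residue number. Gaps in the
#'   numbering are permitted and reported in the `gaps` attribute.
#' @export
extract_calpha_trace <- function(atoms, chain_id = NULL) {
  atoms <- as_tibble(atoms)
  if (is.null(chain_id)) {
    chains <- unique(atoms$chain)
    if (length(chains) != 1) {
      stop_helichir(
        sprintf("structure has %d chains (%s); name one.", length(chains),
                paste(chains, collapse = ", ")),
        "invalid_input"
      )
    }
    chain_id <- chains
  }
  ca <- atoms |>
    filter(.data$chain == chain_id, .data$atom_name == "CA") |>
    arrange(.data$resno)
  if (nrow(ca) == 0) {
    stop_helichir(
      sprintf("chain '%s' contains no CA atoms.", chain_id),
      "empty_trace"
    )
  }
  gaps <- which(diff(ca$resno) > 1)
  trace <- calpha_trace(
    tibble(residue = ca$resno, x = ca$x, y = ca$y, z = ca$z),
    chain = chain_id
  )
  if (length(gaps)) {
    attr(trace, "gaps") <- tibble(after_residue = ca$resno[gaps],
                                  next_residue = ca$resno[gaps + 1])
  }
  trace
}

#' Partition an assembly's atoms into molecules
#'
#' Assigns every atom to exactly one molecule by one of three rules:
#' `by_chain` (one molecule per chain identifier), `by_residue_block`
#' (a new molecule starts wherever the residue numbering restarts or jumps
#' by more than 1), or `by_connectivity_distance` (single-linkage clusters
#' under an interatomic distance cutoff, i.e. covalently plausible
#' contacts).
#'
#' @param atoms Atom table from [read_structure()].
#' @param rule Partition rule; see Details.
#' @param expected_atom_count Optional per-molecule atom count to validate
#'   against (e.g. 43 for a diphenylalanine molecule, so a 258-atom coil
#'   must split into exactly 6 groups).
#' @param cutoff Distance cutoff in Angstrom for `by_connectivity_distance`.
#' @return The atom table with a `molecule_id` column added; the
#'   `partition` attribute holds a per-molecule size summary.
#' @export
partition_molecules <- function(atoms,
                                rule = c("by_chain", "by_residue_block",
                                         "by_connectivity_distance"),
                                expected_atom_count = NULL, cutoff = 1.9) {
  rule <- match.arg(rule)
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) {
    stop_helichir("cannot partition an empty atom table.", "invalid_input")
  }
  id <- switch(rule,
    by_chain = match(atoms$chain, unique(atoms$chain)),
    by_residue_block = {
      jump <- diff(atoms$resno)
      cumsum(c(1L, as.integer(jump < 0 | jump > 1)))
    },
    by_connectivity_distance = connectivity_clusters(atoms, cutoff)
  )
  atoms$molecule_id <- as.integer(id)
  sizes <- atoms |>
    dplyr::count(.data$molecule_id, name = "n_atoms")
  if (!is.null(expected_atom_count) &&
      !all(sizes$n_atoms == expected_atom_count)) {
    off <- sizes[sizes$n_atoms != expected_atom_count, ]
    stop_helichir(
      sprintf("molecule(s) %s have %s atoms; expected %d per molecule.",
              paste(off$molecule_id, collapse = ", "),
              paste(off$n_atoms, collapse = ", "), expected_atom_count),
      "partition"
    )
  }
  attr(atoms, "partition") <- sizes
  atoms
}

# single-linkage connected components under a distance cutoff (union-find)
connectivity_clusters <- function(atoms, cutoff) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  if (n > 1) {
    nearest <- apply(d + diag(Inf, n), 1, min)
    if (any(nearest == 0)) {
      stop_helichir(
        sprintf("degenerate coordinates: atoms %s coincide with another atom.",
                paste(which(nearest == 0), collapse = ", ")),
        "ambiguous_partition"
      )
    }
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pairs <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    ri <- find(pairs[k, 1])
    rj <- find(pairs[k, 2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Center of mass of a group of atoms
#'
#' Mass-weighted mean position, the anchor point of a molecule's
#' dipole-moment vector.
#'
#' @param atoms Atom table (one molecule) with `x`, `y`, `z` and `mass`.
#' @return Named numeric vector `c(x, y, z)` in Angstrom.
#' @export
center_of_mass <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0) {
    stop_helichir("center of mass of an empty group is undefined.",
                  "invalid_input")
  }
  m <- atoms$mass
  check_finite(m, "atomic masses")
  c(x = sum(m * atoms$x), y = sum(m * atoms$y), z = sum(m * atoms$z)) / sum(m)
}

#' Per-molecule centers of mass
#'
#' @param atoms Partitioned atom table (with `molecule_id`, from
#'   [partition_molecules()]).
#' @return Tibble with one row per molecule: `molecule_id`, `x`, `y`, `z`,
#'   `n_atoms`, `total_mass`.
#' @export
molecule_centers <- function(atoms) {
  atoms <- as_tibble(atoms)
  if (!"molecule_id" %in% names(atoms)) {
    stop_helichir("atoms must be partitioned first (no molecule_id column).",
                  "invalid_input")
  }
  atoms |>
    group_by(.data$molecule_id) |>
    summarise(
      x = sum(.data$mass * .data$x) / sum(.data$mass),
      y = sum(.data$mass * .data$y) / sum(.data$mass),
      z = sum(.data$mass * .data$z) / sum(.data$mass),
      n_atoms = n(),
      total_mass = sum(.data$mass),
      .groups = "drop"
    )
}

#' Attach per-atom partial charges to an atom table
#'
#' Charges come either from a PQR file (whose occupancy field carries the
#' charge) matched by atom order, or from a TSV with columns `eleno` and
#' `charge`. Charges are never guessed from the element.
#'
#' @param atoms Atom table from [read_structure()].
#' @param path Path to a PQR or TSV charge file.
#' @return The atom table with a `charge` column (elementary charges).
#' @export
attach_charges <- function(atoms, path) {
  atoms <- as_tibble(atoms)
  if (!file.exists(path)) {
    stop_helichir(sprintf("charge file '%s' does not exist.", path), "io")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "pqr") {
    pqr <- tryCatch(bio3d::read.pqr(path, verbose = FALSE),
                    error = function(e) {
                      stop_helichir(sprintf("cannot parse PQR '%s': %s", path,
                                            conditionMessage(e)), "format")
                    })
    q <- as.numeric(pqr$atom$o)
    if (length(q) != nrow(atoms)) {
      stop_helichir(
        sprintf("PQR has %d atoms but structure has %d.", length(q),
                nrow(atoms)),
        "invalid_input"
      )
    }
    atoms$charge <- q
  } else {
    tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
    names(tab) <- tolower(names(tab))
    if (!all(c("eleno", "charge") %in% names(tab))) {
      stop_helichir("charge TSV needs columns 'eleno' and 'charge'.",
                    "format")
    }
    q <- tab$charge[match(atoms$eleno, tab$eleno)]
    atoms$charge <- as.numeric(q)
  }
  missing <- which(is.na(atoms$charge))
  if (length(missing)) {
    stop_helichir(
      sprintf("no charge for atom(s) eleno %s.",
              paste(atoms$eleno[head(missing, 10)], collapse = ", ")),
      "missing_charge"
    )
  }
  atoms
}

#' Point-charge dipole moment of one molecule
#'
#' Estimates the dipole as the charge-weighted sum of displacement vectors,
#' D = sum q_j (r_j - r_ref), converted from e*Angstrom to Debye
#' (1 e*A = 4.80320 D). This is a classical point-charge estimate from
#' whatever partial charges are supplied; it is not equivalent to
#' quantum-chemical or force-field dipoles and is tagged `"point-charge"`
#' in the output. For net-neutral molecules the result is independent of
#' the reference point.
#'
#' @param atoms Atom table of one molecule, with a `charge` column.
#' @param reference Reference point for displacements: the molecule's
#'   `"center_of_mass"` (default) or `"center_of_charge"` (weighted by
#'   absolute charge).
#' @return One-row tibble with `dx`, `dy`, `dz`, `di` (Debye) and the
#'   center of mass as origin `ox`, `oy`, `oz` (Angstrom).
#' @export
point_charge_dipole <- function(atoms,
                                reference = c("center_of_mass",
                                              "center_of_charge")) {
  reference <- match.arg(reference)
  atoms <- as_tibble(atoms)
  if (!"charge" %in% names(atoms) || anyNA(atoms$charge)) {
    bad <- if (!"charge" %in% names(atoms)) atoms$eleno
           else atoms$eleno[is.na(atoms$charge)]
    stop_helichir(
      sprintf("atoms lack charges (eleno %s); attach a PQR or charge table.",
              paste(head(bad, 10), collapse = ", ")),
      "missing_charge"
    )
  }
  com <- center_of_mass(atoms)
  ref <- if (reference == "center_of_mass") com else {
    w <- abs(atoms$charge)
    if (sum(w) == 0) {
      stop_helichir("all charges are zero; center of charge is undefined.",
                    "invalid_input")
    }
    c(x = sum(w * atoms$x), y = sum(w * atoms$y), z = sum(w * atoms$z)) / sum(w)
  }
  q <- atoms$charge
  d <- EA_TO_DEBYE * c(
    sum(q * (atoms$x - ref[["x"]])),
    sum(q * (atoms$y - ref[["y"]])),
    sum(q * (atoms$z - ref[["z"]]))
  )
  tibble(dx = d[1], dy = d[2], dz = d[3], di = sqrt(sum(d^2)),
         ox = com[["x"]], oy = com[["y"]], oz = com[["z"]])
}

#' Per-molecule point-charge dipoles of a partitioned assembly
#'
#' Computes one point-charge dipole per molecule, orders the molecules along
#' the helix (by ascending azimuth of their centers of mass about the fitted
#' helix axis, starting from the molecule with the lowest axial coordinate),
#' and returns them as a [coil_dipoles] set ready for
#' [full_dipole_analysis()]. With `order = "as_given"` the molecule_id order
#' is kept instead; the traversal order determines the sign of the
#' chirality measure.
#'
#' @param atoms Partitioned atom table with charges.
#' @param reference Passed to [point_charge_dipole()].
#' @param order `"azimuthal"` (default, helix traversal) or `"as_given"`.
#' @param label Optional label for the coil.
#' @return A [coil_dipoles] with origins; the `helix_fit` attribute holds the
#'   fitted helix parameters when azimuthal ordering was used.
#' @export
structure_dipoles <- function(atoms,
                              reference = c("center_of_mass",
                                            "center_of_charge"),
                              order = c("azimuthal", "as_given"),
                              label = NULL) {
  reference <- match.arg(reference)
  order <- match.arg(order)
  atoms <- as_tibble(atoms)
  if (!"molecule_id" %in% names(atoms)) {
    stop_helichir("atoms must be partitioned first (no molecule_id column).",
                  "invalid_input")
  }
  ids <- sort(unique(atoms$molecule_id))
  rows <- purrr::map(ids, function(id) {
    point_charge_dipole(atoms[atoms$molecule_id == id, , drop = FALSE],
                        reference = reference)
  })
  dip <- bind_rows(rows)
  dip$molecule_id <- ids
  fit <- NULL
  if (order == "azimuthal") {
    if (nrow(dip) < 4) {
      stop_helichir(
        "azimuthal ordering needs at least 4 molecules to fit a helix axis.",
        "insufficient_points"
      )
    }
    fit <- fit_helix_params(dip[, c("ox", "oy", "oz")])
    frame <- axis_frame(fit$axis)
    centered <- sweep(as.matrix(dip[, c("ox", "oy", "oz")]), 2, fit$center)
    axial <- centered %*% fit$axis
    phi <- atan2(centered %*% frame$e2, centered %*% frame$e1)
    start <- which.min(axial)
    phi0 <- (phi - phi[start]) %% (2 * pi)
    dip <- dip[order(phi0, axial), , drop = FALSE]
  }
  coil <- coil_dipoles(dip[, c("dx", "dy", "dz", "di", "ox", "oy", "oz")],
                       method = "point-charge", label = label)
  attr(coil, "molecule_id") <- dip$molecule_id
  if (!is.null(fit)) attr(coil, "helix_fit") <- fit
  coil
}
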