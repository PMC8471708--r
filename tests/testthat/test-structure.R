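test_that("PDB fixtures round-trip through the structure reader", {
  # synthetic 2-molecule assembly written by the generator
  path <- withr::local_tempfile(fileext = ".pdb")
  make_supramolecular_coil(n_molecules = 2, atoms_per_molecule = 43,
                           seed = 5, pdb_path = path)
  atoms <- read_structure(path)
  expect_identical(nrow(atoms), 86L)
  expect_identical(sort(unique(atoms$chain)), c("A", "B"))
  expect_true(all(atoms$mass > 0))

  # minimal hand-written 4-residue helical stub bundled with the package
  stub <- read_structure(helichir_fixture("helix4.pdb"))
  trace <- extract_calpha_trace(stub, "A")
  expect_identical(nrow(trace), 4L)
  expect_gt(chi_total_backbone(trace)$c_total, 0)
})

test_that("unknown element symbols raise a mass-lookup error", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  XX  UNK A   1       0.000   0.000   0.000  1.00  0.00          Xx",
    "END"), path)
  expect_error(read_structure(path), class = "helichir_mass_lookup")
})

test_that("Calpha extraction orders by residue number and reports gaps", {
  helix <- make_calpha_helix(n_residues = 6, pdb_path = NULL)
  path <- withr::local_tempfile(fileext = ".pdb")
  df <- as.data.frame(helix)
  df$residue <- c(1, 2, 3, 5, 6, 7)  # numbering gap after residue 3
  write_calpha_pdb(calpha_trace(df, chain = "A"), path)
  atoms <- read_structure(path)
  # shuffle rows: extraction must re-order by residue number
  atoms <- atoms[sample(nrow(atoms)), ]
  trace <- extract_calpha_trace(atoms, "A")
  expect_identical(trace$residue, c(1L, 2L, 3L, 5L, 6L, 7L))
  expect_identical(attr(trace, "gaps")$after_residue, 3L)

  expect_error(extract_calpha_trace(atoms, "Z"), class = "helichir_empty_trace")
})

test_that("a 3-residue chain fails the downstream minimum-points check", {
  helix <- make_calpha_helix(n_residues = 4)
  short <- calpha_trace(as.data.frame(helix)[1:3, ], chain = "A")
  expect_error(chi_total_backbone(short),
               class = "helichir_insufficient_points")
})

test_that("partitioning assigns every atom to exactly one molecule", {
  atoms <- make_supramolecular_coil(n_molecules = 6, atoms_per_molecule = 43,
                                    seed = 9)
  expect_identical(nrow(atoms), 258L)
  for (rule in c("by_chain", "by_residue_block", "by_connectivity_distance")) {
    part <- partition_molecules(atoms, rule = rule, expected_atom_count = 43)
    sizes <- attr(part, "partition")
    expect_identical(nrow(sizes), 6L)
    expect_true(all(sizes$n_atoms == 43L))
    expect_identical(sum(sizes$n_atoms), nrow(atoms))  # a true partition
    expect_false(anyNA(part$molecule_id))
  }
  # single chain of one molecule: identity partition
  one <- partition_molecules(atoms[atoms$chain == "A", ], rule = "by_chain")
  expect_identical(nrow(attr(one, "partition")), 1L)
  expect_error(partition_molecules(atoms[0, ]), class = "helichir_invalid_input")
  # wrong expected size is refused
  expect_error(partition_molecules(atoms, rule = "by_chain",
                                   expected_atom_count = 40),
               class = "helichir_partition")
})

test_that("connectivity partitioning rejects degenerate coincident coordinates", {
  atoms <- make_supramolecular_coil(n_molecules = 2, atoms_per_molecule = 5,
                                    seed = 3)
  atoms$x[2] <- atoms$x[1]; atoms$y[2] <- atoms$y[1]; atoms$z[2] <- atoms$z[1]
  expect_error(partition_molecules(atoms, rule = "by_connectivity_distance"),
               class = "helichir_ambiguous_partition")
})

test_that("center of mass is the mass-weighted mean and is equivariant", {
  two <- tibble::tibble(x = c(0, 2), y = 0, z = 0, mass = c(12, 12))
  expect_equal(center_of_mass(two), c(x = 1, y = 0, z = 0))
  one <- tibble::tibble(x = 1.5, y = -2, z = 7, mass = 16)
  expect_equal(center_of_mass(one), c(x = 1.5, y = -2, z = 7))

  # 43 random atoms: frozen against the explicit weighted-sum formula
  set.seed(13)
  grp <- tibble::tibble(x = rnorm(43), y = rnorm(43), z = rnorm(43),
                        mass = runif(43, 1, 32))
  oracle <- c(x = sum(grp$mass * grp$x), y = sum(grp$mass * grp$y),
              z = sum(grp$mass * grp$z)) / sum(grp$mass)
  expect_equal(center_of_mass(grp), oracle, tolerance = 1e-14)

  # translation equivariance
  shifted <- dplyr::mutate(grp, x = x + 3, y = y - 1, z = z + 10)
  expect_equal(center_of_mass(shifted), oracle + c(x = 3, y = -1, z = 10))
  # rotation equivariance
  rot <- random_rotation(seed = 21)
  rotated <- grp
  xyz <- as.matrix(grp[, c("x", "y", "z")]) %*% t(rot)
  rotated$x <- xyz[, 1]; rotated$y <- xyz[, 2]; rotated$z <- xyz[, 3]
  expect_equal(unname(center_of_mass(rotated)), drop(rot %*% oracle),
               tolerance = 1e-12)
})

test_that("point-charge dipole matches the textbook two-charge case", {
  pair <- tibble::tibble(x = c(1, 0), y = 0, z = 0, mass = c(1, 1),
                         charge = c(1, -1))
  d <- point_charge_dipole(pair, reference = "center_of_charge")
  expect_equal(d$di, 4.80320)  # 1 e.A in Debye
  expect_equal(c(d$dx, d$dy, d$dz), c(4.80320, 0, 0))
})

test_that("neutral-group dipoles are independent of the reference point", {
  atoms <- make_supramolecular_coil(n_molecules = 1, atoms_per_molecule = 20,
                                    seed = 31)
  d_com <- point_charge_dipole(atoms, reference = "center_of_mass")
  d_coc <- point_charge_dipole(atoms, reference = "center_of_charge")
  expect_equal(c(d_com$dx, d_com$dy, d_com$dz),
               c(d_coc$dx, d_coc$dy, d_coc$dz), tolerance = 1e-9)
})

test_that("point-charge dipole matches an explicit charge-sum oracle", {
  set.seed(17)
  q <- rnorm(5); q <- q - mean(q)  # net neutral
  grp <- tibble::tibble(x = rnorm(5), y = rnorm(5), z = rnorm(5),
                        mass = runif(5, 1, 16), charge = q)
  com <- c(sum(grp$mass * grp$x), sum(grp$mass * grp$y),
           sum(grp$mass * grp$z)) / sum(grp$mass)
  oracle <- 4.80320 * c(sum(q * (grp$x - com[1])), sum(q * (grp$y - com[2])),
                        sum(q * (grp$z - com[3])))
  d <- point_charge_dipole(grp)
  expect_equal(c(d$dx, d$dy, d$dz), oracle, tolerance = 1e-12)
  expect_equal(c(d$ox, d$oy, d$oz), unname(com))
})

test_that("missing charges are reported by atom", {
  atoms <- make_supramolecular_coil(n_molecules = 1, atoms_per_molecule = 5,
                                    charges = FALSE, seed = 2)
  err <- expect_error(point_charge_dipole(atoms),
                      class = "helichir_missing_charge")
  expect_match(conditionMessage(err), "eleno")
})

test_that("charges attach from TSV tables and PQR files", {
  atoms <- make_supramolecular_coil(n_molecules = 2, atoms_per_molecule = 10,
                                    charges = TRUE, seed = 8)
  truth <- atoms$charge
  bare <- dplyr::select(atoms, -"charge")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(eleno = atoms$eleno, charge = truth), tsv)
  expect_equal(attach_charges(bare, tsv)$charge, truth, tolerance = 1e-12)

  # PQR: occupancy field carries the charge
  pqr <- withr::local_tempfile(fileext = ".pqr")
  name4 <- ifelse(nchar(atoms$atom_name) >= 4,
                  substr(atoms$atom_name, 1, 4),
                  sprintf(" %-3s", atoms$atom_name))
  writeLines(c(sprintf(
    "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%8.4f%7.4f",
    atoms$eleno, name4, "UNK", atoms$chain,
    atoms$resno, atoms$x, atoms$y, atoms$z, truth, 1.5), "END"), pqr)
  got <- attach_charges(bare, pqr)$charge
  expect_equal(got, round(truth, 4), tolerance = 1e-9)

  # incomplete charge table is an error naming atoms
  short <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(eleno = atoms$eleno[-1],
                                  charge = truth[-1]), short)
  expect_error(attach_charges(bare, short), class = "helichir_missing_charge")
})

test_that("structure dipoles order molecules along the helix traversal", {
  atoms <- make_supramolecular_coil(n_molecules = 6, atoms_per_molecule = 43,
                                    seed = 23)
  part <- partition_molecules(atoms, rule = "by_chain")
  coil <- structure_dipoles(part, order = "azimuthal")
  expect_s3_class(coil, "coil_dipoles")
  expect_identical(nrow(coil), 6L)
  expect_identical(attr(coil, "method"), "point-charge")
  # generator placed centers on an ascending helix; traversal starts at the
  # lowest axial point and ascends
  expect_identical(order(coil$oz), 1:6)
  fit <- attr(coil, "helix_fit")
  expect_false(is.null(fit))
  # azimuthal ordering is invariant to the incoming molecule order
  shuffled <- part[sample(nrow(part)), ]
  coil2 <- structure_dipoles(shuffled, order = "azimuthal")
  expect_equal(as.data.frame(coil2), as.data.frame(coil), tolerance = 1e-9)
})
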