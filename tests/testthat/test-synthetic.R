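test_that("generators are seed-deterministic", {
  a <- make_dipole_rosette(n = 6, noise_sigma = 0.1, seed = 4)
  b <- make_dipole_rosette(n = 6, noise_sigma = 0.1, seed = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- make_dipole_rosette(n = 6, noise_sigma = 0.1, seed = 5)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))

  h1 <- make_calpha_helix(8, noise_sigma = 0.05, seed = 12)
  h2 <- make_calpha_helix(8, noise_sigma = 0.05, seed = 12)
  expect_identical(as.data.frame(h1), as.data.frame(h2))
})

test_that("ideal rosette chirality matches the closed-form oracle", {
  # each of the n-2 triples equals p^2 * z * (2 sin s - sin 2s); for the
  # right-handed traversal (s = -60 deg) and z < 0 every term is
  # p^2 * |z| * sqrt(3)/2, so c_total = 4 * 19^2 * 12 * sqrt(3)/2
  ros <- make_dipole_rosette(n = 6, in_plane_magnitude = 19,
                             z_component = -12, handedness = "right")
  expect_equal(c_total_dipoles(ros), 4 * 361 * 12 * sqrt(3) / 2,
               tolerance = 1e-12)
  expect_gt(c_total_dipoles(ros), 0)  # right-handed, like the L-FF nanotube

  left <- make_dipole_rosette(n = 6, in_plane_magnitude = 19,
                              z_component = -12, handedness = "left")
  expect_equal(c_total_dipoles(left), -c_total_dipoles(ros), tolerance = 1e-12)

  expect_error(make_dipole_rosette(n = 2), class = "helichir_invalid_input")
})

test_that("ideal rosettes cancel their in-plane components around a turn", {
  for (n in c(3, 5, 6, 8)) {
    ros <- make_dipole_rosette(n = n, turns = 1)
    expect_lt(abs(sum(ros$dx)), 1e-9)
    expect_lt(abs(sum(ros$dy)), 1e-9)
  }
})

test_that("backbone helix generator fixes the sign convention", {
  right <- make_calpha_helix(10, handedness = "right")
  expect_gt(chi_total_backbone(right)$c_total, 0)
  left <- make_calpha_helix(10, handedness = "left")
  expect_equal(chi_total_backbone(left)$c_total,
               -chi_total_backbone(right)$c_total, tolerance = 1e-12)
  expect_error(make_calpha_helix(3), class = "helichir_invalid_input")
})

test_that("small coordinate noise perturbs backbone chirality by under 1%", {
  clean <- chi_total_backbone(make_calpha_helix(10))$c_total
  noisy <- chi_total_backbone(make_calpha_helix(10, noise_sigma = 0.01,
                                                seed = 3))$c_total
  expect_lt(abs(noisy - clean) / abs(clean), 0.01)
})

test_that("mirroring is an involution that negates chirality but not magnitudes", {
  ros <- make_dipole_rosette(n = 6, noise_sigma = 0.3, seed = 6)
  for (plane in c("xy", "xz", "yz")) {
    expect_equal(as.data.frame(mirror(mirror(ros, plane), plane)),
                 as.data.frame(ros))
    expect_equal(c_total_dipoles(mirror(ros, plane)), -c_total_dipoles(ros),
                 tolerance = 1e-12)
    expect_equal(d_av(mirror(ros, plane)), d_av(ros), tolerance = 1e-12)
  }
  v <- c(1, -2, 3)
  expect_identical(mirror(v, "xz"), c(1, 2, 3))
})

test_that("random rotations are proper, reproducible and leave chirality invariant", {
  for (seed in c(1, 2, 3)) {
    rot <- random_rotation(seed)
    expect_equal(det(rot), 1, tolerance = 1e-12)
    expect_equal(t(rot) %*% rot, diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(rot, random_rotation(seed))
  }
  lff <- read_fixture_quietly("lff_pm3.tsv")
  ct <- c_total_dipoles(lff)
  for (seed in 1:5) {
    rotated <- rotate(lff, random_rotation(seed))
    expect_equal(c_total_dipoles(rotated), ct, tolerance = 1e-9)
  }
})

test_that("chirality scales cubically while its normalized form is scale-free", {
  coil <- random_coil(7, seed = 33)
  res <- full_dipole_analysis(coil)
  for (lambda in c(0.25, 2, 7.5)) {
    scaled <- coil_dipoles(data.frame(dx = lambda * coil$dx,
                                      dy = lambda * coil$dy,
                                      dz = lambda * coil$dz))
    res_s <- full_dipole_analysis(scaled)
    expect_equal(res_s$c_total, lambda^3 * res$c_total, tolerance = 1e-9)
    expect_equal(res_s$c_norm, res$c_norm, tolerance = 1e-9)
  }
})

test_that("reversing the traversal order negates the chirality sum", {
  for (seed in 1:4) {
    coil <- random_coil(6, seed = seed)
    rev_coil <- coil_dipoles(data.frame(dx = rev(coil$dx), dy = rev(coil$dy),
                                        dz = rev(coil$dz)))
    expect_equal(c_total_dipoles(rev_coil), -c_total_dipoles(coil),
                 tolerance = 1e-9)
  }
})

test_that("generated helix PDB files feed the full backbone pipeline", {
  path <- withr::local_tempfile(fileext = ".pdb")
  make_calpha_helix(10, handedness = "left", pdb_path = path)
  atoms <- read_structure(path)
  trace <- extract_calpha_trace(atoms, "A")
  expect_identical(nrow(trace), 10L)
  expect_identical(chi_total_backbone(trace)$handedness, "left")
})
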