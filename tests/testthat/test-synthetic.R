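test_that("with_seed is reproducible and preserves the caller's stream", {
  a <- enzdyn:::with_seed(42, rnorm(5))
  b <- enzdyn:::with_seed(42, rnorm(5))
  expect_identical(a, b)
  set.seed(7)
  x1 <- rnorm(3)
  set.seed(7)
  invisible(enzdyn:::with_seed(42, rnorm(100)))
  x2 <- rnorm(3)
  expect_identical(x1, x2)
})

test_that("harmonic ensembles are seeded and carry analytic expectations", {
  m <- build_peptide_model(c("ALA", "GLY"))
  t1 <- make_harmonic_trajectory(m, sigma = 0.4, n_frames = 50, seed = 9)
  t2 <- make_harmonic_trajectory(m, sigma = 0.4, n_frames = 50, seed = 9)
  t3 <- make_harmonic_trajectory(m, sigma = 0.4, n_frames = 50, seed = 10)
  expect_identical(t1$xyz, t2$xyz)
  expect_false(identical(t1$xyz, t3$xyz))
  expect_equal(unique(t1$metadata$expected_rmsf), 0.4 * sqrt(3))
  expect_error(make_harmonic_trajectory(m, sigma = -1, n_frames = 10),
               "non-negative")
})

test_that("harmonic displacement moments match sigma", {
  m <- build_peptide_model(c("ALA", "GLY"))
  tr <- make_harmonic_trajectory(m, sigma = 0.7, n_frames = 20000, seed = 3)
  dev <- sweep(tr$xyz, 2, as.vector(t(m$xyz)))
  # per-coordinate sd ~ sigma within sampling error
  sds <- apply(dev, 2, sd)
  expect_lt(max(abs(sds - 0.7)), 0.03)
  # per-atom rms displacement ~ sigma * sqrt(3)
  msf <- colMeans(dev^2)
  per_atom <- msf[seq(1, length(msf), 3)] + msf[seq(2, length(msf), 3)] +
    msf[seq(3, length(msf), 3)]
  expect_lt(max(abs(sqrt(per_atom) - 0.7 * sqrt(3))), 0.05)
})

test_that("correlation blocks plant the requested rho", {
  m <- build_peptide_model(rep("GLY", 6))
  ca <- as.integer(select_atoms(m, "calpha"))
  for (rho in c(-1, 0.5, 1)) {
    tr <- make_harmonic_trajectory(
      m, sigma = 0.5, n_frames = 30000,
      correlation_blocks = list(list(atoms = ca[1:2], rho = rho)), seed = 4)
    dev <- sweep(tr$xyz, 2, as.vector(t(m$xyz)))
    i <- ca[1]; j <- ca[2]
    num <- sum(sapply(1:3, function(k)
      mean(dev[, 3 * (i - 1) + k] * dev[, 3 * (j - 1) + k])))
    den <- sqrt(sum(colMeans(dev[, 3 * (i - 1) + 1:3]^2)) *
                  sum(colMeans(dev[, 3 * (j - 1) + 1:3]^2)))
    expect_lt(abs(num / den - rho), 0.03)
  }
  expect_error(make_harmonic_trajectory(
    m, sigma = 0.5, n_frames = 10,
    correlation_blocks = list(list(atoms = ca[1:3], rho = -0.9))),
    "positive semi-definite")
})

test_that("two-basin ensemble splits frames per p1 with the given offset", {
  m <- build_peptide_model(c("ALA", "GLY"))
  off <- matrix(0, n_atoms(m), 3)
  off[m$atoms$resno == 1, 1] <- 4
  tr <- make_two_basin_trajectory(m, basin_offset = off, p1 = 0.7,
                                  sigma = 0.1, n_frames = 5000, seed = 6)
  basin <- tr$metadata$basin
  expect_setequal(unique(basin), c(1L, 2L))
  expect_lt(abs(mean(basin == 1) - 0.7), 0.03)
  # basin-2 frames actually sit at the offset
  d1 <- tr$xyz[basin == 1, 1]
  d2 <- tr$xyz[basin == 2, 1]
  expect_lt(abs(mean(d2) - mean(d1) - 4), 0.05)
  expect_error(make_two_basin_trajectory(m, basin_offset = off, p1 = 1,
                                         sigma = 0.1, n_frames = 10),
               "p1")
  expect_error(make_two_basin_trajectory(m, basin_offset = off * 0, p1 = 0.5,
                                         sigma = 0.1, n_frames = 10),
               "centres must differ")
})

test_that("hbond fixture satisfies its schedule exactly by construction", {
  fx <- make_interaction_fixture("hbond",
                                 schedule = list(list(on = c(1, 3, 5)),
                                                 list(on = 2:4)),
                                 n_frames = 6)
  a <- fx$model$atoms
  for (p in 1:2) {
    d <- which(a$resno == 2 * p - 1 & a$elety == "OG")
    h <- which(a$resno == 2 * p - 1 & a$elety == "HG")
    acc <- which(a$resno == 2 * p & a$elety == "O")
    for (f in 1:6) {
      co <- frame_coords(fx$trajectory, f)
      dist <- sqrt(sum((co[d, ] - co[acc, ])^2))
      v1 <- co[d, ] - co[h, ]; v2 <- co[acc, ] - co[h, ]
      ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
      on <- f %in% fx$schedule[[p]]$on
      if (on) {
        expect_equal(dist, 2.8, tolerance = 1e-9)
        expect_equal(ang, 170, tolerance = 1e-7)
      } else {
        expect_equal(dist, 3.4, tolerance = 1e-9)
      }
    }
  }
})

test_that("fixture geometry overrides are honoured and validated", {
  fx <- make_interaction_fixture(
    "hbond", schedule = list(list(on = 1, on_distance = 2.5,
                                  off_distance = 3.8, on_angle = 150)),
    n_frames = 2)
  a <- fx$model$atoms
  d <- which(a$resno == 1 & a$elety == "OG")
  h <- which(a$resno == 1 & a$elety == "HG")
  acc <- which(a$resno == 2 & a$elety == "O")
  co <- frame_coords(fx$trajectory, 1)
  expect_equal(sqrt(sum((co[d, ] - co[acc, ])^2)), 2.5, tolerance = 1e-9)
  v1 <- co[d, ] - co[h, ]; v2 <- co[acc, ] - co[h, ]
  expect_equal(acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi,
               150, tolerance = 1e-7)
  co2 <- frame_coords(fx$trajectory, 2)
  expect_equal(sqrt(sum((co2[d, ] - co2[acc, ])^2)), 3.8, tolerance = 1e-9)
  expect_error(make_interaction_fixture(
    "hbond", schedule = list(list(on = 1, on_angle = 80))), "angle")
  expect_error(make_interaction_fixture(
    "hbond", schedule = list(list(on = 5)), n_frames = 3), "frame index")
})

test_that("saltbridge fixture controls the residue-pair minimum distance", {
  fx <- make_interaction_fixture("saltbridge",
                                 schedule = list(list(on = c(2, 3))),
                                 n_frames = 4)
  a <- fx$model$atoms
  od <- which(a$resno == 1 & a$elety %in% c("OD1", "OD2"))
  nz <- which(a$resno == 2 & a$elety == "NZ")
  for (f in 1:4) {
    co <- frame_coords(fx$trajectory, f)
    dmin <- min(sqrt(rowSums((co[od, , drop = FALSE] -
                                matrix(co[nz, ], 2, 3, byrow = TRUE))^2)))
    expect_equal(dmin, if (f %in% 2:3) 3.5 else 4.5, tolerance = 1e-9)
  }
})

test_that("ligand fixture maps every ligand residue to a subsite", {
  fx <- make_interaction_fixture("ligand",
                                 schedule = list(list(on = 1:2),
                                                 list(on = 3)),
                                 n_frames = 4)
  a <- fx$model$atoms
  lig_res <- unique(a$resno[a$is_ligand])
  expect_setequal(names(fx$subsite_map), as.character(lig_res))
  expect_true(all(fx$subsite_map %in% c("-3", "-2", "-1", "+1", "+2", "+3")))
})

test_that("rigid-motion injection changes coordinates but not geometry", {
  m <- build_peptide_model(c("ALA", "SER"))
  tr <- make_harmonic_trajectory(m, sigma = 0.2, n_frames = 5, seed = 2)
  moved <- apply_rigid_motion(tr, seed = 3)
  expect_false(isTRUE(all.equal(tr$xyz, moved$xyz)))
  # internal pairwise distances are invariant frame by frame
  for (f in 1:5) {
    d1 <- dist(frame_coords(tr, f))
    d2 <- dist(frame_coords(moved, f))
    expect_equal(as.vector(d1), as.vector(d2), tolerance = 1e-9)
  }
  # injection is seeded
  moved2 <- apply_rigid_motion(tr, seed = 3)
  expect_identical(moved$xyz, moved2$xyz)
})

test_that("random_rotation yields proper rotations", {
  set.seed(11)
  for (i in 1:5) {
    R <- random_rotation()
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})
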