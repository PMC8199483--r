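test_that("kabsch_fit recovers a known rigid transform", {
  set.seed(21)
  P <- matrix(rnorm(30), 10, 3)
  R <- random_rotation()
  tvec <- c(3, -2, 5)
  Q <- sweep(P %*% R, 2, tvec, "+")
  fit <- kabsch_fit(P, Q)
  expect_equal(fit$rotation, R, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$translation, tvec, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
})

test_that("kabsch_fit never returns a reflection", {
  set.seed(22)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P %*% diag(c(-1, 1, 1))   # mirrored target
  fit <- kabsch_fit(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
})

test_that("kabsch_fit rejects degenerate input", {
  P <- cbind(1:5, 0, 0)  # collinear
  expect_error(kabsch_fit(P, P), "collinear|degenerate")
  expect_error(kabsch_fit(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("superpose removes injected rigid-body motion exactly", {
  m <- build_peptide_model(c("ALA", "SER", "GLY"))
  tr <- make_harmonic_trajectory(m, sigma = 0.3, n_frames = 40, seed = 1)
  moved <- apply_rigid_motion(tr, seed = 2)
  f_tr <- superpose(tr, reference = "average")
  f_mv <- superpose(moved, reference = "average")
  # the fitted ensembles agree up to one global rigid transform: aligning
  # frame 1 maps the whole moved ensemble onto the original
  k <- kabsch_fit(frame_coords(f_mv, 1), frame_coords(f_tr, 1))
  diffs <- vapply(seq_len(n_frames(tr)), function(f) {
    mapped <- sweep(frame_coords(f_mv, f) %*% k$rotation, 2,
                    k$translation, "+")
    max(abs(mapped - frame_coords(f_tr, f)))
  }, numeric(1))
  expect_lt(max(diffs), 1e-6)
  # and the fluctuation profiles are identical outright
  expect_lt(max(abs(rmsf_profile(f_tr)$rmsf - rmsf_profile(f_mv)$rmsf)),
            1e-6)
})

test_that("superpose agrees with an independent implementation", {
  m <- build_peptide_model(c("ALA", "SER", "GLY"))
  tr <- apply_rigid_motion(
    make_harmonic_trajectory(m, sigma = 0.5, n_frames = 25, seed = 3),
    seed = 4)
  bb <- as.integer(select_atoms(m, "backbone"))
  cols <- as.vector(t(outer(3 * (bb - 1), 1:3, "+")))
  ours <- superpose(tr, reference = "first")
  theirs <- bio3d::fit.xyz(tr$xyz[1, ], tr$xyz,
                           fixed.inds = cols, mobile.inds = cols)
  expect_lt(max(abs(ours$xyz - theirs)), 1e-5)
})

test_that("rmsd_series matches a hand computation and handles regions", {
  m <- build_peptide_model(rep("GLY", 6))
  nfr <- 5
  base <- as.vector(t(m$xyz))
  xyz <- matrix(rep(base, nfr), nrow = nfr, byrow = TRUE)
  # displace residue 2's atoms by +1 A in x in frames 2..5 (no fit needed
  # as the rest anchors the structure almost perfectly)
  r2cols <- 3 * (which(m$atoms$resno == 2) - 1) + 1
  xyz[2:nfr, r2cols] <- xyz[2:nfr, r2cols] + 1
  tr <- md_trajectory(xyz, m)
  sel <- select_atoms(m, "backbone")
  rs <- rmsd_series(tr, reference = "first", selection = sel, fit = FALSE)
  expect_equal(rs$rmsd[rs$frame == 1], 0)
  nbb <- length(sel)
  hit <- sum(m$atoms$elety[as.integer(sel)] %in% c("N", "CA", "C") &
               m$atoms$resno[as.integer(sel)] == 2)
  expect_equal(unique(rs$rmsd[rs$frame > 1]), sqrt(hit / nbb),
               tolerance = 1e-12)
  # region series measure only the region but keep the global frames
  rmap <- region_map(data.frame(enzyme = "toy", region = "res2",
                                start = 2, end = 2))
  rs2 <- rmsd_series(tr, reference = "first", selection = sel,
                     regions = rmap, enzyme_label = "toy", fit = FALSE)
  reg <- rs2[rs2$region == "res2", ]
  expect_equal(unique(reg$rmsd[reg$frame > 1]), 1, tolerance = 1e-12)
})

test_that("rmsf_profile recovers sigma*sqrt(3) and the B-factor identity", {
  m <- build_peptide_model(rep(c("ALA", "GLY", "SER", "ALA"), 4))
  tr <- make_harmonic_trajectory(m, sigma = 0.5, n_frames = 8000, seed = 5)
  prof <- rmsf_profile(superpose(tr, reference = "average"))
  expect_equal(nrow(prof), 16)
  expect_lt(abs(mean(prof$rmsf) - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.03)
  expect_equal(prof$bfactor, (8 / 3) * pi^2 * prof$rmsf^2)
  expect_equal(bfactor_profile(prof)$bfactor, prof$bfactor)
})

test_that("rmsf_profile agrees with bio3d's rmsf on fitted coordinates", {
  m <- build_peptide_model(c("ALA", "SER", "GLY", "ALA"))
  tr <- make_harmonic_trajectory(m, sigma = 0.4, n_frames = 500, seed = 6)
  ft <- superpose(tr, reference = "average")
  prof <- rmsf_profile(ft, mass_weighted = FALSE)
  bb <- as.integer(select_atoms(m, "backbone"))
  cols <- as.vector(t(outer(3 * (bb - 1), 1:3, "+")))
  ref_rmsf <- bio3d::rmsf(ft$xyz[, cols])
  # bio3d divides by n-1; rescale to the population definition used here
  nf <- n_frames(ft)
  per_res <- tapply(ref_rmsf^2 * (nf - 1) / nf, m$atoms$resno[bb], mean)
  expect_equal(prof$rmsf, as.vector(sqrt(per_res)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mass weighting matters only when per-atom msf differs", {
  m <- build_peptide_model(c("ALA", "GLY"))
  # heterogeneous sigma: N/CA/C of residue 1 get different amplitudes
  sig <- rep(0.2, n_atoms(m))
  bb1 <- which(m$atoms$resno == 1 & m$atoms$elety %in% c("N", "CA", "C"))
  sig[bb1] <- c(0.2, 0.6, 0.4)
  tr <- make_harmonic_trajectory(m, sigma = sig, n_frames = 20000, seed = 7)
  pw <- rmsf_profile(tr, mass_weighted = TRUE)
  pu <- rmsf_profile(tr, mass_weighted = FALSE)
  expect_false(isTRUE(all.equal(pw$rmsf[1], pu$rmsf[1], tolerance = 1e-6)))
  # hand-computed mass-weighted aggregation from the per-atom attribute
  pa <- attr(pw, "per_atom")
  rows <- pa$resno == 1
  expect_equal(pw$rmsf[1],
               sqrt(sum(pa$mass[rows] * pa$msf[rows]) / sum(pa$mass[rows])))
})

test_that("residues missing backbone atoms are excluded with a warning", {
  m <- build_peptide_model(c("ALA", "GLY", "SER"))
  keep <- !(m$atoms$resno == 2 & m$atoms$elety == "CA")
  m2 <- structure_model(m$atoms[keep, c("elety", "resid", "chain", "resno",
                                        "element", "type")],
                        m$xyz[keep, ])
  tr <- make_harmonic_trajectory(m2, sigma = 0.3, n_frames = 200, seed = 8)
  expect_warning(prof <- rmsf_profile(tr), "missing backbone")
  expect_equal(prof$resno, c(1L, 3L))
})

test_that("profile matching lays profiles onto alignment columns", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "GG-G", ">b", "GGGG"), fa)
  aln <- read_alignment(fa)
  prof_a <- data.frame(chain = "A", resno = 1:3, resid = "GLY",
                       rmsf = c(1, 2, 3))
  prof_a$bfactor <- (8 / 3) * pi^2 * prof_a$rmsf^2
  class(prof_a) <- c("fluctuation_profile", "data.frame")
  prof_b <- data.frame(chain = "A", resno = 1:4, resid = "GLY",
                       rmsf = c(4, 5, 6, 7))
  prof_b$bfactor <- (8 / 3) * pi^2 * prof_b$rmsf^2
  class(prof_b) <- c("fluctuation_profile", "data.frame")
  mm <- match_profiles(prof_a, prof_b, aln, value = "rmsf")
  expect_equal(mm$value_a, c(1, 2, NA, 3))
  expect_equal(mm$value_b, c(4, 5, 6, 7))
  expect_error(match_profiles(prof_a[1:2, ], prof_b, aln), "ungapped")
})
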