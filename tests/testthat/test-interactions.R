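test_that("detect_hbonds matches the brute-force oracle on random fixtures", {
  n_checked <- 0
  for (seed in 1:40) {
    fx <- random_detector_fixture(seed)
    don <- select_atoms(fx$model, "donors", allow_empty = TRUE)
    acc <- select_atoms(fx$model, "acceptors", allow_empty = TRUE)
    if (!length(don) || !length(acc)) next
    frames <- seq_len(fx$n_frames)
    got <- detect_hbonds(fx$traj, don, acc, frames = frames)
    want <- oracle_hbonds(fx$traj, don, acc, frames = frames)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$frame, want$frame)
    expect_equal(got$donor, want$donor)
    expect_equal(got$acceptor, want$acceptor)
    expect_equal(got$distance, want$distance, tolerance = 1e-10)
    expect_equal(got$angle, want$angle, tolerance = 1e-8)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 30)
})

test_that("hydrogen-bond bounds are strict on both criteria", {
  # exactly at the distance cutoff -> no bond; just inside -> bond
  fx_at <- make_interaction_fixture(
    "hbond", schedule = list(list(on = 1, on_distance = 3.0)), n_frames = 1)
  ev_at <- detect_hbonds(fx_at$trajectory)
  expect_equal(nrow(ev_at), 0)
  fx_in <- make_interaction_fixture(
    "hbond", schedule = list(list(on = 1, on_distance = 3.0 - 1e-9)),
    n_frames = 1)
  expect_equal(nrow(detect_hbonds(fx_in$trajectory)), 1)
  # just below the angle cutoff -> no bond; just above -> bond
  fx_ang <- make_interaction_fixture(
    "hbond", schedule = list(list(on = 1, on_angle = 134.999)), n_frames = 1)
  expect_equal(nrow(detect_hbonds(fx_ang$trajectory)), 0)
  fx_ang2 <- make_interaction_fixture(
    "hbond", schedule = list(list(on = 1, on_angle = 135.001)), n_frames = 1)
  expect_equal(nrow(detect_hbonds(fx_ang2$trajectory)), 1)
})

test_that("same-residue pairs are never reported", {
  fx <- make_interaction_fixture("hbond", schedule = list(list(on = 1)),
                                 n_frames = 2)
  ev <- detect_hbonds(fx$trajectory)
  a <- fx$model$atoms
  expect_true(all(a$resno[ev$donor] != a$resno[ev$acceptor]))
})

test_that("detect_hbonds validates its inputs", {
  # a topology without hydrogens
  m <- build_peptide_model("GLY")
  keep <- m$atoms$element != "H"
  m2 <- structure_model(m$atoms[keep, c("elety", "resid", "chain", "resno",
                                        "element", "type")], m$xyz[keep, ])
  tr <- md_trajectory(matrix(as.vector(t(m2$xyz)), 1), m2)
  expect_error(detect_hbonds(tr), "no hydrogens")
  # a donor selection naming an H-less heavy atom
  fx <- make_interaction_fixture("hbond", schedule = list(list(on = 1)))
  a <- fx$model$atoms
  bad <- enzdyn:::.new_selection(which(a$elety == "CB"), "bad donors")
  expect_error(detect_hbonds(fx$trajectory, donors = bad),
               "without a bonded hydrogen")
})

test_that("hb_stats reproduces the worked static/dynamic example", {
  fx <- make_interaction_fixture("hbond",
                                 schedule = list(list(on = 1:10),
                                                 list(on = 1:4)),
                                 n_frames = 10)
  ev <- detect_hbonds(fx$trajectory)
  st <- hb_stats(ev, n_snapshots = 10, sequence_length = 5)
  expect_equal(st$static_count, 0.28)
  expect_equal(st$dynamic_count, 0.4)
  # literal per-snapshot variant
  st2 <- hb_stats(ev, n_snapshots = 10, sequence_length = 5,
                  per_snapshot_dynamic = TRUE)
  expect_equal(st2$dynamic_count, 0.04)
})

test_that("hb_stats counts pair identity by heavy atoms only", {
  # two hydrogens of one LYS NZ donating to the same acceptor in one frame
  # must count as one pair and one event
  ev <- data.frame(frame = c(1L, 1L), donor = c(10L, 10L),
                   hydrogen = c(11L, 12L), acceptor = c(20L, 20L),
                   distance = 2.8, angle = 160)
  attr(ev, "frames") <- 1L
  st <- hb_stats(ev, n_snapshots = 1, sequence_length = 2)
  expect_equal(st$static_count, 1 / 2)
  expect_equal(st$dynamic_count, 1 / 2)
})

test_that("solvent_hb_count counts protein-water bonds both ways", {
  m <- build_peptide_model("SER", n_waters = 1)
  # place the water O exactly 2.8 A from OG along the O-H direction used
  # by the fixture generator: simplest is to borrow detect_hbonds itself
  # on a crafted coordinate set and cross-check by hand counting
  og <- which(m$atoms$elety == "OG")
  hg <- which(m$atoms$elety == "HG")
  wo <- which(m$atoms$resid == "HOH" & m$atoms$elety == "O")
  wh <- which(m$atoms$resid == "HOH" & m$atoms$elety %in% c("H1", "H2"))
  xyz <- m$xyz
  u <- (xyz[og, ] - xyz[hg, ]) / sqrt(sum((xyz[og, ] - xyz[hg, ])^2))
  shift <- (xyz[hg, ] - 1.9 * u) - xyz[wo, ]   # linear O-H...Ow at ~2.9 A
  for (i in c(wo, wh)) xyz[i, ] <- xyz[i, ] + shift
  tr <- md_trajectory(matrix(as.vector(t(xyz)), 1), m)
  cnt <- solvent_hb_count(tr)
  expect_gte(as.numeric(cnt), 1)
  per_frame <- attr(cnt, "per_frame")
  expect_length(per_frame, 1)
  # hand count: enumerate protein<->solvent pairs meeting the criterion
  ora <- oracle_hbonds(tr, select_atoms(m, "all"),
                       enzdyn:::.new_selection(
                         which(m$atoms$element %in% c("N", "O")), "NO"),
                       frames = 1)
  a <- m$atoms
  cross <- xor(a$is_solvent[ora$donor], a$is_solvent[ora$acceptor])
  expect_equal(as.numeric(cnt), sum(cross))
  # no solvent -> error
  m0 <- build_peptide_model("SER")
  tr0 <- md_trajectory(matrix(as.vector(t(m0$xyz)), 1), m0)
  expect_error(solvent_hb_count(tr0), "no solvent")
})

test_that("salt_bridge_occupancy matches the oracle on random fixtures", {
  n_checked <- 0
  for (seed in 101:130) {
    fx <- random_detector_fixture(seed, kinds = c("ASP", "GLU", "LYS",
                                                  "ARG", "GLY"))
    a <- fx$model$atoms
    if (!length(intersect(c("ASP", "GLU"), a$resid)) ||
        !length(intersect(c("LYS", "ARG"), a$resid))) next
    frames <- seq_len(fx$n_frames)
    got <- salt_bridge_occupancy(fx$traj, frames = frames)
    want <- oracle_salt_bridges(fx$traj, frames = frames)
    # compare as sets keyed by chain:resno labels
    key_got <- paste(sub("^[A-Z]+ ", "", got$acidic),
                     sub("^[A-Z]+ ", "", got$basic))
    key_want <- paste(gsub(" ", ":", want$acidic), gsub(" ", ":", want$basic))
    expect_setequal(key_got, key_want)
    occ_want <- want$occupancy[match(key_got, key_want)]
    expect_equal(got$occupancy, occ_want, tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 15)
})

test_that("salt-bridge cutoff is inclusive and pairs use the minimum O-N", {
  fx <- make_interaction_fixture(
    "saltbridge", schedule = list(list(on = 1, on_distance = 4.0)),
    n_frames = 2)
  occ <- salt_bridge_occupancy(fx$trajectory)
  expect_equal(nrow(occ), 1)
  expect_equal(occ$occupancy, 50)
  fx2 <- make_interaction_fixture(
    "saltbridge", schedule = list(list(on = 1, on_distance = 4.0 + 1e-6)),
    n_frames = 2)
  expect_equal(nrow(salt_bridge_occupancy(fx2$trajectory)), 0)
})

test_that("planted salt-bridge occupancy is recovered exactly", {
  fx <- make_interaction_fixture("saltbridge",
                                 schedule = list(list(on = 1:8)),
                                 n_frames = 10)
  occ <- salt_bridge_occupancy(fx$trajectory)
  expect_equal(occ$occupancy, 80)
  expect_equal(occ$n_frames, 10)
  expect_match(occ$acidic, "ASP")
  expect_match(occ$basic, "LYS")
})

test_that("ligand occurrence recovers schedules and applies the threshold", {
  # schedule frames beyond n_frames are rejected at build time
  expect_error(make_interaction_fixture(
    "ligand", schedule = list(list(on = 23:24)), n_frames = 20),
    "frame index")
  fx <- make_interaction_fixture(
    "ligand", schedule = list(list(on = 1:13), list(on = 1:2)),
    n_frames = 20)
  occ_all <- ligand_hb_occurrence(fx$trajectory, fx$subsite_map,
                                  all_rows = TRUE)
  expect_setequal(occ_all$occurrence, c(65, 10))
  occ <- ligand_hb_occurrence(fx$trajectory, fx$subsite_map, threshold = 10)
  expect_setequal(occ$occurrence, c(65, 10))   # 10% stays: >= threshold
  occ2 <- ligand_hb_occurrence(fx$trajectory, fx$subsite_map,
                               threshold = 10.5)
  expect_equal(occ2$occurrence, 65)
  # a ligand residue missing from the map is an error
  bad_map <- fx$subsite_map[1]
  expect_error(ligand_hb_occurrence(fx$trajectory, bad_map),
               "missing from the subsite map")
})

test_that("block_average_se plateaus on AR(1) noise near the exact SE", {
  phi <- 0.9
  n <- 2^15
  x <- numeric(n)
  set.seed(33)
  e <- rnorm(n)
  for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
  se <- block_average_se(x)
  # exact SE of the mean of a long AR(1):
  # var(xbar) ~ sigma2_x * (1+phi)/(1-phi) / n
  sigma2 <- 1 / (1 - phi^2)
  se_exact <- sqrt(sigma2 * (1 + phi) / (1 - phi) / n)
  expect_lt(abs(as.numeric(se) - se_exact) / se_exact, 0.35)
  # naive SE underestimates by ~sqrt((1+phi)/(1-phi)) = 4.4x
  expect_gt(as.numeric(se), 2.5 * sd(x) / sqrt(n))
  expect_true(is.logical(attr(se, "plateau")))
  expect_s3_class(attr(se, "ladder"), "data.frame")
})

test_that("block_average_se is exact for iid data and validates length", {
  set.seed(34)
  x <- rnorm(4096)
  se <- block_average_se(x)
  expect_lt(abs(as.numeric(se) - 1 / sqrt(4096)) * sqrt(4096), 0.2)
  expect_error(block_average_se(rnorm(3)), "too short")
  # constant series -> zero SE, plateau at the smallest block size
  se0 <- block_average_se(rep(2, 64))
  expect_equal(as.numeric(se0), 0)
  expect_true(attr(se0, "plateau"))
})
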