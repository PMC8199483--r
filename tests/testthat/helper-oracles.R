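# Independent brute-force oracles used to cross-check the package's
# detectors.  These are written from the geometric definitions alone and
# deliberately share no code with the package internals.

# Euclidean distance between two atoms in an n x 3 coordinate matrix
.o_dist <- function(co, i, j) sqrt(sum((co[i, ] - co[j, ])^2))

# angle (degrees) at vertex b of the triangle a-b-c
.o_angle <- function(co, a, b, c) {
  v1 <- co[a, ] - co[b, ]
  v2 <- co[c, ] - co[b, ]
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, cosv))) * 180 / pi
}

# all-pairs hydrogen-bond oracle: loops over every frame, every
# (donor, hydrogen) pair and every acceptor; strict bounds, same-residue
# pairs excluded.  Returns a data frame sorted (frame, donor, acceptor).
oracle_hbonds <- function(traj, donors, acceptors, frames,
                          distance_cutoff = 3.0, angle_cutoff = 135.0) {
  model <- traj$topology
  a <- model$atoms
  dh <- donor_hydrogens(model)
  rows <- list()
  for (f in frames) {
    co <- frame_coords(traj, f)
    for (k in seq_len(nrow(dh))) {
      d <- dh$donor[k]
      if (!(d %in% as.integer(donors))) next
      h <- dh$hydrogen[k]
      for (acc in as.integer(acceptors)) {
        if (acc == d) next
        if (a$chain[acc] == a$chain[d] && a$resno[acc] == a$resno[d]) next
        dist <- .o_dist(co, d, acc)
        if (!(dist < distance_cutoff)) next
        ang <- .o_angle(co, d, h, acc)
        if (!(ang > angle_cutoff)) next
        rows[[length(rows) + 1]] <-
          data.frame(frame = f, donor = d, hydrogen = h, acceptor = acc,
                     distance = dist, angle = ang)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), donor = integer(0),
               hydrogen = integer(0), acceptor = integer(0),
               distance = numeric(0), angle = numeric(0))
  out <- out[order(out$frame, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all-pairs salt-bridge oracle: per frame, per acidic/basic residue pair,
# minimum carboxylate-O to basic-N distance <= cutoff (inclusive)
oracle_salt_bridges <- function(traj, frames, cutoff = 4.0) {
  a <- traj$topology$atoms
  ac <- which(a$resid == "ASP" & a$elety %in% c("OD1", "OD2") |
                a$resid == "GLU" & a$elety %in% c("OE1", "OE2"))
  ba <- which(a$resid == "LYS" & a$elety == "NZ" |
                a$resid == "ARG" & a$elety %in% c("NE", "NH1", "NH2"))
  ac_res <- unique(paste(a$chain[ac], a$resno[ac]))
  ba_res <- unique(paste(a$chain[ba], a$resno[ba]))
  res <- list()
  for (ra in ac_res) for (rb in ba_res) {
    ga <- ac[paste(a$chain[ac], a$resno[ac]) == ra]
    gb <- ba[paste(a$chain[ba], a$resno[ba]) == rb]
    formed <- 0
    for (f in frames) {
      co <- frame_coords(traj, f)
      dmin <- Inf
      for (i in ga) for (j in gb) dmin <- min(dmin, .o_dist(co, i, j))
      if (dmin <= cutoff) formed <- formed + 1
    }
    if (formed > 0)
      res[[length(res) + 1]] <- data.frame(
        acidic = ra, basic = rb, occupancy = 100 * formed / length(frames))
  }
  if (length(res)) do.call(rbind, res) else
    data.frame(acidic = character(0), basic = character(0),
               occupancy = numeric(0))
}

# brute-force DCC: per-atom displacement covariance from first principles
oracle_dcc <- function(traj, sel) {
  sel <- as.integer(sel)
  nf <- n_frames(traj)
  m <- length(sel)
  coords <- lapply(seq_len(nf), function(f)
    frame_coords(traj, f)[sel, , drop = FALSE])
  avg <- Reduce(`+`, coords) / nf
  C <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    s <- 0
    for (f in seq_len(nf))
      s <- s + sum((coords[[f]][i, ] - avg[i, ]) * (coords[[f]][j, ] - avg[j, ]))
    C[i, j] <- s / nf
  }
  v <- diag(C)
  C / sqrt(outer(v, v))
}

# random small fixture for the detector oracles: a handful of residues
# jittered around a grid so distances/angles land on both sides of the
# cutoffs
random_detector_fixture <- function(seed, kinds = c("SER", "ALA", "ASP",
                                                    "LYS", "GLY", "ARG",
                                                    "GLU")) {
  set.seed(seed)
  nres <- sample(2:5, 1)
  seqres <- sample(kinds, nres, replace = TRUE)
  model <- build_peptide_model(seqres, spacing = runif(1, 3.5, 7))
  nf <- sample(2:20, 1)
  base <- as.vector(t(model$xyz))
  xyz <- matrix(rep(base, nf), nrow = nf, byrow = TRUE) +
    matrix(rnorm(nf * length(base), sd = runif(1, 0.1, 1.2)),
           nrow = nf)
  list(model = model,
       traj = md_trajectory(xyz, model),
       n_frames = nf)
}
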