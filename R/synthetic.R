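# Synthetic ensembles with analytically known fluctuation, correlation,
# free-energy and interaction structure. These are first-class study
# conditions: an isotropic Gaussian ensemble has RMSF = sigma * sqrt(3)
# per atom in closed form, planted correlation blocks have DCC = rho, a
# two-basin mixture has a free-energy gap kT*ln(p1/p2), and interaction
# fixtures satisfy their occupancy schedules exactly by construction.

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Minimal internal geometries per residue type. Coordinates are offsets
# from the residue anchor; bonded N-H / O-H pairs are kept within 1.0 A so
# donor-hydrogen inference from the reference structure works.
.residue_templates <- list(
  GLY = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0)),
  ALA = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0), CB = c(1.45, 0, 1.5)),
  SER = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0), CB = c(1.45, 0, 1.5),
              OG = c(1.45, 0, 2.9), HG = c(1.45, 0.95, 3.2)),
  ASP = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0), CB = c(1.45, 0, 1.5),
              CG = c(1.45, 0, 3.0), OD1 = c(0.4, 0.6, 3.6),
              OD2 = c(2.5, -0.6, 3.6)),
  GLU = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0), CB = c(1.45, 0, 1.5),
              CG = c(1.45, 0, 3.0), CD = c(1.45, 0, 4.5),
              OE1 = c(0.4, 0.6, 5.1), OE2 = c(2.5, -0.6, 5.1)),
  LYS = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0), CB = c(1.45, 0, 1.5),
              CG = c(1.45, 0, 3.0), CD = c(1.45, 0, 4.5),
              CE = c(1.45, 0, 6.0), NZ = c(1.45, 0, 7.5),
              HZ1 = c(0.6, 0.4, 7.9), HZ2 = c(2.3, 0.4, 7.9),
              HZ3 = c(1.45, -0.9, 7.9)),
  HIS = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0), CB = c(1.45, 0, 1.5),
              CG = c(1.45, 0, 3.0), ND1 = c(0.35, 0.3, 3.75),
              HD1 = c(-0.55, 0.55, 3.4), CD2 = c(2.4, -0.4, 3.85),
              CE1 = c(0.75, 0.2, 5.0), NE2 = c(2.0, -0.25, 5.1)),
  ARG = rbind(N = c(0, 0, 0), H = c(0, -1, 0), CA = c(1.45, 0, 0),
              C = c(2.4, 1.1, 0), O = c(2.4, 2.33, 0), CB = c(1.45, 0, 1.5),
              CG = c(1.45, 0, 3.0), CD = c(1.45, 0, 4.5),
              NE = c(1.45, 0, 6.0), HE = c(0.6, 0.5, 6.3),
              CZ = c(2.4, -0.6, 6.8), NH1 = c(2.3, -0.5, 8.1),
              HH11 = c(1.5, -0.2, 8.6), HH12 = c(3.1, -0.9, 8.6),
              NH2 = c(3.5, -1.3, 6.3), HH21 = c(3.6, -1.4, 5.3),
              HH22 = c(4.3, -1.7, 6.9))
)

#' Build a small protein-like fixture
#'
#' One residue per entry of `sequence`, each placed on a widely spaced
#' grid so no unintended contacts exist, with real PDB atom names
#' (backbone N/H/CA/C/O; ASP OD1/OD2, LYS NZ+HZ*, ARG NE/NH*, SER OG/HG)
#' so selection and donor-inference logic is exercised rather than
#' bypassed.  Optional waters (`HOH` with O/H1/H2) and a bound
#' oligosaccharide-like ligand (`XYS` rings with hydroxyl donors and ring
#' acceptors, written as HETATM).
#'
#' @param sequence character vector of residue names among
#'   GLY/ALA/SER/ASP/GLU/LYS/ARG/HIS.
#' @param n_waters number of water molecules to append.
#' @param n_ligand_units number of xylose-like ligand residues to append.
#' @param spacing grid spacing between residue anchors (Angstrom).
#' @param chain chain id for protein residues.
#' @return a [structure_model()].
#' @export
build_peptide_model <- function(sequence, n_waters = 0, n_ligand_units = 0,
                                spacing = 12, chain = "A") {
  stopifnot(length(sequence) >= 1)
  sequence <- toupper(sequence)
  bad <- setdiff(sequence, names(.residue_templates))
  if (length(bad)) stop("no template for residue type: ",
                        paste(bad, collapse = ", "))
  rows <- list(); coords <- list()
  for (i in seq_along(sequence)) {
    tpl <- .residue_templates[[sequence[i]]]
    anchor <- c((i - 1) * spacing, 0, 0)
    rows[[i]] <- data.frame(elety = rownames(tpl), resid = sequence[i],
                            resno = i, chain = chain, type = "ATOM",
                            stringsAsFactors = FALSE)
    coords[[i]] <- sweep(tpl, 2, anchor, "+")
  }
  next_resno <- length(sequence)
  if (n_waters > 0) {
    wat <- rbind(O = c(0, 0, 0), H1 = c(0.95, 0, 0), H2 = c(-0.3, 0.9, 0))
    for (w in seq_len(n_waters)) {
      next_resno <- next_resno + 1L
      anchor <- c((w - 1) * spacing, spacing * 2, 0)
      rows[[length(rows) + 1]] <-
        data.frame(elety = rownames(wat), resid = "HOH", resno = next_resno,
                   chain = "W", type = "HETATM", stringsAsFactors = FALSE)
      coords[[length(coords) + 1]] <- sweep(wat, 2, anchor, "+")
    }
  }
  if (n_ligand_units > 0) {
    xys <- rbind(C1 = c(0, 0, 0), O5 = c(1.2, 0.6, 0), C2 = c(0, -1.4, 0.3),
                 O2 = c(-1.2, -2.0, 0.1), HO2 = c(-1.1, -2.95, 0.2),
                 O3 = c(1.0, -2.1, 1.1))
    for (u in seq_len(n_ligand_units)) {
      next_resno <- next_resno + 1L
      anchor <- c((u - 1) * spacing, -spacing * 2, 0)
      rows[[length(rows) + 1]] <-
        data.frame(elety = rownames(xys), resid = "XYS", resno = next_resno,
                   chain = "X", type = "HETATM", stringsAsFactors = FALSE)
      coords[[length(coords) + 1]] <- sweep(xys, 2, anchor, "+")
    }
  }
  atoms <- do.call(rbind, rows)
  structure_model(atoms, do.call(rbind, coords))
}

#' Gaussian ensemble about a reference structure
#'
#' Draws `n_frames` frames with independent isotropic per-coordinate
#' Gaussian displacements of standard deviation `sigma` per atom.
#' `correlation_blocks` plant equicorrelated displacements within atom
#' groups: each coordinate component of the grouped atoms shares pairwise
#' correlation `rho`, so the dynamic cross-correlation between grouped
#' atoms is exactly `rho` in expectation while the per-atom fluctuation
#' stays `sigma * sqrt(3)`.
#'
#' @param reference a [structure_model()] whose coordinates are the mean.
#' @param sigma per-coordinate standard deviation (Angstrom); scalar or
#'   one value per atom; zero allowed (frozen atoms).
#' @param n_frames number of frames (>= 2).
#' @param correlation_blocks list of `list(atoms = <indices>, rho = <r>)`.
#' @param seed integer seed; the generator is bit-reproducible.
#' @return an [md_trajectory()] whose `metadata` records the seed and the
#'   analytic expectations (`expected_rmsf = sigma * sqrt(3)`, block
#'   `rho`s).
#' @export
make_harmonic_trajectory <- function(reference, sigma, n_frames,
                                     correlation_blocks = NULL, seed = 1) {
  stopifnot(inherits(reference, "structure_model"), n_frames >= 2)
  na <- n_atoms(reference)
  sigma <- rep_len(sigma, na)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  xyz <- with_seed(seed, {
    disp <- matrix(rnorm(n_frames * 3 * na), nrow = n_frames)
    if (!is.null(correlation_blocks)) {
      for (blk in correlation_blocks) {
        g <- as.integer(blk$atoms); rho <- blk$rho
        m <- length(g)
        if (m < 2) stop("correlation block needs at least two atoms")
        R <- matrix(rho, m, m); diag(R) <- 1
        ev <- eigen(R, symmetric = TRUE)
        if (min(ev$values) < -1e-8)
          stop("correlation rho = ", rho, " over ", m,
               " atoms is not positive semi-definite")
        # matrix square root handles the singular rho = -1 / rho = 1 cases
        S <- ev$vectors %*% (t(ev$vectors) * sqrt(pmax(ev$values, 0)))
        for (k in 1:3) {
          cols <- 3 * (g - 1) + k
          disp[, cols] <- matrix(rnorm(n_frames * m), n_frames) %*% t(S)
        }
      }
    }
    scale_vec <- rep(sigma, each = 3)
    disp <- if (all(sigma == sigma[1])) disp * sigma[1]
    else t(t(disp) * scale_vec)
    # column-major recycling adds the flattened mean to every frame
    disp + rep(.flatten_coords(reference$xyz), each = n_frames)
  })
  md_trajectory(xyz, reference,
                metadata = list(generator = "harmonic", seed = seed,
                                sigma = sigma,
                                expected_rmsf = sigma * sqrt(3),
                                correlation_blocks = correlation_blocks))
}

#' Two-basin conformational-exchange ensemble
#'
#' Each frame is assigned to basin 1 with probability `p1` (seeded draw)
#' and placed at that basin's centre plus isotropic Gaussian noise.  In
#' expectation the free-energy gap between the two basin minima on a
#' Boltzmann-inverted landscape is `kT * ln(p1 / (1 - p1))`.
#'
#' @param reference a [structure_model()] (topology; basin 1 centre
#'   defaults to its coordinates).
#' @param basin_offset displacement vector (or `n_atoms x 3` matrix) from
#'   basin 1 to basin 2; must be non-zero.
#' @param p1 occupancy fraction of basin 1, strictly in (0, 1).
#' @param sigma within-basin per-coordinate standard deviation (Angstrom).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return an [md_trajectory()]; `metadata$basin` holds the per-frame
#'   basin labels and `metadata$p1` the planted occupancy.
#' @export
make_two_basin_trajectory <- function(reference, basin_offset, p1, sigma,
                                      n_frames, seed = 1) {
  stopifnot(inherits(reference, "structure_model"))
  if (!(p1 > 0 && p1 < 1)) stop("p1 must lie strictly within (0, 1)")
  na <- n_atoms(reference)
  off <- if (is.matrix(basin_offset)) basin_offset else
    matrix(basin_offset, na, 3, byrow = TRUE)
  if (all(off == 0)) stop("basin centres must differ")
  c1 <- .flatten_coords(reference$xyz)
  c2 <- c1 + .flatten_coords(off)
  gen <- with_seed(seed, {
    basin <- rbinom(n_frames, 1, 1 - p1) + 1L
    centres <- rbind(c1, c2)[basin, , drop = FALSE]
    list(xyz = centres + matrix(rnorm(n_frames * 3 * na, sd = sigma),
                                n_frames),
         basin = basin)
  })
  md_trajectory(gen$xyz, reference,
                metadata = list(generator = "two_basin", seed = seed,
                                p1 = p1, sigma = sigma, basin = gen$basin))
}

#' Interaction fixture with an exact occupancy schedule
#'
#' Builds a small molecular fixture plus a trajectory in which prescribed
#' donor/acceptor (or acidic/basic, or protein/ligand) pairs satisfy the
#' geometric interaction criterion in exactly the scheduled frames:
#' distances and angles are set analytically per frame (e.g. D-A = 2.8
#' Angstrom at 170 degrees in "on" frames, 3.4 Angstrom in "off" frames),
#' so a correct detector must reproduce the schedule with no sampling
#' error.
#'
#' @param kind `"hbond"`, `"saltbridge"` or `"ligand"`.
#' @param schedule list with one entry per planted pair; each entry is a
#'   list with `on` (integer frame indices in which the criterion holds)
#'   and optional geometry overrides `on_distance`, `off_distance`,
#'   `on_angle` (degrees, hbond/ligand kinds only).
#' @param n_frames number of frames.
#' @param seed integer seed (recorded; the construction is deterministic).
#' @return list with `model` ([structure_model()]), `trajectory`
#'   ([md_trajectory()]), `schedule`, and for `kind = "ligand"` a
#'   `subsite_map` (named vector: ligand resno -> subsite label).
#' @export
make_interaction_fixture <- function(kind = c("hbond", "saltbridge",
                                              "ligand"),
                                     schedule, n_frames = 10, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(length(schedule) >= 1)
  for (s in schedule) {
    if (any(s$on > n_frames | s$on < 1))
      stop("schedule frame index outside 1..n_frames")
    ang <- s$on_angle %||% 170
    if (ang > 180 || ang <= 90)
      stop("infeasible hydrogen-bond angle request: ", ang,
           " degrees (must lie in (90, 180])")
  }
  np <- length(schedule)
  if (kind == "hbond") {
    # donor residue SER (OG-HG) paired with acceptor residue ALA (carbonyl O)
    seqres <- rep(c("SER", "ALA"), np)
    model <- build_peptide_model(seqres)
  } else if (kind == "saltbridge") {
    seqres <- rep(c("ASP", "LYS"), np)
    model <- build_peptide_model(seqres)
  } else {
    seqres <- rep("SER", np)
    model <- build_peptide_model(seqres, n_ligand_units = np)
  }
  base <- .flatten_coords(model$xyz)
  xyz <- matrix(rep(base, n_frames), nrow = n_frames, byrow = TRUE)
  a <- model$atoms
  atom_at <- function(resno, name) which(a$resno == resno & a$elety == name)
  place_acceptor <- function(d_idx, h_idx, dist, angle_deg) {
    # acceptor placed in the plane of D and H so that the D-H-A angle
    # (vertex at H) is angle_deg and |D-A| = dist, exactly
    D <- model$xyz[d_idx, ]; H <- model$xyz[h_idx, ]
    u <- (D - H) / sqrt(sum((D - H)^2))       # H -> D direction
    # orthogonal direction in a fixed plane
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    v <- ref - sum(ref * u) * u
    v <- v / sqrt(sum(v^2))
    alpha <- pi - angle_deg * pi / 180        # angle of H->A from H->D is pi-alpha
    w <- -cos(alpha) * u + sin(alpha) * v     # unit H->A, angle(H->D, H->A)=180-alpha...
    # cos(angle between u and w) = -cos(alpha) => angle = pi - alpha = angle_deg
    dh <- sqrt(sum((D - H)^2))
    # solve |H + t*w - D|^2 = dist^2
    b <- -2 * t(w) %*% (D - H)
    cc <- dh^2 - dist^2
    tt <- (-b + sqrt(b^2 - 4 * cc)) / 2
    H + as.numeric(tt) * w
  }
  subsites <- c("-3", "-2", "-1", "+1", "+2", "+3")
  subsite_map <- NULL
  for (p in seq_len(np)) {
    s <- schedule[[p]]
    d_on <- s$on_distance %||% (if (kind == "saltbridge") 3.5 else 2.8)
    d_off <- s$off_distance %||% (if (kind == "saltbridge") 4.5 else 3.4)
    ang <- s$on_angle %||% 170
    if (kind == "saltbridge") {
      o1 <- atom_at(2 * p - 1, "OD1"); o2 <- atom_at(2 * p - 1, "OD2")
      n_idx <- atom_at(2 * p, "NZ")
      res_idx <- which(a$resno == 2 * p)
      # place NZ at OD1 + target * u with u pointing away from OD2, so
      # the OD1-NZ distance is exactly the residue-pair minimum
      u <- model$xyz[o1, ] - model$xyz[o2, ]
      u <- u / sqrt(sum(u^2))
      for (f in seq_len(n_frames)) {
        target <- if (f %in% s$on) d_on else d_off
        shift <- model$xyz[o1, ] + target * u - model$xyz[n_idx, ]
        for (ai in res_idx) {
          cc2 <- 3 * (ai - 1) + 1:3
          xyz[f, cc2] <- base[cc2] + shift
        }
      }
    } else {
      if (kind == "hbond") {
        d_idx <- atom_at(2 * p - 1, "OG"); h_idx <- atom_at(2 * p - 1, "HG")
        acc_res <- 2 * p
        acc_idx <- atom_at(acc_res, "O")
        acc_block <- acc_idx
      } else {
        d_idx <- atom_at(p, "OG"); h_idx <- atom_at(p, "HG")
        lig_resno <- np + p
        acc_idx <- atom_at(lig_resno, "O2")
        acc_block <- which(a$resno == lig_resno)
        subsite_map <- c(subsite_map,
                         setNames(subsites[((p - 1) %% 6) + 1],
                                  as.character(lig_resno)))
      }
      A_on <- place_acceptor(d_idx, h_idx, d_on, ang)
      A_off <- place_acceptor(d_idx, h_idx, d_off, ang)
      delta_on <- A_on - model$xyz[acc_idx, ]
      delta_off <- A_off - model$xyz[acc_idx, ]
      for (f in seq_len(n_frames)) {
        delta <- if (f %in% s$on) delta_on else delta_off
        for (ai in acc_block) {
          cc2 <- 3 * (ai - 1) + 1:3
          xyz[f, cc2] <- base[cc2] + delta
        }
      }
    }
  }
  traj <- md_trajectory(xyz, model,
                        metadata = list(generator = paste0("fixture_", kind),
                                        seed = seed, schedule = schedule))
  out <- list(model = model, trajectory = traj, schedule = schedule)
  if (kind == "ligand") out$subsite_map <- subsite_map
  out
}

#' Random proper rotation matrix
#' @param n dimension (3 for coordinates).
#' @return orthogonal matrix with determinant +1.
#' @export
random_rotation <- function(n = 3) {
  qr_ <- qr(matrix(rnorm(n * n), n))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), n)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Inject rigid-body motion into a trajectory
#'
#' Rotates each frame by an independent random proper rotation and adds a
#' random translation.  Internal geometry is untouched (all interatomic
#' distances preserved to machine precision), so fluctuation and
#' collective-motion analyses must be invariant once frames are
#' superposed.
#'
#' @param traj an [md_trajectory()].
#' @param seed integer seed.
#' @param max_translation translations drawn uniformly in
#'   `[-max_translation, max_translation]` per axis (Angstrom).
#' @return a new [md_trajectory()].
#' @export
apply_rigid_motion <- function(traj, seed = 1, max_translation = 20) {
  nf <- n_frames(traj)
  na <- ncol(traj$xyz) / 3
  xyz <- with_seed(seed, {
    out <- traj$xyz
    for (f in seq_len(nf)) {
      R <- random_rotation(3)
      tr <- runif(3, -max_translation, max_translation)
      m <- matrix(out[f, ], ncol = 3, byrow = TRUE)
      out[f, ] <- .flatten_coords(sweep(m %*% t(R), 2, tr, "+"))
    }
    out
  })
  md_trajectory(xyz, traj$topology, frame_interval = traj$frame_interval,
                metadata = c(traj$metadata, list(rigid_motion_seed = seed)))
}
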