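# Superposition, RMSD series, RMSF / B-factor profiles and
# alignment-based profile matching.
#
# The per-atom fluctuation is the root of the time-averaged squared
# deviation from the mean position,
#   RMSF_i = sqrt( (1/n) * sum_t || r_i(t) - <r_i> ||^2 ),
# and the temperature factor follows as B_i = (8/3) * pi^2 * RMSF_i^2
# (Angstrom^2).  Frames are least-squares fitted (proper rotations only)
# onto the trajectory average before fluctuations are measured.

#' Optimal rigid-body superposition of two coordinate sets
#'
#' Kabsch algorithm: the least-squares rotation (determinant +1, never a
#' reflection) and translation mapping `mobile` onto `fixed`.
#'
#' @param mobile,fixed `n x 3` coordinate matrices over the same atoms.
#' @return list with `rotation` (3 x 3), `translation` (length 3); the
#'   fitted coordinates are `mobile %*% rotation + translation` (row-wise).
#' @export
kabsch_fit <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3)
  if (nrow(mobile) < 3)
    stop("superposition needs at least 3 atoms (got ", nrow(mobile), ")")
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  P <- sweep(mobile, 2, cm); Q <- sweep(fixed, 2, cf)
  sv <- svd(crossprod(P, Q))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) fit selection: superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # row-vector convention: fitted = P %*% R + cf
  list(rotation = R, translation = cf - as.vector(cm %*% R))
}

# per-frame rigid transforms fitting the atoms in sel_cols of xyz
# (frames x 3N) onto ref coords (N x 3).  The 3 x 3 cross-covariances of
# all frames are assembled with three matrix products; rotations come
# from the vectorized solver.  Returns list(Rot, t1, t2, t3) with Rot an
# nf x 9 matrix holding each frame's rotation column-major.
.fit_transforms <- function(xyz, ref_sel, sel_cols) {
  ix <- sel_cols[seq(1, length(sel_cols), 3)]
  Sx <- xyz[, ix, drop = FALSE]
  Sy <- xyz[, ix + 1L, drop = FALSE]
  Sz <- xyz[, ix + 2L, drop = FALSE]
  if (ncol(Sx) < 3)
    stop("superposition needs at least 3 atoms (got ", ncol(Sx), ")")
  mx <- rowMeans(Sx); my <- rowMeans(Sy); mz <- rowMeans(Sz)
  cf <- colMeans(ref_sel)
  Qc <- sweep(ref_sel, 2, cf)
  # A_f = P_f^T Q with P_f the centred mobile selection of frame f;
  # colSums(Qc) = 0 makes the mobile centring drop out
  Ax <- Sx %*% Qc; Ay <- Sy %*% Qc; Az <- Sz %*% Qc
  Rot <- .kabsch_rotations(Ax, Ay, Az)
  # fitted = P %*% R + (cf - m %*% R); Rot[, 3*(b-1)+a] = R[a, b]
  R_ <- function(a, b) Rot[, 3 * (b - 1) + a]
  list(Rot = Rot,
       t1 = cf[1] - (mx * R_(1, 1) + my * R_(2, 1) + mz * R_(3, 1)),
       t2 = cf[2] - (mx * R_(1, 2) + my * R_(2, 2) + mz * R_(3, 2)),
       t3 = cf[3] - (mx * R_(1, 3) + my * R_(2, 3) + mz * R_(3, 3)))
}

# apply per-frame rigid transforms to all atoms of xyz (frames x 3N)
.apply_transforms <- function(xyz, tr) {
  R_ <- function(a, b) tr$Rot[, 3 * (b - 1) + a]
  jx <- seq(1, ncol(xyz), 3)
  X <- xyz[, jx, drop = FALSE]
  Y <- xyz[, jx + 1L, drop = FALSE]
  Z <- xyz[, jx + 2L, drop = FALSE]
  out <- xyz
  out[, jx] <- X * R_(1, 1) + Y * R_(2, 1) + Z * R_(3, 1) + tr$t1
  out[, jx + 1L] <- X * R_(1, 2) + Y * R_(2, 2) + Z * R_(3, 2) + tr$t2
  out[, jx + 2L] <- X * R_(1, 3) + Y * R_(2, 3) + Z * R_(3, 3) + tr$t3
  out
}

# column means of the fitted coordinates without materializing them:
# mean_fitted[i, b] = (1/nf) sum_f sum_a xyz[f, col_a(i)] R_f[a, b] + mean(t_b)
.fitted_colmeans <- function(xyz, tr) {
  nf <- nrow(xyz)
  R_ <- function(a, b) tr$Rot[, 3 * (b - 1) + a]
  jx <- seq(1, ncol(xyz), 3)
  X <- xyz[, jx, drop = FALSE]
  Y <- xyz[, jx + 1L, drop = FALSE]
  Z <- xyz[, jx + 2L, drop = FALSE]
  out <- numeric(ncol(xyz))
  for (b in 1:3)
    out[jx + b - 1L] <-
      (crossprod(X, R_(1, b)) + crossprod(Y, R_(2, b)) +
         crossprod(Z, R_(3, b))) / nf +
      mean(tr[[paste0("t", b)]])
  out
}

# fit every frame of xyz onto ref coords using the atoms in sel_cols and
# apply the transform to all atoms
.fit_frames <- function(xyz, ref_sel, sel_cols) {
  .apply_transforms(xyz, .fit_transforms(xyz, ref_sel, sel_cols))
}

.sel_cols <- function(sel) as.vector(t(outer(3 * (as.integer(sel) - 1),
                                             1:3, "+")))

# optimal proper rotations for every frame from the per-frame 3 x 3
# cross-covariances A_f (rows of Ax/Ay/Az are A_f's rows).  For frames
# with det(A) clearly positive the Kabsch rotation equals the polar
# factor of A, computed for all frames at once by the Newton iteration
# X <- (X + X^-T)/2 on elementwise vectors; the few frames with
# non-positive determinant (possible reflection) or no convergence fall
# back to an exact per-frame SVD.  Returns an nf x 9 matrix whose rows
# hold R column-major: Rot[f, 3*(b-1)+a] = R[a, b].
.kabsch_rotations <- function(Ax, Ay, Az) {
  nf <- nrow(Ax)
  a11 <- Ax[, 1]; a12 <- Ax[, 2]; a13 <- Ax[, 3]
  a21 <- Ay[, 1]; a22 <- Ay[, 2]; a23 <- Ay[, 3]
  a31 <- Az[, 1]; a32 <- Az[, 2]; a33 <- Az[, 3]
  detA <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  nrm <- sqrt(a11^2 + a12^2 + a13^2 + a21^2 + a22^2 + a23^2 +
                a31^2 + a32^2 + a33^2)
  ok <- which(is.finite(detA) & detA > 0)
  Rot <- matrix(NA_real_, nf, 9)
  if (length(ok)) {
    s <- nrm[ok]
    x11 <- a11[ok] / s; x12 <- a12[ok] / s; x13 <- a13[ok] / s
    x21 <- a21[ok] / s; x22 <- a22[ok] / s; x23 <- a23[ok] / s
    x31 <- a31[ok] / s; x32 <- a32[ok] / s; x33 <- a33[ok] / s
    for (it in 1:40) {
      dX <- x11 * (x22 * x33 - x23 * x32) -
        x12 * (x21 * x33 - x23 * x31) +
        x13 * (x21 * x32 - x22 * x31)
      # scaled Newton (Higham): X <- (mu X + (mu X)^-T)/2 with
      # mu = |det X|^(-1/3); (mu X)^-T = cof(X) / (mu det(X))
      mu <- abs(dX)^(-1 / 3)
      md <- mu * dX
      n11 <- (mu * x11 + (x22 * x33 - x23 * x32) / md) / 2
      n12 <- (mu * x12 + (x23 * x31 - x21 * x33) / md) / 2
      n13 <- (mu * x13 + (x21 * x32 - x22 * x31) / md) / 2
      n21 <- (mu * x21 + (x13 * x32 - x12 * x33) / md) / 2
      n22 <- (mu * x22 + (x11 * x33 - x13 * x31) / md) / 2
      n23 <- (mu * x23 + (x12 * x31 - x11 * x32) / md) / 2
      n31 <- (mu * x31 + (x12 * x23 - x13 * x22) / md) / 2
      n32 <- (mu * x32 + (x13 * x21 - x11 * x23) / md) / 2
      n33 <- (mu * x33 + (x11 * x22 - x12 * x21) / md) / 2
      delta <- suppressWarnings(
        max(abs(n11 - x11), abs(n12 - x12), abs(n13 - x13),
            abs(n21 - x21), abs(n22 - x22), abs(n23 - x23),
            abs(n31 - x31), abs(n32 - x32), abs(n33 - x33), na.rm = TRUE))
      x11 <- n11; x12 <- n12; x13 <- n13
      x21 <- n21; x22 <- n22; x23 <- n23
      x31 <- n31; x32 <- n32; x33 <- n33
      if (is.finite(delta) && delta < 1e-13) break
    }
    # accept only frames whose result is an orthogonal proper rotation;
    # the rest (near-singular cross-covariances) get the exact SVD
    r11 <- x11^2 + x12^2 + x13^2 - 1
    r22 <- x21^2 + x22^2 + x23^2 - 1
    r33 <- x31^2 + x32^2 + x33^2 - 1
    r12 <- x11 * x21 + x12 * x22 + x13 * x23
    r13 <- x11 * x31 + x12 * x32 + x13 * x33
    r23 <- x21 * x31 + x22 * x32 + x23 * x33
    resid <- pmax(abs(r11), abs(r22), abs(r33),
                  abs(r12), abs(r13), abs(r23))
    good <- is.finite(resid) & resid < 1e-9
    keep <- ok[good]
    Rot[keep, 1] <- x11[good]; Rot[keep, 2] <- x21[good]
    Rot[keep, 3] <- x31[good]
    Rot[keep, 4] <- x12[good]; Rot[keep, 5] <- x22[good]
    Rot[keep, 6] <- x32[good]
    Rot[keep, 7] <- x13[good]; Rot[keep, 8] <- x23[good]
    Rot[keep, 9] <- x33[good]
  }
  for (f in which(is.na(Rot[, 1]))) {
    A <- rbind(Ax[f, ], Ay[f, ], Az[f, ])
    sv <- svd(A)
    if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
      stop("degenerate (collinear) fit selection: superposition undefined")
    d <- sign(det(sv$v %*% t(sv$u)))
    Rot[f, ] <- t(sv$v %*% diag(c(1, 1, d)) %*% t(sv$u))  # R, column-major
  }
  Rot
}

#' Superpose a trajectory onto a reference
#'
#' Each frame is transformed by the optimal proper rotation and
#' translation computed on `fit_selection` and applied to all atoms,
#' removing global translation and rotation.  With
#' `reference = "average"` the frames are first fitted onto frame 1 (to
#' bring arbitrarily rotated frames into a common orientation), then
#' fitted onto the running average repeatedly until the average
#' stabilizes below `tol` (at most 20 passes).
#'
#' @param traj an [md_trajectory()].
#' @param reference `"average"`, `"first"`, or an `n_atoms x 3` matrix.
#' @param fit_selection `atom_selection` used to compute the fit (at
#'   least 3 non-collinear atoms); defaults to protein backbone.
#' @param tol drift tolerance (Angstrom) for the fit-to-mean iteration.
#' @return a fitted [md_trajectory()]; `metadata$reference_label` records
#'   which reference was used.
#' @export
superpose <- function(traj, reference = "average", fit_selection = NULL,
                      tol = 1e-6) {
  if (is.null(fit_selection))
    fit_selection <- select_atoms(traj$topology, "backbone")
  sel <- as.integer(fit_selection)
  if (length(sel) < 3)
    stop("fit selection must contain at least 3 atoms")
  cols <- .sel_cols(sel)
  lab <- "matrix"
  if (is.character(reference)) {
    lab <- reference
    if (reference == "first") {
      ref <- matrix(traj$xyz[1, cols], ncol = 3, byrow = TRUE)
      xyz <- .fit_frames(traj$xyz, ref, cols)
    } else if (reference == "average") {
      ref0 <- matrix(traj$xyz[1, cols], ncol = 3, byrow = TRUE)
      xyz <- .fit_frames(traj$xyz, ref0, cols)
      for (it in 1:20) {
        avg <- matrix(colMeans(xyz)[cols], ncol = 3, byrow = TRUE)
        xyz2 <- .fit_frames(xyz, avg, cols)
        drift <- max(abs(colMeans(xyz2) - colMeans(xyz)))
        xyz <- xyz2
        if (drift <= tol) break
      }
    } else stop("unknown reference label '", reference, "'")
  } else {
    ref <- as.matrix(reference)
    if (nrow(ref) == n_atoms(traj$topology))
      ref <- ref[sel, , drop = FALSE]
    xyz <- .fit_frames(traj$xyz, ref, cols)
  }
  md_trajectory(xyz, traj$topology, frame_interval = traj$frame_interval,
                metadata = c(traj$metadata,
                             list(superposed = TRUE, reference_label = lab,
                                  fit_label = attr(fit_selection, "label"))))
}

#' Per-frame RMSD series
#'
#' Root-mean-square deviation of the selected atoms from a reference, per
#' frame, optionally after superposition on a fit selection.  With a
#' region map, one series per region is returned: the fit stays global,
#' only the measurement is restricted to the region's atoms.
#'
#' @param traj an [md_trajectory()].
#' @param reference `"first"` (starting structure), `"average"`, or an
#'   `n_atoms x 3` coordinate matrix.
#' @param selection `atom_selection` measured (default backbone).
#' @param regions optional [region_map()].
#' @param enzyme_label enzyme name in `regions`.
#' @param fit superpose before measuring (default TRUE); the fit uses
#'   `selection`.
#' @return data frame of class `rmsd_series` with columns `frame`,
#'   `region` (`"all"` for the global series) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, reference = "first", selection = NULL,
                        regions = NULL, enzyme_label = NULL, fit = TRUE) {
  if (is.null(selection)) selection <- select_atoms(traj$topology, "backbone")
  if (length(selection) == 0) stop("empty measurement selection")
  ref_coords <- if (is.character(reference)) {
    if (reference == "first") frame_coords(traj, 1)
    else if (reference == "average")
      matrix(colMeans(traj$xyz), ncol = 3, byrow = TRUE)
    else stop("unknown reference label '", reference, "'")
  } else as.matrix(reference)
  ftraj <- if (fit)
    superpose(traj, reference = ref_coords, fit_selection = selection)
  else traj
  measure <- function(sel, name) {
    if (length(sel) == 0) stop("region '", name, "' selects no atoms")
    cols <- .sel_cols(sel)
    refv <- .flatten_coords(ref_coords[as.integer(sel), , drop = FALSE])
    dev <- sweep(ftraj$xyz[, cols, drop = FALSE], 2, refv)
    data.frame(frame = seq_len(nrow(dev)), region = name,
               rmsd = sqrt(rowSums(dev^2) / length(sel)))
  }
  out <- measure(selection, "all")
  if (!is.null(regions)) {
    if (is.null(enzyme_label)) enzyme_label <- unique(regions$enzyme)[1]
    for (rg in unique(regions$region[regions$enzyme == enzyme_label])) {
      sel_rg <- region_atoms(regions, traj$topology, enzyme_label, rg,
                             selection = selection)
      out <- rbind(out, measure(sel_rg, rg))
    }
  }
  attr(out, "reference_label") <-
    if (is.character(reference)) reference else "matrix"
  attr(out, "selection_label") <- attr(selection, "label")
  class(out) <- c("rmsd_series", "data.frame")
  out
}

#' Per-residue RMSF and B-factor profile
#'
#' Expects a trajectory already superposed onto its average structure;
#' the operation recomputes the average and, if the frames still drift,
#' refits once.  Per-atom mean-square fluctuations about the average
#' position are aggregated per residue over the selection's atoms,
#' mass-weighted by default:
#' `RMSF_res = sqrt( sum_i m_i msf_i / sum_i m_i )`, and
#' `B = (8/3) pi^2 RMSF^2`.  Residues missing any backbone atom of the
#' selection are flagged, excluded, and reported via a warning.
#'
#' @param traj an [md_trajectory()], ideally from [superpose()].
#' @param selection `atom_selection`; default protein backbone (N, CA, C).
#' @param mass_weighted mass-weight the per-residue aggregation
#'   (near-equal backbone masses make this nearly indistinguishable from
#'   an unweighted mean; kept as a switch).
#' @param drift_tol tolerance (Angstrom) above which the trajectory is
#'   refitted once onto its average.
#' @return data frame of class `fluctuation_profile` with columns
#'   `chain`, `resno`, `resid`, `rmsf` (Angstrom), `bfactor`
#'   (Angstrom^2); per-atom values in `attr(, "per_atom")`.
#' @export
rmsf_profile <- function(traj, selection = NULL, mass_weighted = TRUE,
                         drift_tol = 1e-4) {
  model <- traj$topology
  if (is.null(selection)) selection <- select_atoms(model, "backbone")
  sel <- as.integer(selection)
  cols <- .sel_cols(sel)
  # drift check: a trajectory fitted on its average has (near-)stationary
  # mean; if not, refit once.  The fitted means are computed without
  # materializing the fitted coordinates, so an already-fitted (or
  # never-rotated) trajectory skips the full transform.
  avg <- matrix(colMeans(traj$xyz)[cols], ncol = 3, byrow = TRUE)
  xyz_sel <- traj$xyz[, cols, drop = FALSE]
  tr <- .fit_transforms(xyz_sel, avg, seq_len(ncol(xyz_sel)))
  drift <- max(abs(.fitted_colmeans(xyz_sel, tr) - colMeans(xyz_sel)))
  if (drift > drift_tol) xyz_sel <- .apply_transforms(xyz_sel, tr)
  mean_sel <- colMeans(xyz_sel)
  dev <- sweep(xyz_sel, 2, mean_sel)
  msf_coord <- colMeans(dev^2)                       # per coordinate
  msf <- msf_coord[seq(1, length(msf_coord), 3)] +
    msf_coord[seq(2, length(msf_coord), 3)] +
    msf_coord[seq(3, length(msf_coord), 3)]          # per atom, A^2
  a <- model$atoms[sel, , drop = FALSE]
  per_atom <- data.frame(atom = sel, chain = a$chain, resno = a$resno,
                         resid = a$resid, elety = a$elety, mass = a$mass,
                         msf = as.numeric(msf))
  res <- residues(model, "protein")
  expected <- if (attr(selection, "label") %in% c("backbone")) 3L else NA
  out <- res
  out$rmsf <- NA_real_
  flagged <- character(0)
  for (i in seq_len(nrow(res))) {
    rows <- per_atom$chain == res$chain[i] & per_atom$resno == res$resno[i]
    k <- sum(rows)
    if (k == 0 || (!is.na(expected) && k < expected)) {
      if (k > 0) flagged <- c(flagged,
                              paste0(res$chain[i], ":", res$resno[i]))
      next
    }
    w <- if (mass_weighted) per_atom$mass[rows] else rep(1, k)
    out$rmsf[i] <- sqrt(sum(w * per_atom$msf[rows]) / sum(w))
  }
  if (length(flagged))
    warning("residues missing backbone atoms excluded from profile: ",
            paste(flagged, collapse = ", "))
  out <- out[!is.na(out$rmsf), , drop = FALSE]
  out$bfactor <- (8 / 3) * pi^2 * out$rmsf^2
  rownames(out) <- NULL
  attr(out, "per_atom") <- per_atom
  attr(out, "selection_label") <- attr(selection, "label")
  attr(out, "mass_weighted") <- mass_weighted
  class(out) <- c("fluctuation_profile", "data.frame")
  out
}

#' Recompute B-factors from a fluctuation profile
#'
#' `B = (8/3) * pi^2 * RMSF^2`, element-wise.
#'
#' @param profile a [rmsf_profile()] result.
#' @return the profile with its `bfactor` column recomputed.
#' @export
bfactor_profile <- function(profile) {
  stopifnot(inherits(profile, "fluctuation_profile"))
  profile$bfactor <- (8 / 3) * pi^2 * profile$rmsf^2
  profile
}

#' Match two per-residue profiles through a sequence alignment
#'
#' Maps each profile onto the alignment columns of an [read_alignment()]
#' pair; gap columns carry `NA` on the gapped side (rendered as curve
#' gaps when plotted).
#'
#' @param profile_a,profile_b [rmsf_profile()] results for the two
#'   enzymes, in residue order.
#' @param aln an `aligned_pair`.
#' @param value profile column to match (default `"bfactor"`).
#' @return data frame of class `matched_profile` with columns `column`,
#'   `res_a`, `res_b`, `value_a`, `value_b`.
#' @export
match_profiles <- function(profile_a, profile_b, aln, value = "bfactor") {
  stopifnot(inherits(aln, "aligned_pair"))
  la <- sum(!is.na(aln$column_map$res_a))
  lb <- sum(!is.na(aln$column_map$res_b))
  if (nrow(profile_a) != la)
    stop("profile A has ", nrow(profile_a), " residues but alignment has ",
         la, " ungapped positions")
  if (nrow(profile_b) != lb)
    stop("profile B has ", nrow(profile_b), " residues but alignment has ",
         lb, " ungapped positions")
  cm <- aln$column_map
  out <- data.frame(column = cm$column, res_a = cm$res_a, res_b = cm$res_b,
                    value_a = ifelse(is.na(cm$res_a), NA,
                                     profile_a[[value]][cm$res_a]),
                    value_b = ifelse(is.na(cm$res_b), NA,
                                     profile_b[[value]][cm$res_b]))
  class(out) <- c("matched_profile", "data.frame")
  out
}
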