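# Salt-bridge occupancy, ligand-contact occurrence tables and
# block-average standard errors.

#' Salt-bridge occupancy along a trajectory
#'
#' A salt bridge between an acidic and a basic residue is formed in a
#' frame when the minimum distance between the acidic side-chain
#' carboxylate oxygens (Asp OD1/OD2, Glu OE1/OE2) and the basic
#' side-chain nitrogens (Lys NZ, Arg NE/NH1/NH2; His optional) does not
#' exceed `cutoff` (inclusive).  Occupancy is the percentage of sampled
#' frames in which the pair is formed; pairs never formed are omitted.
#' A block-average standard error (percent) accompanies each pair.
#'
#' @param traj an [md_trajectory()].
#' @param frames frame indices to sample (default: all).
#' @param cutoff O-N distance bound (Angstrom, inclusive).
#' @param include_his treat His side-chain N as basic.
#' @return data frame of class `salt_bridge_table` with columns
#'   `acidic`, `basic` (residue labels `RES chain:resno`), `occupancy`
#'   (%), `se` (%), `n_frames`.
#' @export
salt_bridge_occupancy <- function(traj, frames = NULL, cutoff = 4.0,
                                  include_his = FALSE) {
  model <- traj$topology
  a <- model$atoms
  ac <- select_atoms(model, "acidic-O", allow_empty = TRUE)
  ba <- select_atoms(model, "basic-N", include_his = include_his,
                     allow_empty = TRUE)
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  res_lab <- function(i) paste0(a$resid[i], " ", a$chain[i], ":", a$resno[i])
  ac_res <- paste(a$chain[ac], a$resno[ac])
  ba_res <- paste(a$chain[ba], a$resno[ba])
  ac_groups <- split(seq_along(ac), ac_res)
  ba_groups <- split(seq_along(ba), ba_res)
  if (!length(ac) || !length(ba)) {
    out <- data.frame(acidic = character(0), basic = character(0),
                      occupancy = numeric(0), se = numeric(0),
                      n_frames = integer(0))
    class(out) <- c("salt_bridge_table", "data.frame")
    return(out)
  }
  npair <- length(ac_groups) * length(ba_groups)
  on <- matrix(FALSE, length(frames), npair)
  c2 <- cutoff^2
  for (fi in seq_along(frames)) {
    co <- frame_coords(traj, frames[fi])
    axyz <- co[as.integer(ac), , drop = FALSE]
    bxyz <- co[as.integer(ba), , drop = FALSE]
    # squared distances acidic-O x basic-N
    d2 <- outer(rowSums(axyz^2), rowSums(bxyz^2), "+") -
      2 * axyz %*% t(bxyz)
    k <- 0
    for (ga in ac_groups) for (gb in ba_groups) {
      k <- k + 1
      on[fi, k] <- min(d2[ga, gb]) <= c2 + 1e-12
    }
  }
  labels_a <- character(npair); labels_b <- character(npair)
  k <- 0
  for (ga in ac_groups) for (gb in ba_groups) {
    k <- k + 1
    labels_a[k] <- res_lab(ac[ga[1]])
    labels_b[k] <- res_lab(ba[gb[1]])
  }
  occ <- colMeans(on) * 100
  keep <- which(occ > 0)
  se <- vapply(keep, function(k)
    tryCatch(block_average_se(as.numeric(on[, k])) * 100,
             error = function(e) NA_real_), numeric(1))
  out <- data.frame(acidic = labels_a[keep], basic = labels_b[keep],
                    occupancy = occ[keep], se = se,
                    n_frames = rep(length(frames), length(keep)))
  out <- out[order(out$acidic, out$basic), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("salt_bridge_table", "data.frame")
  out
}

#' Enzyme-substrate hydrogen-bond occurrence table
#'
#' Percentage of sampled frames in which each protein residue forms at
#' least one hydrogen bond (either donor or acceptor direction) with a
#' ligand residue of a given subsite.  Rows below the reporting threshold
#' are suppressed unless `all_rows = TRUE`.
#'
#' @param traj an [md_trajectory()] of an enzyme-ligand complex.
#' @param subsite_map named character vector mapping ligand residue
#'   numbers (as character) to subsite labels (e.g. `"-3"` ... `"+3"`);
#'   every ligand residue must be mapped.
#' @param frames frame indices to sample; use [snapshot_frames()] with a
#'   `window` to restrict to the first part of a trajectory.
#' @param threshold reporting threshold (%).
#' @param all_rows keep sub-threshold rows.
#' @param distance_cutoff,angle_cutoff geometric criteria as in
#'   [detect_hbonds()].
#' @return data frame of class `occurrence_table` with columns `residue`,
#'   `subsite`, `occurrence` (%), ordered by subsite then residue.
#' @export
ligand_hb_occurrence <- function(traj, subsite_map, frames = NULL,
                                 threshold = 10, all_rows = FALSE,
                                 distance_cutoff = 3.0,
                                 angle_cutoff = 135.0) {
  model <- traj$topology
  a <- model$atoms
  lig <- which(a$is_ligand)
  if (!length(lig)) stop("no ligand present in the topology")
  lig_res <- unique(a$resno[lig])
  missing <- setdiff(as.character(lig_res), names(subsite_map))
  if (length(missing))
    stop("ligand residues missing from the subsite map: ",
         paste(missing, collapse = ", "))
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  prot <- which(!a$is_het)
  dh <- donor_hydrogens(model)
  don_all <- intersect(dh$donor, which(a$element %in% c("N", "O")))
  donors <- .new_selection(sort(unique(intersect(don_all, c(prot, lig)))),
                           "protein+ligand donors")
  acceptors <- .new_selection(
    sort(intersect(which(a$element %in% c("N", "O")), c(prot, lig))),
    "protein+ligand acceptors")
  ev <- detect_hbonds(traj, donors = donors, acceptors = acceptors,
                      frames = frames, distance_cutoff = distance_cutoff,
                      angle_cutoff = angle_cutoff)
  cross_pl <- ev$donor %in% prot & ev$acceptor %in% lig
  cross_lp <- ev$donor %in% lig & ev$acceptor %in% prot
  ev <- ev[cross_pl | cross_lp, , drop = FALSE]
  if (nrow(ev)) {
    prot_atom <- ifelse(ev$donor %in% prot, ev$donor, ev$acceptor)
    lig_atom <- ifelse(ev$donor %in% lig, ev$donor, ev$acceptor)
    prot_res <- paste0(a$resid[prot_atom], a$resno[prot_atom])
    subsite <- unname(subsite_map[as.character(a$resno[lig_atom])])
    key <- paste(prot_res, subsite, sep = "|")
    per <- unique(data.frame(frame = ev$frame, key = key))
    counts <- table(per$key)
    occ <- as.numeric(counts) / length(frames) * 100
    parts <- strsplit(names(counts), "|", fixed = TRUE)
    out <- data.frame(residue = vapply(parts, `[`, "", 1),
                      subsite = vapply(parts, `[`, "", 2),
                      occurrence = occ)
  } else {
    out <- data.frame(residue = character(0), subsite = character(0),
                      occurrence = numeric(0))
  }
  if (!all_rows) out <- out[out$occurrence >= threshold, , drop = FALSE]
  out <- out[order(out$subsite, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- if (all_rows) 0 else threshold
  attr(out, "n_frames") <- length(frames)
  class(out) <- c("occurrence_table", "data.frame")
  out
}

#' Block-average standard error of a correlated series
#'
#' The series is split into contiguous equal blocks; for each block size
#' on a geometric ladder (powers of two with at least `min_blocks`
#' blocks) the standard error of the overall mean is estimated as the
#' standard deviation of block means divided by the square root of the
#' block count.  The reported value is the plateau: the first ladder
#' size whose estimate changes by less than 5% against the next size;
#' when no plateau is reached the largest-size estimate is returned and
#' flagged (`attr(, "plateau") = FALSE`).
#'
#' @param x numeric series (length at least `min_blocks`).
#' @param min_blocks minimum number of blocks per ladder step.
#' @return standard error (scalar) with attributes `block_size`,
#'   `plateau`, and the full `ladder` data frame.
#' @export
block_average_se <- function(x, min_blocks = 4) {
  n <- length(x)
  if (n < min_blocks)
    stop("series too short for block averaging: length ", n,
         " with at least ", min_blocks, " blocks required")
  sizes <- 2^(0:floor(log2(n / min_blocks)))
  ladder <- data.frame(size = sizes, n_blocks = NA_integer_, se = NA_real_)
  for (i in seq_along(sizes)) {
    s <- sizes[i]
    nb <- floor(n / s)
    means <- colMeans(matrix(x[seq_len(nb * s)], nrow = s))
    ladder$n_blocks[i] <- nb
    ladder$se[i] <- sd(means) / sqrt(nb)
  }
  plateau <- FALSE
  pick <- nrow(ladder)
  for (i in seq_len(nrow(ladder) - 1)) {
    a <- ladder$se[i]; b <- ladder$se[i + 1]
    if ((a == 0 && b == 0) || (a > 0 && abs(b - a) / a < 0.05)) {
      pick <- i; plateau <- TRUE; break
    }
  }
  out <- ladder$se[pick]
  attr(out, "block_size") <- ladder$size[pick]
  attr(out, "plateau") <- plateau
  attr(out, "ladder") <- ladder
  out
}
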