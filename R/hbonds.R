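# Geometric hydrogen-bond detection and trajectory statistics.
#
# A hydrogen bond is recorded when the donor-heavy-atom to acceptor
# distance D-A is below 3.0 Angstrom and the angle at the hydrogen
# (D-H-A, vertex at H) exceeds 135 degrees; both bounds strict.  Pairs
# within one residue are never counted.

#' Regularly spaced snapshot indices
#'
#' @param nf number of frames available.
#' @param n_snapshots snapshots wanted (default 1000, clamped to `nf`).
#' @param window optional upper frame bound (e.g. the first part of a
#'   trajectory); snapshots are drawn from `1..window`.
#' @return integer frame indices.
#' @export
snapshot_frames <- function(nf, n_snapshots = 1000, window = NULL) {
  if (!is.null(window)) nf <- min(nf, window)
  n <- min(n_snapshots, nf)
  unique(round(seq(1, nf, length.out = n)))
}

#' Detect hydrogen bonds along a trajectory
#'
#' Emits every (donor, hydrogen, acceptor) triple meeting the geometric
#' criterion per sampled frame, in deterministic (frame, donor, acceptor)
#' order.  Donor-hydrogen bonding is inferred once from the reference
#' structure (see [donor_hydrogens()]); a donor selection containing
#' heavy atoms with no bonded hydrogen is an error naming those atoms,
#' as is a topology carrying no hydrogens at all.
#'
#' @param traj an [md_trajectory()].
#' @param donors `atom_selection` of donor heavy atoms (default: N/O with
#'   a bonded hydrogen, non-solvent).
#' @param acceptors `atom_selection` of acceptor heavy atoms (default:
#'   all non-solvent N/O).
#' @param frames integer frame indices to scan (default: all).
#' @param distance_cutoff D-A distance bound (Angstrom, strict `<`).
#' @param angle_cutoff D-H-A angle bound (degrees, strict `>`).
#' @return data frame of class `hbond_events` with columns `frame`,
#'   `donor`, `hydrogen`, `acceptor`, `distance`, `angle`;
#'   `attr(, "frames")` records the sampled frames.
#' @export
detect_hbonds <- function(traj, donors = NULL, acceptors = NULL,
                          frames = NULL, distance_cutoff = 3.0,
                          angle_cutoff = 135.0) {
  model <- traj$topology
  a <- model$atoms
  if (!any(a$element == "H"))
    stop("topology contains no hydrogens; hydrogen-bond analysis needs a ",
         "protonated structure")
  if (is.null(donors)) donors <- select_atoms(model, "donors")
  if (is.null(acceptors)) acceptors <- select_atoms(model, "acceptors")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  dh <- donor_hydrogens(model)
  don <- as.integer(donors)
  no_h <- setdiff(don, dh$donor)
  if (length(no_h))
    stop("donor atoms without a bonded hydrogen: ",
         paste(paste0(a$chain[no_h], ":", a$resno[no_h], ":",
                      a$elety[no_h]), collapse = ", "))
  acc <- as.integer(acceptors)
  dh <- dh[dh$donor %in% don, , drop = FALSE]
  dh <- dh[order(dh$donor, dh$hydrogen), , drop = FALSE]
  res_key <- paste(a$chain, a$resno)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    co <- frame_coords(traj, f)
    dxyz <- co[dh$donor, , drop = FALSE]
    hxyz <- co[dh$hydrogen, , drop = FALSE]
    # D-A distances for all (donor-H entry) x acceptor pairs
    rows <- list()
    d2cut <- distance_cutoff^2
    for (k in seq_len(nrow(dh))) {
      dv <- sweep(co[acc, , drop = FALSE], 2, dxyz[k, ])
      d2 <- rowSums(dv^2)
      cand <- which(d2 < d2cut & acc != dh$donor[k] &
                      res_key[acc] != res_key[dh$donor[k]])
      if (!length(cand)) next
      hv <- hxyz[k, ]
      v1 <- dxyz[k, ] - hv
      v1 <- v1 / sqrt(sum(v1^2))
      av <- sweep(co[acc[cand], , drop = FALSE], 2, hv)
      avn <- sqrt(rowSums(av^2))
      cosang <- (av %*% v1) / avn
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      keep <- ang > angle_cutoff
      if (any(keep))
        rows[[length(rows) + 1]] <-
          data.frame(frame = f, donor = dh$donor[k],
                     hydrogen = dh$hydrogen[k],
                     acceptor = acc[cand][keep],
                     distance = sqrt(d2[cand][keep]),
                     angle = ang[keep])
    }
    if (length(rows)) out[[fi]] <- do.call(rbind, rows)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev))
    ev <- data.frame(frame = integer(0), donor = integer(0),
                     hydrogen = integer(0), acceptor = integer(0),
                     distance = numeric(0), angle = numeric(0))
  ev <- ev[order(ev$frame, ev$donor, ev$acceptor), , drop = FALSE]
  rownames(ev) <- NULL
  attr(ev, "frames") <- frames
  attr(ev, "distance_cutoff") <- distance_cutoff
  attr(ev, "angle_cutoff") <- angle_cutoff
  class(ev) <- c("hbond_events", "data.frame")
  ev
}

#' Static and dynamic hydrogen-bond statistics
#'
#' The static count is the total number of hydrogen bonds observed over
#' the sampled snapshots divided by the snapshot count and the sequence
#' length (bonds per residue per snapshot).  The dynamic count is the
#' number of distinct donor/acceptor pairs observed in at least one
#' snapshot, divided by the sequence length; a literal variant that also
#' divides by the snapshot count is available
#' (`per_snapshot_dynamic = TRUE`) but note that a >=1-occurrence count
#' does not scale with snapshots.  Pair identity is the donor heavy atom
#' and acceptor atom (the hydrogen is ignored, so rotating -NH3+ protons
#' are not multiply counted).  A block-average standard error of the
#' static count is attached.
#'
#' @param events a [detect_hbonds()] result.
#' @param n_snapshots number of sampled snapshots (defaults to the frame
#'   count recorded on `events`).
#' @param sequence_length number of protein residues used for
#'   normalization.
#' @param per_snapshot_dynamic also divide the dynamic count by
#'   `n_snapshots`.
#' @return list of class `hb_stats`: `static_count`, `dynamic_count`,
#'   `static_se` (block method; `NA` when too few snapshots),
#'   `n_snapshots`, `sequence_length`, `normalization` metadata.
#' @export
hb_stats <- function(events, n_snapshots = NULL, sequence_length,
                     per_snapshot_dynamic = FALSE) {
  stopifnot(sequence_length >= 1)
  frames <- attr(events, "frames")
  if (is.null(n_snapshots))
    n_snapshots <- if (!is.null(frames)) length(frames) else
      max(events$frame, 1)
  stopifnot(n_snapshots >= 1)
  # hydrogen-agnostic pair identity
  ue <- unique(events[, c("frame", "donor", "acceptor")])
  static <- nrow(ue) / (n_snapshots * sequence_length)
  pairs <- unique(ue[, c("donor", "acceptor")])
  dynamic <- nrow(pairs) / sequence_length
  if (per_snapshot_dynamic) dynamic <- dynamic / n_snapshots
  se <- NA_real_
  if (!is.null(frames) && length(frames) >= 4) {
    per_frame <- tabulate(match(ue$frame, frames), nbins = length(frames)) /
      sequence_length
    se <- tryCatch(block_average_se(per_frame), error = function(e) NA_real_)
  }
  structure(list(static_count = static, dynamic_count = dynamic,
                 static_se = as.numeric(se), n_snapshots = n_snapshots,
                 sequence_length = sequence_length,
                 normalization = list(
                   static = "events / (snapshots * residues)",
                   dynamic = if (per_snapshot_dynamic)
                     "distinct pairs / (snapshots * residues)"
                   else "distinct pairs / residues",
                   pair_identity = "donor heavy atom + acceptor atom")),
            class = "hb_stats")
}

#' @export
print.hb_stats <- function(x, ...) {
  cat(sprintf("hb_stats: static %.4f (SE %.4f), dynamic %.4f over %d snapshots, %d residues\n",
              x$static_count, x$static_se, x$dynamic_count, x$n_snapshots,
              x$sequence_length))
  invisible(x)
}

#' Mean protein-solvent hydrogen-bond count per snapshot
#'
#' Counts hydrogen bonds with the donor on the protein and acceptor on
#' the solvent or vice versa, averaged over the sampled frames.
#'
#' @param traj an [md_trajectory()].
#' @param frames frame indices to sample (default: all).
#' @param distance_cutoff,angle_cutoff geometric criteria as in
#'   [detect_hbonds()].
#' @return mean count per snapshot, with the per-frame series in
#'   `attr(, "per_frame")`.
#' @export
solvent_hb_count <- function(traj, frames = NULL, distance_cutoff = 3.0,
                             angle_cutoff = 135.0) {
  model <- traj$topology
  a <- model$atoms
  if (!any(a$is_solvent)) stop("no solvent present in the topology")
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  dh <- donor_hydrogens(model)
  prot <- which(!a$is_het)
  solv <- which(a$is_solvent)
  don_all <- intersect(dh$donor, which(a$element %in% c("N", "O")))
  donors <- .new_selection(sort(unique(c(intersect(don_all, prot),
                                         intersect(don_all, solv)))),
                           "protein+solvent donors")
  acceptors <- .new_selection(
    sort(c(intersect(which(a$element %in% c("N", "O")), prot),
           intersect(which(a$element %in% c("N", "O")), solv))),
    "protein+solvent acceptors")
  ev <- detect_hbonds(traj, donors = donors, acceptors = acceptors,
                      frames = frames, distance_cutoff = distance_cutoff,
                      angle_cutoff = angle_cutoff)
  cross <- (ev$donor %in% prot & ev$acceptor %in% solv) |
    (ev$donor %in% solv & ev$acceptor %in% prot)
  ue <- unique(ev[cross, c("frame", "donor", "acceptor")])
  per_frame <- tabulate(match(ue$frame, frames), nbins = length(frames))
  out <- mean(per_frame)
  attr(out, "per_frame") <- per_frame
  out
}
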