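# Shrake-Rupley solvent-accessible surface area.
#
# Each atom is inflated by the probe radius and covered with a
# deterministic quasi-uniform point set (Fibonacci sphere); the exposed
# fraction of points, times the inflated sphere area 4*pi*(r+probe)^2,
# is the atom's accessible area.

# Deterministic molecule-fixed frame from the principal axes of the
# solute, signs fixed by the first non-zero odd moment along each axis.
# Expressing the quadrature directions in this frame makes the computed
# area covariant: rigidly moving the solute rotates the point set with
# it, so the occlusion pattern (and hence the area) is unchanged.
.principal_frame <- function(co) {
  if (nrow(co) < 3) return(diag(3))
  cc <- sweep(co, 2, colMeans(co))
  V <- eigen(crossprod(cc), symmetric = TRUE)$vectors
  for (k in 1:3) {
    proj <- cc %*% V[, k]
    s <- sum(proj^3)
    if (abs(s) < 1e-8 * max(abs(proj))^3) s <- sum(proj^5)
    if (s < 0) V[, k] <- -V[, k]
  }
  V
}

# n quasi-uniform points on the unit sphere (deterministic)
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  phi <- pi * (3 - sqrt(5)) * (k - 0.5)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param model a [structure_model()] providing radii and the solute
#'   definition.
#' @param xyz optional coordinates (`n_atoms x 3`); defaults to the
#'   model's reference coordinates.
#' @param selection `atom_selection` defining the solute; default all
#'   non-solvent atoms.  Solvent is never part of the solute.
#' @param probe_radius probe radius (Angstrom; 1.4 emulates water).
#' @param n_points sphere quadrature points per atom (error roughly
#'   `1/sqrt(n_points)`; 960 keeps it well below 1%).
#' @return list of class `sasa_result`: `total_area` (Angstrom^2),
#'   `per_atom_area`, `probe_radius`, `n_sphere_points`.
#' @export
sasa <- function(model, xyz = NULL, selection = NULL, probe_radius = 1.4,
                 n_points = 960) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  if (is.null(selection)) {
    idx <- which(!a$is_solvent)
  } else {
    idx <- setdiff(as.integer(selection), which(a$is_solvent))
  }
  if (!length(idx)) stop("empty solute selection")
  co <- if (is.null(xyz)) model$xyz else as.matrix(xyz)
  co <- co[idx, , drop = FALSE]
  radii <- a$vdw_radius[idx] + probe_radius
  pts <- .sphere_points(n_points) %*% t(.principal_frame(co))
  n <- length(idx)
  per_atom <- numeric(n)
  # neighbour lists from pairwise distances
  d2 <- outer(rowSums(co^2), rowSums(co^2), "+") - 2 * co %*% t(co)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (radii[i] + radii)^2 & seq_len(n) != i)
    p <- sweep(pts * radii[i], 2, co[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dv <- sweep(p, 2, co[j, ])
      exposed <- exposed & rowSums(dv^2) > radii[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- mean(exposed) * 4 * pi * radii[i]^2
  }
  structure(list(total_area = sum(per_atom), per_atom_area = per_atom,
                 atom_index = idx, probe_radius = probe_radius,
                 n_sphere_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: total %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total_area, length(x$per_atom_area), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' Mean SASA over a trajectory
#'
#' Per-frame Shrake-Rupley totals, their time mean and the block-average
#' standard error.
#'
#' @param traj an [md_trajectory()].
#' @param frames frame indices to sample (default: all).
#' @inheritParams sasa
#' @return list of class `sasa_series`: `mean_area`, `se` (block
#'   method; `NA` for very short series), `per_frame` totals.
#' @export
sasa_trajectory <- function(traj, frames = NULL, selection = NULL,
                            probe_radius = 1.4, n_points = 960) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  per_frame <- vapply(frames, function(f)
    sasa(traj$topology, xyz = frame_coords(traj, f), selection = selection,
         probe_radius = probe_radius, n_points = n_points)$total_area,
    numeric(1))
  se <- if (length(per_frame) >= 4) as.numeric(block_average_se(per_frame))
  else NA_real_
  structure(list(mean_area = mean(per_frame), se = se,
                 per_frame = per_frame, probe_radius = probe_radius,
                 n_sphere_points = n_points),
            class = "sasa_series")
}
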