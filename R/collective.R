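# Dynamic cross-correlation, essential-dynamics PCA and Boltzmann
# inversion free-energy landscapes.
#
# DCC between residues i and j is the normalized covariance of their
# C-alpha displacement vectors,
#   C_ij = ( <r_i . r_j> - <r_i> . <r_j> )
#          / sqrt( (<r_i^2> - <r_i>^2) (<r_j^2> - <r_j>^2) ),
# in [-1, 1] with +1 fully correlated and -1 fully anticorrelated.
# PCA diagonalizes the 3N x 3N coordinate covariance; the free-energy
# landscape over the first two principal components is
#   G_a = -kT ln( P(q_a) / P_max(q) ).

#' Boltzmann constant in kJ/(mol K)
#' @export
BOLTZMANN_KJ_MOL_K <- 0.0083145

#' Dynamic cross-correlation matrix
#'
#' @param traj an [md_trajectory()] superposed onto its average structure
#'   (see [superpose()]); at least two frames.
#' @param selection `atom_selection` of one atom per residue (default:
#'   C-alpha).
#' @return symmetric matrix of class `dcc_matrix` with residue labels;
#'   atoms with zero positional variance give `NA` rows/columns and a
#'   warning.
#' @export
dcc_matrix <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2) stop("DCC needs at least 2 frames")
  model <- traj$topology
  if (is.null(selection)) selection <- select_atoms(model, "calpha")
  sel <- as.integer(selection)
  cols <- .sel_cols(sel)
  X <- traj$xyz[, cols, drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  nf <- nrow(X)
  m <- length(sel)
  idx <- function(k) seq(k, 3 * m, by = 3)
  num <- (crossprod(X[, idx(1)]) + crossprod(X[, idx(2)]) +
            crossprod(X[, idx(3)])) / nf
  v <- diag(num)
  zero <- v < 1e-12
  denom <- sqrt(outer(v, v))
  C <- num / denom
  if (any(zero)) {
    warning(sum(zero), " atom(s) with zero positional variance masked ",
            "in the DCC matrix")
    C[zero, ] <- NA; C[, zero] <- NA
  }
  ok <- which(!zero)
  C[cbind(ok, ok)] <- 1
  a <- model$atoms[sel, ]
  labs <- paste0(a$chain, ":", a$resno)
  dimnames(C) <- list(labs, labs)
  class(C) <- c("dcc_matrix", "matrix", "array")
  C
}

#' Essential-dynamics principal component analysis
#'
#' Eigendecomposition of the 3N x 3N covariance of the selected atoms'
#' coordinates (frames assumed superposed onto their average; unweighted
#' coordinates).  Projections of each centred frame onto the retained
#' eigenvectors and the per-component contribution fractions
#' (eigenvalue / trace) are returned.
#'
#' @param traj an [md_trajectory()], superposed.
#' @param selection `atom_selection` (default C-alpha).
#' @param n_components components to retain (default: all; clamped to 3N
#'   with a warning when larger).
#' @param divisor `"n"` (population covariance, default) or `"n-1"`.
#' @return list of class `pca_result`: `eigenvalues` (Angstrom^2,
#'   descending, clamped at 0), `eigenvectors` (orthonormal columns),
#'   `projections` (frames x components), `contributions`, `center`,
#'   `trace`.
#' @export
pca_decompose <- function(traj, selection = NULL, n_components = NULL,
                          divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (n_frames(traj) < 2) stop("PCA needs at least 2 frames")
  model <- traj$topology
  if (is.null(selection)) selection <- select_atoms(model, "calpha")
  cols <- .sel_cols(as.integer(selection))
  X <- traj$xyz[, cols, drop = FALSE]
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  nf <- nrow(Xc)
  denom <- if (divisor == "n") nf else nf - 1
  C <- crossprod(Xc) / denom
  ndim <- ncol(C)
  if (is.null(n_components)) n_components <- ndim
  if (n_components > ndim) {
    warning("n_components clamped from ", n_components, " to ", ndim)
    n_components <- ndim
  }
  ei <- eigen(C, symmetric = TRUE)
  vals <- pmax(ei$values, 0)
  vecs <- ei$vectors[, seq_len(n_components), drop = FALSE]
  proj <- Xc %*% vecs
  structure(list(eigenvalues = vals, eigenvectors = vecs,
                 projections = proj,
                 contributions = if (sum(vals) > 0) vals / sum(vals)
                 else vals,
                 center = ctr, trace = sum(vals), divisor = divisor,
                 selection_label = attr(selection, "label")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat("pca_result:", ncol(x$projections), "components retained of",
      length(x$eigenvalues), "\n  leading contributions:",
      paste(sprintf("%.1f%%", 100 * x$contributions[1:k]), collapse = " "),
      "\n")
  invisible(x)
}

#' Free-energy landscape from principal-component projections
#'
#' Two-dimensional histogram over the observed projection ranges,
#' Boltzmann-inverted: `G = -kT ln(count / max_count)` (kJ/mol), so the
#' most populated bin sits at G = 0 and empty bins are masked (`NA`
#' sentinel, never a large finite number).  Local minima of the
#' populated grid (8-neighbourhood, strict inequality, ties broken by
#' lowest bin index) are listed with a representative frame: the frame
#' whose projection lies nearest the minimum's bin centre.
#'
#' @param pc1,pc2 projection vectors (equal length, finite).
#' @param temperature_K simulation temperature (K, positive).
#' @param n_bins bins per axis.
#' @return list of class `fel_grid`: `G` (n_bins x n_bins, kJ/mol,
#'   `NA`-masked), `counts`, `x_mids`, `y_mids`, `x_edges`, `y_edges`,
#'   `temperature`, `minima` (data frame `ix`, `iy`, `G`, `frame`).
#' @export
fel_from_projections <- function(pc1, pc2, temperature_K, n_bins = 50) {
  if (temperature_K <= 0) stop("temperature must be positive (Kelvin)")
  stopifnot(length(pc1) == length(pc2))
  if (!all(is.finite(pc1)) || !all(is.finite(pc2)))
    stop("projections must be finite")
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  xr <- pad(range(pc1)); yr <- pad(range(pc2))
  xe <- seq(xr[1], xr[2], length.out = n_bins + 1)
  ye <- seq(yr[1], yr[2], length.out = n_bins + 1)
  bx <- pmin(pmax(findInterval(pc1, xe, rightmost.closed = TRUE), 1), n_bins)
  by <- pmin(pmax(findInterval(pc2, ye, rightmost.closed = TRUE), 1), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(bx)) counts[bx[i], by[i]] <- counts[bx[i], by[i]] + 1L
  kT <- BOLTZMANN_KJ_MOL_K * temperature_K
  G <- matrix(NA_real_, n_bins, n_bins)
  pop <- counts > 0
  G[pop] <- -kT * log(counts[pop] / max(counts))
  xm <- (xe[-1] + xe[-length(xe)]) / 2
  ym <- (ye[-1] + ye[-length(ye)]) / 2
  # local minima on populated bins; unpopulated neighbours count as +Inf
  minima <- list()
  for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
    if (!pop[i, j]) next
    g <- G[i, j]
    is_min <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n_bins || jj < 1 || jj > n_bins) next
      if (pop[ii, jj] && G[ii, jj] <= g) { is_min <- FALSE; break }
    }
    if (is_min)
      minima[[length(minima) + 1]] <- data.frame(ix = i, iy = j, G = g)
  }
  minima <- if (length(minima)) do.call(rbind, minima)
  else data.frame(ix = integer(0), iy = integer(0), G = numeric(0))
  minima <- minima[order(minima$G, minima$ix, minima$iy), , drop = FALSE]
  minima$frame <- vapply(seq_len(nrow(minima)), function(k) {
    cx <- xm[minima$ix[k]]; cy <- ym[minima$iy[k]]
    which.min((pc1 - cx)^2 + (pc2 - cy)^2)
  }, integer(1))
  rownames(minima) <- NULL
  structure(list(G = G, counts = counts, x_mids = xm, y_mids = ym,
                 x_edges = xe, y_edges = ye, temperature = temperature_K,
                 k_boltzmann = BOLTZMANN_KJ_MOL_K, minima = minima),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  cat(sprintf("fel_grid: %d x %d bins at %g K; %d populated, %d minima (G range 0-%.2f kJ/mol)\n",
              nrow(x$G), ncol(x$G), x$temperature, sum(!is.na(x$G)),
              nrow(x$minima), max(x$G, na.rm = TRUE)))
  invisible(x)
}

#' Free-energy gap between the two deepest basins
#'
#' Convenience for two-state systems.  The second basin is the lowest
#' local minimum that is genuinely distinct from the global one: at
#' least `min_separation` bins away (Chebyshev distance) and with the
#' straight bin path from the global minimum crossing a ridge at least
#' `min_barrier` kJ/mol above the candidate (unpopulated bins count as
#' an infinite ridge), and holding at least a fraction `min_population`
#' of all frames in its steepest-descent basin.  The barrier requirement
#' rejects shallow sampling-noise dimples on the slope of the global
#' basin; the population requirement rejects isolated outlier bins in
#' the tails, which are "minima" separated by empty space but represent
#' only a handful of frames.
#'
#' Two estimators of the gap are offered.  `"population"` (default)
#' assigns every populated bin to a basin by steepest descent on the
#' grid and returns `kT ln(P_global / P_second)` over the integrated
#' basin populations; summing counts over whole basins makes its
#' sampling error far smaller than any single bin's.  `"minima"` is the
#' literal difference of the two minima's G values; it is noisier
#' because the extremes of Poisson-fluctuating bins are biased.
#'
#' @param fel a [fel_from_projections()] result.
#' @param min_separation Chebyshev bin distance below which minima are
#'   considered part of the same basin.
#' @param min_barrier required ridge height above the candidate minimum
#'   (kJ/mol); default one kT at the landscape's temperature.
#' @param min_population smallest fraction of all frames a candidate's
#'   steepest-descent basin may hold.
#' @param method `"population"` or `"minima"` (see above).
#' @return gap in kJ/mol, or `NA` when no second basin exists.
#' @export
fel_basin_gap <- function(fel, min_separation = 3, min_barrier = NULL,
                          min_population = 0.01,
                          method = c("population", "minima")) {
  method <- match.arg(method)
  m <- fel$minima
  if (nrow(m) < 2) return(NA_real_)
  if (is.null(min_barrier))
    min_barrier <- fel$k_boltzmann * fel$temperature
  g0 <- m[1, ]
  n <- nrow(fel$G)
  pop <- !is.na(fel$G)
  # max G along the straight bin path between two bins (NA -> Inf)
  path_barrier <- function(i1, j1, i2, j2) {
    ns <- max(abs(i2 - i1), abs(j2 - j1))
    t <- seq(0, 1, length.out = ns + 1)
    ii <- round(i1 + t * (i2 - i1)); jj <- round(j1 + t * (j2 - j1))
    g <- fel$G[cbind(ii, jj)]
    if (anyNA(g)) Inf else max(g)
  }
  # population method machinery: steepest-descent basin assignment
  descend <- function(i, j) {
    repeat {
      bi <- i; bj <- j; bg <- fel$G[i, j]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n || jj < 1 || jj > n) next
        if (pop[ii, jj] && fel$G[ii, jj] < bg) {
          bg <- fel$G[ii, jj]; bi <- ii; bj <- jj
        }
      }
      if (bi == i && bj == j) return(c(i, j))
      i <- bi; j <- bj
    }
  }
  # integrated basin populations for a given pair of centres; each
  # terminal local minimum maps to the centre reachable over the lower
  # ridge relative to itself, ties broken by the nearer centre (isolated
  # outlier bins with no populated path to either centre)
  basin_counts <- function(second) {
    centre_of <- new.env(parent = emptyenv())
    which_centre <- function(ti, tj) {
      key <- paste(ti, tj)
      hit <- centre_of[[key]]
      if (!is.null(hit)) return(hit)
      b0 <- path_barrier(ti, tj, g0$ix, g0$iy) - fel$G[ti, tj]
      b1 <- path_barrier(ti, tj, second$ix, second$iy) - fel$G[ti, tj]
      res <- if (b0 < b1) 1L else if (b1 < b0) 2L else {
        d0 <- (ti - g0$ix)^2 + (tj - g0$iy)^2
        d1 <- (ti - second$ix)^2 + (tj - second$iy)^2
        if (d0 <= d1) 1L else 2L
      }
      centre_of[[key]] <- res
      res
    }
    counts <- c(0, 0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!pop[i, j]) next
      term <- descend(i, j)
      b <- which_centre(term[1], term[2])
      counts[b] <- counts[b] + fel$counts[i, j]
    }
    counts
  }
  second <- NULL
  for (k in 2:nrow(m)) {
    if (max(abs(m$ix[k] - g0$ix), abs(m$iy[k] - g0$iy)) < min_separation)
      next
    bar <- path_barrier(g0$ix, g0$iy, m$ix[k], m$iy[k])
    if (bar - m$G[k] < min_barrier) next
    counts <- basin_counts(m[k, ])
    if (counts[2] / sum(counts) < min_population) next
    second <- m[k, ]
    break
  }
  if (is.null(second)) return(NA_real_)
  if (method == "minima") return(second$G - g0$G)
  kT <- fel$k_boltzmann * fel$temperature
  kT * log(counts[1] / counts[2])
}
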