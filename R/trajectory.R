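#' Construct a trajectory
#'
#' Frames-by-coordinates container bound to a topology.  Coordinates are
#' stored as an `n_frames x 3*n_atoms` matrix in x1,y1,z1,x2,... order
#' (the layout used throughout the structural-bioinformatics R ecosystem),
#' in Angstrom.
#'
#' @param xyz numeric matrix `n_frames x 3*n_atoms`, or an
#'   `n_frames x n_atoms x 3` array.
#' @param topology the [structure_model()] the frames refer to.
#' @param frame_interval optional time between saved frames (informational,
#'   any unit; the analyses are time-unit agnostic).
#' @param metadata optional list carried along (e.g. generator parameters).
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(xyz, topology, frame_interval = NULL,
                          metadata = list()) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.array(xyz) && length(dim(xyz)) == 3) {
    d <- dim(xyz)  # frames x atoms x 3
    flat <- matrix(0, d[1], 3 * d[2])
    for (k in 1:3) flat[, seq(k, 3 * d[2], by = 3)] <- xyz[, , k]
    xyz <- flat
  }
  xyz <- as.matrix(xyz)
  na <- n_atoms(topology)
  if (ncol(xyz) != 3 * na)
    stop("trajectory has ", ncol(xyz) / 3, " atoms per frame but topology ",
         "has ", na, " atoms (expected ", 3 * na, " coordinates, observed ",
         ncol(xyz), ")")
  if (nrow(xyz) < 1) stop("trajectory must contain at least one frame")
  # range() detects NA/NaN/Inf without allocating a logical copy
  if (!all(is.finite(range(xyz))))
    stop("non-finite trajectory coordinates")
  structure(list(xyz = xyz, topology = topology,
                 frame_interval = frame_interval, metadata = metadata),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", nrow(x$xyz), "frames x", ncol(x$xyz) / 3, "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Coordinates of one frame
#' @param traj an `md_trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

# n_atoms x 3 matrix -> flat 3N vector (x1,y1,z1,...)
.flatten_coords <- function(m) as.vector(t(m))

#' Read a coordinate trajectory
#'
#' Multi-model PDB or binary (CHARMM-style) DCD.  Frames are returned in
#' file order; the atom count of every frame must match the topology.
#'
#' @param path trajectory file; format chosen by extension (`.pdb` or
#'   `.dcd`) unless `format` is given.
#' @param topology the [structure_model()] the frames refer to.
#' @param format `"pdb"`, `"dcd"`, or `NULL` to infer from the extension.
#' @param frame_interval optional time between frames (informational).
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, topology, format = NULL,
                            frame_interval = NULL) {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  if (is.null(format))
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  xyz <- switch(format,
    pdb = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      unclass(pdb$xyz)
    },
    dcd = unclass(bio3d::read.dcd(path, verbose = FALSE)),
    stop("unknown trajectory format '", format, "'"))
  na <- n_atoms(topology)
  if (ncol(xyz) != 3 * na)
    stop("atom-count mismatch: topology has ", na,
         " atoms, trajectory frames have ", ncol(xyz) / 3)
  md_trajectory(xyz, topology, frame_interval = frame_interval)
}

#' Write a trajectory as a multi-model PDB
#'
#' One MODEL per frame, with the topology's atom names, residue numbers
#' and chains.  Coordinates are written at the PDB's printed precision
#' (1e-3 Angstrom), which bounds the round-trip error.
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  a <- traj$topology$atoms
  bio3d::write.pdb(file = path, xyz = traj$xyz, type = a$type,
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Write a structure as a single-model PDB
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @param xyz optional replacement coordinates (`n_atoms x 3`).
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path, xyz = NULL) {
  a <- model$atoms
  coords <- if (is.null(xyz)) model$xyz else xyz
  bio3d::write.pdb(file = path, xyz = .flatten_coords(coords), type = a$type,
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Write a trajectory as a CHARMM-format DCD file
#'
#' Minimal single-precision DCD writer (Fortran record markers, CORD
#' header, per-frame x/y/z blocks) compatible with standard DCD readers.
#'
#' @param traj an [md_trajectory()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nf <- n_frames(traj)
  na <- ncol(traj$xyz) / 3
  rec <- function(writer) {
    # Fortran unformatted record: length prefix + payload + length suffix
    tmp <- raw(0)
    tcon <- rawConnection(tmp, "wb")
    writer(tcon)
    payload <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf      # number of frames
  icntrl[2] <- 1L      # first step
  icntrl[3] <- 1L      # save interval
  icntrl[4] <- nf      # total steps
  icntrl[20] <- 24L    # CHARMM version flag
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(icntrl, c2, size = 4, endian = "little")
  })
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeChar(formatC("written by enzdyn", width = -80), c2, nchars = 80,
              eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(na), c2, size = 4, endian = "little"))
  xi <- seq(1, 3 * na, by = 3)
  for (f in seq_len(nf)) {
    fr <- traj$xyz[f, ]
    for (off in 0:2)
      rec(local({ o <- off; function(c2)
        writeBin(fr[xi + o], c2, size = 4, endian = "little") }))
  }
  invisible(path)
}
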