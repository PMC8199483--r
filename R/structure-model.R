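#' @importFrom stats sd setNames rnorm rbinom runif
#' @importFrom utils write.table read.table head
NULL

# Default per-element masses (amu) and van der Waals radii (Angstrom, Bondi).
# Radii feed directly into SASA; unknown elements are never guessed.
.element_defaults <- data.frame(
  element = c("H", "C", "N", "O", "S", "P", "F", "CL", "BR", "I", "NA", "K",
              "MG", "CA", "ZN", "FE"),
  mass = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 18.998, 35.45,
           79.904, 126.904, 22.990, 39.098, 24.305, 40.078, 65.38, 55.845),
  vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80, 1.47, 1.75, 1.85, 1.98,
                 2.27, 2.75, 1.73, 2.31, 1.39, 1.94),
  stringsAsFactors = FALSE
)

#' Element property table
#'
#' Masses (amu) and van der Waals radii (Angstrom) used when building a
#' [structure_model()].  User overrides extend or replace rows; elements
#' absent from the table are a hard error downstream, never guessed.
#'
#' @param overrides optional data frame with columns `element`, `mass`,
#'   `vdw_radius` that is merged over the defaults.
#' @return data frame with columns `element`, `mass`, `vdw_radius`.
#' @export
element_table <- function(overrides = NULL) {
  tab <- .element_defaults
  if (!is.null(overrides)) {
    stopifnot(is.data.frame(overrides),
              all(c("element", "mass", "vdw_radius") %in% names(overrides)))
    overrides$element <- toupper(overrides$element)
    tab <- tab[!tab$element %in% overrides$element, , drop = FALSE]
    tab <- rbind(tab, overrides[, c("element", "mass", "vdw_radius")])
  }
  tab
}

# PDB atom-name -> element symbol. Uses the elesy column when present,
# otherwise strips digits and leading digit prefixes ("1HB" -> H).
.guess_element <- function(elety) {
  nm <- toupper(trimws(elety))
  nm <- sub("^[0-9]+", "", nm)
  out <- character(length(nm))
  two <- c("CL", "BR", "NA", "MG", "ZN", "FE")
  for (i in seq_along(nm)) {
    s <- gsub("[0-9']", "", nm[i])
    if (nchar(s) >= 2 && substr(s, 1, 2) %in% two &&
        !substr(s, 1, 2) %in% c("CA", "CB", "CD", "CE", "CG", "CZ", "ND",
                                "NE", "NH", "NZ", "OD", "OE", "OG", "OH",
                                "SD", "SG", "CH", "OX")) {
      out[i] <- substr(s, 1, 2)
    } else {
      out[i] <- substr(s, 1, 1)
    }
  }
  out
}

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET",
                  "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Construct a structure model
#'
#' The topology container against which all selections resolve: one row per
#' atom with PDB-style names, residue numbering (1-based as read), chain
#' ids, element, mass and van der Waals radius, plus reference coordinates.
#'
#' @param atoms data frame with columns `elety` (atom name), `resid`
#'   (3-letter residue name), `resno` (integer residue number), `chain`,
#'   and optionally `element`, `type` ("ATOM"/"HETATM").
#' @param xyz numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param solvent_names residue names classified as solvent.
#' @param elements optional element-table overrides (see [element_table()]).
#' @return object of class `structure_model` with components `atoms`
#'   (augmented data frame) and `xyz`.
#' @export
structure_model <- function(atoms, xyz,
                            solvent_names = c("HOH", "WAT", "TIP3"),
                            elements = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(atoms) || ncol(xyz) != 3)
    stop("coordinate matrix must be n_atoms x 3 (got ",
         nrow(xyz), " x ", ncol(xyz), " for ", nrow(atoms), " atoms)")
  if (!all(is.finite(xyz)))
    stop("non-finite reference coordinates")
  atoms$elety <- trimws(as.character(atoms$elety))
  atoms$resid <- toupper(trimws(as.character(atoms$resid)))
  atoms$resno <- as.integer(atoms$resno)
  atoms$chain <- as.character(atoms$chain)
  atoms$chain[is.na(atoms$chain)] <- "A"
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$element) || all(is.na(atoms$element)))
    atoms$element <- .guess_element(atoms$elety)
  atoms$element <- toupper(trimws(atoms$element))

  key <- paste(atoms$chain, atoms$resno, atoms$elety)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate atom (chain, residue, name): ", d)
  }
  tab <- element_table(elements)
  m <- match(atoms$element, tab$element)
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop("unknown element '", atoms$element[bad], "' for atom ",
         atoms$elety[bad], " of residue ", atoms$resid[bad], " ",
         atoms$chain[bad], ":", atoms$resno[bad],
         " (extend the element table to add it)")
  }
  atoms$mass <- tab$mass[m]
  atoms$vdw_radius <- tab$vdw_radius[m]
  stopifnot(all(atoms$mass > 0), all(atoms$vdw_radius > 0))
  # classification is by residue name, not record type: standard residues
  # are protein even when written as HETATM, and vice versa
  atoms$is_het <- !(atoms$resid %in% .standard_aa)
  atoms$is_solvent <- atoms$resid %in% toupper(solvent_names)
  atoms$is_ligand <- atoms$is_het & !atoms$is_solvent
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz,
                 solvent_names = toupper(solvent_names)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno)[!a$is_het])), "protein residues,",
      sum(a$is_ligand), "ligand atoms,", sum(a$is_solvent), "solvent atoms\n")
  invisible(x)
}

#' Number of atoms in a structure model
#' @param model a `structure_model`.
#' @return integer atom count.
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records via bio3d; the first MODEL provides the
#' reference coordinates.  HETATM records are retained and classified as
#' ligand or solvent by residue name.  Masses and radii come from the
#' built-in element table; an atom whose element is not in the table is an
#' error (never guessed), as is a duplicated (chain, residue, atom name).
#'
#' @inheritParams structure_model
#' @param path PDB file.
#' @return a [structure_model()].  When the file holds several MODELs the
#'   full coordinate set is kept in `attr(, "all_models_xyz")` so
#'   [read_trajectory()] can reuse it.
#' @export
read_structure <- function(path, solvent_names = c("HOH", "WAT", "TIP3"),
                           elements = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB '", path, "': ",
                         conditionMessage(e)))
  a <- pdb$atom
  atoms <- data.frame(elety = a$elety, resid = a$resid, resno = a$resno,
                      chain = a$chain, type = a$type,
                      element = if ("elesy" %in% names(a)) a$elesy else NA,
                      stringsAsFactors = FALSE)
  if (all(is.na(atoms$element)) || any(is.na(atoms$element)))
    atoms$element <- ifelse(is.na(atoms$element) | atoms$element == "",
                            .guess_element(atoms$elety),
                            toupper(trimws(atoms$element)))
  xyz1 <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  model <- structure_model(atoms, xyz1, solvent_names = solvent_names,
                           elements = elements)
  if (nrow(pdb$xyz) > 1) attr(model, "all_models_xyz") <- unclass(pdb$xyz)
  model
}

.selection_keywords <- c("all", "heavy", "protein", "backbone", "calpha",
                         "sidechain", "solvent", "ligand", "acidic-O",
                         "basic-N", "donors", "acceptors", "hydrogens")

.new_selection <- function(idx, label) {
  structure(as.integer(idx), label = label, class = "atom_selection")
}

#' Select atoms from a structure model
#'
#' Deterministic, order-stable selections by keyword or residue-range
#' expression.  `backbone` is the N/CA/C set of protein residues;
#' `acidic-O` the side-chain carboxylate oxygens of Asp/Glu; `basic-N` the
#' side-chain nitrogens of Lys/Arg (His optional); `donors` are N/O heavy
#' atoms carrying at least one bonded hydrogen and `acceptors` all N/O
#' heavy atoms.  A residue-range expression has the form
#' `"resno 10-20,30-35"` (1-based inclusive PDB numbering).
#'
#' @param model a [structure_model()].
#' @param label selection keyword or residue-range expression.
#' @param include_his treat histidine side-chain N as basic for
#'   `basic-N`.
#' @param allow_empty return an empty selection (with a warning) instead
#'   of erroring when nothing matches.
#' @return integer vector of atom indices with class `atom_selection`.
#' @export
select_atoms <- function(model, label, include_his = FALSE,
                         allow_empty = TRUE) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  protein <- !a$is_het
  idx <- if (grepl("^resno", label)) {
    spec <- sub("^resno[[:space:]]*", "", label)
    iv <- .parse_intervals(spec)
    keep <- rep(FALSE, nrow(a))
    for (k in seq_len(nrow(iv)))
      keep <- keep | (a$resno >= iv$start[k] & a$resno <= iv$end[k])
    which(keep)
  } else {
    switch(label,
      "all" = seq_len(nrow(a)),
      "heavy" = which(a$element != "H"),
      "protein" = which(protein),
      "backbone" = which(protein & a$elety %in% c("N", "CA", "C")),
      "calpha" = which(protein & a$elety == "CA"),
      "sidechain" = which(protein &
        !a$elety %in% c("N", "CA", "C", "O", "OXT", "H", "HA")),
      "solvent" = which(a$is_solvent),
      "ligand" = which(a$is_ligand),
      "acidic-O" = which((a$resid == "ASP" & a$elety %in% c("OD1", "OD2")) |
                         (a$resid == "GLU" & a$elety %in% c("OE1", "OE2"))),
      "basic-N" = which((a$resid == "LYS" & a$elety == "NZ") |
                        (a$resid == "ARG" &
                           a$elety %in% c("NE", "NH1", "NH2")) |
                        (include_his &
                           a$resid %in% c("HIS", "HID", "HIE", "HIP") &
                           a$elety %in% c("ND1", "NE2"))),
      "donors" = .donor_indices(model),
      "acceptors" = which(a$element %in% c("N", "O") & !a$is_solvent),
      "hydrogens" = which(a$element == "H"),
      stop("unknown selection keyword '", label, "'; known keywords: ",
           paste(.selection_keywords, collapse = ", "))
    )
  }
  if (length(idx) == 0) {
    if (!allow_empty) stop("selection '", label, "' matched no atoms")
    warning("selection '", label, "' matched no atoms")
  }
  .new_selection(sort(idx), label)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat("atom_selection '", attr(x, "label"), "': ", length(x), " atoms\n",
      sep = "")
  invisible(x)
}

#' Donor hydrogen map
#'
#' For every hydrogen, the N/O heavy atom of the same residue within the
#' covalent-bond distance (1.2 Angstrom) on the reference coordinates.
#' The bond topology is inferred once from the reference structure and
#' reused for all frames.
#'
#' @param model a [structure_model()].
#' @return data frame with columns `donor` and `hydrogen` (atom indices).
#' @export
donor_hydrogens <- function(model) {
  a <- model$atoms
  h_idx <- which(a$element == "H")
  out_d <- integer(0); out_h <- integer(0)
  if (length(h_idx)) {
    heavy <- which(a$element %in% c("N", "O"))
    for (h in h_idx) {
      cand <- heavy[a$chain[heavy] == a$chain[h] &
                    a$resno[heavy] == a$resno[h]]
      if (!length(cand)) next
      d2 <- rowSums((model$xyz[cand, , drop = FALSE] -
                       matrix(model$xyz[h, ], length(cand), 3,
                              byrow = TRUE))^2)
      j <- which.min(d2)
      if (d2[j] < 1.2^2) {
        out_d <- c(out_d, cand[j]); out_h <- c(out_h, h)
      }
    }
  }
  data.frame(donor = out_d, hydrogen = out_h)
}

.donor_indices <- function(model) {
  dh <- donor_hydrogens(model)
  a <- model$atoms
  sort(unique(dh$donor[a$element[dh$donor] %in% c("N", "O") &
                         !a$is_solvent[dh$donor]]))
}

# "4-62,76-95,199-216" -> data.frame(start, end); also accepts single "7"
.parse_intervals <- function(spec) {
  parts <- trimws(strsplit(as.character(spec), ",")[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("empty interval specification")
  iv <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^([0-9]+)[-–]?([0-9]*)$", p))[[1]]
    if (!length(m)) stop("malformed residue interval '", p, "'")
    s <- as.integer(m[2])
    e <- if (nzchar(m[3])) as.integer(m[3]) else s
    if (s > e) stop("invalid residue interval '", p,
                    "': start exceeds end")
    c(s, e)
  })
  iv <- do.call(rbind, iv)
  data.frame(start = iv[, 1], end = iv[, 2])
}

#' Residue identifiers of a model
#'
#' @param model a [structure_model()].
#' @param which one of "protein", "ligand", "solvent", "all".
#' @return data frame with columns `chain`, `resno`, `resid`, one row per
#'   residue, in file order.
#' @export
residues <- function(model, which = "protein") {
  a <- model$atoms
  keep <- switch(which,
                 protein = !a$is_het,
                 ligand = a$is_ligand,
                 solvent = a$is_solvent,
                 all = rep(TRUE, nrow(a)),
                 stop("unknown residue class '", which, "'"))
  r <- a[keep, c("chain", "resno", "resid")]
  r[!duplicated(paste(r$chain, r$resno)), , drop = FALSE]
}
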