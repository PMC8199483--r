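#' Load a structural-region definition table
#'
#' Region maps name functional regions of a fold (for GH-11 xylanases:
#' fingers, thumb, palm, cord, helix and their loops) as 1-based inclusive
#' residue-number intervals per enzyme, mirroring the published table
#' layout.  The YAML layout is
#'
#' ```yaml
#' enzymes:
#'   NpXyn11A:
#'     Fingers: "4-62,76-95,199-216"
#'     Thumb: "137-167"
#' ```
#'
#' Multi-interval regions are preserved as interval lists.
#'
#' @param path YAML file as above.
#' @return data frame of class `region_map` with columns `enzyme`,
#'   `region`, `start`, `end` (one row per interval).
#' @export
load_region_map <- function(path) {
  if (!file.exists(path)) stop("cannot read region file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$enzymes)) stop("region file lacks an 'enzymes' section")
  rows <- list()
  for (enz in names(cfg$enzymes)) {
    regs <- cfg$enzymes[[enz]]
    if (anyDuplicated(names(regs)))
      stop("duplicate region name for enzyme ", enz, ": ",
           names(regs)[duplicated(names(regs))][1])
    for (rg in names(regs)) {
      iv <- .parse_intervals(regs[[rg]])
      rows[[length(rows) + 1]] <-
        data.frame(enzyme = enz, region = rg, start = iv$start, end = iv$end,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("region_map", "data.frame")
  out
}

#' Build a region map from a data frame
#'
#' @param df data frame with columns `enzyme`, `region`, `start`, `end`.
#' @return a `region_map`.
#' @export
region_map <- function(df) {
  stopifnot(all(c("enzyme", "region", "start", "end") %in% names(df)))
  if (any(df$start > df$end)) stop("region interval with start > end")
  key <- unique(df[, c("enzyme", "region")])
  class(df) <- c("region_map", "data.frame")
  df
}

#' Residue count of a region
#'
#' Sum over the region's intervals of `end - start + 1`.
#'
#' @param map a [region_map()] / [load_region_map()] result.
#' @param enzyme_label enzyme name as in the map.
#' @param region_name region name as in the map.
#' @return integer residue count.
#' @export
region_residue_count <- function(map, enzyme_label, region_name) {
  stopifnot(inherits(map, "region_map"))
  rows <- map$enzyme == enzyme_label & map$region == region_name
  if (!any(rows)) {
    avail <- unique(map$region[map$enzyme == enzyme_label])
    stop("unknown region '", region_name, "' for enzyme '", enzyme_label,
         "'; available: ", paste(avail, collapse = ", "))
  }
  sum(map$end[rows] - map$start[rows] + 1L)
}

#' Atom indices of a region
#'
#' @param map a region map.
#' @param model a [structure_model()].
#' @param enzyme_label,region_name region identity.
#' @param selection optional `atom_selection` to intersect with (e.g.
#'   backbone); defaults to all protein atoms.
#' @return an `atom_selection` restricted to the region's residues.
#' @export
region_atoms <- function(map, model, enzyme_label, region_name,
                         selection = NULL) {
  rows <- which(map$enzyme == enzyme_label & map$region == region_name)
  if (!length(rows))
    stop("unknown region '", region_name, "' for enzyme '", enzyme_label, "'")
  base <- if (is.null(selection)) select_atoms(model, "protein") else selection
  resno <- model$atoms$resno[base]
  keep <- rep(FALSE, length(base))
  for (k in rows)
    keep <- keep | (resno >= map$start[k] & resno <= map$end[k])
  .new_selection(base[keep], paste0(region_name, "|",
                                    attr(base, "label") %||% "protein"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
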