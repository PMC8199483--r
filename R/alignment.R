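#' Read a pairwise sequence alignment
#'
#' Aligned FASTA with exactly two records of equal gapped length, used to
#' match per-residue profiles between two homologous enzymes.  The column
#' map gives, per alignment column, the 1-based ungapped residue index on
#' each side, with `NA` marking a gap.
#'
#' @param path aligned FASTA file.
#' @return object of class `aligned_pair`: list with `id_a`, `id_b`,
#'   `seq_a`, `seq_b` (gapped character vectors) and `column_map`
#'   (data frame `column`, `res_a`, `res_b`).
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("cannot read alignment file: ", path)
  aln <- bio3d::read.fasta(path, rm.dup = FALSE)
  n <- nrow(aln$ali)
  if (n != 2)
    stop("alignment must contain exactly two records (found ", n, ")")
  a <- toupper(aln$ali[1, ]); b <- toupper(aln$ali[2, ])
  if (anyNA(a) || anyNA(b))
    stop("alignment records have unequal gapped lengths (",
         sum(!is.na(a)), " vs ", sum(!is.na(b)), ")")
  gap <- function(x) x %in% c("-", ".")
  res_a <- ifelse(gap(a), NA_integer_, cumsum(!gap(a)))
  res_b <- ifelse(gap(b), NA_integer_, cumsum(!gap(b)))
  structure(list(id_a = aln$id[1], id_b = aln$id[2], seq_a = a, seq_b = b,
                 column_map = data.frame(column = seq_along(a),
                                         res_a = res_a, res_b = res_b)),
            class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("aligned_pair: ", x$id_a, " (", sum(!is.na(x$column_map$res_a)),
      " aa) / ", x$id_b, " (", sum(!is.na(x$column_map$res_b)),
      " aa), ", length(x$seq_a), " columns\n", sep = "")
  invisible(x)
}
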