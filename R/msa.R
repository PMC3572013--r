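# Alignments are character matrices (one character per cell, rownames =
# taxon names) over the alphabet A, C, G, T, '-' (gap) and '?' (missing).

#' Build an alignment matrix from aligned strings
#'
#' @param x named character vector of equal-length (gapped) sequences.
#' @return character matrix with one row per sequence.
#' @export
msa_from_strings <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)))
  if (length(unique(nchar(x))) > 1) stop("sequences differ in length")
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

#' Collapse an alignment matrix to one string per row
#' @param m character matrix.
#' @return named character vector.
#' @export
msa_to_strings <- function(m) {
  stats::setNames(apply(m, 1, paste0, collapse = ""), rownames(m))
}

#' Remove gap characters from sequences
#' @param x alignment matrix or named character vector of gapped sequences.
#' @return named character vector of ungapped sequences.
#' @export
degap <- function(x) {
  if (is.matrix(x)) x <- msa_to_strings(x)
  stats::setNames(gsub("[-?]", "", x), names(x))
}

#' Per-column gap fraction of an alignment
#' @param m character matrix; '?' counts as a gap for this purpose.
#' @return numeric vector of length `ncol(m)`.
#' @export
gap_fraction <- function(m) {
  colMeans(m == "-" | m == "?")
}

#' Read sequences from a FASTA file
#' @param path file path.
#' @return named character vector of (possibly gapped) sequences.
#' @export
read_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  stats::setNames(toupper(vapply(as.character(x), paste0, "", collapse = "")),
                  names(x))
}

#' Write sequences to a FASTA file
#' @param x named character vector or alignment matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.matrix(x)) x <- msa_to_strings(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    writeLines(x[[i]], con)
  }
  invisible(path)
}

#' Homologous column-pair recall of a test alignment
#'
#' Both alignments are decomposed into the sets of residue pairs they place
#' in the same column (identifying each residue by its taxon and its ordinal
#' position in the ungapped sequence). The recall is the fraction of the
#' reference alignment's pairs recovered by the test alignment. Used to
#' score inferred alignments against the simulator's true alignment.
#'
#' @param test,ref character alignment matrices over the same sequences.
#' @return a number in `[0, 1]` (1 if the reference has no pairs).
#' @export
column_pair_recall <- function(test, ref) {
  pairs <- function(m) {
    res <- m != "-" & m != "?"
    pos <- res
    pos[] <- 0L
    for (i in seq_len(nrow(m))) pos[i, res[i, ]] <- seq_len(sum(res[i, ]))
    out <- character(0)
    tx <- rownames(m)
    for (j in seq_len(ncol(m))) {
      rows <- which(res[, j])
      if (length(rows) < 2) next
      cmb <- utils::combn(rows, 2)
      out <- c(out, paste(tx[cmb[1, ]], pos[cbind(cmb[1, ], j)],
                          tx[cmb[2, ]], pos[cbind(cmb[2, ], j)], sep = "|"))
    }
    out
  }
  ref <- ref[rownames(test), , drop = FALSE]
  pr <- pairs(ref)
  if (length(pr) == 0) return(1)
  pt <- pairs(test)
  mean(pr %in% pt)
}
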