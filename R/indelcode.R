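# Simple indel coding: each distinct gap extent (start, end) observed in
# any row becomes one binary presence/absence character, treating a
# contiguous gap run as a single evolutionary event.

# maximal gap runs of one row: integer matrix with columns start, end
# (1-based, inclusive)
gap_runs <- function(row) {
  g <- row == "-"
  if (!any(g)) return(matrix(integer(0), 0, 2))
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Simple indel coding of alignment gaps
#'
#' Every distinct maximal gap run (same start and end columns) observed in
#' any row defines one binary character. A taxon scores 1 when it carries
#' exactly that run, 0 when it does not, and '?' (NA) when one of its own
#' gap runs strictly contains the character's extent (the event is then
#' unobservable for that taxon). Runs touching the alignment ends are
#' terminal: with `terminal_gaps = "missing"` they define no character and
#' the affected taxon scores '?' for any character extent lying inside its
#' terminal run. Ambiguity codes such as N are residues, not gaps.
#'
#' @param msa character alignment matrix.
#' @param terminal_gaps `"missing"` (treat leading/trailing gap runs as
#'   missing data) or `"coded"` (treat them like internal runs).
#' @return object of class `indel_matrix`: list with `matrix` (taxa x
#'   characters, values 0/1/NA) and `characters` (data frame with `start`,
#'   `end`, 1-based inclusive column extents, ordered by (start, end)).
#' @export
simple_indel_coding <- function(msa, terminal_gaps = c("missing", "coded")) {
  terminal_gaps <- match.arg(terminal_gaps)
  stopifnot(is.matrix(msa), ncol(msa) >= 1)
  L <- ncol(msa)
  runs <- lapply(seq_len(nrow(msa)), function(i) gap_runs(msa[i, ]))
  is_terminal <- function(r) r[1] == 1L || r[2] == L
  # character definitions
  defs <- unique(do.call(rbind, c(list(matrix(integer(0), 0, 2)), runs)))
  if (terminal_gaps == "missing" && nrow(defs) > 0)
    defs <- defs[!apply(defs, 1, is_terminal), , drop = FALSE]
  if (nrow(defs) > 0)
    defs <- defs[order(defs[, 1], defs[, 2]), , drop = FALSE]
  nch <- nrow(defs)
  m <- matrix(0L, nrow(msa), nch, dimnames = list(rownames(msa), NULL))
  for (i in seq_len(nrow(msa))) {
    ri <- runs[[i]]
    for (k in seq_len(nch)) {
      s <- defs[k, 1]; e <- defs[k, 2]
      score <- 0L
      for (q in seq_len(nrow(ri))) {
        qs <- ri[q, 1]; qe <- ri[q, 2]
        terminal_q <- terminal_gaps == "missing" && is_terminal(ri[q, ])
        if (qs == s && qe == e && !terminal_q) { score <- 1L; break }
        strictly_contains <- qs <= s && qe >= e && (qs < s || qe > e)
        if ((terminal_q && qs <= s && qe >= e) || strictly_contains) {
          score <- NA_integer_; break
        }
      }
      m[i, k] <- score
    }
  }
  chars <- data.frame(start = as.integer(defs[, 1]), end = as.integer(defs[, 2]))
  structure(list(matrix = m, characters = chars), class = "indel_matrix")
}

#' @export
print.indel_matrix <- function(x, ...) {
  cat("Binary indel matrix:", nrow(x$matrix), "taxa x",
      ncol(x$matrix), "characters\n")
  invisible(x)
}

#' Count parsimony-informative indel characters
#'
#' A character is parsimony informative when at least two taxa score 0 and
#' at least two score 1; '?' scores are ignored.
#'
#' @param m an `indel_matrix` (or plain 0/1/NA matrix).
#' @return integer count.
#' @export
count_parsimony_informative <- function(m) {
  if (inherits(m, "indel_matrix")) m <- m$matrix
  if (ncol(m) == 0) return(0L)
  sum(apply(m, 2, function(col) {
    sum(col == 0L, na.rm = TRUE) >= 2 && sum(col == 1L, na.rm = TRUE) >= 2
  }))
}

#' Write a combined DNA + binary-indel NEXUS file
#'
#' Writes a MrBayes-compatible NEXUS file with a mixed datatype DATA block
#' (DNA followed by the binary indel characters) and a charset line per
#' partition.
#'
#' @param aln a [partitioned_alignment()] (or plain matrix).
#' @param indels an `indel_matrix` (may have zero characters).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_combined_nexus <- function(aln, indels, path) {
  m <- unclass(aln)
  parts <- attr(aln, "partitions")
  if (is.null(parts)) parts <- list(all = c(1L, ncol(m)))
  bm <- if (is.null(indels) || ncol(indels$matrix) == 0) NULL else indels$matrix
  taxa <- rownames(m)
  ndna <- ncol(m)
  nbin <- if (is.null(bm)) 0L else ncol(bm)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("#NEXUS")
  w("BEGIN DATA;")
  w("  DIMENSIONS NTAX=", length(taxa), " NCHAR=", ndna + nbin, ";")
  if (nbin > 0) {
    w("  FORMAT DATATYPE=MIXED(DNA:1-", ndna, ",RESTRICTION:", ndna + 1, "-",
      ndna + nbin, ") GAP=- MISSING=? INTERLEAVE=NO;")
  } else {
    w("  FORMAT DATATYPE=DNA GAP=- MISSING=? INTERLEAVE=NO;")
  }
  w("  MATRIX")
  pad <- max(nchar(taxa)) + 2L
  for (i in seq_along(taxa)) {
    dna <- paste0(m[i, ], collapse = "")
    bin <- if (nbin > 0) {
      v <- bm[i, ]
      paste0(ifelse(is.na(v), "?", v), collapse = "")
    } else ""
    w("  ", formatC(taxa[i], width = -pad), dna, bin)
  }
  w("  ;")
  w("END;")
  w("BEGIN SETS;")
  for (nm in names(parts)) {
    w("  CHARSET ", nm, " = ", parts[[nm]][1], "-", parts[[nm]][2], ";")
  }
  if (nbin > 0) w("  CHARSET indels = ", ndna + 1, "-", ndna + nbin, ";")
  w("END;")
  invisible(path)
}

#' Read a combined NEXUS file written by [write_combined_nexus()]
#'
#' @param path file path.
#' @return list with `aln` (a [partitioned_alignment()]) and `indels`
#'   (taxa x characters matrix of 0/1/NA, or NULL when the file holds DNA
#'   only).
#' @export
read_combined_nexus <- function(path) {
  lines <- readLines(path)
  dimline <- grep("DIMENSIONS", lines, value = TRUE)[1]
  nchar_tot <- as.integer(sub(".*NCHAR=([0-9]+).*", "\\1", dimline))
  fmtline <- grep("FORMAT", lines, value = TRUE)[1]
  mixed <- grepl("MIXED", fmtline)
  ndna <- if (mixed) as.integer(sub(".*DNA:1-([0-9]+).*", "\\1", fmtline))
          else nchar_tot
  i0 <- grep("^\\s*MATRIX\\s*$", lines)[1] + 1L
  i1 <- grep("^\\s*;\\s*$", lines)
  i1 <- i1[i1 > i0][1] - 1L
  taxa <- character(0); rows <- character(0)
  for (ln in lines[i0:i1]) {
    ln <- trimws(ln)
    if (ln == "") next
    sp <- regmatches(ln, regexpr("^\\S+", ln))
    taxa <- c(taxa, sp)
    rows <- c(rows, gsub("\\s", "", substring(ln, nchar(sp) + 1)))
  }
  M <- do.call(rbind, strsplit(rows, ""))
  rownames(M) <- taxa
  dna <- M[, seq_len(ndna), drop = FALSE]
  # charsets
  sets <- grep("CHARSET", lines, value = TRUE)
  parts <- list()
  for (s in sets) {
    nm <- sub("\\s*CHARSET\\s+(\\S+)\\s*=.*", "\\1", s)
    rg <- sub(".*=\\s*([0-9]+)-([0-9]+).*", "\\1,\\2", s)
    rg <- as.integer(strsplit(rg, ",")[[1]])
    if (rg[1] <= ndna) parts[[nm]] <- rg
  }
  if (length(parts) == 0) parts <- list(all = c(1L, ndna))
  indels <- NULL
  if (ndna < nchar_tot) {
    b <- M[, (ndna + 1):nchar_tot, drop = FALSE]
    b[b == "?"] <- NA_character_
    indels <- matrix(as.integer(b), nrow(b), ncol(b),
                     dimnames = list(taxa, NULL))
  }
  list(aln = partitioned_alignment(dna, parts), indels = indels)
}
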