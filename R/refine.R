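# The central loop: align the indel-rich locus with a guide tree, filter
# gapped columns, concatenate with the indel-free loci, infer a tree, feed
# the tree back as the next guide tree, and repeat until the topology
# stabilizes.

#' Remove columns exceeding a gap-fraction threshold
#'
#' A column is kept iff its gap fraction (gaps and '?' over rows) is at
#' most `max_gap_fraction`; the default mirrors the "at most half of the
#' sequences may contain a gap" rule.
#'
#' @param msa character alignment matrix.
#' @param max_gap_fraction maximum allowed gap fraction per column.
#' @return list with `msa` (filtered matrix, row order preserved) and
#'   `report` (list: `kept` column indices, `removed` count,
#'   `max_gap_fraction`).
#' @export
gap_filter <- function(msa, max_gap_fraction = 0.5) {
  gf <- gap_fraction(msa)
  kept <- which(gf <= max_gap_fraction)
  list(msa = msa[, kept, drop = FALSE],
       report = list(kept = kept, removed = ncol(msa) - length(kept),
                     max_gap_fraction = max_gap_fraction))
}

#' Concatenate locus alignments into a partitioned supermatrix
#'
#' The taxon set is the union over loci; taxa absent from a locus are
#' filled with `fill` across that partition.
#'
#' @param loci named list of character alignment matrices.
#' @param fill fill character for missing taxa (default `"?"`).
#' @return a [partitioned_alignment()] with one partition per locus.
#' @export
concatenate_loci <- function(loci, fill = "?") {
  stopifnot(is.list(loci), !is.null(names(loci)))
  if (anyDuplicated(names(loci))) stop("duplicate locus names")
  taxa <- sort(unique(unlist(lapply(loci, rownames))))
  widths <- vapply(loci, ncol, 0L)
  out <- matrix(fill, length(taxa), sum(widths),
                dimnames = list(taxa, NULL))
  partitions <- list()
  at <- 0L
  for (nm in names(loci)) {
    m <- loci[[nm]]
    out[rownames(m), at + seq_len(ncol(m))] <- m
    partitions[[nm]] <- c(at + 1L, at + ncol(m))
    at <- at + ncol(m)
  }
  partitioned_alignment(out, partitions)
}

#' Alignment undermatching index
#'
#' The ratio of inferred to true alignment length. Values above 1 indicate
#' that homologous blocks were split into separate insertion events,
#' inflating the alignment.
#'
#' @param msa inferred alignment (matrix).
#' @param true_msa true alignment (matrix).
#' @return a nonnegative real number.
#' @export
undermatching_index <- function(msa, true_msa) {
  ncol(msa) / ncol(true_msa)
}

#' Iterative guide-tree refinement of an indel-rich alignment
#'
#' Iteration 0 builds a rough guide tree by neighbor joining on p-distances
#' from pairwise alignments of the indel-rich locus. Each iteration then
#' (1) aligns the locus progressively along the current guide tree,
#' (2) removes heavily gapped columns for tree estimation only,
#' (3) concatenates with the other loci (`mode = "multilocus"`) or uses the
#' filtered locus alone (`mode = "single"`),
#' (4) estimates a tree by NJ + NNI maximum likelihood,
#' (5) resolves any polytomy, midpoint-roots the tree, and feeds it back as
#' the next guide tree.
#' The loop stops when the inferred topology is identical (RF distance 0)
#' to the previous iteration's, or after `max_iter` iterations. The
#' unfiltered alignment is what is carried between iterations and returned;
#' the gap filter only affects tree estimation.
#'
#' @param its_seqs named character vector of unaligned indel-rich sequences.
#' @param other_loci named list of gapless alignment matrices (may be
#'   empty; ignored when `mode = "single"`).
#' @param params an [align_params()].
#' @param models a [gtr_model()] or per-partition named list (partitions:
#'   the indel-rich locus plus each of `other_loci`).
#' @param max_iter maximum number of align/estimate iterations.
#' @param seed integer seed (polytomy resolution, tie-breaking).
#' @param mode `"multilocus"` or `"single"`.
#' @param max_gap_fraction gap filter threshold for tree estimation.
#' @return an object of class `refine_fit`: list with `alignment` (final
#'   `annotated_msa`), `tree` (final inferred tree), `trace` (data frame:
#'   iteration, alignment length, lnL, RF distance to previous tree),
#'   `trees`, `guide_trees`, `converged`, `mode`.
#' @export
refine <- function(its_seqs, other_loci = list(),
                   params = align_params(), models = gtr_model(alpha = 0.8),
                   max_iter = 10L, seed = 1L,
                   mode = c("multilocus", "single"),
                   max_gap_fraction = 0.5) {
  mode <- match.arg(mode)
  if (length(its_seqs) == 0) stop("empty input: no sequences to refine")
  stopifnot(is.character(its_seqs), !is.null(names(its_seqs)))
  if (mode == "single") other_loci <- list()

  # iteration 0: p-distance NJ guide from pairwise alignments
  guide <- initial_guide_tree(its_seqs, params, seed)

  trace <- data.frame(iteration = integer(0), length = integer(0),
                      lnl = numeric(0), rf = integer(0))
  trees <- list(); guides <- list()
  prev_tree <- NULL
  aln <- NULL; tree <- NULL
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    guides[[it]] <- guide
    aln <- progressive_align(its_seqs, guide, params)
    filt <- gap_filter(unclass_msa(aln), max_gap_fraction)$msa
    loci <- c(list(its = filt), other_loci)
    supermat <- concatenate_loci(loci)
    mods <- models_for(models, names(attr(supermat, "partitions")))
    start <- nj_tree(p_distance_matrix(supermat))
    tree <- nni_search(start, supermat, mods)
    rf <- if (is.null(prev_tree)) NA_integer_ else rf_distance(tree, prev_tree)
    trace <- rbind(trace, data.frame(iteration = it, length = ncol(aln),
                                     lnl = attr(tree, "lnl"),
                                     rf = rf))
    trees[[it]] <- tree
    if (!is.na(rf) && rf == 0) { converged <- TRUE; break }
    prev_tree <- tree
    nxt <- resolve_polytomies(tree, seed = seed + it)
    nxt <- phangorn::midpoint(ape::unroot(nxt))
    # drop any taxa that are not part of the indel-rich locus
    extra <- setdiff(nxt$tip.label, names(its_seqs))
    if (length(extra) > 0) nxt <- ape::drop.tip(nxt, extra)
    # branch lengths from a multilocus tree sit on the concatenation scale;
    # re-estimate them on the indel-rich locus itself (topology fixed) so
    # the aligner's substitution scores see the locus' own divergence
    guide <- relength_guide(nxt, filt, models_for(models, "its")[[1]], seed)
  }
  if (!converged)
    warning("refinement did not converge within ", max_iter, " iterations")
  structure(list(alignment = aln, tree = tree, trace = trace,
                 trees = trees, guide_trees = guides,
                 converged = converged, mode = mode),
            class = "refine_fit")
}

#' Single-locus refinement
#'
#' [refine()] with the tree stage driven by the filtered indel-rich locus
#' alone (no other loci).
#'
#' @inheritParams refine
#' @return a `refine_fit`.
#' @export
single_locus_refine <- function(its_seqs, params = align_params(),
                                models = gtr_model(alpha = 0.8),
                                max_iter = 10L, seed = 1L,
                                max_gap_fraction = 0.5) {
  refine(its_seqs, list(), params, models, max_iter, seed,
         mode = "single", max_gap_fraction = max_gap_fraction)
}

# re-estimate guide branch lengths on the locus alignment, topology fixed,
# and midpoint-root the result
relength_guide <- function(tree, its_aln, model, seed) {
  if (length(tree$tip.label) < 3) return(tree)
  opt <- optimize_branch_lengths(tree, its_aln, model, nsweeps = 5)
  phangorn::midpoint(opt)
}

# strip annotated_msa attributes down to a plain character matrix
unclass_msa <- function(x) {
  attr(x, "origin") <- NULL
  attr(x, "permanent") <- NULL
  unclass(x)
}

models_for <- function(models, part_names) {
  if (inherits(models, "gtr_model"))
    return(stats::setNames(rep(list(models), length(part_names)), part_names))
  if (!all(part_names %in% names(models)))
    stop("missing models for partitions: ",
         paste(setdiff(part_names, names(models)), collapse = ", "))
  models[part_names]
}

initial_guide_tree <- function(seqs, params, seed) {
  n <- length(seqs)
  if (n == 2) {
    tr <- ape::read.tree(text = paste0("(", names(seqs)[1], ":0.5,",
                                       names(seqs)[2], ":0.5);"))
    return(tr)
  }
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pa <- pairwise_align(seqs[[i]], seqs[[j]], params)$alignment
    rownames(pa) <- c(names(seqs)[i], names(seqs)[j])
    D[i, j] <- D[j, i] <- p_distance_matrix(pa)[1, 2]
  }
  tr <- nj_tree(D)
  tr <- phangorn::midpoint(tr)
  resolve_polytomies(tr, seed)
}

#' @export
print.refine_fit <- function(x, ...) {
  cat("Iterative guide-tree refinement (", x$mode, " mode)\n", sep = "")
  cat("  iterations:", nrow(x$trace),
      if (x$converged) "(converged, RF = 0)" else "(not converged)", "\n")
  cat("  alignment length:", x$trace$length[1], "->",
      x$trace$length[nrow(x$trace)], "columns\n")
  invisible(x)
}

#' @export
summary.refine_fit <- function(object, ...) {
  cat("Refinement trace:\n")
  print(object$trace, row.names = FALSE)
  cat("Final alignment:", nrow(object$alignment), "taxa x",
      ncol(object$alignment), "columns;",
      sum(attr(object$alignment, "permanent")), "permanent insertion columns\n")
  invisible(object$trace)
}

#' @export
plot.refine_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$trace$iteration, x$trace$length, type = "b",
                 xlab = "iteration", ylab = "alignment length (columns)",
                 main = "Alignment length", ...)
  graphics::plot(x$trace$iteration, x$trace$rf, type = "b",
                 xlab = "iteration", ylab = "RF distance to previous tree",
                 main = "Topological change", ...)
  invisible(x)
}
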