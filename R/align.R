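# Insertion-aware progressive alignment guided by a rooted tree.
#
# Profiles are merged in postorder. Columns created opposite a gap are
# annotated as insertions at the child whose subtree carries the residues;
# with `fix_insertions = TRUE` such columns become permanent: they are
# excluded from all later profile-profile matching and are carried upward
# as gap-only columns for the rest of the taxa. This reproduces, at desk
# scale, the mechanism by which insertion-fixing progressive aligners split
# homologous blocks into separate insertion events when the guide tree
# groups the wrong taxa -- alignment undermatching.

#' Alignment scoring parameters
#'
#' Substitution scores are either log-odds scores derived from a GTR model
#' at the branch length connecting the two profiles, or a fixed
#' match/mismatch pair. Gap runs of length k cost
#' `gap_open + (k - 1) * gap_extend` (both penalties are negative numbers;
#' linear gap costs are obtained with `gap_extend == gap_open`).
#'
#' @param model a [gtr_model()] used to derive substitution scores.
#' @param gap_open,gap_extend gap penalties (`gap_extend >= gap_open`).
#' @param fix_insertions logical; permanently fix inferred insertion
#'   columns (the "+F" behaviour).
#' @param match,mismatch optional fixed scores overriding the model-derived
#'   matrix.
#' @param min_t,max_t clamp on the branch length at which model scores are
#'   evaluated.
#' @return an object of class `align_params`.
#' @export
align_params <- function(model = gtr_model(alpha = 0.8),
                         gap_open = -5, gap_extend = -0.5,
                         fix_insertions = TRUE,
                         match = NULL, mismatch = NULL,
                         min_t = 0.05, max_t = 2) {
  if (gap_extend < gap_open)
    stop("'gap_extend' must be >= 'gap_open' (extension may not cost more)")
  if (gap_open >= 0) stop("'gap_open' must be negative")
  structure(list(model = model, gap_open = gap_open, gap_extend = gap_extend,
                 fix_insertions = isTRUE(fix_insertions),
                 match = match, mismatch = mismatch,
                 min_t = min_t, max_t = max_t),
            class = "align_params")
}

# 4x4 substitution score matrix at branch length t
score_matrix <- function(params, t) {
  if (!is.null(params$match)) {
    S <- matrix(params$mismatch, 4, 4)
    diag(S) <- params$match
    return(S)
  }
  t <- min(max(t, params$min_t), params$max_t)
  P <- transition_matrix(params$model, t)
  log(pmax(P, 1e-12) / rep(params$model$pi, each = 4))
}

seq_to_ints <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(v)) stop("sequences must be over the alphabet A, C, G, T")
  v
}

# profile of an aligned character matrix restricted to given columns:
# 4 x ncol matrix of residue frequencies (gap mass omitted)
profile_freq <- function(aln, cols) {
  n <- nrow(aln)
  out <- matrix(0, 4, length(cols))
  b <- c("A", "C", "G", "T")
  for (k in 1:4) out[k, ] <- colSums(aln[, cols, drop = FALSE] == b[k]) / n
  out
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap costs and fixed
#' tie-breaking (match preferred over a gap in the second sequence,
#' preferred over a gap in the first).
#'
#' @param x,y sequences over A, C, G, T (character strings). An empty
#'   sequence is aligned as an all-gap row.
#' @param params an [align_params()].
#' @param t branch length at which model-derived scores are evaluated.
#' @return list with `alignment` (2-row character matrix) and `score`.
#' @export
pairwise_align <- function(x, y, params = align_params(), t = 0.5) {
  nx <- nchar(x); ny <- nchar(y)
  if (nx == 0 || ny == 0) {
    n <- max(nx, ny)
    aln <- rbind(strsplit(paste0(x, strrep("-", n - nx)), "")[[1]],
                 strsplit(paste0(y, strrep("-", n - ny)), "")[[1]])
    if (n == 0) aln <- matrix(character(0), 2, 0)
    score <- if (n == 0) 0 else params$gap_open + (n - 1) * params$gap_extend
    return(list(alignment = aln, score = score))
  }
  xi <- seq_to_ints(x); yi <- seq_to_ints(y)
  SM <- score_matrix(params, t)
  S12 <- SM[xi, yi, drop = FALSE]
  res <- C_profile_align(S12, params$gap_open, params$gap_extend)
  ops <- res$ops
  xs <- strsplit(toupper(x), "")[[1]]; ys <- strsplit(toupper(y), "")[[1]]
  rx <- character(length(ops)); ry <- character(length(ops))
  i <- 0; j <- 0
  for (k in seq_along(ops)) {
    if (ops[k] == 1L) { i <- i + 1; j <- j + 1; rx[k] <- xs[i]; ry[k] <- ys[j] }
    else if (ops[k] == 2L) { i <- i + 1; rx[k] <- xs[i]; ry[k] <- "-" }
    else { j <- j + 1; rx[k] <- "-"; ry[k] <- ys[j] }
  }
  list(alignment = rbind(rx, ry), score = res$score)
}

#' Progressive multiple alignment along a guide tree
#'
#' Sequences are merged in the postorder of the (rooted, binary) guide
#' tree. Profile-profile scores are average-of-pairs over column residue
#' frequencies, with substitution scores evaluated at the sum of the two
#' child branch lengths. Columns aligned against a gap are annotated as
#' insertions originating at the child carrying the residues; with
#' `fix_insertions` these become permanent and are never matched again.
#'
#' @param seqs named character vector of unaligned sequences.
#' @param guide_tree a `phylo`; leaves must match `names(seqs)`. Unrooted
#'   trees are midpoint-rooted; polytomies must be resolved first (see
#'   [resolve_polytomies()]).
#' @param params an [align_params()].
#' @return an `annotated_msa`: character matrix with attributes `origin`
#'   (per column: `"match"` or `"ins@<node>"`) and `permanent` (logical per
#'   column).
#' @export
progressive_align <- function(seqs, guide_tree, params = align_params()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)),
            inherits(guide_tree, "phylo"))
  if (!setequal(guide_tree$tip.label, names(seqs))) {
    bad <- c(setdiff(guide_tree$tip.label, names(seqs)),
             setdiff(names(seqs), guide_tree$tip.label))
    stop("guide tree leaves and sequence names differ: ",
         paste(bad, collapse = ", "))
  }
  if (!ape::is.rooted(guide_tree)) guide_tree <- phangorn::midpoint(guide_tree)
  if (!ape::is.binary(guide_tree))
    stop("guide tree must be binary; resolve polytomies first")
  if (length(seqs) == 1) {
    m <- matrix(strsplit(toupper(seqs), "")[[1]], 1,
                dimnames = list(names(seqs), NULL))
    return(new_annotated_msa(m, rep("match", ncol(m)), rep(FALSE, ncol(m))))
  }
  tr <- ape::reorder.phylo(guide_tree, "postorder")
  ntip <- length(tr$tip.label)
  prof <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) {
    v <- seq_to_ints(seqs[[tr$tip.label[i]]])
    m <- matrix(c("A", "C", "G", "T")[v], 1,
                dimnames = list(tr$tip.label[i], NULL))
    prof[[i]] <- list(aln = m, origin = rep("match", ncol(m)),
                      perm = rep(FALSE, ncol(m)), depth = 0)
  }
  # merge children; substitution scores are evaluated at the expected
  # leaf-to-leaf divergence across the merge (mean leaf depth within each
  # profile plus the two connecting branches), which average-of-pairs
  # profile scoring implies
  for (v in unique(tr$edge[, 1])) {
    ce <- which(tr$edge[, 1] == v)
    ch <- tr$edge[ce, 2]
    px <- prof[[ch[1]]]; py <- prof[[ch[2]]]
    dx <- px$depth + tr$edge.length[ce[1]]
    dy <- py$depth + tr$edge.length[ce[2]]
    prof[[v]] <- merge_profiles(px, py, dx + dy, ch[1], ch[2], params)
    nx <- nrow(px$aln); ny <- nrow(py$aln)
    prof[[v]]$depth <- (nx * dx + ny * dy) / (nx + ny)
  }
  root <- ntip + 1L
  p <- prof[[root]]
  aln <- p$aln[names(seqs), , drop = FALSE]
  new_annotated_msa(aln, p$origin, p$perm)
}

new_annotated_msa <- function(m, origin, perm) {
  structure(m, origin = origin, permanent = perm, class = "annotated_msa")
}

#' @export
print.annotated_msa <- function(x, ...) {
  cat("Annotated MSA:", nrow(x), "sequences x", ncol(x), "columns;",
      sum(attr(x, "permanent")), "permanent insertion columns\n")
  invisible(x)
}

merge_profiles <- function(px, py, t, cx, cy, params) {
  mx <- which(!px$perm); my <- which(!py$perm)
  SM <- score_matrix(params, t)
  Fx <- profile_freq(px$aln, mx)
  Fy <- profile_freq(py$aln, my)
  S12 <- t(Fx) %*% SM %*% Fy
  ops <- if (length(mx) == 0 && length(my) == 0) integer(0)
         else if (length(mx) == 0) rep(3L, length(my))
         else if (length(my) == 0) rep(2L, length(mx))
         else C_profile_align(S12, params$gap_open, params$gap_extend)$ops
  nx <- ncol(px$aln); ny <- ncol(py$aln)
  # output column plan: (x column or NA, y column or NA, origin, permanent)
  xs <- integer(0); ys <- integer(0); org <- character(0); prm <- logical(0)
  emit <- function(xc, yc, o, p) {
    xs[length(xs) + 1L] <<- xc; ys[length(ys) + 1L] <<- yc
    org[length(org) + 1L] <<- o; prm[length(prm) + 1L] <<- p
  }
  ix <- 1L; iy <- 1L
  flush_perm <- function() {
    while (ix <= nx && px$perm[ix]) {
      emit(ix, NA_integer_, px$origin[ix], TRUE); ix <<- ix + 1L
    }
    while (iy <= ny && py$perm[iy]) {
      emit(NA_integer_, iy, py$origin[iy], TRUE); iy <<- iy + 1L
    }
  }
  for (op in ops) {
    flush_perm()
    if (op == 1L) {
      emit(ix, iy, "match", FALSE); ix <- ix + 1L; iy <- iy + 1L
    } else if (op == 2L) {
      emit(ix, NA_integer_, paste0("ins@", cx), params$fix_insertions)
      ix <- ix + 1L
    } else {
      emit(NA_integer_, iy, paste0("ins@", cy), params$fix_insertions)
      iy <- iy + 1L
    }
  }
  flush_perm()
  ncols <- length(xs)
  aln <- matrix("-", nrow(px$aln) + nrow(py$aln), ncols)
  rownames(aln) <- c(rownames(px$aln), rownames(py$aln))
  rx <- seq_len(nrow(px$aln)); ry <- nrow(px$aln) + seq_len(nrow(py$aln))
  kx <- which(!is.na(xs)); ky <- which(!is.na(ys))
  aln[rx, kx] <- px$aln[, xs[kx], drop = FALSE]
  aln[ry, ky] <- py$aln[, ys[ky], drop = FALSE]
  list(aln = aln, origin = org, perm = prm)
}

#' Random guide tree over a set of taxa
#'
#' A random rooted binary topology with random branch lengths, used to
#' contrast alignments under poor guide trees with those under the true
#' tree. When a `template` tree is given the branch lengths are rescaled
#' to the template's total tree length, so the comparison isolates the
#' effect of topology from that of branch-length scale.
#'
#' @param taxa character vector of taxon names.
#' @param seed integer seed.
#' @param template optional `phylo` whose total branch length sets the
#'   scale of the random tree.
#' @return a rooted binary `phylo`.
#' @export
random_guide_tree <- function(taxa, seed = 1L, template = NULL) {
  set.seed(seed)
  tr <- ape::rtree(length(taxa))
  tr$tip.label <- sample(taxa)
  if (!is.null(template) && !is.null(template$edge.length)) {
    tr$edge.length <- tr$edge.length *
      sum(template$edge.length) / sum(tr$edge.length)
  }
  tr
}
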