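# Tree estimation and likelihood machinery: p-distances, neighbor joining,
# partitioned GTR+Gamma pruning likelihood (compiled core), NNI hill
# climbing, bootstrap supports, majority-rule consensus, polytomy
# resolution, Robinson-Foulds distances and the 70%-bootstrap conflict test.

#' Pairwise p-distance matrix under pairwise deletion
#'
#' The proportion of differing sites among columns where both rows carry a
#' residue (A/C/G/T). Rows with no comparable columns get `max_dist`.
#'
#' @param msa character alignment matrix (or named character vector of
#'   equal-length gapped sequences).
#' @param max_dist distance assigned when no sites are comparable.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa, max_dist = 0.75) {
  if (!is.matrix(msa)) msa <- msa_from_strings(msa)
  n <- nrow(msa)
  if (n < 2) stop("need at least 2 sequences")
  res <- msa %in% c("A", "C", "G", "T")
  dim(res) <- dim(msa)
  D <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- res[i, ] & res[j, ]
    nc <- sum(comp)
    d <- if (nc == 0) max_dist else sum(msa[i, comp] != msa[j, comp]) / nc
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Standard NJ via [ape::nj()]; negative branch-length estimates are
#' clamped to zero.
#'
#' @param D symmetric distance matrix with taxon dimnames.
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa")
  tr <- ape::nj(as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

# ---- bipartitions ------------------------------------------------------

# canonical non-trivial splits of a tree: character keys, each the sorted
# taxa of the side containing the lexicographically smallest taxon
tree_splits <- function(tree) {
  taxa <- sort(tree$tip.label)
  anchor <- taxa[1]
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next
    side <- below[[ch]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    if (!(anchor %in% side)) side <- setdiff(tr$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

split_sides <- function(key) strsplit(key, ",", fixed = TRUE)[[1]]

# two splits of the same leaf set are compatible iff one of the four
# side intersections is empty
splits_incompatible <- function(key1, key2, taxa) {
  s1 <- split_sides(key1); s2 <- split_sides(key2)
  c1 <- setdiff(taxa, s1); c2 <- setdiff(taxa, s2)
  length(intersect(s1, s2)) > 0 && length(intersect(s1, c2)) > 0 &&
    length(intersect(c1, s2)) > 0 && length(intersect(c1, c2)) > 0
}

#' Bootstrap support for bipartitions
#'
#' Columns are resampled with replacement; a tree is estimated from each
#' replicate and supports are bipartition frequencies.
#'
#' @param aln character alignment matrix.
#' @param estimator `"nj"` (p-distance + NJ) or `"ml"` (NJ start + NNI
#'   search; requires `models`).
#' @param reps number of replicates (>= 1).
#' @param seed integer seed.
#' @param models per-partition models for `estimator = "ml"`.
#' @return an object of class `bootstrap_support`: list with `taxa`,
#'   `support` (named by canonical split key), `reps`.
#' @export
bootstrap_support <- function(aln, estimator = c("nj", "ml"), reps = 100L,
                              seed = 1L, models = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(reps >= 1)
  set.seed(seed)
  counts <- new.env(parent = emptyenv())
  for (r in seq_len(reps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    rep_aln <- aln[, cols, drop = FALSE]
    tr <- nj_tree(p_distance_matrix(rep_aln))
    if (estimator == "ml") {
      tr <- nni_search(tr, rep_aln, models)
    }
    for (k in tree_splits(tr)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  sup <- vapply(keys, function(k) counts[[k]] / reps, 0)
  structure(list(taxa = sort(rownames(aln)), support = sup, reps = reps),
            class = "bootstrap_support")
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat("Bootstrap supports over", x$reps, "replicates,",
      length(x$support), "bipartitions of", length(x$taxa), "taxa\n")
  invisible(x)
}

#' Detect conflicting strongly supported bipartitions between two loci
#'
#' A pair of bipartitions is reported when the two cannot co-exist in one
#' tree and each reaches the support threshold in its own locus -- the
#' signature of significant inter-locus conflict.
#'
#' @param s1,s2 `bootstrap_support` objects over the same taxa.
#' @param threshold minimum support in both loci (default 0.70).
#' @return data frame with columns `split1`, `split2`, `support1`,
#'   `support2` (zero rows when there is no conflict).
#' @export
detect_conflicts <- function(s1, s2, threshold = 0.70) {
  stopifnot(inherits(s1, "bootstrap_support"),
            inherits(s2, "bootstrap_support"))
  if (!identical(s1$taxa, s2$taxa)) stop("support maps are over different taxa")
  k1 <- names(s1$support)[s1$support >= threshold]
  k2 <- names(s2$support)[s2$support >= threshold]
  out <- data.frame(split1 = character(0), split2 = character(0),
                    support1 = numeric(0), support2 = numeric(0))
  for (a in k1) for (b in k2) {
    if (a == b) next
    if (splits_incompatible(a, b, s1$taxa)) {
      out <- rbind(out, data.frame(split1 = a, split2 = b,
                                   support1 = unname(s1$support[a]),
                                   support2 = unname(s2$support[b])))
    }
  }
  out
}

#' Strict majority-rule consensus tree
#'
#' Bipartitions occurring in strictly more than `min_freq` of the trees are
#' retained (a split in exactly half of the trees is excluded). Clade
#' frequencies are attached as node labels.
#'
#' @param trees list of `phylo` (or `multiPhylo`) over the same taxa.
#' @param min_freq frequency that must be exceeded (default 0.5).
#' @return a `phylo`, possibly with polytomies; node labels carry clade
#'   frequencies.
#' @export
majority_consensus <- function(trees, min_freq = 0.5) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ntr <- length(trees)
  taxa <- sort(trees[[1]]$tip.label)
  counts <- table(unlist(lapply(trees, tree_splits)))
  keep <- counts[counts / ntr > min_freq]
  anchor <- taxa[1]
  # work with rooted clades: the side NOT containing the anchor taxon
  clades <- lapply(names(keep), function(k) {
    s <- split_sides(k)
    if (anchor %in% s) setdiff(taxa, s) else s
  })
  freqs <- as.numeric(keep) / ntr
  ord <- order(vapply(clades, length, 0L), decreasing = TRUE)
  clades <- clades[ord]; freqs <- freqs[ord]
  # recursive newick construction over the nested clade hierarchy
  build <- function(members, sub, subfreq) {
    top <- rep(TRUE, length(sub))
    for (i in seq_along(sub)) for (j in seq_along(sub)) {
      if (i != j && top[i] && all(sub[[i]] %in% sub[[j]])) top[i] <- FALSE
    }
    parts <- character(0)
    used <- character(0)
    for (i in which(top)) {
      inner <- sub[lengths(sub) < length(sub[[i]]) &
                     vapply(sub, function(x) all(x %in% sub[[i]]), TRUE)]
      innerf <- subfreq[lengths(sub) < length(sub[[i]]) &
                          vapply(sub, function(x) all(x %in% sub[[i]]), TRUE)]
      parts <- c(parts, paste0(build(sub[[i]], inner, innerf),
                               format(round(subfreq[i], 4))))
      used <- c(used, sub[[i]])
    }
    singles <- setdiff(members, used)
    paste0("(", paste(c(parts, singles), collapse = ","), ")")
  }
  top_members <- taxa
  nwk <- paste0(build(top_members, clades, freqs), ";")
  ape::read.tree(text = nwk)
}

#' Randomly resolve polytomies to zero-length branches
#'
#' @param tree a `phylo`.
#' @param seed integer seed (resolution is deterministic given the seed).
#' @return a binary `phylo`; every introduced branch has length 0.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  set.seed(seed)
  had_el <- !is.null(tree$edge.length)
  if (!had_el) tree$edge.length <- rep(1, nrow(tree$edge))
  rooted <- ape::is.rooted(tree)
  tr <- ape::multi2di(tree, random = TRUE)
  if (!rooted) tr <- ape::unroot(tr)   # keep unrooted trees unrooted
  # multi2di assigns introduced branches length 0; clamp defensively
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!had_el) tr$edge.length <- NULL
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the two unrooted trees'
#' non-trivial bipartition sets.
#'
#' @param t1,t2 `phylo` objects over the same taxa.
#' @return a nonnegative integer.
#' @export
rf_distance <- function(t1, t2) {
  as.integer(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                               check.labels = TRUE))
}

# ---- partitioned alignments and likelihood -----------------------------

#' Partitioned alignment
#'
#' @param m character alignment matrix over A, C, G, T, '-', '?'.
#' @param partitions named list of length-2 integer vectors `c(first, last)`
#'   (1-based, inclusive); intervals must be disjoint and cover all columns.
#' @return object of class `partitioned_alignment` (the matrix with a
#'   `partitions` attribute).
#' @export
partitioned_alignment <- function(m, partitions) {
  stopifnot(is.matrix(m), is.list(partitions), !is.null(names(partitions)))
  cov <- unlist(lapply(partitions, function(p) seq.int(p[1], p[2])))
  if (length(cov) != ncol(m) || anyDuplicated(cov) ||
      !setequal(cov, seq_len(ncol(m))))
    stop("partitions must be disjoint and cover all columns")
  structure(m, partitions = partitions, class = "partitioned_alignment")
}

# tip state integers for the compiled engine: 0 = missing, 1..4 = ACGT
encode_states <- function(m) {
  s <- match(m, c("A", "C", "G", "T"))
  s[is.na(s)] <- 0L
  matrix(as.integer(s), nrow(m), ncol(m))
}

# pattern-compress one partition block; returns engine part list + site map
make_part <- function(block, model) {
  st <- encode_states(block)
  key <- apply(st, 2, paste, collapse = ",")
  u <- !duplicated(key)
  tip <- st[, u, drop = FALSE]
  idx <- match(key, key[u])
  w <- tabulate(idx, nbins = sum(u))
  list(part = list(tip = tip, w = as.numeric(w), pi = model$pi,
                   U = model$U, Uinv = model$Uinv, lam = model$lambda,
                   rates = model$rates),
       site_map = idx)
}

prepare_parts <- function(tree, aln, models) {
  if (inherits(aln, "partitioned_alignment")) {
    parts_def <- attr(aln, "partitions")
  } else {
    parts_def <- list(all = c(1L, ncol(aln)))
  }
  if (inherits(models, "gtr_model"))
    models <- stats::setNames(rep(list(models), length(parts_def)),
                              names(parts_def))
  if (!setequal(rownames(aln), tree$tip.label))
    stop("tree leaves and alignment rows differ: ",
         paste(c(setdiff(tree$tip.label, rownames(aln)),
                 setdiff(rownames(aln), tree$tip.label)), collapse = ", "))
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  parts <- list(); site_maps <- list()
  for (nm in names(parts_def)) {
    rg <- parts_def[[nm]]
    pk <- make_part(m[, seq.int(rg[1], rg[2]), drop = FALSE], models[[nm]])
    parts[[nm]] <- pk$part
    site_maps[[nm]] <- pk$site_map
  }
  list(parts = parts, site_maps = site_maps, parts_def = parts_def)
}

postorder_edges <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, el = tr$edge.length, tree = tr)
}

#' Log-likelihood of a tree under partitioned GTR+Gamma
#'
#' Felsenstein pruning with a discrete gamma mixture per partition. Gaps
#' and '?' are treated as missing data (all-ones conditionals). Branch
#' lengths are shared across partitions; substitution models are not.
#'
#' @param tree a `phylo` with branch lengths; leaves must match alignment
#'   rows.
#' @param aln character matrix or [partitioned_alignment()].
#' @param models a [gtr_model()] or named list of models, one per partition.
#' @param per_site also return the per-site log-likelihood vector
#'   (concatenated in column order).
#' @return total log-likelihood; if `per_site`, a list with `total` and
#'   `per_site`.
#' @export
tree_loglik <- function(tree, aln, models, per_site = FALSE) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  pr <- prepare_parts(tree, aln, models)
  po <- postorder_edges(tree)
  if (!per_site) {
    return(C_total_lnl(po$edge, po$el, length(tree$tip.label), pr$parts))
  }
  v <- C_persite_lnl(po$edge, po$el, length(tree$tip.label), pr$parts)
  persite <- unlist(lapply(seq_along(v), function(i) v[[i]][pr$site_maps[[i]]]),
                    use.names = FALSE)
  list(total = sum(persite), per_site = persite)
}

#' Optimize branch lengths by per-branch sweeps
#'
#' Golden-section optimization of each branch in turn against cached
#' partial likelihoods, repeated for `nsweeps` sweeps. If a sweep fails to
#' improve the exact likelihood the input lengths are kept.
#'
#' @param tree `phylo` with branch lengths (missing lengths start at 0.1).
#' @param aln alignment (matrix or [partitioned_alignment()]).
#' @param models model or per-partition model list.
#' @param nsweeps number of sweeps.
#' @param iters golden-section iterations per branch.
#' @return the tree with optimized `edge.length` and attribute `lnl`.
#' @export
optimize_branch_lengths <- function(tree, aln, models, nsweeps = 10L,
                                    iters = 25L, tol = 0.01) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  # a degree-2 root makes the two root branches jointly redundant, which
  # stalls the per-branch sweeps; optimize the unrooted tree instead
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2)
    tree <- ape::unroot(tree)
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  pr <- prepare_parts(tree, aln, models)
  po <- postorder_edges(tree)
  ntip <- length(tree$tip.label)
  el <- po$el
  lnl <- C_total_lnl(po$edge, el, ntip, pr$parts)
  for (s in seq_len(nsweeps)) {
    res <- C_optimize_bl(po$edge, el, ntip, pr$parts, 1L, 1e-8, 10,
                         as.integer(iters))
    if (res$lnl < lnl) break       # Jacobi sweep failed to improve; keep old
    improved <- res$lnl - lnl
    el <- as.numeric(res$el)
    lnl <- res$lnl
    if (improved < tol) break
  }
  tr <- po$tree
  tr$edge.length <- el
  attr(tr, "lnl") <- lnl
  tr
}

# all NNI neighbours of an unrooted binary tree, branch lengths carried
# with the subtrees
nni_neighbors <- function(tree) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tr$tip.label)
  out <- list()
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2]
    if (ch <= ntip) next                  # need internal child
    p <- tr$edge[e, 1]
    f <- which(tr$edge[, 1] == ch)        # child edges of ch
    g <- setdiff(which(tr$edge[, 1] == p), e)[1]  # one sibling edge at p
    for (fe in f) {
      t2 <- tr
      tmp <- t2$edge[fe, 2]
      t2$edge[fe, 2] <- t2$edge[g, 2]
      t2$edge[g, 2] <- tmp
      # the swap can violate ape's node-numbering convention; normalize
      t2 <- ape::read.tree(text = ape::write.tree(t2))
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

# does the (unrooted) tree contain every required clade as a bipartition?
satisfies_constraint <- function(tree, clades) {
  if (is.null(clades) || length(clades) == 0) return(TRUE)
  keys <- tree_splits(tree)
  taxa <- sort(tree$tip.label)
  anchor <- taxa[1]
  for (cl in clades) {
    if (length(cl) < 2 || length(cl) > length(taxa) - 2) next # trivially true
    side <- if (anchor %in% cl) sort(cl) else sort(setdiff(taxa, cl))
    if (!(paste(side, collapse = ",") %in% keys)) return(FALSE)
  }
  TRUE
}

#' NNI hill-climbing search for the maximum-likelihood tree
#'
#' Starting from a binary tree, all nearest-neighbour-interchange
#' rearrangements are scored at the current branch lengths; the most
#' promising candidates are re-scored with branch-length optimization and
#' the best accepted if it improves the likelihood by more than `tol`.
#' Moves that would break a required clade are rejected.
#'
#' @param tree starting binary tree (rooted trees are unrooted first).
#' @param aln alignment (matrix or [partitioned_alignment()]).
#' @param models model or per-partition model list.
#' @param constraint optional list of taxon vectors that must remain
#'   monophyletic.
#' @param tol minimum likelihood improvement to accept a move.
#' @param max_rounds cap on accepted moves.
#' @param top_k number of top fixed-length candidates re-scored with branch
#'   optimization each round.
#' @return the maximum-likelihood tree found, with attribute `lnl`.
#' @export
nni_search <- function(tree, aln, models, constraint = NULL, tol = 1e-6,
                       max_rounds = 50L, top_k = 5L) {
  cur <- ape::unroot(tree)
  if (is.null(cur$edge.length)) cur$edge.length <- rep(0.1, nrow(cur$edge))
  cur <- optimize_branch_lengths(cur, aln, models)
  cur_lnl <- attr(cur, "lnl")
  pr <- prepare_parts(cur, aln, models)
  ntip <- length(cur$tip.label)
  for (round in seq_len(max_rounds)) {
    cands <- nni_neighbors(cur)
    if (!is.null(constraint))
      cands <- Filter(function(x) satisfies_constraint(x, constraint), cands)
    if (length(cands) == 0) break
    # tip label order is preserved by the NNI surgery, so the encoded
    # patterns can be shared across candidates
    quick <- vapply(cands, function(x) {
      po <- postorder_edges(x)
      C_total_lnl(po$edge, po$el, ntip, pr$parts)
    }, 0)
    ord <- order(quick, decreasing = TRUE)[seq_len(min(top_k, length(cands)))]
    best <- NULL; best_lnl <- cur_lnl
    for (i in ord) {
      opt <- optimize_branch_lengths(cands[[i]], aln, models)
      if (attr(opt, "lnl") > best_lnl + tol) {
        best <- opt; best_lnl <- attr(opt, "lnl")
      }
    }
    if (is.null(best)) break
    cur <- best; cur_lnl <- best_lnl
  }
  attr(cur, "lnl") <- cur_lnl
  cur
}
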