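# Constrained topology searches and the approximately unbiased (AU) test
# computed from multiscale RELL bootstrap proportions of per-site
# log-likelihoods.

#' Monophyly constraint specification
#'
#' Required clades must be pairwise nested or disjoint; taxa not named in
#' any clade may attach anywhere.
#'
#' @param clades list of character vectors (taxon sets required to be
#'   monophyletic).
#' @param taxa full taxon set (checked against the clades).
#' @return object of class `constraint_spec`.
#' @export
constraint_spec <- function(clades, taxa) {
  stopifnot(is.list(clades))
  for (cl in clades) {
    if (!all(cl %in% taxa)) stop("unknown taxa in constraint: ",
                                 paste(setdiff(cl, taxa), collapse = ", "))
  }
  for (i in seq_along(clades)) for (j in seq_along(clades)) {
    if (i >= j) next
    a <- clades[[i]]; b <- clades[[j]]
    inter <- intersect(a, b)
    if (length(inter) > 0 && !all(a %in% b) && !all(b %in% a))
      stop("constraint clades must be pairwise nested or disjoint")
  }
  structure(list(clades = clades, taxa = taxa), class = "constraint_spec")
}

# random rooted binary tree respecting nested/disjoint required clades
random_constrained_tree <- function(taxa, clades, seed = 1L) {
  set.seed(seed)
  build <- function(members, sub) {
    # top-level groups: maximal clades plus free singletons
    top <- rep(TRUE, length(sub))
    for (i in seq_along(sub)) for (j in seq_along(sub)) {
      if (i != j && top[i] && all(sub[[i]] %in% sub[[j]]) &&
          length(sub[[i]]) < length(sub[[j]])) top[i] <- FALSE
    }
    groups <- list()
    used <- character(0)
    for (i in which(top)) {
      inner <- Filter(function(x) all(x %in% sub[[i]]) &&
                        length(x) < length(sub[[i]]), sub)
      groups[[length(groups) + 1L]] <- build(sub[[i]], inner)
      used <- c(used, sub[[i]])
    }
    for (s in setdiff(members, used)) groups[[length(groups) + 1L]] <- s
    # random binary join order
    while (length(groups) > 1) {
      pick <- sample.int(length(groups), 2)
      joined <- paste0("(", groups[[pick[1]]], ",", groups[[pick[2]]], ")")
      groups <- c(groups[-pick], joined)
    }
    groups[[1]]
  }
  nwk <- paste0(build(taxa, clades), ";")
  tr <- ape::read.tree(text = nwk)
  tr$edge.length <- rep(0.1, nrow(tr$edge))
  tr
}

#' Maximum-likelihood tree search under monophyly constraints
#'
#' Hill-climbing NNI search in which rearrangements breaking a required
#' clade are rejected, repeated from `n_starts` random constraint-
#' respecting starting trees (plus an NJ start when it satisfies the
#' constraint).
#'
#' @param aln alignment (matrix or [partitioned_alignment()]).
#' @param models model or per-partition model list.
#' @param constraint a [constraint_spec()] or NULL for unconstrained search.
#' @param n_starts number of random starting trees.
#' @param seed integer seed.
#' @return the best tree found (attribute `lnl`), with every required
#'   clade present as a bipartition.
#' @export
constrained_search <- function(aln, models, constraint = NULL,
                               n_starts = 10L, seed = 1L) {
  clades <- if (is.null(constraint)) NULL else constraint$clades
  taxa <- rownames(aln)
  best <- NULL
  starts <- list()
  njt <- try(nj_tree(p_distance_matrix(aln)), silent = TRUE)
  if (!inherits(njt, "try-error") &&
      (is.null(clades) || satisfies_constraint(njt, clades)))
    starts[[length(starts) + 1L]] <- njt
  for (s in seq_len(n_starts)) {
    starts[[length(starts) + 1L]] <-
      random_constrained_tree(taxa, if (is.null(clades)) list() else clades,
                              seed + s * 613L)
  }
  for (st in starts) {
    fit <- nni_search(st, aln, models, constraint = clades)
    if (is.null(best) || attr(fit, "lnl") > attr(best, "lnl")) best <- fit
  }
  best
}

#' Per-site log-likelihood matrix for a set of trees
#'
#' @param trees list of trees with branch lengths (branch lengths are
#'   re-optimized when `optimize = TRUE`).
#' @param aln alignment (matrix or [partitioned_alignment()]).
#' @param models model or per-partition model list.
#' @param optimize re-optimize branch lengths per tree.
#' @return matrix (trees x sites) of per-site log-likelihoods; row sums
#'   are the total log-likelihoods.
#' @export
site_loglik_matrix <- function(trees, aln, models, optimize = TRUE) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  rows <- lapply(trees, function(tr) {
    if (optimize) tr <- optimize_branch_lengths(tr, aln, models)
    tree_loglik(tr, aln, models, per_site = TRUE)$per_site
  })
  out <- do.call(rbind, rows)
  rownames(out) <- paste0("tree", seq_along(trees))
  out
}

#' Approximately unbiased (AU) test from per-site log-likelihoods
#'
#' Multiscale RELL bootstrap: for each scale r the sites are resampled
#' with replacement to ceiling(r * n) columns and the frequency with which
#' each tree attains the best resampled total is recorded. The normal
#' quantiles of these bootstrap proportions are regressed on
#' d * sqrt(r) + c / sqrt(r) by weighted least squares (binomial variance
#' weights, proportions clamped away from 0 and 1), and the AU p-value of
#' each tree is 1 - pnorm(d - c). Ties for the best tree are broken
#' uniformly at random, so exactly equal rows share wins.
#'
#' @param site_lnl trees x sites matrix of per-site log-likelihoods.
#' @param scales resampling scale factors (default 0.5 to 1.4 by 0.1).
#' @param reps_per_scale bootstrap replicates per scale.
#' @param seed integer seed.
#' @return object of class `au_result`: data frame with `tree`, `p_au`,
#'   `bp` (naive proportion at scale 1), `d`, `c`, `degenerate` flag.
#' @export
au_test <- function(site_lnl, scales = seq(0.5, 1.4, by = 0.1),
                    reps_per_scale = 10000L, seed = 1L) {
  stopifnot(is.matrix(site_lnl))
  ntree <- nrow(site_lnl); n <- ncol(site_lnl)
  if (ntree == 1) {
    lab <- if (is.null(rownames(site_lnl))) "tree1" else rownames(site_lnl)
    return(structure(data.frame(tree = lab, p_au = 1,
                                bp = 1, d = NA_real_, c = NA_real_,
                                degenerate = TRUE),
                     class = c("au_result", "data.frame")))
  }
  if (n < 2) stop("need at least 2 sites")
  set.seed(seed)
  B <- as.integer(reps_per_scale)
  bp <- matrix(0, ntree, length(scales))
  for (si in seq_along(scales)) {
    m <- ceiling(scales[si] * n)
    # multinomial column counts give the RELL totals directly
    counts <- stats::rmultinom(B, m, rep(1 / n, n))
    totals <- site_lnl %*% counts              # ntree x B
    # best tree per replicate; exact ties split uniformly at random
    best <- max.col(t(totals), ties.method = "random")
    bp[, si] <- tabulate(best, nbins = ntree) / B
  }
  sq <- sqrt(scales)
  X <- cbind(d = sq, c = 1 / sq)
  out <- data.frame(tree = if (is.null(rownames(site_lnl)))
                              paste0("tree", seq_len(ntree))
                            else rownames(site_lnl),
                    p_au = NA_real_, bp = bp[, which.min(abs(scales - 1))],
                    d = NA_real_, c = NA_real_, degenerate = FALSE)
  eps <- 1 / (2 * B)
  for (i in seq_len(ntree)) {
    p <- bp[i, ]
    if (all(p == 0)) {
      out$p_au[i] <- 0; out$degenerate[i] <- TRUE
      next
    }
    if (all(p == 1)) {
      out$p_au[i] <- 1; out$degenerate[i] <- TRUE
      next
    }
    pc <- pmin(pmax(p, eps), 1 - eps)
    z <- stats::qnorm(1 - pc)
    w <- B * stats::dnorm(z)^2 / (pc * (1 - pc))
    fit <- stats::lm.wfit(X, z, w)
    d <- fit$coefficients["d"]; cc <- fit$coefficients["c"]
    out$d[i] <- d; out$c[i] <- cc
    out$p_au[i] <- 1 - stats::pnorm(d - cc)
  }
  structure(out, class = c("au_result", "data.frame"))
}

#' @export
print.au_result <- function(x, ...) {
  cat("AU test over", nrow(x), "trees\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run constrained-topology hypothesis tests
#'
#' For each hypothesis, `n_starts` unconstrained and `n_starts` constrained
#' trees are inferred, pooled and deduplicated by topology; per-site
#' log-likelihoods are computed for the pool and the AU test applied. The
#' p-value range over the constrained trees is reported per hypothesis.
#'
#' @param aln alignment (matrix or [partitioned_alignment()]).
#' @param models model or per-partition model list.
#' @param hypotheses named list of [constraint_spec()] objects.
#' @param n_starts searches per (un)constrained set.
#' @param seed integer seed.
#' @param reps_per_scale AU bootstrap replicates per scale.
#' @return data frame with one row per hypothesis: `hypothesis`, `p_min`,
#'   `p_max` (over that hypothesis' constrained trees), `n_trees` tested.
#' @export
run_constraint_analysis <- function(aln, models, hypotheses, n_starts = 10L,
                                    seed = 1L, reps_per_scale = 10000L) {
  stopifnot(is.list(hypotheses), !is.null(names(hypotheses)))
  uncon <- lapply(seq_len(n_starts), function(s)
    constrained_search(aln, models, NULL, n_starts = 1L,
                       seed = seed + 17L * s))
  res <- data.frame(hypothesis = character(0), p_min = numeric(0),
                    p_max = numeric(0), n_trees = integer(0))
  for (h in names(hypotheses)) {
    con <- lapply(seq_len(n_starts), function(s)
      constrained_search(aln, models, hypotheses[[h]], n_starts = 1L,
                         seed = seed + 1009L * s))
    pool <- c(uncon, con)
    is_con <- c(rep(FALSE, length(uncon)), rep(TRUE, length(con)))
    # deduplicate by topology, keeping the constrained flag of survivors
    keep <- rep(TRUE, length(pool))
    for (i in seq_along(pool)) {
      if (!keep[i]) next
      for (j in seq_along(pool)) {
        if (j <= i || !keep[j]) next
        if (rf_distance(pool[[i]], pool[[j]]) == 0) {
          keep[j] <- FALSE
          # a topology reachable without the constraint counts as such
          if (!is_con[j]) is_con[i] <- FALSE
        }
      }
    }
    pool <- pool[keep]; is_con <- is_con[keep]
    slnl <- site_loglik_matrix(pool, aln, models, optimize = FALSE)
    au <- au_test(slnl, reps_per_scale = reps_per_scale, seed = seed)
    pv <- au$p_au[is_con]
    if (length(pv) == 0) pv <- au$p_au  # constraint matched the ML tree
    res <- rbind(res, data.frame(hypothesis = h, p_min = min(pv),
                                 p_max = max(pv), n_trees = nrow(slnl)))
  }
  res
}
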