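# Sequence simulation along a tree under GTR+Gamma with an explicit
# insertion/deletion process. Column identities are tracked through the
# whole simulation so the true alignment is available as an oracle for the
# aligner and the refinement loop.

#' Simulate a rooted binary tree under a Yule (pure-birth) process
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate speciation rate (> 0).
#' @param seed integer seed; the same seed gives an identical tree.
#' @return a rooted binary `phylo` with tips `t1 ... tn` and positive
#'   branch lengths.
#' @export
simulate_yule <- function(n_taxa, birth_rate = 1, seed = 1L) {
  if (!is.numeric(n_taxa) || n_taxa < 2) stop("'n_taxa' must be >= 2")
  if (birth_rate <= 0) stop("'birth_rate' must be > 0")
  set.seed(seed)
  tr <- ape::rphylo(as.integer(n_taxa), birth = birth_rate, death = 0)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  # guard against zero-length branches (rphylo can round tiny waiting times)
  tr$edge.length[tr$edge.length <= 0] <- 1e-8
  tr
}

#' Evolve sequences along a tree with substitutions and indels
#'
#' Substitutions follow `subst` (GTR+Gamma; each column keeps its gamma
#' category for the whole tree). Indel events occur along each branch as
#' Poisson processes with per-site rates from `indels`; fragment lengths are
#' geometric. Insertions place new, unrelated residues (drawn from `pi`)
#' uniformly between existing sites; deletions start at a uniform site and
#' are truncated at the sequence end. Column identities are preserved, so
#' the true multiple alignment of the tip sequences is returned alongside
#' the unaligned sequences.
#'
#' @param tree rooted binary `phylo` with branch lengths.
#' @param subst a [gtr_model()].
#' @param indels an [indel_model()].
#' @param root_length number of sites in the root sequence (>= 1).
#' @param seed integer seed.
#' @param rate_scale multiplier applied to all branch lengths (per-locus
#'   rate scaler).
#' @return An object of class `true_history`: list with `tree`, `true_msa`
#'   (character matrix over tips), `sequences` (ungapped tip sequences),
#'   `n_ins_events`, `n_del_events`.
#' @export
evolve_along_tree <- function(tree, subst, indels, root_length,
                              seed = 1L, rate_scale = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(subst, "gtr_model"),
            inherits(indels, "indel_model"))
  if (root_length < 1) stop("'root_length' must be >= 1")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  ncat <- subst$ncat
  rates <- subst$rates

  # per-column state, indexed by column id
  cat_of <- integer(0)
  next_id <- 1L
  new_cols <- function(n) {
    ids <- seq.int(next_id, length.out = n)
    next_id <<- next_id + n
    cat_of[ids] <<- sample.int(ncat, n, replace = TRUE)
    ids
  }

  master <- integer(0)           # global column order (the true alignment)
  master_insert <- function(ids, after_id, before_id) {
    if (!is.na(after_id)) {
      k <- match(after_id, master)
      master <<- append(master, ids, after = k)
    } else if (!is.na(before_id)) {
      k <- match(before_id, master)
      master <<- append(master, ids, after = k - 1L)
    } else {
      master <<- c(master, ids)
    }
  }

  root_ids <- new_cols(root_length)
  master <- root_ids
  root_seq <- list(ids = root_ids,
                   base = sample.int(4L, root_length, replace = TRUE,
                                     prob = subst$pi))

  n_ins_events <- 0L
  n_del_events <- 0L

  evolve_branch <- function(sq, t) {
    t <- t * rate_scale
    # indel events, counts drawn at branch-start length, applied sequentially
    L0 <- length(sq$ids)
    n_ins <- stats::rpois(1, indels$ins_rate * (L0 + 1) * t)
    n_del <- stats::rpois(1, indels$del_rate * L0 * t)
    ev <- sample(c(rep("i", n_ins), rep("d", n_del)))
    for (e in ev) {
      L <- length(sq$ids)
      len <- stats::rgeom(1, indels$len_p) + 1L
      if (e == "i") {
        pos <- sample.int(L + 1L, 1L) - 1L      # 0 .. L, uniform
        ids <- new_cols(len)
        after_id <- if (pos > 0) sq$ids[pos] else NA_integer_
        before_id <- if (pos == 0 && L > 0) sq$ids[1] else NA_integer_
        master_insert(ids, after_id, before_id)
        sq$ids <- append(sq$ids, ids, after = pos)
        sq$base <- append(sq$base,
                          sample.int(4L, len, replace = TRUE, prob = subst$pi),
                          after = pos)
        n_ins_events <<- n_ins_events + 1L
      } else {
        if (L == 0) next
        start <- sample.int(L, 1L)
        drop <- start:min(L, start + len - 1L)
        sq$ids <- sq$ids[-drop]
        sq$base <- sq$base[-drop]
        n_del_events <<- n_del_events + 1L
      }
    }
    # substitutions, vectorized per gamma category and starting base
    if (length(sq$ids) > 0 && t > 0) {
      cats <- cat_of[sq$ids]
      old <- sq$base
      for (k in unique(cats)) {
        P <- transition_matrix(subst, t * rates[k])
        idx <- which(cats == k)
        for (a in 1:4) {
          ii <- idx[old[idx] == a]
          if (length(ii) > 0)
            sq$base[ii] <- sample.int(4L, length(ii), replace = TRUE,
                                      prob = P[a, ])
        }
      }
    }
    sq
  }

  # preorder traversal
  tr <- ape::reorder.phylo(tree, "cladewise")
  node_seq <- vector("list", ntip + nnode)
  node_seq[[ntip + 1L]] <- root_seq
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    node_seq[[ch]] <- evolve_branch(node_seq[[p]], tr$edge.length[e])
  }

  # true alignment over columns present in at least one tip
  tip_seqs <- node_seq[seq_len(ntip)]
  used <- sort(unique(unlist(lapply(tip_seqs, `[[`, "ids"))))
  cols <- master[master %in% used]
  aln <- matrix("-", ntip, length(cols),
                dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(ntip)) {
    k <- match(tip_seqs[[i]]$ids, cols)
    aln[i, k] <- bases[tip_seqs[[i]]$base]
  }
  seqs <- stats::setNames(
    vapply(tip_seqs, function(s) paste0(bases[s$base], collapse = ""), ""),
    tree$tip.label)
  structure(list(tree = tree, true_msa = aln, sequences = seqs,
                 n_ins_events = n_ins_events, n_del_events = n_del_events),
            class = "true_history")
}

#' @export
print.true_history <- function(x, ...) {
  cat("Simulated history:", nrow(x$true_msa), "taxa,",
      ncol(x$true_msa), "true-alignment columns,",
      x$n_ins_events, "insertions,", x$n_del_events, "deletions\n")
  invisible(x)
}

#' Default three-locus configuration
#'
#' One fast, indel-rich ITS-like locus plus two slower indel-free loci
#' (nrLSU-like and EF1-alpha-like), all evolved on the same tree with
#' per-locus rate scalers.
#'
#' @return a named list of locus specifications.
#' @export
default_locus_config <- function() {
  list(
    ITS = list(root_length = 300L, rate_scale = 0.10,
               indels = indel_model(0.02, 0.02, 0.5)),
    LSU = list(root_length = 500L, rate_scale = 0.03,
               indels = indel_model(0, 0, 0.5)),
    EF  = list(root_length = 450L, rate_scale = 0.05,
               indels = indel_model(0, 0, 0.5))
  )
}

#' Simulate a multilocus dataset with known truth
#'
#' All loci are evolved on one shared tree. Loci with zero indel rates come
#' out as gapless alignments; indel-rich loci additionally retain their true
#' alignment. Per-locus random streams are derived from the root seed.
#'
#' @param n_taxa number of tips (ignored if `tree` is given).
#' @param seed root seed; per-locus seeds are derived from it.
#' @param config locus configuration as in [default_locus_config()].
#' @param subst a [gtr_model()] shared by all loci.
#' @param tree optional rooted binary `phylo` to use instead of simulating.
#' @param birth_rate Yule rate for the simulated tree.
#' @return list with `tree` and `loci` (per locus: the `true_history`, the
#'   unaligned `sequences`, and `alignment` = the true alignment).
#' @export
simulate_dataset <- function(n_taxa = 16L, seed = 1L,
                             config = default_locus_config(),
                             subst = gtr_model(pi = c(0.26, 0.22, 0.24, 0.28),
                                               exch = c(1, 3, 1.5, 1.2, 3.5, 1),
                                               alpha = 0.8),
                             tree = NULL, birth_rate = 1) {
  if (anyDuplicated(names(config))) stop("duplicate locus names")
  if (is.null(names(config)) || any(names(config) == ""))
    stop("loci must be named")
  if (is.null(tree)) tree <- simulate_yule(n_taxa, birth_rate, seed)
  loci <- vector("list", length(config))
  names(loci) <- names(config)
  for (i in seq_along(config)) {
    cf <- config[[i]]
    locus_seed <- (as.integer(seed) %% 1000003L) * 101L + i * 1009L
    h <- evolve_along_tree(tree, subst, cf$indels, cf$root_length,
                           seed = locus_seed, rate_scale = cf$rate_scale)
    loci[[i]] <- list(history = h, sequences = h$sequences,
                      alignment = h$true_msa)
  }
  list(tree = tree, loci = loci, subst = subst, config = config, seed = seed)
}
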