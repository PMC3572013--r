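# Independent reference implementations used as oracles. These deliberately
# take the slow, direct route (explicit enumeration, quadratic scans) and
# share no code with the package internals they check.

# Brute-force GTR+Gamma tree likelihood: sum over all internal-node state
# assignments and gamma categories. Gaps/'?' at tips are summed over too.
brute_force_loglik <- function(tree, aln, model) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  ints <- sort(unique(tr$edge[, 1]))
  m <- aln[tr$tip.label, , drop = FALSE]
  states <- match(m, c("A", "C", "G", "T"))
  dim(states) <- dim(m)
  ncat <- length(model$rates)
  Pcat <- lapply(seq_len(ncat), function(cat)
    lapply(seq_len(nrow(tr$edge)), function(e)
      transition_matrix(model, tr$edge.length[e] * model$rates[cat])))
  tot <- 0
  for (site in seq_len(ncol(m))) {
    tip_sets <- lapply(seq_len(ntip), function(i) {
      s <- states[i, site]
      if (is.na(s)) 1:4 else s
    })
    Lsite <- 0
    for (cat in seq_len(ncat)) {
      P <- Pcat[[cat]]
      grid <- expand.grid(c(tip_sets,
                            rep(list(1:4), length(ints))))
      s <- 0
      for (r in seq_len(nrow(grid))) {
        asgn <- integer(nn)
        asgn[seq_len(ntip)] <- as.integer(grid[r, seq_len(ntip)])
        asgn[ints] <- as.integer(grid[r, ntip + seq_along(ints)])
        pr <- model$pi[asgn[root]]
        for (e in seq_len(nrow(tr$edge)))
          pr <- pr * P[[e]][asgn[tr$edge[e, 1]], asgn[tr$edge[e, 2]]]
        s <- s + pr
      }
      Lsite <- Lsite + s / ncat
    }
    tot <- tot + log(Lsite)
  }
  tot
}

# the 15 distinct unrooted 5-taxon topologies as newick strings
all_five_taxon_topologies <- function(labels = c("a", "b", "c", "d", "e")) {
  stopifnot(length(labels) == 5)
  out <- character(0)
  # choose the cherry pair {i, j} and the taxon k attached to the middle
  for (i in 1:4) for (j in (i + 1):5) {
    rest <- setdiff(1:5, c(i, j))
    for (k in rest) {
      oth <- setdiff(rest, k)
      nwk <- sprintf("((%s,%s),%s,(%s,%s));", labels[i], labels[j], labels[k],
                     labels[oth[1]], labels[oth[2]])
      out <- c(out, nwk)
    }
  }
  trees <- lapply(out, function(x) ape::read.tree(text = x))
  # deduplicate by RF distance
  keep <- rep(TRUE, length(trees))
  for (i in seq_along(trees)) for (j in seq_along(trees)) {
    if (j <= i || !keep[i] || !keep[j]) next
    if (phangorn::RF.dist(trees[[i]], trees[[j]]) == 0) keep[j] <- FALSE
  }
  trees[keep]
}

# quadratic reference for simple indel coding: enumerate gap runs per row,
# collect distinct internal extents, score each (row, extent) pair directly
sic_reference <- function(msa, terminal_gaps = "missing") {
  L <- ncol(msa)
  row_runs <- function(i) {
    x <- msa[i, ] == "-"
    runs <- list()
    j <- 1
    while (j <= L) {
      if (x[j]) {
        k <- j
        while (k < L && x[k + 1]) k <- k + 1
        runs[[length(runs) + 1]] <- c(j, k)
        j <- k + 1
      } else j <- j + 1
    }
    runs
  }
  allruns <- lapply(seq_len(nrow(msa)), row_runs)
  extents <- unique(do.call(rbind, c(list(matrix(0, 0, 2)),
                                     lapply(allruns, function(r)
                                       if (length(r)) do.call(rbind, r)
                                       else matrix(0, 0, 2)))))
  if (terminal_gaps == "missing" && nrow(extents) > 0) {
    term <- extents[, 1] == 1 | extents[, 2] == L
    extents <- extents[!term, , drop = FALSE]
  }
  if (nrow(extents) > 0)
    extents <- extents[order(extents[, 1], extents[, 2]), , drop = FALSE]
  sc <- matrix(0L, nrow(msa), nrow(extents))
  for (i in seq_len(nrow(msa))) for (k in seq_len(nrow(extents))) {
    s <- extents[k, 1]; e <- extents[k, 2]
    val <- 0L
    for (r in allruns[[i]]) {
      term_r <- terminal_gaps == "missing" && (r[1] == 1 || r[2] == L)
      if (!term_r && r[1] == s && r[2] == e) { val <- 1L; break }
      contains <- r[1] <= s && r[2] >= e
      strict <- contains && (r[1] < s || r[2] > e)
      if ((term_r && contains) || strict) { val <- NA_integer_; break }
    }
    sc[i, k] <- val
  }
  rownames(sc) <- rownames(msa)
  list(matrix = sc, characters = extents)
}

# naive Robinson-Foulds via explicit bipartition sets
rf_reference <- function(t1, t2) {
  sides <- function(tr) {
    tr <- ape::unroot(tr)
    taxa <- sort(tr$tip.label)
    out <- character(0)
    tr <- ape::reorder.phylo(tr, "postorder")
    ntip <- length(tr$tip.label)
    below <- vector("list", ntip + tr$Nnode)
    for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      below[[p]] <- c(below[[p]], below[[ch]])
      if (ch > ntip) {
        side <- sort(below[[ch]])
        if (length(side) >= 2 && length(side) <= ntip - 2) {
          if (!(taxa[1] %in% side)) side <- sort(setdiff(taxa, side))
          out <- c(out, paste(side, collapse = "|"))
        }
      }
    }
    unique(out)
  }
  a <- sides(t1); b <- sides(t2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# random alignment with gap runs for indel-coding tests
random_gappy_alignment <- function(ntaxa, ncols, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * ncols, replace = TRUE),
              ntaxa, ncols, dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  for (i in seq_len(ntaxa)) {
    nruns <- sample(0:4, 1)
    for (r in seq_len(nruns)) {
      start <- sample.int(ncols, 1)
      len <- sample.int(6, 1)
      m[i, start:min(ncols, start + len - 1)] <- "-"
    }
  }
  m
}

# a balanced 8-tip test tree with resolvable internal branches
balanced8 <- function(bl = 1) {
  ape::read.tree(text = sprintf(
    "(((a:%f,b:%f):%f,(c:%f,d:%f):%f):%f,((e:%f,f:%f):%f,(g:%f,h:%f):%f):%f);",
    bl, bl, bl, bl, bl, bl, bl, bl, bl, bl, bl, bl, bl, bl))
}
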