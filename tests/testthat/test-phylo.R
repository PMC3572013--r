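test_that("p-distances use pairwise deletion and a comparability fallback", {
  m <- msa_from_strings(c(a = "ACGT", b = "ACGT"))
  expect_equal(p_distance_matrix(m)["a", "b"], 0)
  m <- msa_from_strings(c(a = "ACGT", b = "ACGA"))
  expect_equal(p_distance_matrix(m)["a", "b"], 0.25)
  m <- msa_from_strings(c(a = "AC-T", b = "ACGT"))
  expect_equal(p_distance_matrix(m)["a", "b"], 0)        # 3 comparable sites
  m <- msa_from_strings(c(a = "A---", b = "-CGT"))
  expect_equal(p_distance_matrix(m, max_dist = 0.9)["a", "b"], 0.9)
  D <- p_distance_matrix(msa_from_strings(c(a = "ACGT", b = "TGCA",
                                            c = "ACCT")))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
})

test_that("NJ recovers additive trees exactly, with branch lengths", {
  # three taxa: closed-form branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), letters[1:3])
  cp <- ape::cophenetic.phylo(tr)[letters[1:3], letters[1:3]]
  expect_equal(cp, D, tolerance = 1e-12)
  # additive five-taxon matrix from a known tree
  set.seed(7)
  src <- ape::rtree(5)
  D5 <- ape::cophenetic.phylo(src)
  tr5 <- nj_tree(D5)
  expect_equal(rf_distance(tr5, src), 0)
  expect_equal(ape::cophenetic.phylo(tr5)[rownames(D5), colnames(D5)], D5,
               tolerance = 1e-9)
  expect_error(nj_tree(D[1:2, 1:2]), "at least 3")
})

test_that("NJ picks the least-squares topology on ultrametric 4-taxon data", {
  # brute-force oracle: ordinary least squares over the 3 topologies
  set.seed(11)
  tr <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1.2,d:1.2):0.3);")
  D <- ape::cophenetic.phylo(tr) + 0 # exact additive, unique optimum
  fitted <- nj_tree(D)
  tops <- list("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  # ordinary least squares via phangorn
  ss <- vapply(tops, function(nwk) {
    t0 <- ape::unroot(ape::read.tree(text = nwk))
    f <- phangorn::nnls.tree(as.dist(D), t0, method = "unrooted")
    sum((ape::cophenetic.phylo(f)[rownames(D), colnames(D)] - D)^2)
  }, 0)
  best <- ape::read.tree(text = tops[[which.min(ss)]])
  expect_equal(rf_distance(fitted, best), 0)
})

test_that("pruning likelihood matches limits and is rerooting-invariant", {
  m <- gtr_model(pi = c(0.3, 0.2, 0.3, 0.2), exch = c(1, 2, 1, 1, 2, 1),
                 alpha = 0.7)
  # identical sequences at vanishing distance: lnL -> sum log pi
  aln <- msa_from_strings(c(a = "ACGT", b = "ACGT"))
  tr <- ape::read.tree(text = "(a:1e-9,b:1e-9);")
  expect_equal(tree_loglik(tr, aln, m), sum(log(m$pi[c(1, 2, 3, 4)])),
               tolerance = 1e-6)
  # rerooting invariance on an unrooted 6-taxon tree
  set.seed(5)
  tr6 <- ape::unroot(ape::rtree(6))
  aln6 <- msa_from_strings(setNames(
    replicate(6, paste0(sample(c("A", "C", "G", "T"), 30, TRUE),
                        collapse = "")), tr6$tip.label))
  l0 <- tree_loglik(tr6, aln6, m)
  for (og in c("t2", "t5")) {
    tr_r <- ape::root(tr6, outgroup = og, resolve.root = FALSE)
    expect_equal(tree_loglik(tr_r, aln6, m), l0, tolerance = 1e-9)
  }
})

test_that("per-site log-likelihoods sum to the total, gaps as missing", {
  m <- gtr_model(alpha = 0.9)
  set.seed(2)
  tr <- ape::rtree(5)
  aln <- msa_from_strings(setNames(c("ACG-TACGTA", "AC?TTACGTA", "GCGTTAC-TA",
                                     "ACGTTACGAA", "ACGTT?CGTA"),
                                   tr$tip.label))
  res <- tree_loglik(tr, aln, m, per_site = TRUE)
  expect_length(res$per_site, 10)
  expect_equal(sum(res$per_site), res$total, tolerance = 1e-9)
  expect_equal(res$total, brute_force_loglik(tr, aln, m), tolerance = 1e-8)
})

test_that("partitioned likelihood is the sum of per-partition likelihoods", {
  set.seed(3)
  tr <- ape::rtree(4)
  m1 <- gtr_model(pi = c(0.4, 0.2, 0.2, 0.2), alpha = 0.5)
  m2 <- gtr_model(pi = c(0.1, 0.4, 0.4, 0.1), alpha = 2)
  a1 <- msa_from_strings(setNames(c("ACGTAC", "ACGTTC", "GCGTAC", "ACATAC"),
                                  tr$tip.label))
  a2 <- msa_from_strings(setNames(c("TTTT", "TTCT", "TGTT", "CTTT"),
                                  tr$tip.label))
  pa <- partitioned_alignment(cbind(a1, a2), list(p1 = c(1, 6), p2 = c(7, 10)))
  tot <- tree_loglik(tr, pa, list(p1 = m1, p2 = m2))
  expect_equal(tot, tree_loglik(tr, a1, m1) + tree_loglik(tr, a2, m2),
               tolerance = 1e-9)
})

test_that("NNI search finds the 4-taxon optimum and improves monotonically", {
  set.seed(13)
  src <- ape::read.tree(text = "((a:0.15,b:0.15):0.2,(c:0.15,d:0.15):0.2);")
  m <- gtr_model(alpha = 1)
  h <- evolve_along_tree(src, m, indel_model(0, 0, 0.5), 400, seed = 6)
  aln <- h$true_msa
  # exhaustive oracle: optimize every 4-taxon topology fully
  tops <- lapply(c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));"),
                 function(x) ape::read.tree(text = x))
  lnls <- vapply(tops, function(t0) {
    t0$edge.length <- rep(0.1, nrow(t0$edge))
    attr(optimize_branch_lengths(t0, aln, m, nsweeps = 20, tol = 1e-6), "lnl")
  }, 0)
  start <- tops[[2]]
  start$edge.length <- rep(0.1, nrow(start$edge))
  found <- nni_search(start, aln, m)
  expect_equal(attr(found, "lnl"), max(lnls), tolerance = 1e-3)
  # starting at the optimum returns the same topology
  again <- nni_search(found, aln, m)
  expect_equal(rf_distance(again, found), 0)
  expect_gte(attr(again, "lnl"), attr(found, "lnl") - 1e-6)
})

test_that("bootstrap supports are frequencies and deterministic", {
  set.seed(1)
  src <- balanced8(0.3)
  h <- evolve_along_tree(src, gtr_model(), indel_model(0, 0, 0.5), 500,
                         seed = 14)
  b1 <- bootstrap_support(h$true_msa, "nj", reps = 50, seed = 9)
  b2 <- bootstrap_support(h$true_msa, "nj", reps = 50, seed = 9)
  expect_identical(b1$support, b2$support)
  expect_true(all(b1$support >= 0 & b1$support <= 1))
  # strong clean signal: true splits at high support
  true_keys <- indelrefine:::tree_splits(src)
  expect_true(all(b1$support[true_keys] >= 0.95))
})

test_that("an alignment of repeated identical columns bootstraps to 0/1", {
  col <- c(a = "A", b = "A", c = "T", d = "T", e = "G")
  m <- matrix(rep(col, 40), nrow = 5,
              dimnames = list(names(col), NULL))
  b <- bootstrap_support(m, "nj", reps = 20, seed = 2)
  expect_true(all(b$support %in% c(0, 1)))
})

test_that("majority consensus applies the strict >50% rule", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  t3 <- ape::read.tree(text = "((a,b),(c,d),e);")
  cons <- majority_consensus(list(t1, t2, t3))
  keys <- indelrefine:::tree_splits(cons)
  expect_true(all(c("a,b", "a,b,e") %in% keys) ||
                all(c("a,b", "a,b,d") %in% keys) == FALSE) # {c,d} kept as complement
  expect_equal(rf_distance(cons, t1), 0)
  # identical input trees reproduce themselves with all frequencies 1
  cons_same <- majority_consensus(list(t1, t1, t1))
  expect_equal(rf_distance(cons_same, t1), 0)
  expect_true(all(as.numeric(cons_same$node.label[cons_same$node.label != ""])
                  == 1))
  # split in exactly half of the trees is excluded
  cons2 <- majority_consensus(list(t1, t2))
  keys2 <- indelrefine:::tree_splits(cons2)
  expect_false(any(grepl("^c,d$|^c,e$", keys2)))
  expect_true("a,b" %in% keys2)
})

test_that("polytomies resolve to binary trees with zero-length branches", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  r <- resolve_polytomies(star, seed = 3)
  expect_true(ape::is.binary(r))
  expect_equal(sort(r$edge.length), c(0, 1, 1, 1, 1))
  # already binary: unchanged
  bin <- ape::read.tree(text = "((a:1,b:1):1,c:1,d:1);")
  expect_identical(resolve_polytomies(bin, 1), bin)
  # n-taxon star gains n - 3 internal branches
  star8 <- ape::read.tree(text = paste0("(", paste0("t", 1:8, ":1",
                                                    collapse = ","), ");"))
  r8 <- resolve_polytomies(star8, seed = 4)
  expect_true(ape::is.binary(r8))
  expect_equal(sum(r8$edge.length == 0), 8 - 3)
  expect_identical(ape::write.tree(resolve_polytomies(star8, seed = 4)),
                   ape::write.tree(r8))
})

test_that("RF distance agrees with a naive bipartition-set oracle", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(rf_distance(t1, t1), 0)
  expect_equal(rf_distance(t1, t2), 2)
  set.seed(21)
  for (k in 1:10) {
    x <- ape::rtree(8); y <- ape::rtree(8)
    expect_equal(rf_distance(x, y), rf_reference(x, y))
  }
})

test_that("conflict detection reports exactly the constructed conflicts", {
  taxa <- c("A", "B", "C", "D", "E")
  sup <- function(keys, s) structure(list(taxa = taxa,
                                          support = setNames(s, keys),
                                          reps = 100),
                                     class = "bootstrap_support")
  s1 <- sup("A,B", 0.90)
  s2 <- sup("A,C", 0.85)
  out <- detect_conflicts(s1, s2, threshold = 0.70)
  expect_equal(nrow(out), 1)
  expect_equal(out$split1, "A,B")
  expect_equal(out$split2, "A,C")
  # identical maps: nothing
  expect_equal(nrow(detect_conflicts(s1, s1)), 0)
  # below threshold: nothing
  expect_equal(nrow(detect_conflicts(s1, sup("A,C", 0.65))), 0)
  # compatible splits: nothing even at high support
  expect_equal(nrow(detect_conflicts(s1, sup("A,B,C", 0.99))), 0)
})
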