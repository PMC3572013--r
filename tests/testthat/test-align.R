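linear_params <- function(match = 2, mismatch = -1, gap = -2, fix = TRUE)
  align_params(match = match, mismatch = mismatch,
               gap_open = gap, gap_extend = gap, fix_insertions = fix)

test_that("pairwise alignment handles identity, gaps and degenerate input", {
  p <- linear_params()
  r <- pairwise_align("ACGT", "ACGT", p)
  expect_equal(r$score, 4 * 2)
  expect_true(all(r$alignment != "-"))

  # expected values frozen from exhaustive enumeration of all global
  # alignments of ACGT vs AGT under match 2 / mismatch -1 / gap -2
  r <- pairwise_align("ACGT", "AGT", p)
  expect_equal(r$score, 4)
  expect_equal(unname(apply(r$alignment, 1, paste0, collapse = "")),
               c("ACGT", "A-GT"))

  r <- pairwise_align("", "ACG", p)
  expect_equal(ncol(r$alignment), 3)
  expect_equal(unname(r$alignment[1, ]), c("-", "-", "-"))
  expect_equal(r$score, 3 * -2)
})

test_that("pairwise optimum matches exhaustive search on random pairs", {
  # enumeration oracle: all global alignments via recursion
  best_score <- function(x, y, match, mismatch, gap) {
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    memo <- new.env()
    rec <- function(i, j) {
      key <- paste(i, j)
      if (!is.null(memo[[key]])) return(memo[[key]])
      res <- if (i == 0 && j == 0) 0
      else {
        cand <- -Inf
        if (i > 0 && j > 0)
          cand <- max(cand, rec(i - 1, j - 1) +
                        if (xs[i] == ys[j]) match else mismatch)
        if (i > 0) cand <- max(cand, rec(i - 1, j) + gap)
        if (j > 0) cand <- max(cand, rec(i, j - 1) + gap)
        cand
      }
      memo[[key]] <- res
      res
    }
    rec(length(xs), length(ys))
  }
  set.seed(42)
  p <- linear_params()
  for (k in 1:20) {
    x <- paste0(sample(c("A", "C", "G", "T"), sample(3:9, 1), TRUE),
                collapse = "")
    y <- paste0(sample(c("A", "C", "G", "T"), sample(3:9, 1), TRUE),
                collapse = "")
    expect_equal(pairwise_align(x, y, p)$score, best_score(x, y, 2, -1, -2))
  }
})

test_that("two-sequence progressive alignment equals the pairwise core", {
  p <- linear_params()
  seqs <- c(x = "ACGTTGCA", y = "ACGTGCA")
  guide <- ape::read.tree(text = "(x:0.25,y:0.25);")
  pro <- progressive_align(seqs, guide, p)
  pw <- pairwise_align(seqs[["x"]], seqs[["y"]], p)
  expect_identical(unname(unclass(pro)[c("x", "y"), ]),
                   unname(pw$alignment))
})

test_that("identical sequences align without gaps under any guide", {
  seqs <- setNames(rep("ACGTACGTAC", 4), c("a", "b", "c", "d"))
  for (nwk in c("((a:1,b:1):1,(c:1,d:1):1);", "((a:1,c:1):1,(b:1,d:1):1);")) {
    g <- ape::read.tree(text = nwk)
    aln <- progressive_align(seqs, g, align_params(fix_insertions = FALSE))
    expect_equal(ncol(aln), 10)
    expect_true(all(unclass(aln) != "-"))
    aln2 <- progressive_align(seqs, g, align_params(fix_insertions = TRUE))
    expect_true(all(unclass(aln2) != "-"))
  }
})

test_that("a misgrouping guide tree splits a shared insertion block", {
  # A and B share block X; C and D lack it
  core <- "ACGGTCAATGCC"
  X <- "TTTTTT"
  seqs <- c(A = paste0(substr(core, 1, 6), X, substr(core, 7, 12)),
            B = paste0(substr(core, 1, 6), X, substr(core, 7, 12)),
            C = core, D = core)
  good <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.2);")
  bad <- ape::read.tree(text = "((A:0.1,C:0.1):0.2,(B:0.1,D:0.1):0.2);")
  p <- align_params(fix_insertions = TRUE)
  aln_good <- progressive_align(seqs, good, p)
  aln_bad <- progressive_align(seqs, bad, p)
  expect_equal(ncol(aln_good), nchar(seqs[["A"]]))
  expect_gt(ncol(aln_bad), ncol(aln_good))
  # under the bad guide the X block appears as (at least) two disjoint
  # insertion blocks: insertion-origin columns where only A (only B) has
  # residues
  org <- attr(aln_bad, "origin")
  ins_cols <- grep("^ins@", org)
  m <- unclass(aln_bad)
  only_a <- sum(m["A", ins_cols] != "-" & m["B", ins_cols] == "-" &
                  m["C", ins_cols] == "-" & m["D", ins_cols] == "-")
  only_b <- sum(m["B", ins_cols] != "-" & m["A", ins_cols] == "-" &
                  m["C", ins_cols] == "-" & m["D", ins_cols] == "-")
  expect_gte(only_a, nchar(X))
  expect_gte(only_b, nchar(X))
})

test_that("alignments always de-gap to their inputs and are wide enough", {
  for (seed in 1:4) {
    d <- simulate_dataset(8, seed = seed)
    seqs <- d$loci$ITS$sequences
    for (guide in list(d$tree, random_guide_tree(names(seqs), seed))) {
      aln <- progressive_align(seqs, guide)
      expect_identical(degap(unclass(aln)[names(seqs), ]), seqs)
      expect_gte(ncol(aln), max(nchar(seqs)))
      expect_equal(length(attr(aln, "origin")), ncol(aln))
      # permanent insertion columns have residues only below their origin
      org <- attr(aln, "origin")
      perm <- attr(aln, "permanent")
      expect_true(all(grepl("^ins@", org[perm])))
    }
  }
})

test_that("true-guide alignment recovers almost all true homologies", {
  # low-divergence simulation
  cfg <- default_locus_config()["ITS"]
  cfg$ITS$rate_scale <- 0.04
  rec <- vapply(1:5, function(seed) {
    d <- simulate_dataset(10, seed = seed, config = cfg)
    gt <- d$tree
    gt$edge.length <- gt$edge.length * cfg$ITS$rate_scale
    aln <- progressive_align(d$loci$ITS$sequences, gt)
    column_pair_recall(unclass(aln), d$loci$ITS$alignment)
  }, 0)
  expect_gte(mean(rec), 0.9)
})

test_that("guide/sequence mismatches are reported with names", {
  seqs <- c(a = "ACGT", b = "ACGT")
  g <- ape::read.tree(text = "(a:1,zzz:1);")
  expect_error(progressive_align(seqs, g), "zzz")
})
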