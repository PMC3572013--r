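# indelrefine

Iterative guide-tree refinement for the alignment and phylogenetic
analysis of indel-rich loci.

## The problem

Fast-evolving non-coding markers such as the nuclear ribosomal ITS region
accumulate insertions and deletions, and progressive aligners place those
indels according to a guide tree. Aligners that permanently *fix* inferred
insertions (once a column is created as an insertion it is never matched
again) are especially sensitive: under a poor guide tree a single
homologous insertion block is inferred as several independent events, and
the alignment grows without gaining false homologies — **alignment
undermatching**. The remedy implemented here is iterative: use the
phylogenetic signal of easily aligned loci to estimate a better tree, feed
it back as the guide tree, realign, and repeat until the topology
stabilizes.

Formally, sequences evolve under GTR+Γ (rate matrix scaled to one expected
substitution per site per unit branch length, four discrete gamma
categories), indels arise as Poisson events along branches with geometric
fragment lengths, and alignment quality is scored against the simulator's
true alignment by the column-count ratio `len(inferred) / len(true)` (the
undermatching index) and by homologous column-pair recall. Downstream
stages implement simple indel coding (each distinct gap extent becomes a
binary presence/absence character, with `?` for taxa whose gaps strictly
contain the extent), the 70 %-bootstrap conflict test between loci,
constrained topology searches with the approximately unbiased (AU) test
(multiscale RELL bootstrap, p = 1 − Φ(d − c)), and Mk-model
ancestral-state reconstruction with stochastic character mapping.

The package is aimed at method-minded phylogeneticists who want the whole
loop — simulator, aligner, tree machinery, refinement, indel coding, ASR,
topology tests — as small, testable R functions with known-truth oracles.

## A worked example

```r
library(indelrefine)

# a 16-taxon, three-locus dataset with known truth: one indel-rich
# ITS-like locus plus two indel-free loci on a shared tree
d <- simulate_dataset(16, seed = 11)

fit <- refine(d$loci$ITS$sequences,
              list(LSU = d$loci$LSU$alignment, EF = d$loci$EF$alignment),
              seed = 5)
print(fit)
#> Iterative guide-tree refinement (multilocus mode)
#>   iterations: 2 (converged, RF = 0)
#>   alignment length: 364 -> 364 columns

rf_distance(fit$tree, d$tree)
#> [1] 0

undermatching_index(fit$alignment, d$loci$ITS$alignment)
#> [1] 1.155556
```

The loop aligned the ITS-like locus, estimated a maximum-likelihood tree
from the filtered concatenation, fed it back as the guide, and stopped as
soon as the topology stopped changing (Robinson–Foulds distance 0 between
successive trees). Here it converged in two iterations, recovered the true
topology exactly, and the final alignment is 15.6 % longer than the true
alignment. Contrast a deliberately bad guide:

```r
seqs <- d$loci$ITS$sequences
gt <- d$tree
gt$edge.length <- gt$edge.length * 0.10        # the locus' own rate scale
rg <- random_guide_tree(names(seqs), seed = 1, template = gt)
ncol(progressive_align(seqs, rg))   # 447 columns
ncol(progressive_align(seqs, gt))   # 364 columns
ncol(d$loci$ITS$alignment)          # 315 true columns
```

The random-topology guide inflates the alignment by ~42 % over the true
alignment — the undermatching signature — while the true guide stays
within ~16 %. Downstream:

```r
m <- unclass(fit$alignment)
attr(m, "origin") <- NULL; attr(m, "permanent") <- NULL
ic <- simple_indel_coding(m)
ncol(ic$matrix)                      # 61 indel characters
count_parsimony_informative(ic)      # 38 of them parsimony-informative
```

See the vignette (`vignettes/guide-tree-refinement.Rmd`) for the models,
parameter meanings, and numerical choices.

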