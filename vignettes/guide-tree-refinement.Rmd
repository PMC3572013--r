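---
title: "Guide-tree refinement for indel-rich loci: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide-tree refinement for indel-rich loci: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelrefine)
```

## The problem

Fast-evolving, non-coding phylogenetic markers such as the nuclear
ribosomal internal transcribed spacer (ITS) accumulate insertions and
deletions at a high rate. Progressive multiple aligners place those indels
according to a guide tree, and aligners that *fix* inferred insertions
(so that a column once created as an insertion is never matched again)
depend on that guide tree even more strongly: when the guide tree groups
the wrong sequences, a single homologous insertion block is inferred as
two or more independent insertion events. The alignment grows without
gaining false homologies — *alignment undermatching*. This package
implements that mechanism at desk scale and the iterative remedy: use
phylogenetic signal from easily aligned loci to build a better guide tree,
realign, re-estimate, and repeat until the topology stabilizes.

`indelrefine` contains the full loop and its downstream stages:

* a multilocus sequence simulator with an explicit indel process that
  retains the true alignment and true tree as oracles;
* an insertion-aware progressive aligner with permanent insertion fixing;
* partitioned GTR+Γ likelihood machinery (NJ, NNI search, bootstrap,
  consensus, RF distances, a 70 %-bootstrap conflict test);
* the iterative refinement loop (`refine()`);
* simple indel coding of gaps into binary characters;
* Mk-model ancestral-state reconstruction with stochastic mapping;
* constrained topology searches and the approximately unbiased (AU) test.

## The simulator

Sequences evolve along a rooted Yule tree under GTR+Γ. The gamma
distribution of site rates is discretized into four categories at quantile
midpoints, normalized to mean 1; each alignment column keeps its category
for the whole tree. No invariant-sites class is modelled — rate
heterogeneity is carried by the gamma shape alone, because a separate
invariant class duplicates what a small shape parameter already expresses.

Indels follow the simplest process that produces nested and overlapping
gap structure. Along a branch of (scaled) length $t$, insertion events
occur with rate `ins_rate` per site and deletions with `del_rate` per
site; counts are Poisson with the branch-start length, fragment lengths
are geometric with parameter `len_p` (mean $1/p$), insertions land
uniformly between sites and draw new residues from the stationary base
frequencies, deletions start at a uniform site and truncate at the
sequence end. Column identities are threaded through the whole simulation,
so de-gapping any row of the true alignment reproduces the emitted
sequence exactly — the invariant every aligner test relies on.

The default three-locus configuration emulates the empirical setting the
package is aimed at: one indel-rich ITS-like locus (300 bp at the root,
rate scaler 0.10, `ins_rate = del_rate = 0.02`, `len_p = 0.5`) and two
indel-free loci (LSU-like, 500 bp at scaler 0.03; EF-like, 450 bp at
scaler 0.05) sharing one tree. With 16–24 taxa these defaults produce
roughly 15–25 % gapped columns in the ITS-like true alignment. The locus
lengths are scaled down from typical empirical loci (≈700/1300/1200 bp)
so that a full refinement experiment over dozens of replicates runs on a
single CPU in minutes; rates and proportions, not absolute sizes, carry
the scientific content here. No published indel-rate estimates exist for
ITS at this scale, so the rates were chosen once to hit that gapped-column
range and are exposed as configuration.

What the simulator does *not* emulate: rate variation beyond discrete
gamma, context-dependent or long-tailed indel lengths, alignment
ambiguity from repeats, and gene-tree discordance (all loci share one
tree, as a concatenation framework assumes). Passing tests therefore show
that the machinery is correct under its stated model, not that real ITS
data meet that model.

## The aligner and insertion fixing

Profiles are merged in the postorder of the guide tree. Profile–profile
scores are average-of-pairs over column residue frequencies, with
substitution scores $s(a,b) = \log P_t(a\to b)/\pi_b$ evaluated at the
expected leaf-to-leaf divergence across the merge — the mean leaf depth
within each profile plus the two connecting branches, clamped to
$[0.05, 2]$ — which is the distance an average-of-pairs score implies.
Because the scores read branch lengths as expected substitutions per
site, guide trees should carry lengths on the locus' own substitution
scale; the refinement loop re-estimates guide branch lengths on the
indel-rich locus for exactly this reason, and the undermatching
experiments rescale random guide topologies to the true guide's total
length so the contrast isolates topology. Gap runs have affine (`gap_open = -5`, `gap_extend = -0.5` by default; a run of $k$ gaps
costs `gap_open + (k-1) gap_extend`). The dynamic program breaks ties in a
fixed order (match, then gap in the second profile, then gap in the first)
so outputs are byte-stable.

A column aligned against a gap is annotated as an insertion at the child
whose subtree carries the residues. With `fix_insertions = TRUE`
(the default) such columns become *permanent*: they are excluded from the
scoring of all later merges and carried upward as gap-only columns for
the other taxa. This is a deliberately simplified, score-based rendering
of insertion-fixing probabilistic aligners — it claims fidelity to the
mechanism (guide-tree-dependent indel placement), not to any specific
program's output. The mechanism is exactly what produces undermatching:
under a wrong guide tree a shared insertion is created independently in
two subtrees, the two column blocks can never be matched afterwards, and
the alignment is strictly longer than under the true tree.

The guide tree must be rooted and binary; unrooted inputs are
midpoint-rooted (insertions can only be told from deletions on a rooted
tree) and polytomies must be resolved first.

## Likelihood machinery

Felsenstein pruning under partitioned GTR+Γ is implemented in compiled
code with per-site log-likelihood vectors, pattern compression, and
branch-length optimization by per-branch golden-section sweeps against
cached partial likelihoods (sweeps are Jacobi-style: caches are rebuilt
between sweeps, and a sweep that fails to improve the exact likelihood is
discarded). Degree-2 roots are collapsed before optimization because the
two root branches are jointly unidentifiable and stall coordinate ascent.
Branch lengths are shared across partitions while substitution parameters
are per partition. Gaps and `?` are missing data (all-ones conditionals).

Tree search is NJ (p-distance, pairwise deletion) followed by
hill-climbing over nearest-neighbour interchanges: candidates are scored
cheaply at current branch lengths, the best few re-scored with full
branch optimization, and a move is accepted only if it improves the
likelihood by more than `tol` (default `1e-6`). This replaces the MCMC
and large-scale ML searches used in empirical studies — a documented,
desk-scale substitution isolated behind one function, so the refinement
loop's contract (a tree per iteration) is unchanged. Where a posterior
tree sample is required downstream, bootstrap tree sets stand in for it
behind the same multi-tree interface.

## The refinement loop

`refine()` starts from a neighbor-joining guide tree built on p-distances
from pairwise alignments (iteration 0). Each iteration aligns the
indel-rich locus along the current guide, removes columns whose gap
fraction exceeds 0.5 *for tree estimation only*, concatenates with the
indel-free loci ('?' fills missing taxa), estimates a tree (NJ + NNI),
randomly resolves any polytomy to zero-length branches, midpoint-roots
the result, and feeds it back as the next guide. The loop stops when the
unrooted topology is identical to the previous iteration's
(Robinson–Foulds distance 0) or after `max_iter` (default 10, with a
warning). The unfiltered alignment is what is carried between iterations
and returned: indel coding must see the full gap structure, while the
tree stage should not be driven by half-empty columns.

One subtlety is deliberate: branch lengths of a multilocus tree sit on
the concatenation's rate scale, dominated by the slow loci. Using them
directly would make the aligner evaluate its substitution scores at
implausibly small distances for the fast locus and over-penalize
mismatches. The loop therefore re-estimates branch lengths on the
indel-rich locus itself (topology fixed) before each alignment stage.
`single_locus_refine()` runs the same loop with the tree stage driven by
the filtered indel-rich locus alone, for comparing the two strategies.

Convergence is defined on unrooted topologies over the shared taxon set.
The undermatching diagnostic is the plain column-count ratio
`len(inferred) / len(true)`; on simulated data the true alignment is
available, and the package's tests verify that random guide trees inflate
it relative to the true guide.

## Simple indel coding

Every distinct maximal gap run (identical start and end columns) observed
in any row becomes one binary presence/absence character: a taxon scores
1 when it carries exactly that run, `?` when one of its own runs strictly
contains the extent (the event is unobservable for that taxon), and 0
otherwise. Leading and trailing runs are treated as missing data by
default (`terminal_gaps = "missing"`): they define no characters, and a
taxon whose terminal run covers a character extent scores `?`. Ambiguity
codes are residues, not gaps. Characters are ordered by (start, end).
A character is parsimony-informative when at least two taxa score 0 and
two score 1, `?` ignored. The combined DNA + binary matrix exports to a
MrBayes-compatible mixed-datatype NEXUS that round-trips through the
package's own reader.

## Ancestral states

Discrete traits evolve under an unrestricted Mk model (two states:
`q01`, `q10`; three states: six free rates). Rates are estimated by
bounded quasi-Newton optimization on the log scale with 25 random
restarts by default. The root prior is flat, with a stationary option;
note that for degenerate data (a constant character) the flat prior
leaves the loss rate unidentified, while the stationary prior pins the
root to the observed state. Two-state transition probabilities use the
closed form; three-state ones use scaling-and-squaring.

`mrca_state_probability()` targets, per tree in a sample, the least
inclusive common ancestor of a named taxon set — on trees where the set
is not monophyletic the target simply subtends more taxa, which is how
topological uncertainty is absorbed. Marginal probabilities come from
clamping the node to each state at the per-tree MLE rates and normalizing
the clamped likelihoods; the per-state clamped likelihoods reassemble the
free likelihood exactly, which the tests assert. `fixed_state_test()`
re-optimizes the rates under each clamp and calls a mean difference of
two log-likelihood units significant.

Stochastic mapping samples node states from their joint conditional
distribution (backward filtering, forward sampling) and branch paths by
endpoint-conditioned simulation: rejection sampling with a cap of 100
attempts per branch, falling back to a uniformization sampler, which
bounds runtime without biasing the counts. Gains are 0→1 changes and
losses 1→0; multi-character tables (e.g. the additive binary recoding of
the three-state stipe-covering character) are mapped per character.

## The AU test

Per-site log-likelihoods for a set of trees are RELL-resampled at ten
scales (0.5–1.4 in steps of 0.1, the conventional default), 10 000
replicates per scale by default. Exact ties for the best resampled tree
are split uniformly at random, so duplicated topologies share wins
instead of the first row absorbing them (this is what makes the
symmetric two-tree case come out at p ≈ 0.5). The normal quantiles of the
winning proportions are fitted to $d\sqrt{r} + c/\sqrt{r}$ by weighted
least squares with binomial variance weights, proportions clamped to
$[1/2B, 1 - 1/2B]$, and the AU p-value is $1 - \Phi(d - c)$. A tree that
never wins at any scale is reported with p = 0 and a degenerate-fit flag.
Constrained searches reject NNI moves that would break a required clade
(clades must be pairwise nested or disjoint); constrained-tree
attachment at an induced polytomy is left to the constrained search
rather than fixed a priori. Pooled unconstrained and constrained trees
are deduplicated by topology before testing; whether an empirical study
would deduplicate is not knowable from a p-value range, so this choice is
documented rather than inferred.

## Numerical choices and limitations

* Discrete gamma: 4 categories, quantile midpoints, mean-normalized.
* Branch-length optimization: golden section on the log scale over
  $[10^{-8}, 10]$, 25 iterations per branch, sweeps until the exact
  improvement drops below 0.01 (10 sweeps cap).
* NNI termination: no candidate improves by more than $10^{-6}$.
* DP tie-breaking and all stochastic steps (polytomy resolution,
  restarts, mapping, RELL) take explicit seeds; identical seeds give
  byte-identical outputs.
* The pruning engine targets small alignments (tens of taxa); it does not
  rescale partial likelihoods per node, which is safe at these sizes but
  would underflow for hundreds of taxa. The Mk engine does rescale.
* The aligner is score-based, not a pair-HMM with posterior decoding; it
  reproduces guide-tree-dependent insertion fixing, not any particular
  aligner's output. Anchoring and other production heuristics are out of
  scope.
* p-distances saturate at high divergence; the initial guide tree is
  intentionally rough, which is precisely what the refinement loop is
  for.

## Problem sizes used by the test suite

The package's own experiments run at 8–16 taxa: the undermatching and
refinement properties use 50 replicates of the default 16-taxon
three-locus configuration; likelihood oracles enumerate 5-taxon trees;
ASR calibration uses 2000 forward simulations on a fixed 8-tip tree; the
AU null uses 200 simulated site-likelihood matrices at 1000 replicates
per scale. These sizes were chosen so the whole suite exercises every
stage end-to-end in minutes on one CPU while keeping Monte-Carlo errors
well inside the asserted tolerances.
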