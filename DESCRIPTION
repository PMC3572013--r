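Package: indelrefine
Title: Iterative Guide-Tree Refinement for Alignment and Phylogenetics of
    Indel-Rich Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how guide-tree quality shapes progressive
    multiple sequence alignment of indel-rich loci such as the nuclear
    ribosomal ITS region. Provides a sequence simulator with an explicit
    insertion/deletion process that retains the true alignment, an
    insertion-aware progressive aligner with permanent fixing of inferred
    insertions (the mechanism behind alignment undermatching under poor
    guide trees), an iterative multilocus alignment-and-tree refinement
    loop, simple indel coding of gaps into binary characters, partitioned
    GTR+Gamma likelihood machinery with neighbor-joining and NNI search,
    bootstrap-based conflict tests, constrained topology searches with the
    approximately unbiased (AU) test, and Mk-model ancestral state
    reconstruction with stochastic character mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
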