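Package: lapasm
Title: Maximum-Likelihood Genome Assembly by Annealing over Assembly-Graph Walks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores genome assemblies with a probabilistic read model -- the
    log average probability (LAP) of observing the reads given the assembly --
    that transparently combines heterogeneous sequencing datasets (single-end
    and paired-end short reads with normal insert-size models, and long noisy
    reads scored by a banded forward algorithm), and searches for a
    high-likelihood assembly by simulated annealing over walks in a
    conservative de Bruijn assembly graph. Provides internal read alignment
    with k-mer and min-hash candidate filtering, incremental likelihood
    evaluation over overlapping walk windows, ambiguity-breaking
    postprocessing, improvement of existing assemblies, and a synthetic
    genome/read simulator used for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
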