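Package: opsinevo
Title: Molecular Evolution of Opsins: Codon Selection Tests, Omega-Trees
    and Ancestral Photic-Character Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retracing dim-light ('nocturnal bottleneck') adaptation
    in the mammalian visual system from opsin coding sequences. Implements
    Goldman-Yang style codon substitution models with beta-distributed site
    classes (M7, M8, M8a) and branch-heterogeneous dN/dS schemes (one-ratio,
    two-ratio, free-ratios) fitted by maximum likelihood via Felsenstein
    pruning; likelihood-ratio tests and naive empirical Bayes identification
    of positively selected sites; omega-tree construction with robust outlier
    recalculation, root-to-tip linearization (omega-lineages) and
    median/interquartile-range standardization; ancestral reconstruction of
    photic characters on omega-trees using Mk models (ER/SYM/ARD) for discrete
    states and Brownian motion for continuous traits, gated by Moran's I
    phylogenetic autocorrelation with Bonferroni correction; spectral-tuning
    classification rules for SWS1 opsins (violet- versus ultraviolet-sensitive)
    and site-93 segregation summaries; and seeded simulators for codon
    alignments, discrete and continuous traits used to validate every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
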