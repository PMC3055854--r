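Package: KaKsEval
Title: Eight-Method Pairwise Ka/Ks Estimation and Cross-Method Consistency Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates pairwise nonsynonymous (Ka) and synonymous (Ks)
    substitution rates for protein-coding gene pairs with eight methods
    spanning approximate counting (NG, LWL, MLWL, LPB, MLPB) and model-based
    (YN, MYN, GY) approaches, quantifies cross-method consistency through
    normalized divergence indexes and shared-gene percentages, classifies
    genes into fast-, intermediately- and slow-evolving groups by Ka
    percentile, performs functional-category enrichment with Holm-corrected
    Fisher tests and expression-by-class comparisons, and ships a Markov
    codon-model simulator with exactly computable expected rates for
    validation of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Genetics, Phylogenetics, SequenceMatching, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
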