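Package: codonMatch
Title: Codon Usage Matching Between Giant Viruses and Their Amoeba Hosts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well the codon usage of large DNA viruses matches
    that of candidate protist hosts. Provides codon usage tables, GC3 and the
    effective number of codons (ENC) with the no-selection null curve, the
    codon adaptation index (CAI), and the COUSIN similarity indices
    (family-weighted and amino-acid-weighted variants), together with robust
    comparison of per-gene score distributions (Huber M-estimator of location,
    MAD, Wilcoxon rank-sum with continuity correction, Hodges-Lehmann location
    shift). Includes a synthetic coding-sequence simulator with configurable
    codon-usage regimes and expression-linked bias, and sliding-window GC /
    terminal-inverted-repeat characterization of candidate endogenous viral
    elements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Biostrings,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'genetic-code.R'
    'cds-set.R'
    'codon-usage.R'
    'codon-indices.R'
    'robust-compare.R'
    'simulate.R'
    'eve-scan.R'
    'cli.R'
    'codonMatch-package.R'
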