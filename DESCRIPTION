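Package: refstab
Title: Reference Gene Stability Evaluation and Relative Quantification for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evaluation of candidate RT-qPCR reference (housekeeping) genes by
    four stability methods - the comparative delta-Ct method, GeNorm (M values,
    iterative exclusion and pairwise variation), NormFinder (model-based
    variance decomposition with or without sample groups) and BestKeeper
    (descriptive Ct dispersion) - together with a RefFinder-style consensus
    ranking by the geometric mean of per-method ranks. Also provides
    standard-curve amplification-efficiency fitting, relative quantification by
    the 2^-ddCt method with one or several reference genes, classification of
    odorant-binding and chemosensory proteins by conserved-cysteine spacing
    patterns, and seeded simulators of Ct matrices, dilution series and motif
    sequences with known ground truth for benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
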