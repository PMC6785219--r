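Package: mirforest
Title: MicroRNA Discovery from Small RNA-Seq with Stacked Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers microRNA loci from aligned small RNA-seq reads using a
    two-layer (stacked) random forest classifier: a mature-product layer that
    scores read stacks as plausible mature microRNAs, and a hairpin-precursor
    layer that scores candidate precursor spans derived from miR:miR* duplex
    energy (duplex-focused spans) or from pairs of products (product-focused
    spans). Includes adjusted reads-per-million (ARPM) normalization for
    multi-mapping reads, engineered sequence, structure and read-distribution
    features computed from RNA secondary structure, F-score-optimizing grid
    tuning, stringent annotation-based evaluation with precision-recall
    curves, homology/cluster/family post-processing, and a synthetic-data
    generator that plants hairpin loci with Dicer/Drosha-style read stacks
    for training and validation. Secondary-structure prediction is delegated
    to the ViennaRNA command-line programs (RNAfold, RNAduplex), which must
    be on the PATH.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    ranger,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: ViennaRNA (RNAfold, RNAduplex on PATH)
RoxygenNote: 7.3.3
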