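Package: mevax
Title: Multi-Epitope mRNA Vaccine Design Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for in silico multi-epitope mRNA vaccine
    design. Implements epitope triage (top-k retention plus antigenicity,
    allergenicity, toxicity, binding-rank and conservation filters),
    IEDB-style HLA population-coverage mathematics (Hardy-Weinberg hit
    distributions, locus convolution, coverage / average hits / pc90),
    a convolutional 5'UTR mean-ribosome-load regressor with uAUG/uORF
    annotation and candidate ranking, mRNA construct assembly and parsing
    (signal peptide, GPGPG/KK/AAY linker schedule, Kozak, MITD, poly(A)),
    ProtParam-style protein physicochemical profiling, and codon-level
    sequence metrics (CAI, GC content, codon optimization, and a
    base-pair-maximization structure proxy). Synthetic generators with
    known ground truth make the whole workflow testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
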