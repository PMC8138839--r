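Package: transcds
Title: CDS and UTR Annotation in Transcripts with Explicit-Duration
    Generalized Hidden Markov Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the single protein-coding region (CDS) and the flanking
    untranslated regions in full-length or fragmentary eukaryotic transcript
    sequences. Two generalized hidden Markov model architectures -- one for
    complete transcripts, one for partials missing the start and/or stop
    codon -- are decoded with an exact explicit-duration Viterbi algorithm.
    Coding segments are scored by three-periodic Markov chains, start and
    stop codons by anchored positional weight models with hard codon
    constraints, and segment lengths by smoothed empirical duration
    distributions with geometric tails. Models are trained from annotated
    transcripts, partitioned into GC-content sub-models, and serialized as
    versioned text bundles. The package ships a strand-blind decoding mode,
    a coding-potential classifier, an evaluation kit implementing
    stop-codon-match and whole-CDS-match accuracy metrics with standard
    test-set constructions, and a synthetic transcript generator for fully
    self-contained training and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    Rcpp,
    Biostrings,
    S4Vectors,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
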