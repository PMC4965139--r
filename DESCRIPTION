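Package: editome
Title: A-to-I RNA Editome Calling, Conservation Typing and Selection Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing adenosine-to-inosine (A-to-I) RNA editing
    across related species from pileup-derived read-count tables. Implements a
    six-criterion editing-site caller with background, SNP-overlap and
    ADAR-null false-positive estimators; coverage-based UTR refinement and
    synonymous/non-synonymous recoding annotation; classification of coding
    editing events into three conservation types over homologous gene
    families; an observed-versus-all-possible editing-frequency selection
    test; Nei-Gojobori (1986) Ka/Ks with 11-codon sliding windows;
    tissue/stage presence profiling with binary hierarchical clustering; and
    hypergeometric/binomial enrichment with Benjamini-Hochberg control. A
    synthetic-data generator emulates multi-species gene families, editing
    events with per-type recoding bias, binomially sampled edited reads,
    sequencing error, an editing-null sample and SNP contamination, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
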