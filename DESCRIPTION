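Package: NTermFinder
Title: Stringent Selection and Curation of N-Terminal Peptides as
    Translational Evidence for Noncoding-Transcript Proteoforms
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding whether N-terminal peptides from
    N-terminomics (COFRADIC) experiments constitute translational evidence
    for proteins encoded by noncoding transcripts (NTRs). Implements the
    custom proteoform-database conventions used with Ribo-Seq-derived
    sequence databases (accession parsing, redundancy collapsing, category
    priorities), an in-silico digestion and mass-spectrometry detectability
    model (peptide mass, charge at acidic pH, m/z criteria, I/L-aware
    uniqueness), a rule-based selection pipeline that classifies N-terminal
    peptides by acetylation state, initiator-methionine processing and
    ribosome-profiling support, downstream curation (ungapped homology
    scanning, single-nucleotide-variant plausibility, fragment-ion rank
    concordance, splice-aware peptide-to-genome mapping), and a synthetic
    data generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, MassSpectrometry, Proteogenomics, RiboSeq
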