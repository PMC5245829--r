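Package: dinomir
Title: Small RNA Duplex Discovery and Strand-Aware Profiling for
    Dinoflagellate Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for miRNA-candidate discovery in stranded
    small RNA-seq libraries, built around the duplex geometry of Dicer
    products. Provides a read-cleaning cascade with per-stage accounting
    (adapter trimming, polyA-read removal, rRNA/tRNA/organelle subtraction,
    size selection), abundance collapsing with a minimum-copy filter,
    exact-overlap contig assembly to flag mRNA degradation fragments,
    an exhaustive search for miRNA/miRNA* duplexes with 2-nt 3' overhangs
    (up to 3 mismatches and 1 single-base bulge), strand-aware profiling of
    small RNAs against reference transcripts, and a deterministic
    synthetic-library simulator with a ground-truth manifest for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
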