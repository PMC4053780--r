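Package: parclipbg
Title: Background Quantification and Correction for PAR-CLIP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies covalently crosslinked background in PAR-CLIP
    (photoactivatable-ribonucleoside-enhanced crosslinking and
    immunoprecipitation) experiments and corrects for it. Implements
    utilized-read filtering on T-to-C conversions, binding-site (group)
    and cluster calling, whole-site subtraction against a background-site
    union, depth-thresholded replicate overlap, library-membership
    binning, k-mer motif analysis with a dinucleotide-preserving shuffle
    null, IUPAC motif scanning, matched-pairs k-mer comparison before and
    after correction, genomic category and positional (TSS / transcript
    3'-terminus) analyses, and sequencing-saturation curves by read
    subsampling. A seeded synthetic PAR-CLIP simulator with ground-truth
    tables exercises every stage without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
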