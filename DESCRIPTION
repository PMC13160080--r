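Package: isosieve
Title: Kmer-Sketch Preprocessing of Long RNA-Seq Reads for Novel Isoform Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pseudo-aligns long RNA-seq reads to a reference transcriptome
    using positional FracMinHash kmer sketches and a simplified banded
    colinear anchor-chaining dynamic program, then selects the reads most
    likely to originate from novel isoforms (discovery mode) or a balanced
    per-isoform subsample with abundance scale factors (quantify mode),
    so that expensive base-level alignment is only spent on informative
    reads. Includes a synthetic transcriptome and read simulator with
    ground-truth event labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
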