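Package: ssnat
Title: Sequence Similarity Network Classification of GNAT Acetyltransferases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of the eukaryotic GNAT acetyltransferase
    superfamily from protein sequence alone. Builds sequence similarity
    networks (SSNs) from all-vs-all Smith-Waterman statistics with
    Karlin-Altschul E-values, detects dense possibly-overlapping
    isofunctional clusters with a cohesiveness-based greedy algorithm,
    contracts clustered networks into cluster-level pivot networks,
    selects small-world components for downstream phylogeny, discovers
    per-cluster sequence motifs under a ZOOPS model and turns them into
    regular-expression fingerprints of N-terminal acetyltransferase (NAT)
    groups, scans sequences with motif fingerprints using exact
    convolution p-values, and nominates candidate NAT clusters among the
    neighbours of known NATs. Ships a synthetic-superfamily generator
    with planted families and motifs so the whole pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    ape,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    withr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
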