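Package: entroclust
Title: Alignment-Free Genome Clustering from Block-Entropy Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Alignment-free comparison of DNA genomes through the
    variability of their local Shannon entropy. Genomes are partitioned
    into fixed-size blocks, per-block entropies are histogrammed into a
    normalized distribution whose own entropy ("superinformation")
    summarizes local compositional variability, and genomes are compared
    by the Jensen-Shannon metric between their block-entropy
    distributions. Distance matrices feed hierarchical clustering (UPGMA,
    complete, single, neighbor-joining) with Newick export. Includes a
    synthetic-genome generator with controlled along-sequence GC
    composition for validation, and command-style entry points for
    profile, superinformation, block-size sweep, distance-matrix and
    clustering workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
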