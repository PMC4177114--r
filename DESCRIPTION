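Package: tsapipe
Title: Two-Step Assembly of Plastid and Mitochondrial Genomes from
    Mixed-Organelle Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for obtaining plastid and mitochondrial genomes
    simultaneously from a single mixed-organelle sequencing library.
    Implements efficiency-corrected qPCR relative quantification of
    plastid/mitochondrial/nuclear DNA copy folds and dataset-size
    prediction; a paired-end read simulator with quadripartite plastid
    structure and a plastid-homologous mitochondrial tract; read-pair
    quality filtering; depth-stratified de Bruijn assembly with k-mer
    frequency and edge-coverage thresholds; exact-match read placement
    and pair partitioning; reference-guided scaffold ordering into an
    N-gapped draft; strict iterative anchored gap closure; and pairwise
    genome comparison with SNP/MNP/indel/complex-variant classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
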