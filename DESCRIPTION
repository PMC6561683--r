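Package: kferqscan
Title: Proteome-Wide Identification and Analysis of KFERQ-Like Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects KFERQ-like pentapeptide motifs, the targeting signals of
    chaperone-mediated autophagy (CMA) and endosomal microautophagy, in
    protein sequences, and provides the downstream analyses used to
    characterise them at proteome scale: motif classification into canonical,
    phosphorylation-generated and acetylation-generated classes (plus
    asparagine variants), per-protein hierarchical grouping and fractional
    motif composition, positional distributions and N-terminal depletion,
    amino-acid position preferences against scrambled-proteome baselines,
    protein-length regression with Cook's distance outlier handling,
    solvent-exposure profiling around motifs, cross-species motif
    conservation scoring from ortholog alignments including LAMP-2A tail
    detection, and annotation-term enrichment with Fisher tests, resampled
    z-scores and combined scores. Includes seeded synthetic-data generators
    for every analysis and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
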