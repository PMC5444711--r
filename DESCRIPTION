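Package: gpinstab
Title: GPI-Anchor Pathway Expression and Genomic Instability in Myeloid Neoplasms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis toolkit linking glycosylphosphatidylinositol (GPI)
    anchor biosynthesis gene expression to genomic instability in
    myelodysplastic syndromes (MDS) and acute myeloid leukemia (AML).
    Provides instability-panel scoring of expression cohorts (CIN70 and
    GPI-anchor panels, per-sample principal-component scores, random-forest
    permutation importance), detection of partial intron retention from
    splice-junction evidence with premature-termination and truncated-protein
    prediction, GPI-anchored-protein deficiency frequency estimation from
    proaerolysin-selection colony assays, paired variant-profile comparison,
    and classification of transcript/protein expression aberrations.
    A synthetic-data module generates inputs with the statistical structure
    each stage assumes, so the full pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    randomForest,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
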