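Package: transqc
Title: Contamination Screening, Spliced-Leader Detection and Co-Expression
    Analytics for De Novo Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Downstream analytics for de novo transcriptome assemblies of
    non-model eukaryotes such as Euglena gracilis: assembly summary
    statistics (Nxx, GC), BLAST-based contamination screening with a
    read-removal score rule, spliced-leader (SL) remnant scanning at
    transcript 5' ends, MEGAN-like last-common-ancestor taxonomic
    affiliation, tetranucleotide-frequency composition analysis with
    sub-sampled PCA, TPM expression pooling and transformation,
    partitioning-around-medoids co-expression clustering with a
    correlation-ratio criterion for the number of clusters, and
    hypergeometric term enrichment with Cohen's-kappa term networks.
    Seeded generators produce synthetic inputs with the statistical
    structure each stage assumes, so the whole pipeline is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
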