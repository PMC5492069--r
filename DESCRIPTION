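Package: hbugkit
Title: Downstream Annotation and Expression Triage for De Novo Insect
    Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Post-assembly processing and annotation triage for de novo
    transcriptome surveys of the harlequin bug and related pentatomids.
    Provides poly-A/T tail clipping, minimum-length filtering and
    vector-screen purging of assembled transcripts; gold/silver/bronze
    homology-confidence tiering from protein alignment summaries;
    gene-family membership calling (GST/COE style) with six-frame
    longest-ORF support and best-hit clustering for cytochrome P450
    triage; Pfam-to-GO annotation with GO-Slim resolution by
    penultimate-ancestor is_a traversal; TPM normalisation, read-group
    pooling and replicate-free log2 fold-change contrasts with floor and
    sentinel semantics; plus a synthetic-data generator with known
    ground truth and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, Annotation, GeneExpression, Software
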