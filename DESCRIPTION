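Package: tfnresponse
Title: Transcription Factor Network Topology and Genome-Wide Responses to
    RNA Polymerase Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating the topology and logic of the
    Escherichia coli transcription factor network (TFN) to genome-wide
    transcriptional responses following shifts in RNA polymerase (RNAP)
    concentration. Builds signed, directed, gene-level regulatory graphs
    from RegulonDB-style interaction tables with operon/transcription-unit
    expansion; computes per-gene regulatory bias |b| and input-TF counts
    K_TF; classifies differentially expressed genes with a two-stage
    FDR-plus-|LFC| rule; assembles with-replacement gene cohorts constrained
    on mean bias or mean in-degree (the ensemble approach); regresses output
    on input |LFC| at minimum path lengths L = 1..3 with null-model and
    maximal-correlation bounds; and provides the uncertainty-aware fitting
    layer (Monte-Carlo expanded ordinary least squares with linearity tests
    and 68.2% confidence bands, sigmoid Monte-Carlo fits, ANCOVA line
    comparison). A mechanistic synthetic-data generator simulates staged
    short- and mid-term responses on random signed networks with operon
    structure, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml,
    stringi,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
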