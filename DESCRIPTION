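Package: fflnet
Title: miRNA-TF Co-Regulatory Network Construction and Feed-Forward Loop
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs disease-specific microRNA-transcription factor
    co-regulatory networks from predicted and experimentally validated
    regulation evidence. Provides evidence-aware target integration
    (prediction intersection, binding-site Z-score filtering, predicted/
    validated merging, disease-scope restriction), enumeration and
    classification of miRNA-TF-gene feed-forward loops and miRNA-TF
    feedback loops, network assembly with degree-based hub detection and
    pathway-seeded subnetworks, a random-gene permutation test for
    feed-forward loop count significance with an exact small-universe
    oracle, hypergeometric pathway over-representation, a recurrence-stage
    differential-expression pipeline, and a synthetic tripartite graph
    generator with closed-form motif expectations for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    fgsea,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
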