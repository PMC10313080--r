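Package: grnlink
Title: Multi-Task Link and Regulation-Type Prediction on Gene Regulatory Knowledge Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint prediction of transcription-factor-target-gene interactions and their
    regulation type (activation/repression, possibly both) from the topology of a
    heterogeneous knowledge graph built from typed edge lists. Implements a
    multi-subgraph graph convolution network (per-relation linear message passing with
    destination-side summation), a sigmoid dot-product link decoder, a multilabel
    edge-type head, and GradNorm adaptive balancing of the two task losses, together
    with chemical-profile cosine node features, k-fold edge cross-validation with
    seeded negative sampling, a planted-block synthetic graph generator, and the full
    evaluation metric suite (ROC/AUC, accuracy/precision/recall/F1, Hamming loss and
    example-based multilabel precision/recall/F1).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
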