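Package: abte
Title: Hybrid Drug-Drug Interaction Prediction from Interaction Networks and Biomedical Text Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts drug-drug interactions (DDIs) by combining adjacency
    matrix factorization with latent-factor propagation (AMFP) over the known
    interaction network with a feed-forward classifier over pre-trained
    biomedical text embeddings, fused by a stacking combiner and a cold-start
    switching rule (ABTE). Includes edge-list and word2vec-text ingestion,
    per-epoch implicit-feedback negative sampling, temporal holdout
    evaluation with ranking metrics (AUROC, AUPR, precision at K, recall at
    K) and rare-drug stratification, and a planted-partition synthetic study
    generator so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
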