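# Synthetic study generator. A planted-partition (stochastic block model)
# interaction network in which cluster co-membership drives both the
# interaction probability and the text embeddings -- the premise under
# test, that literature-derived vectors carry interaction signal, holds by
# construction. A fraction of the drawn edges is moved to a "future"
# release (the temporal holdout), and a designated subset of drugs is
# forced cold by capping their training interactions.

#' Configuration for a synthetic DDI study
#'
#' @param n_drugs Number of drugs.
#' @param n_clusters Number of planted clusters; must not exceed
#'   `embed_dim`.
#' @param embed_dim Embedding dimension (100, the size of the pre-trained
#'   tables the pipeline consumes).
#' @param edge_prob_within,edge_prob_between Bernoulli edge probabilities
#'   inside and across clusters.
#' @param embed_noise_sd Per-coordinate Gaussian noise added to the cluster
#'   centroid when generating a drug's embedding vector.
#' @param holdout_frac Fraction of drawn edges moved to the future (test)
#'   release.
#' @param cold_frac Fraction of drugs forced cold.
#' @param cold_max_links Maximum training interactions a cold drug keeps;
#'   the default 2 puts every cold drug inside the rare stratum (< 3).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_drugs = 300, n_clusters = 6, embed_dim = 100,
                         edge_prob_within = 0.25, edge_prob_between = 0.01,
                         embed_noise_sd = 0.3, holdout_frac = 0.5,
                         cold_frac = 0.15, cold_max_links = 2, seed = 1L) {
  stopifnot(n_drugs >= 2, n_clusters >= 1, embed_dim >= n_clusters,
            edge_prob_within >= 0, edge_prob_within <= 1,
            edge_prob_between >= 0, edge_prob_between <= 1,
            holdout_frac >= 0, holdout_frac < 1,
            cold_frac >= 0, cold_frac < 1,
            cold_max_links >= 0)
  structure(
    list(n_drugs = as.integer(n_drugs), n_clusters = as.integer(n_clusters),
         embed_dim = as.integer(embed_dim),
         edge_prob_within = edge_prob_within,
         edge_prob_between = edge_prob_between,
         embed_noise_sd = embed_noise_sd, holdout_frac = holdout_frac,
         cold_frac = cold_frac, cold_max_links = as.integer(cold_max_links),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Generate a synthetic DDI study
#'
#' Draws the study described by the configuration: drugs are assigned to
#' clusters uniformly; each unordered pair interacts with probability
#' `edge_prob_within` inside a cluster and `edge_prob_between` across
#' clusters; embeddings are the cluster centroid (orthogonal unit basis
#' vectors) plus isotropic Gaussian noise; `holdout_frac` of the edges move
#' to the future release; and each cold drug keeps at most
#' `cold_max_links` training edges, the excess moving to the future
#' release too. Train and test edge sets are disjoint and their union is
#' exactly the drawn edge set.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `ddi_study`: a list with `train` and `test`
#'   (`interaction_dataset`s over one catalog), `embeddings` (an
#'   `embedding_table` keyed by drug ID), and `drugs`, a tibble with the
#'   ground-truth `cluster` and `cold` flags.
#' @export
simulate_ddi_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_drugs
  drugs <- sprintf("D%0*d", nchar(n), seq_len(n))

  local_seed(cfg$seed, {
    cluster <- sample.int(cfg$n_clusters, n, replace = TRUE)

    ij <- index_to_pair(seq_len(n_pairs(n)))
    same <- cluster[ij[, "i"]] == cluster[ij[, "j"]]
    p_edge <- ifelse(same, cfg$edge_prob_within, cfg$edge_prob_between)
    drawn <- runif(length(p_edge)) < p_edge
    edges <- tibble(i = ij[drawn, "i"], j = ij[drawn, "j"])
    if (nrow(edges) == 0) {
      abort("configuration produced zero interactions; raise the edge probabilities")
    }

    in_test <- rep(FALSE, nrow(edges))
    n_hold <- floor(cfg$holdout_frac * nrow(edges))
    if (n_hold > 0) in_test[sample.int(nrow(edges), n_hold)] <- TRUE

    cold <- rep(FALSE, n)
    n_cold <- floor(cfg$cold_frac * n)
    if (n_cold > 0) cold[sample.int(n, n_cold)] <- TRUE
    for (d in which(cold)) {
      mine <- which(!in_test & (edges$i == d | edges$j == d))
      if (length(mine) > cfg$cold_max_links) {
        keep <- sample(mine, cfg$cold_max_links)
        in_test[setdiff(mine, keep)] <- TRUE
      }
    }
    if (all(in_test)) {
      abort("configuration left zero training interactions; lower holdout_frac")
    }

    centroids <- diag(1, cfg$n_clusters, cfg$embed_dim)
    vectors <- centroids[cluster, , drop = FALSE] +
      matrix(rnorm(n * cfg$embed_dim, sd = cfg$embed_noise_sd),
             n, cfg$embed_dim)
    rownames(vectors) <- drugs

    to_ds <- function(sel) {
      interaction_dataset(
        tibble(drug_a = drugs[edges$i[sel]], drug_b = drugs[edges$j[sel]]),
        catalog = drugs
      )
    }
    test <- if (any(in_test)) to_ds(in_test) else NULL

    structure(
      list(
        train = to_ds(!in_test),
        test = test,
        embeddings = structure(list(dim = cfg$embed_dim, vectors = vectors),
                               class = "embedding_table"),
        drugs = tibble(drug = drugs, cluster = cluster, cold = cold),
        config = cfg
      ),
      class = "ddi_study"
    )
  })
}

#' @export
print.ddi_study <- function(x, ...) {
  cat(sprintf(
    "<ddi_study> %d drugs in %d clusters | train %d, test %d interactions, %d cold drugs\n",
    nrow(x$drugs), x$config$n_clusters,
    sum(x$train$counts) / 2,
    if (is.null(x$test)) 0 else sum(x$test$counts) / 2,
    sum(x$drugs$cold)
  ))
  invisible(x)
}

#' Write a synthetic study to plain-text files
#'
#' Writes `train.tsv` and `test.tsv` edge lists, `embeddings.txt` in
#' word2vec text format, and `truth.json` with the ground-truth cluster
#' labels and cold flags.
#'
#' @param study A `ddi_study` from [simulate_ddi_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ddi_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(study$train, file.path(dir, "train.tsv"))
  if (!is.null(study$test)) {
    write_edge_list(study$test, file.path(dir, "test.tsv"))
  }
  write_word2vec(study$embeddings, file.path(dir, "embeddings.txt"))
  jsonlite::write_json(study$drugs, file.path(dir, "truth.json"),
                       dataframe = "columns")
  invisible(dir)
}
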