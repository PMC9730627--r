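# Shared fixture builders: tiny datasets, hand-assembled models, and
# independent oracles used across test files.

ds_from_edges <- function(a, b, catalog = NULL) {
  interaction_dataset(tibble::tibble(drug_a = a, drug_b = b),
                      catalog = catalog)
}

# A network with explicitly chosen weights (list of input x output matrices)
# and biases (list of 1 x output matrices).
make_mlp <- function(W, b) {
  widths <- c(nrow(W[[1]]), vapply(W, ncol, 1L))
  structure(list(W = W, b = b, widths = widths), class = "mlp_net")
}

make_biotext <- function(net, Lmat, variant = "concat", id_emb = NULL) {
  structure(
    list(drugs = rownames(Lmat), Lmat = Lmat, variant = variant, net = net,
         dropout = 0, id_embedding = id_emb, hidden = integer(),
         history = tibble::tibble(epoch = integer(), loss = numeric())),
    class = "biotext_model"
  )
}

make_amfp <- function(U, w, b, b0, R, alpha = 0, propagation = TRUE) {
  structure(
    list(drugs = as.character(seq_len(nrow(U))), R = R, U = U, w = w, b = b,
         b0 = b0, alpha = alpha, k = ncol(U), propagation = propagation,
         history = tibble::tibble(epoch = integer(), loss = numeric())),
    class = "amfp_model"
  )
}

# Exhaustive Mann-Whitney AUROC: every positive-negative pair compared.
auroc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# A small random symmetric interaction dataset.
random_ds <- function(n, p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      ij <- abte:::index_to_pair(seq_len(n * (n - 1) / 2))
      keep <- runif(nrow(ij)) < p
      if (sum(keep) >= 2) break
    }
    drugs <- sprintf("d%02d", seq_len(n))
    ds_from_edges(drugs[ij[keep, "i"]], drugs[ij[keep, "j"]],
                  catalog = drugs)
  })
}

# Embedding table with cluster-centroid structure for separability tests.
clustered_embeddings <- function(drugs, cluster, dim = 10, noise = 0.1,
                                 seed = 1) {
  withr::with_seed(seed, {
    cents <- diag(1, max(cluster), dim)
    v <- cents[cluster, , drop = FALSE] +
      matrix(rnorm(length(drugs) * dim, sd = noise), length(drugs), dim)
    rownames(v) <- drugs
    structure(list(dim = dim, vectors = v), class = "embedding_table")
  })
}
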