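# The bio-text pair classifier: a feed-forward network over the pre-trained
# per-drug text embedding vectors of a pair. Four feature constructions are
# supported: concatenation, element-wise multiplication (plus a bias
# component), and the two "feature combination" variants that splice a
# jointly trained drug-ID embedding into the same network. Text vectors are
# frozen; only network weights (and, in feature-combination variants, the
# drug-ID embedding) are learned.

biotext_variants <- c("concat", "multiply",
                      "concat_feature_combination",
                      "multiply_feature_combination")

#' Build the input features of a drug pair
#'
#' Constructs the classifier input from the two text embedding vectors
#' (and, for feature-combination variants, the two drug-ID embedding
#' vectors):
#' * `concat`: `[L_i, L_j]` (length `2e`)
#' * `multiply`: `[L_i * L_j, 1]` (length `e + 1`; the trailing 1 is the
#'   bias component)
#' * `concat_feature_combination`: `[L_i, L_j, id_i * id_j]`
#' * `multiply_feature_combination`: `[L_i * L_j, id_i * id_j]`
#'
#' @param L_i,L_j Numeric text-embedding vectors of equal length `e`.
#' @param variant One of `"concat"`, `"multiply"`,
#'   `"concat_feature_combination"`, `"multiply_feature_combination"`.
#' @param id_i,id_j Drug-ID embedding vectors; required by (and only by)
#'   the feature-combination variants.
#' @return A numeric feature vector.
#' @export
build_pair_features <- function(L_i, L_j, variant = "concat",
                                id_i = NULL, id_j = NULL) {
  variant <- match.arg(variant, biotext_variants)
  if (length(L_i) != length(L_j)) {
    abort("`L_i` and `L_j` must have the same length")
  }
  fc <- grepl("feature_combination", variant)
  if (fc) {
    if (is.null(id_i) || is.null(id_j)) {
      abort("feature-combination variants require `id_i` and `id_j`")
    }
    if (length(id_i) != length(id_j)) {
      abort("`id_i` and `id_j` must have the same length")
    }
  } else if (!is.null(id_i) || !is.null(id_j)) {
    abort("`id_i`/`id_j` are only used by feature-combination variants")
  }
  switch(variant,
    concat = c(L_i, L_j),
    multiply = c(L_i * L_j, 1),
    concat_feature_combination = c(L_i, L_j, id_i * id_j),
    multiply_feature_combination = c(L_i * L_j, id_i * id_j)
  )
}

# Batched feature construction over catalog indices.
pair_feature_matrix <- function(Lmat, i, j, variant, id_emb = NULL) {
  Li <- Lmat[i, , drop = FALSE]
  Lj <- Lmat[j, , drop = FALSE]
  switch(variant,
    concat = cbind(Li, Lj),
    multiply = cbind(Li * Lj, 1),
    concat_feature_combination =
      cbind(Li, Lj, id_emb[i, , drop = FALSE] * id_emb[j, , drop = FALSE]),
    multiply_feature_combination =
      cbind(Li * Lj, id_emb[i, , drop = FALSE] * id_emb[j, , drop = FALSE])
  )
}

biotext_input_width <- function(variant, e, id_dim) {
  switch(variant,
    concat = 2L * e,
    multiply = e + 1L,
    concat_feature_combination = 2L * e + id_dim,
    multiply_feature_combination = e + id_dim
  )
}

#' Train the bio-text pair classifier
#'
#' Fits a feed-forward network (ReLU hidden layers, sigmoid output, binary
#' cross-entropy, Adam) on per-epoch negative-sampled pair batches. Hidden
#' activations use inverted dropout in training only; inference is
#' deterministic. Weights are Glorot-normal initialized. For
#' concatenation-based variants each batch contains both orderings of every
#' pair, and prediction averages the scores of the two orderings, so the
#' reported pair score is well defined for an undirected interaction.
#'
#' @param ds An `interaction_dataset` (training release).
#' @param dvm A `drug_vector_map` over the same catalog
#'   (see [resolve_drugs()]).
#' @param variant Feature construction; see [build_pair_features()].
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout Dropout rate in `[0, 0.9]` applied to hidden activations
#'   during training (default 0.3; with frozen per-drug input vectors the
#'   network otherwise memorizes individual drugs rather than their
#'   neighbourhood in embedding space).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs (0 returns the initialization).
#' @param neg_ratio Negatives per positive per epoch.
#' @param id_dim Drug-ID embedding size (feature-combination variants only).
#' @param seed Integer seed; training is deterministic given it.
#' @return An object of class `biotext_model`: the network, the frozen text
#'   embedding matrix, the (optional) trained drug-ID embedding, and the
#'   per-epoch loss `history`.
#' @export
train_biotext <- function(ds, dvm, variant = "concat", hidden = c(256, 128),
                          dropout = 0.3, lr = 0.01, batch_size = 256,
                          epochs = 30, neg_ratio = 1, id_dim = 32,
                          seed = 1L) {
  stopifnot(inherits(ds, "interaction_dataset"),
            inherits(dvm, "drug_vector_map"))
  variant <- match.arg(variant, biotext_variants)
  if (!identical(ds$drugs, dvm$drugs)) {
    abort("`ds` and `dvm` must share one drug catalog")
  }
  if (!is.numeric(lr) || lr <= 0) abort("`lr` must be positive")
  if (!is.numeric(epochs) || epochs < 0) abort("`epochs` must be >= 0")
  if (dropout < 0 || dropout > 0.9) abort("`dropout` must be in [0, 0.9]")
  if (any(hidden <= 0)) abort("`hidden` widths must be positive")
  n <- length(ds$drugs)
  Lmat <- dvm$matrix
  e <- ncol(Lmat)
  fc <- grepl("feature_combination", variant)
  concat_like <- startsWith(variant, "concat")

  local_seed(seed, {
    net <- mlp_init(c(biotext_input_width(variant, e, as.integer(id_dim)),
                      as.integer(hidden), 1L))
    id_emb <- if (fc) glorot_normal(n, as.integer(id_dim)) else NULL
    params <- net_params(net)
    if (fc) params <- c(params, list(id = id_emb))
    opt <- adam_init(params)
    history <- numeric(epochs)

    for (epoch in seq_len(epochs)) {
      batch <- negative_sample(ds, ratio = neg_ratio, seed = seed,
                               epoch = epoch)
      if (concat_like) {
        # both orderings: the concatenation is not symmetric in (i, j)
        batch <- tibble(i = c(batch$i, batch$j), j = c(batch$j, batch$i),
                        label = c(batch$label, batch$label))
      }
      perm <- sample.int(nrow(batch))
      bi <- batch$i[perm]; bj <- batch$j[perm]; by <- batch$label[perm]
      starts <- seq(1, length(by), by = batch_size)
      losses <- numeric(length(starts))
      for (s in seq_along(starts)) {
        idx <- starts[s]:min(starts[s] + batch_size - 1, length(by))
        i <- bi[idx]; j <- bj[idx]; y <- by[idx]
        if (fc) id_emb <- params$id
        X <- pair_feature_matrix(Lmat, i, j, variant, id_emb)
        fw <- mlp_forward(net, X, dropout = dropout, training = TRUE,
                          cache = TRUE)
        losses[s] <- bce_loss(fw$p, y)
        dz <- (fw$p - y) / length(y)
        g <- mlp_grads(net, fw, dz, want_dX = fc)
        grads <- c(g$W, g$b)
        if (fc) {
          id_cols <- (ncol(X) - ncol(id_emb) + 1):ncol(X)
          gid <- g$dX[, id_cols, drop = FALSE]
          rows <- rowsum(rbind(gid * id_emb[j, , drop = FALSE],
                               gid * id_emb[i, , drop = FALSE]),
                         group = c(i, j))
          gid_full <- matrix(0, n, ncol(id_emb))
          gid_full[as.integer(rownames(rows)), ] <- rows
          grads <- c(grads, list(id = gid_full))
        }
        step <- adam_step(params, grads, opt, lr)
        params <- step$params
        opt <- step$state
        net <- net_set_params(net, params[seq_len(2 * length(net$W))])
      }
      history[epoch] <- mean(losses)
    }

    structure(
      list(
        drugs = ds$drugs, Lmat = Lmat, variant = variant, net = net,
        dropout = dropout, id_embedding = if (fc) params$id else NULL,
        hidden = as.integer(hidden),
        history = tibble(epoch = seq_len(epochs), loss = history)
      ),
      class = "biotext_model"
    )
  })
}

#' Forward pass of the bio-text classifier on explicit features
#'
#' Applies the trained network to an already-built feature vector (or a
#' matrix with one feature row per instance). Dropout is inactive.
#'
#' @param model A `biotext_model`.
#' @param features Numeric vector (one instance) or matrix (instances in
#'   rows) matching the network input width.
#' @return Probability vector in (0, 1).
#' @export
biotext_forward <- function(model, features) {
  stopifnot(inherits(model, "biotext_model"))
  mlp_forward(model$net, features, training = FALSE)
}

# Pair scores by catalog index; concat-like variants average both orderings.
biotext_score <- function(model, i, j) {
  if (any(i == j)) abort("self-pairs (i == j) cannot be scored")
  s <- mlp_forward(model$net,
                   pair_feature_matrix(model$Lmat, i, j, model$variant,
                                       model$id_embedding))
  if (startsWith(model$variant, "concat")) {
    s2 <- mlp_forward(model$net,
                      pair_feature_matrix(model$Lmat, j, i, model$variant,
                                          model$id_embedding))
    s <- (s + s2) / 2
  }
  s
}

#' Predict method for the bio-text classifier
#'
#' @param object A fitted `biotext_model`.
#' @param pairs Tibble with columns `i`, `j` or `drug_a`, `drug_b`.
#' @param ... Unused.
#' @return `pairs` with a `.score` column appended.
#' @export
predict.biotext_model <- function(object, pairs, ...) {
  pairs <- resolve_pair_indices(pairs, object$drugs)
  dplyr::mutate(pairs, .score = biotext_score(object, pairs$i, pairs$j))
}

#' @export
print.biotext_model <- function(x, ...) {
  cat(sprintf(
    "<biotext_model> variant '%s', hidden [%s], %d epochs%s\n",
    x$variant, paste(x$hidden, collapse = ", "), nrow(x$history),
    if (nrow(x$history) > 0)
      sprintf(", final loss %.4f", x$history$loss[nrow(x$history)]) else ""
  ))
  invisible(x)
}
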