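# Adjacency matrix factorization with latent-factor propagation (AMFP).
# One latent vector per drug, shared between the rows and columns of the
# symmetric interaction matrix; the pair score is a learned element-wise
# multiplication of the two (propagated) latent vectors plus per-drug and
# global biases, squashed by a sigmoid. Propagation blends each drug's
# latent vector with the mean of its training neighbours' vectors.

#' Propagate latent factors over the interaction neighbourhood
#'
#' Blends each drug's latent vector with the mean latent vector of its
#' training interaction partners: `U'_i = (1 - alpha) U_i + alpha *
#' mean(U_j, j in N(i))`. Drugs without training partners keep their vector
#' unchanged, and `alpha = 0` returns `U` exactly (the propagation-free
#' factorization, AMF, is the `alpha = 0` limit of AMFP).
#'
#' @param U Numeric n x k matrix of latent factors, one row per drug.
#' @param R Symmetric binary n x n (sparse) interaction matrix.
#' @param alpha Propagation factor in `[0, 1]`; the weight of the
#'   neighbourhood mean.
#' @return An n x k numeric matrix of propagated factors.
#' @export
propagate <- function(U, R, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    abort("`alpha` must be a single number in [0, 1]")
  }
  if (alpha == 0) return(U)
  as.matrix(prop_matrix(R, alpha) %*% U)
}

# P such that propagate(U, R, alpha) == P %*% U. Rows of drugs with no
# neighbours reduce to the identity row.
prop_matrix <- function(R, alpha) {
  n <- nrow(R)
  deg <- Matrix::rowSums(R)
  dinv <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(n, x = ifelse(deg > 0, 1 - alpha, 1)) +
    alpha * Matrix::Diagonal(n, x = dinv) %*% R
}

#' Train the adjacency-factorization component
#'
#' Fits per-drug latent factors `U`, element-wise multiplication weights
#' `w`, per-drug biases and a global bias by Adam on binary cross-entropy.
#' The score of a pair is
#' `sigmoid(w' (U~_i * U~_j) + b_i + b_j + b0)` where `U~` is the propagated
#' factor matrix (see [propagate()]); propagation sits inside every forward
#' pass, so its gradient flows back into `U`. Each epoch trains on all
#' positives plus a fresh uniformly drawn negative sample
#' ([negative_sample()]). All weights are Glorot-normal initialized; biases
#' start at zero. Training is deterministic given `seed`.
#'
#' `train_amf()` is the propagation-free variant: the same model and
#' optimization with the propagation step omitted entirely.
#'
#' @param ds An `interaction_dataset` (training release).
#' @param k Number of latent factors per drug.
#' @param alpha Propagation factor in `[0, 1]` (AMFP only).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Number of training epochs (0 returns the initialization).
#' @param neg_ratio Negatives per positive in each epoch's batch.
#' @param seed Integer seed controlling initialization, sampling and
#'   shuffling.
#' @return An object of class `amfp_model` with elements `U`, `w`, `b`,
#'   `b0`, `alpha`, `propagation`, the training `history` (tibble of
#'   per-epoch mean batch loss), and the catalog/adjacency needed for
#'   prediction.
#' @export
train_amfp <- function(ds, k = 32, alpha = 0.5, lr = 0.01, batch_size = 256,
                       epochs = 30, neg_ratio = 1, seed = 1L) {
  train_amfp_impl(ds, k, alpha, lr, batch_size, epochs, neg_ratio, seed,
                  use_propagation = TRUE)
}

#' @rdname train_amfp
#' @export
train_amf <- function(ds, k = 32, lr = 0.01, batch_size = 256,
                      epochs = 30, neg_ratio = 1, seed = 1L) {
  train_amfp_impl(ds, k, alpha = 0, lr, batch_size, epochs, neg_ratio, seed,
                  use_propagation = FALSE)
}

train_amfp_impl <- function(ds, k, alpha, lr, batch_size, epochs, neg_ratio,
                            seed, use_propagation) {
  stopifnot(inherits(ds, "interaction_dataset"))
  if (!is.numeric(k) || k <= 0) abort("`k` must be a positive integer")
  if (!is.numeric(lr) || lr <= 0) abort("`lr` must be positive")
  if (!is.numeric(epochs) || epochs < 0) abort("`epochs` must be >= 0")
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  n <- length(ds$drugs)
  k <- as.integer(k)

  local_seed(seed, {
    params <- list(
      U = glorot_normal(n, k),
      w = glorot_normal(k, 1),
      b = numeric(n),
      b0 = 0
    )
    opt <- adam_init(params)
    do_prop <- use_propagation && alpha > 0
    P <- if (do_prop) prop_matrix(ds$R, alpha) else NULL
    history <- numeric(epochs)

    for (epoch in seq_len(epochs)) {
      batch <- negative_sample(ds, ratio = neg_ratio, seed = seed,
                               epoch = epoch)
      perm <- sample.int(nrow(batch))
      bi <- batch$i[perm]; bj <- batch$j[perm]; by <- batch$label[perm]
      starts <- seq(1, length(by), by = batch_size)
      losses <- numeric(length(starts))
      for (s in seq_along(starts)) {
        idx <- starts[s]:min(starts[s] + batch_size - 1, length(by))
        i <- bi[idx]; j <- bj[idx]; y <- by[idx]
        B <- length(idx)
        Ut <- if (do_prop) as.matrix(P %*% params$U) else params$U
        Ui <- Ut[i, , drop = FALSE]
        Uj <- Ut[j, , drop = FALSE]
        H <- Ui * Uj
        z <- drop(H %*% params$w) + (params$b[i] + params$b[j]) + params$b0
        p <- sigmoid(z)
        losses[s] <- bce_loss(p, y)
        dz <- (p - y) / B
        wrow <- matrix(params$w, B, k, byrow = TRUE)
        dUt_rows <- rowsum(rbind(Uj * wrow * dz, Ui * wrow * dz),
                           group = c(i, j))
        dUt <- matrix(0, n, k)
        dUt[as.integer(rownames(dUt_rows)), ] <- dUt_rows
        db_rows <- rowsum(c(dz, dz), group = c(i, j))
        db <- numeric(n)
        db[as.integer(rownames(db_rows))] <- db_rows
        grads <- list(
          U = if (do_prop) as.matrix(Matrix::crossprod(P, dUt)) else dUt,
          w = crossprod(H, dz),
          b = db,
          b0 = sum(dz)
        )
        step <- adam_step(params, grads, opt, lr)
        params <- step$params
        opt <- step$state
      }
      history[epoch] <- mean(losses)
    }

    structure(
      list(
        drugs = ds$drugs, R = ds$R,
        U = params$U, w = drop(params$w), b = params$b, b0 = params$b0,
        alpha = alpha, k = k, propagation = use_propagation,
        history = tibble(epoch = seq_len(epochs), loss = history)
      ),
      class = if (use_propagation) "amfp_model" else c("amf_model", "amfp_model")
    )
  })
}

# Propagated factor matrix of a fitted model.
amfp_factors <- function(model) {
  if (model$propagation && model$alpha > 0) {
    propagate(model$U, model$R, model$alpha)
  } else {
    model$U
  }
}

#' Score drug pairs with a factorization model
#'
#' @param model A fitted `amfp_model`.
#' @param i,j Integer catalog indices (vectors of equal length), `i != j`
#'   elementwise.
#' @return Probabilities in (0, 1), symmetric in `(i, j)`.
#' @export
predict_pair_amfp <- function(model, i, j) {
  stopifnot(inherits(model, "amfp_model"))
  if (any(i == j)) abort("self-pairs (i == j) cannot be scored")
  Ut <- amfp_factors(model)
  H <- Ut[i, , drop = FALSE] * Ut[j, , drop = FALSE]
  # biases grouped so the score is bitwise symmetric in (i, j)
  unname(sigmoid(drop(H %*% model$w) + (model$b[i] + model$b[j]) + model$b0))
}

#' Predict method for factorization models
#'
#' @param object A fitted `amfp_model`.
#' @param pairs A tibble with integer columns `i`, `j` (catalog indices) or
#'   character columns `drug_a`, `drug_b`.
#' @param ... Unused.
#' @return `pairs` with a `.score` column appended.
#' @export
predict.amfp_model <- function(object, pairs, ...) {
  pairs <- resolve_pair_indices(pairs, object$drugs)
  dplyr::mutate(pairs, .score = predict_pair_amfp(object, pairs$i, pairs$j))
}

# Accept pairs given by index or by drug ID.
resolve_pair_indices <- function(pairs, drugs) {
  stopifnot(is.data.frame(pairs))
  pairs <- as_tibble(pairs)
  if (!all(c("i", "j") %in% names(pairs))) {
    if (!all(c("drug_a", "drug_b") %in% names(pairs))) {
      abort("`pairs` needs columns i/j or drug_a/drug_b")
    }
    i <- match(pairs$drug_a, drugs)
    j <- match(pairs$drug_b, drugs)
    if (anyNA(i) || anyNA(j)) {
      missing <- unique(c(pairs$drug_a[is.na(i)], pairs$drug_b[is.na(j)]))
      abort(sprintf("drug ID(s) not in the model catalog: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    pairs$i <- i
    pairs$j <- j
  }
  pairs
}

#' @export
print.amfp_model <- function(x, ...) {
  cat(sprintf(
    "<%s> %d drugs, k = %d%s, %d epochs%s\n",
    if (x$propagation) "amfp_model" else "amf_model",
    length(x$drugs), x$k,
    if (x$propagation) sprintf(", alpha = %.2f", x$alpha) else "",
    nrow(x$history),
    if (nrow(x$history) > 0)
      sprintf(", final loss %.4f", x$history$loss[nrow(x$history)]) else ""
  ))
  invisible(x)
}
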