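# Minimal feed-forward network engine: Glorot-normal initialization, ReLU
# hidden layers, sigmoid output, inverted dropout, binary cross-entropy,
# and Adam. Shared by the bio-text pair classifier, the stacking combiner,
# and (for the optimizer) the factorization component.

# widths: c(n_input, hidden widths..., 1). Consumes RNG; callers seed.
mlp_init <- function(widths) {
  stopifnot(length(widths) >= 2, widths[length(widths)] == 1L)
  L <- length(widths) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- glorot_normal(widths[l], widths[l + 1])
    b[[l]] <- matrix(0, 1, widths[l + 1])
  }
  structure(list(W = W, b = b, widths = widths), class = "mlp_net")
}

# X: B x n_input. Returns probabilities and, when cache = TRUE, the
# intermediates needed for the backward pass. Dropout is applied to hidden
# activations only, and only in training mode (inference is deterministic).
mlp_forward <- function(net, X, dropout = 0, training = FALSE, cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != net$widths[1]) {
    abort(sprintf("feature width %d does not match network input width %d",
                  ncol(X), net$widths[1]))
  }
  L <- length(net$W)
  A <- vector("list", L)      # input to each layer (post-dropout)
  relu_on <- vector("list", L - 1)
  masks <- vector("list", L - 1)
  a <- X
  for (l in seq_len(L - 1)) {
    A[[l]] <- a
    z <- sweep(a %*% net$W[[l]], 2, net$b[[l]], "+")
    relu_on[[l]] <- z > 0
    a <- z * relu_on[[l]]
    if (training && dropout > 0) {
      keep <- 1 - dropout
      masks[[l]] <- matrix(runif(length(a)) < keep, nrow(a), ncol(a)) / keep
      a <- a * masks[[l]]
    }
  }
  A[[L]] <- a
  z_out <- unname(drop(a %*% net$W[[L]] + net$b[[L]][1, 1]))
  p <- sigmoid(z_out)
  if (!cache) return(p)
  list(p = p, A = A, relu_on = relu_on, masks = masks)
}

# dz_out: d(loss)/d(z_out), length B. Returns parameter gradients and the
# gradient with respect to the input features (needed when a trainable
# drug-ID embedding feeds the input layer).
mlp_grads <- function(net, fw, dz_out, want_dX = FALSE) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  d <- matrix(dz_out, ncol = 1)
  gW[[L]] <- crossprod(fw$A[[L]], d)
  gb[[L]] <- matrix(colSums(d), 1)
  dA <- d %*% t(net$W[[L]])
  for (l in rev(seq_len(L - 1))) {
    if (!is.null(fw$masks[[l]])) dA <- dA * fw$masks[[l]]
    dZ <- dA * fw$relu_on[[l]]
    gW[[l]] <- crossprod(fw$A[[l]], dZ)
    gb[[l]] <- matrix(colSums(dZ), 1)
    dA <- dZ %*% t(net$W[[l]])
  }
  out <- list(W = gW, b = gb)
  if (want_dX) out$dX <- dA
  out
}

#' Binary cross-entropy loss
#'
#' Mean over instances of `-(y log p + (1 - y) log(1 - p))`, with
#' predictions clipped to `[eps, 1 - eps]` for numerical stability.
#'
#' @param predictions Numeric vector of probabilities.
#' @param labels Binary vector (0/1) of the same length.
#' @param eps Clipping constant, default `1e-7`.
#' @return A single non-negative number.
#' @examples
#' bce_loss(c(0.5, 0.5), c(1, 0))  # log(2)
#' @export
bce_loss <- function(predictions, labels, eps = 1e-7) {
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have the same length")
  }
  p <- pmin(pmax(predictions, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- Adam over a flat list of numeric arrays ------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)  # zeros with p's exact shape
  list(m = zeros, v = zeros, t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / c1) / (sqrt(state$v[[k]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Flatten/unflatten an mlp_net's parameters for the Adam loop.
net_params <- function(net) c(net$W, net$b)

net_set_params <- function(net, params) {
  L <- length(net$W)
  net$W <- params[seq_len(L)]
  net$b <- params[L + seq_len(L)]
  net
}
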