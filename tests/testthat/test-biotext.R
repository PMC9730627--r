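test_that("pair features have the documented layout for every variant", {
  e100 <- rnorm(100)
  expect_length(build_pair_features(e100, rnorm(100), "concat"), 200)

  # multiply annihilates on a zero vector but keeps the bias component
  f <- build_pair_features(rep(0, 5), rnorm(5), "multiply")
  expect_equal(f, c(rep(0, 5), 1))

  # concat feature combination: e=3 text + k=2 id -> 3+3+2
  f2 <- build_pair_features(1:3, 4:6, "concat_feature_combination",
                            id_i = c(1, 2), id_j = c(3, 4))
  expect_length(f2, 8)
  expect_equal(f2, c(1:3, 4:6, 3, 8))

  f3 <- build_pair_features(c(1, 2), c(3, 4), "multiply_feature_combination",
                            id_i = c(1, 1), id_j = c(2, 2))
  expect_equal(f3, c(3, 8, 2, 2))

  expect_error(build_pair_features(1:3, 1:4, "concat"), "same length")
  expect_error(build_pair_features(1:3, 1:3, "concat", id_i = 1:2, id_j = 1:2),
               "only used by feature-combination")
  expect_error(build_pair_features(1:3, 1:3, "concat_feature_combination"),
               "require")
})

test_that("the forward pass reproduces hand-computed values", {
  # H=1: W0=[[1],[-1]], b0=0, output weight 2, bias -1, input [3,1]
  net <- make_mlp(
    W = list(matrix(c(1, -1), 2, 1), matrix(2, 1, 1)),
    b = list(matrix(0, 1, 1), matrix(-1, 1, 1))
  )
  Lmat <- rbind(c(3), c(1))
  rownames(Lmat) <- c("a", "b")
  model <- make_biotext(net, Lmat, variant = "concat")
  # hidden = ReLU(3 - 1) = 2; output = sigmoid(2*2 - 1) = sigmoid(3)
  expect_equal(biotext_forward(model, c(3, 1)), 1 / (1 + exp(-3)),
               tolerance = 1e-12)
  expect_equal(biotext_forward(model, c(3, 1)), 0.9526, tolerance = 1e-4)

  # all-zero weights: sigmoid(0) = 0.5
  zero <- make_mlp(W = list(matrix(0, 2, 3), matrix(0, 3, 1)),
                   b = list(matrix(0, 1, 3), matrix(0, 1, 1)))
  expect_equal(biotext_forward(make_biotext(zero, Lmat), c(1, 2)), 0.5)

  # a unit with negative pre-activation contributes exactly nothing
  net_dead <- make_mlp(
    W = list(matrix(c(1, -1, -5, -5), 2, 2), matrix(c(2, 7), 2, 1)),
    b = list(matrix(0, 1, 2), matrix(-1, 1, 1))
  )
  m_dead <- make_biotext(net_dead, Lmat)
  expect_identical(biotext_forward(m_dead, c(3, 1)),
                   biotext_forward(model, c(3, 1)))

  expect_error(biotext_forward(model, c(1, 2, 3)), "width")
})

test_that("binary cross-entropy matches analytic values", {
  expect_lte(bce_loss(c(1, 0), c(1, 0)), 1.1e-7)  # clipped perfection
  expect_equal(bce_loss(c(0.5, 0.5, 0.5), c(1, 0, 1)), log(2))
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)),
               -(log(0.9) + log(0.8)) / 2)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), 0.164252, tolerance = 1e-6)
  expect_error(bce_loss(c(0.5), c(1, 0)), "same length")
})

test_that("analytic gradients agree with numerical differentiation", {
  withr::with_seed(7, {
    net <- abte:::mlp_init(c(3, 4, 3, 1))
    X <- matrix(rnorm(15), 5, 3)
    y <- c(1, 0, 1, 1, 0)
  })
  fw <- abte:::mlp_forward(net, X, cache = TRUE)
  g <- abte:::mlp_grads(net, fw, (fw$p - y) / length(y), want_dX = TRUE)
  loss_at <- function(net2, X2 = X) {
    bce_loss(abte:::mlp_forward(net2, X2), y, eps = 0)
  }
  h <- 1e-5
  check <- function(analytic, get, set) {
    for (idx in seq_along(analytic)) {
      up <- set(idx, h); down <- set(idx, -h)
      num <- (loss_at(up$net, up$X) - loss_at(down$net, down$X)) / (2 * h)
      rel <- abs(analytic[idx] - num) / max(1e-8, abs(analytic[idx]) + abs(num))
      expect_lt(rel, 1e-4)
    }
  }
  for (l in 1:3) {
    check(as.numeric(g$W[[l]]),
          set = function(idx, d) {
            n2 <- net; n2$W[[l]][idx] <- n2$W[[l]][idx] + d
            list(net = n2, X = X)
          })
    check(as.numeric(g$b[[l]]),
          set = function(idx, d) {
            n2 <- net; n2$b[[l]][idx] <- n2$b[[l]][idx] + d
            list(net = n2, X = X)
          })
  }
  # input gradient (used by the trainable drug-ID embedding)
  check(as.numeric(g$dX[, 1]),
        set = function(idx, d) {
          X2 <- X; X2[idx, 1] <- X2[idx, 1] + d
          list(net = net, X = X2)
        })
})

test_that("pair scoring is symmetric and inference deterministic", {
  withr::with_seed(3, {
    Lmat <- matrix(rnorm(6 * 4), 6, 4)
    rownames(Lmat) <- sprintf("d%d", 1:6)
    net_c <- abte:::mlp_init(c(8, 5, 1))
    net_m <- abte:::mlp_init(c(5, 5, 1))
  })
  mc <- make_biotext(net_c, Lmat, variant = "concat")
  mm <- make_biotext(net_m, Lmat, variant = "multiply")
  for (p in list(c(1, 2), c(3, 5), c(2, 6))) {
    # multiply variants are symmetric by construction (exact)
    expect_identical(abte:::biotext_score(mm, p[1], p[2]),
                     abte:::biotext_score(mm, p[2], p[1]))
    # concat variants are symmetrized by order averaging
    expect_equal(abte:::biotext_score(mc, p[1], p[2]),
                 abte:::biotext_score(mc, p[2], p[1]), tolerance = 1e-12)
  }
  s1 <- abte:::biotext_score(mc, 1:3, 4:6)
  s2 <- abte:::biotext_score(mc, 1:3, 4:6)
  expect_identical(s1, s2)
  expect_error(abte:::biotext_score(mc, 2, 2), "self-pairs")
})

test_that("training separates embedding clusters on held-out pairs", {
  n <- 30
  drugs <- sprintf("d%02d", 1:n)
  cluster <- rep(1:3, each = 10)
  tab <- clustered_embeddings(drugs, cluster, dim = 10, noise = 0.1, seed = 4)
  suppressMessages(dvm <- resolve_drugs(drugs, tab))
  # training edges: a sampled subset of same-cluster pairs
  all_pairs <- expand.grid(i = 1:n, j = 1:n)
  all_pairs <- all_pairs[all_pairs$i < all_pairs$j, ]
  same <- cluster[all_pairs$i] == cluster[all_pairs$j]
  withr::with_seed(9, keep <- same & runif(nrow(all_pairs)) < 0.6)
  ds <- ds_from_edges(drugs[all_pairs$i[keep]], drugs[all_pairs$j[keep]],
                      catalog = drugs)
  m <- train_biotext(ds, dvm, hidden = c(32, 16), epochs = 40, seed = 1)
  held <- !keep  # pairs unseen in training; label = shared cluster
  s <- abte:::biotext_score(m, all_pairs$i[held], all_pairs$j[held])
  expect_gt(auroc(s, as.integer(same[held])), 0.9)
})

test_that("feature-combination training learns a drug-ID embedding jointly", {
  ds <- random_ds(10, p = 0.4, seed = 6)
  tab <- clustered_embeddings(ds$drugs, rep(1:2, 5), dim = 6, seed = 2)
  suppressMessages(dvm <- resolve_drugs(ds$drugs, tab))
  m0 <- train_biotext(ds, dvm, variant = "multiply_feature_combination",
                      hidden = 8, id_dim = 4, epochs = 0, seed = 5)
  m <- train_biotext(ds, dvm, variant = "multiply_feature_combination",
                     hidden = 8, id_dim = 4, epochs = 10, seed = 5)
  expect_equal(dim(m$id_embedding), c(10, 4))
  expect_false(identical(m0$id_embedding, m$id_embedding))  # it trains
  # text vectors stay frozen
  expect_identical(m$Lmat, dvm$matrix)
})

test_that("zero-epoch training yields reproducible initial predictions", {
  ds <- random_ds(8, p = 0.4, seed = 3)
  tab <- clustered_embeddings(ds$drugs, rep(1:2, 4), dim = 5, seed = 1)
  suppressMessages(dvm <- resolve_drugs(ds$drugs, tab))
  a <- train_biotext(ds, dvm, hidden = 6, epochs = 0, seed = 2)
  b <- train_biotext(ds, dvm, hidden = 6, epochs = 0, seed = 2)
  expect_identical(abte:::biotext_score(a, 1, 2), abte:::biotext_score(b, 1, 2))
  expect_equal(nrow(a$history), 0)
  expect_error(train_biotext(ds, dvm, dropout = 0.95), "0.9")
})
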