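test_that("edge lists load into symmetric binary matrices with correct counts", {
  ds <- ds_from_edges(c("A", "B"), c("B", "C"))
  expect_equal(ds$drugs, c("A", "B", "C"))
  expect_equal(unname(ds$counts), c(1L, 2L, 1L))
  expect_equal(as.matrix(ds$R), t(as.matrix(ds$R)))
  expect_true(all(Matrix::diag(ds$R) == 0))

  # duplicate rows in either orientation collapse to one undirected edge
  dup <- ds_from_edges(c("A", "B"), c("B", "A"))
  expect_equal(unname(dup$counts), c(1L, 1L))
  expect_equal(sum(dup$R), 2)
})

test_that("edge-list file reading handles comments, duplicates and errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# release 5.0.0", "B\tA", "A\tB", "B\tC"), f)
  ds <- load_interactions(f)
  expect_equal(ds$drugs, c("A", "B", "C"))
  expect_equal(unname(ds$counts), c(1L, 2L, 1L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "C\tC"), bad)
  expect_error(load_interactions(bad), "line 2.*self-interaction")

  expect_error(
    load_interactions(f, catalog = c("A", "B")),
    "'C'.*absent from the supplied catalog"
  )
})

test_that("edge lists restricted to a shared catalog keep only catalog pairs", {
  shared <- c("A", "B", "C")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tC"), f)
  test_ds <- load_interactions(f, catalog = shared)
  expect_equal(test_ds$drugs, shared)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tD"), f2)
  expect_error(load_interactions(f2, catalog = shared), "'D'")
})

test_that("edge list writing round-trips exactly", {
  ds <- random_ds(8, p = 0.4, seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(ds, f)
  back <- load_interactions(f, catalog = ds$drugs)
  expect_identical(as.matrix(back$R), as.matrix(ds$R))
})

test_that("temporal split labels added interactions and drops train positives", {
  cat3 <- c("A", "B", "C")
  train <- ds_from_edges("A", "B", catalog = cat3)
  test <- ds_from_edges(c("A", "A"), c("B", "C"), catalog = cat3)
  ev <- temporal_split(train, test)
  expect_equal(nrow(ev), 2)  # C(3,2) - 1 train positive
  expect_equal(ev$label[ev$drug_a == "A" & ev$drug_b == "C"], 1L)
  expect_equal(ev$label[ev$drug_a == "B" & ev$drug_b == "C"], 0L)

  same <- temporal_split(train, train)
  expect_equal(sum(same$label), 0)

  other <- ds_from_edges("X", "Y")
  expect_error(temporal_split(train, other), "share one drug catalog")
})

test_that("temporal split enumerates exactly the non-train pairs (exhaustive)", {
  for (seed in 1:5) {
    n <- 4 + seed %% 4
    train <- random_ds(n, p = 0.3, seed = seed)
    test <- random_ds(n, p = 0.5, seed = seed + 100)
    ev <- temporal_split(train, test)
    # brute force over all C(n,2) pairs
    expected <- 0L
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (train$R[i, j] == 0) expected <- expected + 1L
    }
    expect_equal(nrow(ev), expected)
    expect_true(all(ev$i < ev$j))
    for (r in seq_len(nrow(ev))) {
      expect_equal(ev$label[r],
                   as.integer(test$R[ev$i[r], ev$j[r]] != 0))
    }
  }
})

test_that("validation split holds out the requested fractions and partitions positives", {
  ds <- random_ds(12, p = 0.3, seed = 2)
  n_pos <- sum(ds$counts) / 2
  sp <- validation_split(ds, fraction = 0.2, seed = 9)
  expect_equal(sum(sp$validation$label), floor(0.2 * n_pos))
  expect_equal(sum(sp$train$counts) / 2, n_pos - floor(0.2 * n_pos))

  # same seed twice gives an identical split
  sp2 <- validation_split(ds, fraction = 0.2, seed = 9)
  expect_identical(sp$validation, sp2$validation)
  expect_identical(as.matrix(sp$train$R), as.matrix(sp2$train$R))

  # sub-train positives and validation positives partition the originals
  ds4 <- ds_from_edges(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  sp4 <- validation_split(ds4, fraction = 0.5, seed = 1)
  val_pos <- sp4$validation[sp4$validation$label == 1, c("drug_a", "drug_b")]
  sub_pos <- abte:::positive_edges(sp4$train)
  combined <- dplyr::arrange(dplyr::bind_rows(val_pos, sub_pos), drug_a, drug_b)
  expect_equal(combined, abte:::positive_edges(ds4))

  expect_error(validation_split(ds, fraction = 1.2), "between 0 and 1")
  expect_error(validation_split(ds, fraction = 0), "between 0 and 1")
})

test_that("negative sampling honours the ratio and never hits edges or self-pairs", {
  # 5 positives over 6 drugs: C(6,2) = 15 pairs, 10 non-edges
  ds <- ds_from_edges(c("A", "A", "B", "C", "D"),
                      c("B", "C", "C", "D", "E"),
                      catalog = c("A", "B", "C", "D", "E", "F"))
  b1 <- negative_sample(ds, ratio = 1, seed = 4, epoch = 1)
  expect_equal(nrow(b1), 10)
  expect_equal(sum(b1$label == 0), 5)

  # every drawn negative is a genuine non-edge, never a self-pair
  for (epoch in 1:20) {
    b <- negative_sample(ds, ratio = 1, seed = 4, epoch = epoch)
    neg <- b[b$label == 0, ]
    expect_true(all(neg$i < neg$j))
    expect_true(all(ds$R[cbind(neg$i, neg$j)] == 0))
    pos <- b[b$label == 1, ]
    expect_true(all(ds$R[cbind(pos$i, pos$j)] == 1))
  }

  expect_equal(sum(negative_sample(ds, ratio = 2, seed = 1)$label == 0), 10)
  expect_identical(negative_sample(ds, ratio = 1, seed = 7, epoch = 3),
                   negative_sample(ds, ratio = 1, seed = 7, epoch = 3))
  expect_false(identical(negative_sample(ds, ratio = 1, seed = 7, epoch = 3),
                         negative_sample(ds, ratio = 1, seed = 7, epoch = 4)))
})

test_that("negative sampling errors when the non-edge pool is exhausted", {
  full <- ds_from_edges(c("A", "A", "B"), c("B", "C", "C"))  # complete K3
  expect_error(negative_sample(full, ratio = 1), "only 0 non-interacting")
  ds <- ds_from_edges(c("A", "A", "B", "C", "D"), c("B", "C", "C", "D", "E"))
  expect_error(negative_sample(ds, ratio = 2), "non-interacting pairs exist")
})

test_that("interaction counts equal brute-force row sums", {
  star <- ds_from_edges(rep("hub", 4), c("l1", "l2", "l3", "l4"))
  cnt <- interaction_counts(star)
  expect_equal(cnt$n_interactions[cnt$drug == "hub"], 4L)
  expect_equal(cnt$n_interactions[cnt$drug != "hub"], rep(1L, 4))

  ds <- random_ds(6, p = 0.4, seed = 11)
  expect_equal(interaction_counts(ds)$n_interactions,
               as.integer(rowSums(as.matrix(ds$R))))
})

test_that("loaded matrices are always symmetric with empty diagonal", {
  for (seed in 1:6) {
    ds <- random_ds(5 + 3 * seed, p = 0.25, seed = seed)
    M <- as.matrix(ds$R)
    expect_identical(M, t(M))
    expect_true(all(diag(M) == 0))
  }
})
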