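# Interaction data ingestion: edge lists, symmetric adjacency matrices,
# temporal and validation splits, per-epoch negative sampling.

#' Read a drug-drug interaction edge list
#'
#' Reads a tab-separated file with two drug-identifier columns, one
#' undirected interaction per line. Lines starting with `#` are ignored.
#' Duplicate rows (in either orientation) are collapsed to a single edge.
#'
#' @param path Path to a TSV file with columns `drug_id_a<TAB>drug_id_b`.
#' @return A tibble with character columns `drug_a` and `drug_b`, one row per
#'   unique undirected edge, canonicalized so `drug_a < drug_b`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    abort(sprintf("line %d of '%s': expected two tab-separated drug IDs",
                  lineno[bad[1]], path))
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  self <- which(a == b)
  if (length(self) > 0) {
    abort(sprintf("line %d of '%s': self-interaction '%s' is not allowed",
                  lineno[self[1]], path, a[self[1]]))
  }
  canonicalize_edges(tibble(drug_a = a, drug_b = b))
}

#' Write an edge list to a TSV file
#'
#' @param edges A tibble with columns `drug_a`, `drug_b`, or an
#'   `interaction_dataset` whose training edges are written.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "interaction_dataset")) edges <- positive_edges(edges)
  writeLines(paste(edges$drug_a, edges$drug_b, sep = "\t"), path)
  invisible(path)
}

# Canonical undirected form: drug_a < drug_b, duplicates collapsed,
# deterministic row order.
canonicalize_edges <- function(edges) {
  a <- pmin(edges$drug_a, edges$drug_b)
  b <- pmax(edges$drug_a, edges$drug_b)
  out <- dplyr::distinct(tibble(drug_a = a, drug_b = b))
  dplyr::arrange(out, .data$drug_a, .data$drug_b)
}

#' Build an interaction dataset from an edge table
#'
#' Constructs the symmetric binary adjacency matrix over a drug catalog,
#' together with per-drug interaction counts. When no catalog is supplied it
#' is built from the union of drug IDs in the edges, sorted lexicographically
#' so that matrix indices are reproducible across runs.
#'
#' @param edges Tibble with character columns `drug_a`, `drug_b` (one row per
#'   undirected interaction), as returned by [read_edge_list()].
#' @param catalog Optional character vector of drug IDs fixing the matrix
#'   order. Every edge endpoint must appear in it.
#' @return An object of class `interaction_dataset`: a list with elements
#'   `drugs` (the catalog), `R` (sparse symmetric 0/1 matrix with zero
#'   diagonal) and `counts` (named integer vector of per-drug training
#'   interaction counts).
#' @examples
#' edges <- tibble::tibble(drug_a = c("A", "B"), drug_b = c("B", "C"))
#' ds <- interaction_dataset(edges)
#' interaction_counts(ds)
#' @export
interaction_dataset <- function(edges, catalog = NULL) {
  edges <- canonicalize_edges(edges)
  ids <- unique(c(edges$drug_a, edges$drug_b))
  if (is.null(catalog)) {
    catalog <- sort(ids, method = "radix")
  } else {
    catalog <- as.character(catalog)
    if (anyDuplicated(catalog)) abort("catalog contains duplicated drug IDs")
    missing <- setdiff(ids, catalog)
    if (length(missing) > 0) {
      abort(sprintf("drug ID '%s' in the edge list is absent from the supplied catalog",
                    missing[1]))
    }
  }
  n <- length(catalog)
  if (n < 2) abort("an interaction dataset needs at least two drugs")
  i <- match(edges$drug_a, catalog)
  j <- match(edges$drug_b, catalog)
  R <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(catalog, catalog)
  )
  R@x[] <- 1  # collapse any duplicate accumulation back to binary
  new_interaction_dataset(catalog, R)
}

new_interaction_dataset <- function(drugs, R) {
  counts <- as.integer(Matrix::rowSums(R))
  names(counts) <- drugs
  structure(
    list(drugs = drugs, R = R, counts = counts),
    class = "interaction_dataset"
  )
}

#' Load an interaction dataset from an edge-list file
#'
#' @inheritParams read_edge_list
#' @inheritParams interaction_dataset
#' @return An `interaction_dataset`; see [interaction_dataset()].
#' @export
load_interactions <- function(path, catalog = NULL) {
  interaction_dataset(read_edge_list(path), catalog = catalog)
}

#' @export
print.interaction_dataset <- function(x, ...) {
  cat(sprintf(
    "<interaction_dataset> %d drugs, %d interactions (density %.4f)\n",
    length(x$drugs), sum(x$counts) / 2,
    sum(x$counts) / 2 / n_pairs(length(x$drugs))
  ))
  invisible(x)
}

# Positive (training) pairs as integer indices i < j.
positive_pair_indices <- function(ds) {
  up <- Matrix::triu(ds$R, k = 1)
  s <- Matrix::summary(up)
  ord <- order(s$j, s$i)
  cbind(i = s$i[ord], j = s$j[ord])
}

# Positive pairs as a drug-ID tibble.
positive_edges <- function(ds) {
  p <- positive_pair_indices(ds)
  tibble(drug_a = ds$drugs[p[, "i"]], drug_b = ds$drugs[p[, "j"]])
}

#' Per-drug interaction counts
#'
#' The number of training partners of each drug, i.e. the row degree of the
#' symmetric training adjacency matrix. These counts drive the cold-start
#' switching rule and the rare-drug stratification.
#'
#' @param ds An `interaction_dataset`.
#' @return A tibble with columns `drug` and `n_interactions`, in catalog order.
#' @export
interaction_counts <- function(ds) {
  stopifnot(inherits(ds, "interaction_dataset"))
  tibble(drug = ds$drugs, n_interactions = unname(ds$counts))
}

#' Enumerate temporal evaluation pairs
#'
#' Given a training release and a later test release over the same drug
#' catalog, enumerates every unordered drug pair not already interacting in
#' the training data. A pair is labelled 1 when it appears in the test
#' release -- the retrospective prediction target is exactly the interactions
#' added between the two releases.
#'
#' @param train,test `interaction_dataset` objects sharing one catalog.
#' @return A tibble with columns `drug_a`, `drug_b`, `i`, `j` (catalog
#'   indices, `i < j`) and integer `label`.
#' @export
temporal_split <- function(train, test) {
  stopifnot(inherits(train, "interaction_dataset"),
            inherits(test, "interaction_dataset"))
  if (!identical(train$drugs, test$drugs)) {
    abort("train and test datasets must share one drug catalog")
  }
  n <- length(train$drugs)
  all_k <- seq_len(n_pairs(n))
  train_k <- pair_to_index(positive_pair_indices(train)[, "i"],
                           positive_pair_indices(train)[, "j"])
  test_k <- pair_to_index(positive_pair_indices(test)[, "i"],
                          positive_pair_indices(test)[, "j"])
  eval_k <- setdiff(all_k, train_k)
  ij <- index_to_pair(eval_k)
  tibble(
    drug_a = train$drugs[ij[, "i"]],
    drug_b = train$drugs[ij[, "j"]],
    i = ij[, "i"], j = ij[, "j"],
    label = as.integer(eval_k %in% setdiff(test_k, train_k))
  )
}

#' Hold out a validation set of existing and non-existing interactions
#'
#' Samples the given fraction of positive pairs and, independently, the same
#' fraction of non-interacting pairs uniformly at random into a validation
#' set. Selected positives are removed from the returned sub-training
#' dataset; component models are fit on the sub-training matrix and the
#' validation pairs supply scores for stacking and for tuning the switching
#' threshold.
#'
#' @param ds An `interaction_dataset`.
#' @param fraction Proportion in (0, 1) of positives (and of non-edges) to
#'   hold out. Defaults to 0.2.
#' @param seed Integer seed; the split is reproducible given the seed.
#' @return A list with elements `train` (an `interaction_dataset` with the
#'   validation positives removed) and `validation` (a pair tibble with
#'   columns `i`, `j`, `drug_a`, `drug_b`, `label`).
#' @export
validation_split <- function(ds, fraction = 0.2, seed = 1L) {
  stopifnot(inherits(ds, "interaction_dataset"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single number strictly between 0 and 1")
  }
  n <- length(ds$drugs)
  pos <- positive_pair_indices(ds)
  pos_k <- pair_to_index(pos[, "i"], pos[, "j"])
  neg_k <- setdiff(seq_len(n_pairs(n)), pos_k)
  n_pos_val <- floor(fraction * length(pos_k))
  n_neg_val <- floor(fraction * length(neg_k))
  sel <- local_seed(seed, {
    list(pos = sort(sample(pos_k, n_pos_val)),
         neg = sort(sample(neg_k, n_neg_val)))
  })
  val_k <- c(sel$pos, sel$neg)
  ij <- index_to_pair(val_k)
  validation <- tibble(
    i = ij[, "i"], j = ij[, "j"],
    drug_a = ds$drugs[ij[, "i"]], drug_b = ds$drugs[ij[, "j"]],
    label = as.integer(val_k %in% sel$pos)
  )
  keep <- !(pos_k %in% sel$pos)
  sub <- interaction_dataset(
    tibble(drug_a = ds$drugs[pos[keep, "i"]], drug_b = ds$drugs[pos[keep, "j"]]),
    catalog = ds$drugs
  )
  list(train = sub, validation = validation)
}

#' Draw a training batch by negative sampling
#'
#' Builds the per-epoch training batch: every known (positive) interaction,
#' plus `floor(ratio * n_positives)` negatives drawn uniformly without
#' replacement from the non-interacting pairs. An unobserved pair is treated
#' as implicit feedback -- usable as a negative, not a verified
#' non-interaction. A different negative sample is drawn each epoch; the draw
#' is deterministic given `(seed, epoch)`.
#'
#' @param ds An `interaction_dataset`.
#' @param ratio Negatives per positive (positive number). Defaults to 1.
#' @param seed Integer base seed.
#' @param epoch Integer epoch number; varying it varies the negative draw.
#' @return A pair-batch tibble with columns `i`, `j` (`i < j`) and `label`.
#' @export
negative_sample <- function(ds, ratio = 1, seed = 1L, epoch = 1L) {
  stopifnot(inherits(ds, "interaction_dataset"))
  if (!is.numeric(ratio) || ratio <= 0) abort("`ratio` must be positive")
  n <- length(ds$drugs)
  pos <- positive_pair_indices(ds)
  pos_k <- pair_to_index(pos[, "i"], pos[, "j"])
  neg_pool <- setdiff(seq_len(n_pairs(n)), pos_k)
  n_neg <- floor(ratio * length(pos_k))
  if (n_neg > length(neg_pool)) {
    abort(sprintf(
      "requested %d negatives but only %d non-interacting pairs exist",
      n_neg, length(neg_pool)
    ))
  }
  neg_k <- local_seed(mix_seed(seed, epoch), sample(neg_pool, n_neg))
  ij <- index_to_pair(c(pos_k, neg_k))
  tibble(
    i = ij[, "i"], j = ij[, "j"],
    label = rep(c(1L, 0L), c(length(pos_k), n_neg))
  )
}
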