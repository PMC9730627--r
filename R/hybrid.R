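# The hybrid ABTE model: a stacking combiner over the two component
# predictions plus the cold-start switching rule. A pair is routed to the
# stacker when both drugs have at least M training interactions; otherwise
# the factorization factors are uninformative and the text-only score is
# returned unchanged.

#' Train the stacking combiner
#'
#' A small feed-forward network (sigmoid output, binary cross-entropy,
#' Adam) over the two scalar component predictions. The components are
#' trained separately first; the stacker is fit on their scores for
#' held-out validation pairs so it sees honest, not training-fit,
#' probabilities.
#'
#' @param text_scores,amfp_scores Component probability vectors for the
#'   same instances.
#' @param labels Binary labels aligned to the scores.
#' @param hidden Hidden-layer widths of the combiner.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed Integer seed.
#' @return An object of class `stacking_model`.
#' @export
train_stacking <- function(text_scores, amfp_scores, labels, hidden = 8,
                           lr = 0.01, batch_size = 256, epochs = 100,
                           seed = 1L) {
  if (length(text_scores) != length(labels) ||
      length(amfp_scores) != length(labels)) {
    abort("scores and labels must have the same length")
  }
  X_all <- cbind(text_scores, amfp_scores)
  local_seed(seed, {
    net <- mlp_init(c(2L, as.integer(hidden), 1L))
    params <- net_params(net)
    opt <- adam_init(params)
    history <- numeric(epochs)
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(length(labels))
      starts <- seq(1, length(labels), by = batch_size)
      losses <- numeric(length(starts))
      for (s in seq_along(starts)) {
        idx <- perm[starts[s]:min(starts[s] + batch_size - 1, length(labels))]
        fw <- mlp_forward(net, X_all[idx, , drop = FALSE], training = TRUE,
                          cache = TRUE)
        y <- labels[idx]
        losses[s] <- bce_loss(fw$p, y)
        g <- mlp_grads(net, fw, (fw$p - y) / length(y))
        step <- adam_step(params, c(g$W, g$b), opt, lr)
        params <- step$params
        opt <- step$state
        net <- net_set_params(net, params)
      }
      history[epoch] <- mean(losses)
    }
    structure(
      list(net = net, history = tibble(epoch = seq_len(epochs), loss = history)),
      class = "stacking_model"
    )
  })
}

#' Predict method for the stacking combiner
#'
#' @param object A `stacking_model`.
#' @param text_scores,amfp_scores Component probability vectors.
#' @param ... Unused.
#' @return Combined probability vector.
#' @export
predict.stacking_model <- function(object, text_scores, amfp_scores, ...) {
  mlp_forward(object$net, cbind(text_scores, amfp_scores))
}

#' Tune the switching threshold M
#'
#' Evaluates every candidate threshold on validation pairs: pairs where
#' both drugs have at least `M` training interactions take the stacking
#' score, the rest the text score, and the candidate maximizing validation
#' AUPR wins (ties broken toward the smallest `M`).
#'
#' @param text_scores,stacking_scores Probability vectors on the validation
#'   pairs.
#' @param labels Binary validation labels.
#' @param counts_i,counts_j Training interaction counts of each pair's two
#'   drugs.
#' @param candidates Integer vector of thresholds to try (the search range
#'   used here is 0 to 10).
#' @return A list with `M` (the selected threshold) and `metrics`, a tibble
#'   of per-candidate validation AUPR/AUROC.
#' @export
tune_M <- function(text_scores, stacking_scores, labels, counts_i, counts_j,
                   candidates = 0:10) {
  if (length(candidates) == 0) abort("`candidates` must be non-empty")
  candidates <- sort(unique(as.integer(candidates)))
  mins <- pmin(counts_i, counts_j)
  metrics <- purrr::map_dfr(candidates, function(M) {
    routed <- ifelse(mins >= M, stacking_scores, text_scores)
    tibble(M = M,
           aupr = aupr(routed, labels),
           auroc = auroc(routed, labels),
           n_stacking = sum(mins >= M))
  })
  list(M = metrics$M[which.max(metrics$aupr)], metrics = metrics)
}

#' Train the full hybrid ABTE model
#'
#' Orchestrates the whole fit: holds out a validation set
#' ([validation_split()]), trains the bio-text classifier and the
#' factorization component separately on the sub-training matrix, fits the
#' stacking combiner on their validation scores, and (unless `M` is given)
#' tunes the switching threshold on the validation pairs. Switching uses
#' interaction counts from the full training release.
#'
#' @param ds An `interaction_dataset` (training release).
#' @param dvm A `drug_vector_map` over the same catalog.
#' @param variant Bio-text feature construction (see
#'   [build_pair_features()]).
#' @param M Switching threshold; `NULL` (default) tunes it over
#'   `M_candidates`.
#' @param M_candidates Candidate thresholds for tuning.
#' @param validation_fraction Fraction of positives and of non-edges held
#'   out for the stacker and for tuning `M`.
#' @param text_args,amfp_args,stack_args Named lists of extra arguments
#'   passed to [train_biotext()], [train_amfp()] and [train_stacking()].
#' @param seed Integer seed governing the split and all component fits.
#' @return An object of class `abte_model` holding both components, the
#'   stacker, the threshold `M`, the per-drug training counts used for
#'   switching, and (when tuned) the per-candidate metric table `m_table`.
#' @export
train_abte <- function(ds, dvm, variant = "concat", M = NULL,
                       M_candidates = 0:10, validation_fraction = 0.2,
                       text_args = list(), amfp_args = list(),
                       stack_args = list(), seed = 1L) {
  stopifnot(inherits(ds, "interaction_dataset"),
            inherits(dvm, "drug_vector_map"))
  split <- validation_split(ds, fraction = validation_fraction, seed = seed)
  sub <- split$train
  val <- split$validation

  biotext <- do.call(train_biotext,
                     c(list(ds = sub, dvm = dvm, variant = variant,
                            seed = seed), text_args))
  amfp <- do.call(train_amfp, c(list(ds = sub, seed = seed), amfp_args))

  text_val <- biotext_score(biotext, val$i, val$j)
  amfp_val <- predict_pair_amfp(amfp, val$i, val$j)
  stacker <- do.call(train_stacking,
                     c(list(text_scores = text_val, amfp_scores = amfp_val,
                            labels = val$label, seed = seed), stack_args))
  stack_val <- predict(stacker, text_val, amfp_val)

  counts <- ds$counts  # switching depends on training-release counts
  m_table <- NULL
  if (is.null(M)) {
    tm <- tune_M(text_val, stack_val, val$label,
                 counts[val$i], counts[val$j], candidates = M_candidates)
    M <- tm$M
    m_table <- tm$metrics
  }
  if (M < 0) abort("`M` must be a non-negative integer")

  structure(
    list(drugs = ds$drugs, biotext = biotext, amfp = amfp, stacker = stacker,
         M = as.integer(M), counts = counts, m_table = m_table,
         variant = variant),
    class = "abte_model"
  )
}

#' Score drug pairs with the hybrid model
#'
#' Routes each pair by the switching rule: the stacking combiner when both
#' drugs have at least `M` training interactions, otherwise the bio-text
#' component's score, returned exactly as the component computes it.
#'
#' @param model A fitted `abte_model`.
#' @param i,j Integer catalog indices, `i != j` elementwise.
#' @return Probability vector.
#' @export
abte_predict <- function(model, i, j) {
  stopifnot(inherits(model, "abte_model"))
  if (any(i == j)) abort("self-pairs (i == j) cannot be scored")
  text <- biotext_score(model$biotext, i, j)
  out <- text
  warm <- unname(model$counts[i] >= model$M & model$counts[j] >= model$M)
  if (any(warm)) {
    amfp <- predict_pair_amfp(model$amfp, i[warm], j[warm])
    out[warm] <- predict(model$stacker, text[warm], amfp)
  }
  out
}

#' Predict method for the hybrid model
#'
#' @param object A fitted `abte_model`.
#' @param pairs Tibble with columns `i`, `j` or `drug_a`, `drug_b`.
#' @param ... Unused.
#' @return `pairs` with `.score` and `.branch` (`"text"` or `"stacking"`)
#'   columns appended.
#' @export
predict.abte_model <- function(object, pairs, ...) {
  pairs <- resolve_pair_indices(pairs, object$drugs)
  warm <- unname(object$counts[pairs$i] >= object$M &
                   object$counts[pairs$j] >= object$M)
  dplyr::mutate(pairs,
                .score = abte_predict(object, pairs$i, pairs$j),
                .branch = ifelse(warm, "stacking", "text"))
}

#' @export
print.abte_model <- function(x, ...) {
  cat(sprintf(
    "<abte_model> %d drugs, variant '%s', M = %d (%s)\n",
    length(x$drugs), x$variant, x$M,
    if (is.null(x$m_table)) "fixed" else "tuned on validation AUPR"
  ))
  invisible(x)
}
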