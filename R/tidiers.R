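# broom-style tidiers and ggplot2 autoplot methods for fitted objects and
# evaluation reports.

#' Tidy a factorization model
#'
#' @param x An `amfp_model`.
#' @param ... Unused.
#' @return A tibble with one row per drug: its bias, training interaction
#'   count, and latent factors in columns `f1..fk`.
#' @export
tidy.amfp_model <- function(x, ...) {
  U <- x$U
  colnames(U) <- paste0("f", seq_len(ncol(U)))
  dplyr::bind_cols(
    tibble(drug = x$drugs, bias = x$b,
           n_interactions = as.integer(Matrix::rowSums(x$R))),
    as_tibble(U)
  )
}

#' @rdname tidy.amfp_model
#' @export
glance.amfp_model <- function(x, ...) {
  tibble(
    n_drugs = length(x$drugs), k = x$k,
    alpha = if (x$propagation) x$alpha else 0,
    propagation = x$propagation,
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history) > 0) x$history$loss[nrow(x$history)]
                 else NA_real_
  )
}

#' Tidy the bio-text classifier
#'
#' @param x A `biotext_model`.
#' @param ... Unused.
#' @return A tibble with one row per network layer: input and output width
#'   and parameter count.
#' @export
tidy.biotext_model <- function(x, ...) {
  w <- x$net$widths
  tibble(
    layer = seq_len(length(w) - 1),
    input_width = w[-length(w)],
    output_width = w[-1],
    n_parameters = w[-length(w)] * w[-1] + w[-1]
  )
}

#' @rdname tidy.biotext_model
#' @export
glance.biotext_model <- function(x, ...) {
  tibble(
    variant = x$variant,
    n_drugs = length(x$drugs),
    hidden = paste(x$hidden, collapse = "x"),
    dropout = x$dropout,
    epochs = nrow(x$history),
    final_loss = if (nrow(x$history) > 0) x$history$loss[nrow(x$history)]
                 else NA_real_
  )
}

#' Tidy the hybrid model
#'
#' @param x An `abte_model`.
#' @param ... Unused.
#' @return The per-candidate threshold metric table from tuning (tibble
#'   with columns `M`, `aupr`, `auroc`, `n_stacking`), or a one-row tibble
#'   with the fixed `M` when the threshold was not tuned.
#' @export
tidy.abte_model <- function(x, ...) {
  if (!is.null(x$m_table)) return(x$m_table)
  tibble(M = x$M, aupr = NA_real_, auroc = NA_real_, n_stacking = NA_integer_)
}

#' @rdname tidy.abte_model
#' @export
glance.abte_model <- function(x, ...) {
  tibble(
    n_drugs = length(x$drugs), variant = x$variant, M = x$M,
    tuned = !is.null(x$m_table),
    n_rare_drugs = sum(x$counts < x$M)
  )
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A long tibble with columns `stratum`, `metric`, `value`.
#' @export
tidy.eval_report <- function(x, ...) {
  rows <- list(
    tibble(stratum = "overall", metric = c("auroc", "aupr"),
           value = c(x$overall$auroc, x$overall$aupr)),
    tibble(stratum = "overall",
           metric = paste0("precision@", x$precision_recall$k),
           value = x$precision_recall$precision),
    tibble(stratum = "overall",
           metric = paste0("recall@", x$precision_recall$k),
           value = x$precision_recall$recall)
  )
  if (!is.null(x$rare)) {
    rows <- c(rows, list(
      tibble(stratum = "rare", metric = c("auroc", "aupr"),
             value = c(x$rare$auroc, x$rare$aupr))
    ))
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(
    n_pairs = x$overall$n_pairs, n_positive = x$overall$n_positive,
    auroc = x$overall$auroc, aupr = x$overall$aupr,
    rare_auroc = if (!is.null(x$rare)) x$rare$auroc else NA_real_,
    rare_aupr = if (!is.null(x$rare)) x$rare$aupr else NA_real_
  )
}

#' Plot a training-loss trajectory
#'
#' @param object A fitted `amfp_model` or `biotext_model`.
#' @param ... Unused.
#' @return A ggplot of per-epoch mean batch loss.
#' @export
autoplot.amfp_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  title = "Factorization training loss") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.amfp_model
#' @export
autoplot.biotext_model <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy",
                  title = sprintf("Bio-text ('%s') training loss", object$variant)) +
    ggplot2::theme_minimal()
}

#' Plot the switching-threshold tuning curve
#'
#' @param object A tuned `abte_model`.
#' @param ... Unused.
#' @return A ggplot of validation AUPR against candidate `M`.
#' @export
autoplot.abte_model <- function(object, ...) {
  if (is.null(object$m_table)) {
    abort("this model was fit with a fixed M; no tuning curve to plot")
  }
  ggplot2::ggplot(object$m_table, ggplot2::aes(x = .data$M, y = .data$aupr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$M, linetype = "dashed") +
    ggplot2::labs(x = "switching threshold M", y = "validation AUPR",
                  title = "Switching-threshold tuning") +
    ggplot2::theme_minimal()
}

#' Plot precision@K and recall@K curves
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot with one panel per metric.
#' @export
autoplot.eval_report <- function(object, ...) {
  pr <- tidyr::pivot_longer(object$precision_recall,
                            cols = c("precision", "recall"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "K (top-ranked pairs)", y = NULL,
                  title = "Ranking performance at K") +
    ggplot2::theme_minimal()
}

#' Plot component gain by training interaction count
#'
#' @param gain The tibble from [gain_by_interaction_count()].
#' @param metric `"aupr"` (default) or `"auroc"` gain.
#' @return A ggplot of percent gain over the baseline per count bin.
#' @export
plot_gain <- function(gain, metric = c("aupr", "auroc")) {
  metric <- match.arg(metric)
  col <- paste0(metric, "_gain_pct")
  ggplot2::ggplot(gain,
                  ggplot2::aes(x = .data$bin, y = .data[[col]],
                               colour = .data$model, group = .data$model)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training interactions (min of the pair)",
                  y = sprintf("%s gain over baseline (%%)", toupper(metric))) +
    ggplot2::theme_minimal()
}
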