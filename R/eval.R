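# Ranking evaluation: AUROC (Mann-Whitney), AUPR (step summation /
# average precision), precision@K and recall@K, rare-drug stratification,
# and the gain-vs-interaction-count analysis.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a random
#' positive outscores a random negative, counting ties as one half.
#'
#' @param scores Numeric score vector.
#' @param labels Binary (0/1) labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  check_scored(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("AUROC needs both a positive and a negative instance")
  }
  r <- rank(scores)  # average ranks handle ties as half-wins
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over ranked thresholds (the average-precision form):
#' `sum_k (R_k - R_{k-1}) * P_k`, where `(P_k, R_k)` are precision and
#' recall after admitting the instances at the k-th distinct score value.
#' Trapezoidal interpolation in PR space is biased and deliberately not
#' used.
#'
#' @inheritParams auroc
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(scores, labels) {
  check_scored(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) abort("AUPR needs at least one positive instance")
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  k <- seq_along(y)
  # thresholds fall at the last index of each distinct score value
  last <- which(s != c(s[-1], NA_real_))
  last[length(last) + 1] <- length(s)
  last <- unique(last)
  P <- tp[last] / k[last]
  R <- tp[last] / n_pos
  sum((R - c(0, R[-length(R)])) * P)
}

#' Precision and recall at top K
#'
#' Ranks instances by score (ties broken deterministically by original
#' position) and reports, for each requested `K`: the fraction of the top
#' `K` that are positive (precision@K) and the fraction of all positives
#' captured in the top `K` (recall@K).
#'
#' @inheritParams auroc
#' @param k Integer vector of cutoffs, each at most `length(scores)`.
#' @return A tibble with columns `k`, `precision`, `recall`.
#' @export
precision_recall_at_k <- function(scores, labels, k) {
  check_scored(scores, labels)
  if (any(k < 1) || any(k > length(scores))) {
    abort(sprintf("each `k` must be between 1 and %d", length(scores)))
  }
  ord <- order(-scores)  # stable: ties keep ascending original index
  hits <- cumsum(labels[ord])
  n_pos <- sum(labels == 1)
  tibble(
    k = as.integer(k),
    precision = hits[k] / k,
    recall = if (n_pos > 0) hits[k] / n_pos else NA_real_
  )
}

check_scored <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length")
  }
  if (!all(labels %in% c(0, 1))) abort("`labels` must be binary (0/1)")
  invisible(TRUE)
}

#' Stratified ranking evaluation report
#'
#' Evaluates scored evaluation pairs overall, on the rare-drug stratum, per
#' interaction-count bin, and per rare drug. A pair belongs to the rare
#' stratum when the smaller of its two drugs' training interaction counts
#' is below `rare_threshold` (default 3, the tuned switching threshold, so
#' "rare" and "routed to text" coincide). Two rare-drug views are emitted:
#' pooled metrics over all rare pairs, and per-drug metrics (each rare
#' drug's candidate pairs ranked separately) averaged across drugs. Also
#' included is the cumulative distribution of drugs, and of test-set
#' positives, over training-count bins.
#'
#' @param pairs A scored pair tibble with columns `i`, `j`, `label` and
#'   `score` (a `.score` column is accepted).
#' @param counts Per-drug training interaction counts: the tibble from
#'   [interaction_counts()], a named vector, or a plain vector in catalog
#'   order.
#' @param rare_threshold A drug is rare when its count is strictly below
#'   this.
#' @param k Cutoffs for precision/recall@K on the pooled strata.
#' @param k_per_drug Cutoffs for the per-drug averaged precision/recall@K
#'   (each rare drug usually has far fewer candidate pairs than the pool).
#' @param bins Left-open break points for the count bins.
#' @return An object of class `eval_report`: a list of tibbles `overall`,
#'   `rare`, `rare_per_drug`, `strata`, `precision_recall` and
#'   `distribution`.
#' @export
stratified_report <- function(pairs, counts, rare_threshold = 3,
                              k = c(10, 50, 100, 250),
                              k_per_drug = c(1, 3, 5, 10),
                              bins = c(0, 3, 10, 20, 50, Inf)) {
  stopifnot(is.data.frame(pairs))
  pairs <- as_tibble(pairs)
  if (!"score" %in% names(pairs) && ".score" %in% names(pairs)) {
    pairs$score <- pairs$.score
  }
  stopifnot(all(c("i", "j", "label", "score") %in% names(pairs)))
  if (is.data.frame(counts)) counts <- counts$n_interactions
  counts <- as.numeric(counts)
  min_count <- pmin(counts[pairs$i], counts[pairs$j])
  k <- k[k <= nrow(pairs)]

  summarise_pool <- function(sub) {
    both <- length(unique(sub$label)) == 2
    tibble(
      n_pairs = nrow(sub),
      n_positive = sum(sub$label),
      auroc = if (both) auroc(sub$score, sub$label) else NA_real_,
      aupr = if (sum(sub$label) > 0) aupr(sub$score, sub$label) else NA_real_
    )
  }

  overall <- summarise_pool(pairs)
  pr <- precision_recall_at_k(pairs$score, pairs$label, k)

  rare_idx <- min_count < rare_threshold
  rare <- if (any(rare_idx)) summarise_pool(pairs[rare_idx, ]) else NULL

  # per-drug view: each rare drug's candidate pairs ranked on their own
  rare_drugs <- which(counts < rare_threshold)
  per_drug <- purrr::map_dfr(rare_drugs, function(d) {
    sub <- pairs[pairs$i == d | pairs$j == d, , drop = FALSE]
    if (nrow(sub) == 0 || sum(sub$label) == 0) return(NULL)
    kk <- k_per_drug[k_per_drug <= nrow(sub)]
    prd <- precision_recall_at_k(sub$score, sub$label, kk)
    both <- length(unique(sub$label)) == 2
    tibble(drug = d, k = prd$k, precision = prd$precision,
           recall = prd$recall,
           auroc = if (both) auroc(sub$score, sub$label) else NA_real_)
  })
  rare_per_drug <- if (nrow(per_drug) > 0) {
    dplyr::summarise(
      dplyr::group_by(per_drug, .data$k),
      n_drugs = dplyr::n(),
      precision = mean(.data$precision),
      recall = mean(.data$recall),
      auroc = mean(.data$auroc, na.rm = TRUE),
      .groups = "drop"
    )
  } else {
    NULL
  }

  bin_lab <- cut(min_count, breaks = bins, include.lowest = TRUE, right = FALSE)
  strata <- purrr::map_dfr(levels(bin_lab), function(lv) {
    sub <- pairs[!is.na(bin_lab) & bin_lab == lv, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    dplyr::bind_cols(tibble(bin = lv), summarise_pool(sub))
  })

  drug_bin <- cut(counts, breaks = bins, include.lowest = TRUE, right = FALSE)
  pos <- pairs[pairs$label == 1, , drop = FALSE]
  pos_bin <- cut(pmin(counts[pos$i], counts[pos$j]),
                 breaks = bins, include.lowest = TRUE, right = FALSE)
  distribution <- tibble(
    bin = levels(drug_bin),
    pct_drugs = 100 * as.numeric(table(drug_bin)) / length(counts),
    pct_test_positives = 100 * as.numeric(table(pos_bin)) /
      max(1, nrow(pos))
  )
  distribution$cum_pct_drugs <- cumsum(distribution$pct_drugs)
  distribution$cum_pct_test_positives <- cumsum(distribution$pct_test_positives)

  structure(
    list(overall = overall, rare = rare, rare_per_drug = rare_per_drug,
         strata = strata, precision_recall = pr, distribution = distribution,
         rare_threshold = rare_threshold),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d pairs, %d positives | AUROC %.3f, AUPR %.3f\n",
              x$overall$n_pairs, x$overall$n_positive,
              x$overall$auroc, x$overall$aupr))
  if (!is.null(x$rare)) {
    cat(sprintf("  rare stratum (min count < %d): %d pairs | AUROC %.3f, AUPR %.3f\n",
                x$rare_threshold, x$rare$n_pairs, x$rare$auroc, x$rare$aupr))
  }
  invisible(x)
}

#' Component gain as a function of training interaction count
#'
#' Bins evaluation pairs by the smaller of the two drugs' training
#' interaction counts and, per bin, compares each scoring column's
#' AUROC/AUPR against a baseline column, expressed as percent gain. This
#' is the analysis that motivates the switching rule: the text component
#' wins on low-count bins, the stacker on high-count bins.
#'
#' @param pairs Scored pair tibble with `i`, `j`, `label` and one numeric
#'   column per model.
#' @param counts Per-drug training counts (as in [stratified_report()]).
#' @param score_cols Names of the score columns to compare.
#' @param baseline Name of the baseline score column (gain 0 by
#'   definition).
#' @param bins Break points for the count bins.
#' @return A tibble with columns `bin`, `model`, `auroc`, `aupr`,
#'   `auroc_gain_pct`, `aupr_gain_pct`, `n_pairs`.
#' @export
gain_by_interaction_count <- function(pairs, counts,
                                      score_cols = c("text", "stacking"),
                                      baseline = "amfp",
                                      bins = c(0, 3, 10, 20, 50, Inf)) {
  stopifnot(is.data.frame(pairs),
            all(c(score_cols, baseline) %in% names(pairs)))
  if (is.data.frame(counts)) counts <- counts$n_interactions
  min_count <- pmin(counts[pairs$i], counts[pairs$j])
  bin_lab <- cut(min_count, breaks = bins, include.lowest = TRUE, right = FALSE)
  purrr::map_dfr(levels(bin_lab), function(lv) {
    sub <- pairs[!is.na(bin_lab) & bin_lab == lv, , drop = FALSE]
    if (nrow(sub) == 0 || length(unique(sub$label)) < 2) return(NULL)
    base_auroc <- auroc(sub[[baseline]], sub$label)
    base_aupr <- aupr(sub[[baseline]], sub$label)
    purrr::map_dfr(c(baseline, score_cols), function(m) {
      a <- auroc(sub[[m]], sub$label)
      p <- aupr(sub[[m]], sub$label)
      tibble(bin = lv, model = m, auroc = a, aupr = p,
             auroc_gain_pct = 100 * (a - base_auroc) / base_auroc,
             aupr_gain_pct = 100 * (p - base_aupr) / base_aupr,
             n_pairs = nrow(sub))
    })
  })
}

#' Write an evaluation report to JSON
#'
#' @param report An `eval_report` from [stratified_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(
    auroc = report$overall$auroc,
    aupr = report$overall$aupr,
    precision_at = setNames(as.list(report$precision_recall$precision),
                            report$precision_recall$k),
    recall_at = setNames(as.list(report$precision_recall$recall),
                         report$precision_recall$k),
    rare = if (!is.null(report$rare)) as.list(report$rare) else NULL,
    strata = report$strata,
    distribution = report$distribution
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
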