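# Building a K-TSP classifier: greedy gene-disjoint pair selection and
# data-driven choice of K and the vote threshold tau by resubstitution ROC
# analysis under a 100% training-sensitivity constraint.

#' Greedily select K gene-disjoint top-scoring pairs
#'
#' Implements the rank-remove-repeat search: identify the top-scoring pair,
#' remove its two genes from the gene set, rescore all pairs among the
#' remaining genes, and repeat until `k_max` pairs are selected. Rescoring
#' after each removal matters: the gamma tie-break uses ranks within the
#' surviving gene profile, so scores are recomputed on the reduced matrix
#' at every step.
#'
#' @param cohort a [ktsp_cohort()].
#' @param k_max number of pairs to select; requires at least `2 * k_max`
#'   genes.
#' @return `data.frame` of `k_max` gene-disjoint scored pairs in selection
#'   order (columns as in [score_all_pairs()]).
#' @export
select_disjoint_pairs <- function(cohort, k_max) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  k_max <- as.integer(k_max)
  if (length(k_max) != 1L || is.na(k_max) || k_max < 1L) {
    stop_ktsp("k_max must be a positive integer", "ktsp_input_error")
  }
  if (2L * k_max > nrow(cohort$values)) {
    stop_ktsp(sprintf(
      "cannot select %d gene-disjoint pairs from %d genes (need %d)",
      k_max, nrow(cohort$values), 2L * k_max), "ktsp_capacity_error")
  }
  remaining <- cohort
  selected <- vector("list", k_max)
  for (i in seq_len(k_max)) {
    ranked <- score_all_pairs(remaining)
    top <- ranked[1L, , drop = FALSE]
    selected[[i]] <- top
    keep <- setdiff(rownames(remaining$values), c(top$gene_a, top$gene_b))
    remaining$values <- remaining$values[keep, , drop = FALSE]
  }
  out <- do.call(rbind, selected)
  rownames(out) <- NULL
  out
}

#' @noRd
poor_vote_matrix <- function(values, pairs) {
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(values))
  if (length(missing)) {
    stop_ktsp(sprintf("gene(s) absent from expression matrix: %s",
                      paste(missing, collapse = ", ")),
              "ktsp_identifier_error")
  }
  a <- values[pairs$gene_a, , drop = FALSE]
  b <- values[pairs$gene_b, , drop = FALSE]
  votes <- matrix(FALSE, nrow(pairs), ncol(values))
  lt <- pairs$orientation == "lt"
  gt <- pairs$orientation == "gt"
  votes[lt, ] <- a[lt, , drop = FALSE] < b[lt, , drop = FALSE]
  votes[gt, ] <- a[gt, , drop = FALSE] > b[gt, , drop = FALSE]
  colnames(votes) <- colnames(values)
  votes
}

#' Per-sample prognostic vote scores
#'
#' The prognostic score of a sample is the number of pairs whose observed
#' strict ordering matches their poor-prognosis orientation; it ranges over
#' `0..K` and higher scores mean more evidence for poor prognosis.
#'
#' @param x a [ktsp_cohort()] or a gene-by-sample expression matrix
#'   containing at least the pairs' genes.
#' @param pairs scored pairs (`data.frame` as from [score_all_pairs()] or
#'   [select_disjoint_pairs()], or a model's `pairs` element).
#' @return Named integer vector of per-sample scores in `[0, K]`.
#' @export
prognostic_scores <- function(x, pairs) {
  values <- if (inherits(x, "ktsp_cohort")) x$values else x
  validate_expression_matrix(values)
  votes <- poor_vote_matrix(values, pairs)
  colSums(votes)
}

#' Resubstitution AUC of integer vote scores
#'
#' Area under the ROC curve over all score thresholds, computed as the
#' normalized Mann-Whitney statistic with ties counted one-half: the
#' probability that a random poor-class sample scores above a random
#' good-class sample.
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels `"poor"` / `"good"` per sample (poor is the positive
#'   class).
#' @return AUC in `[0, 1]`.
#' @export
resubstitution_auc <- function(scores, labels) {
  auc_mann_whitney(scores, labels)
}

#' @noRd
auc_mann_whitney <- function(scores, labels) {
  poor <- labels == "poor"
  n_poor <- sum(poor)
  n_good <- sum(!poor)
  if (n_poor == 0L || n_good == 0L) {
    stop_ktsp("AUC needs both classes present", "ktsp_degenerate_error")
  }
  if (length(scores) != length(labels)) {
    stop_ktsp("scores and labels differ in length", "ktsp_alignment_error")
  }
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[poor]) - n_poor * (n_poor + 1) / 2) / (n_poor * n_good)
}

#' Train a K-TSP model: choose K and the vote threshold tau
#'
#' For each candidate K, the training vote scores of the first K disjoint
#' pairs are computed, and the admissible thresholds tau are those with
#' training sensitivity exactly 1 (every poor-class sample scores at least
#' tau). Among all admissible (K, tau), the pair maximizing training
#' specificity is chosen -- equivalently, for each K the largest tau
#' keeping 100% sensitivity. Resubstitution estimates are used only for
#' this model selection, never as a performance claim: the vote scores are
#' sums of binary decisions and are not prone to overfitting the way
#' continuous-score classifiers are.
#'
#' Ties in specificity are broken by smallest K, then largest tau
#' (parsimony first). The AUC-versus-K curve is computed for `1..k_curve_max`
#' pairs for inspection, but selection is restricted to `k_range`.
#'
#' @param cohort a [ktsp_cohort()] with both classes non-empty.
#' @param k_range integer vector `c(k_min, k_max)`; the default `c(6, 10)`
#'   searches the peak region of a typical AUC-versus-K curve.
#' @param k_curve_max largest K for the exported AUC curve (capped by gene
#'   capacity); default 15.
#' @param seed optional integer recorded in the model metadata (the
#'   training procedure itself is deterministic).
#' @return A [ktsp_model()] whose `metadata` records `k_range`, the
#'   candidate table (per-K admissible tau and specificity), the AUC curve,
#'   class sizes, package version and `seed`.
#' @examples
#' cohort <- generate_cohort(n_genes = 20, n_poor = 20, n_good = 20,
#'                           planted = data.frame(pair = 1:2, p_poor = 0.95,
#'                                                p_good = 0.05),
#'                           seed = 7)
#' model <- ktsp_train(cohort, k_range = c(2, 4))
#' model
#' @export
ktsp_train <- function(cohort, k_range = c(6L, 10L), k_curve_max = 15L,
                       seed = NULL) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  sizes <- check_two_classes(cohort)
  k_range <- as.integer(range(k_range))
  k_min <- k_range[1]
  k_max <- k_range[2]
  if (k_min < 1L) {
    stop_ktsp("k_range must be >= 1", "ktsp_input_error")
  }
  capacity <- nrow(cohort$values) %/% 2L
  if (k_max > capacity) {
    stop_ktsp(sprintf(
      "k_range up to %d needs %d genes; matrix has %d",
      k_max, 2L * k_max, nrow(cohort$values)), "ktsp_capacity_error")
  }
  k_curve_max <- min(as.integer(k_curve_max), capacity)
  k_top <- max(k_max, k_curve_max)

  pairs <- select_disjoint_pairs(cohort, k_top)
  votes <- poor_vote_matrix(cohort$values, pairs)
  score_by_k <- apply(votes, 2, cumsum)           # k_top x N cumulative scores
  if (k_top == 1L) score_by_k <- matrix(score_by_k, nrow = 1L)
  poor <- cohort$labels == "poor"

  auc_curve <- data.frame(
    k = seq_len(k_curve_max),
    auc = vapply(seq_len(k_curve_max), function(k) {
      auc_mann_whitney(score_by_k[k, ], cohort$labels)
    }, numeric(1)))

  # admissible tau for each K: sensitivity 1 <=> tau <= min poor score
  candidates <- do.call(rbind, lapply(k_min:k_max, function(k) {
    s <- score_by_k[k, ]
    tau <- min(s[poor])
    if (tau < 1L) return(NULL)  # some poor sample has zero votes
    data.frame(k = k, tau = as.integer(tau),
               specificity = mean(s[!poor] < tau))
  }))
  if (is.null(candidates) || nrow(candidates) == 0L) {
    diag <- vapply(k_min:k_max, function(k) min(score_by_k[k, poor]),
                   numeric(1))
    stop_ktsp(sprintf(
      "no vote threshold achieves 100%% training sensitivity for K in [%d, %d] (min poor score per K: %s)",
      k_min, k_max, paste(diag, collapse = ", ")),
      "ktsp_selection_error")
  }
  best <- candidates[order(-candidates$specificity, candidates$k,
                           -candidates$tau), ][1L, ]

  ktsp_model(
    pairs = pairs[seq_len(best$k), , drop = FALSE],
    threshold = best$tau,
    metadata = list(
      k_range = c(k_min, k_max),
      candidates = candidates,
      auc_curve = auc_curve,
      n_poor = unname(sizes[["poor"]]),
      n_good = unname(sizes[["good"]]),
      training_specificity = best$specificity,
      version = as.character(utils::packageVersion("ktsp")),
      seed = seed))
}
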