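# Rank-based pair scoring: how consistently does the within-sample ordering
# of a gene pair switch between the two prognostic classes?

#' Class-conditional ordering counts for one gene pair
#'
#' For each class, counts the samples in which `gene_a` is expressed
#' strictly below `gene_b`. Ties (equal expression) are counted as "not
#' less than": the comparison is strict everywhere in the package, so users
#' who want ties broken should jitter beforehand.
#'
#' @param cohort a [ktsp_cohort()] with both classes non-empty.
#' @param gene_a,gene_b gene identifiers.
#' @return Named integer vector
#'   `(n_lt_poor, n_poor, n_lt_good, n_good)`: the count of poor-class
#'   samples with `expr(gene_a) < expr(gene_b)`, the poor class size, and
#'   the same for the good class.
#' @export
ordering_counts <- function(cohort, gene_a, gene_b) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  check_two_classes(cohort)
  missing <- setdiff(c(gene_a, gene_b), rownames(cohort$values))
  if (length(missing)) {
    stop_ktsp(sprintf("unknown gene identifier(s): %s",
                      paste(missing, collapse = ", ")),
              "ktsp_identifier_error")
  }
  lt <- cohort$values[gene_a, ] < cohort$values[gene_b, ]
  poor <- cohort$labels == "poor"
  c(n_lt_poor = sum(lt & poor), n_poor = sum(poor),
    n_lt_good = sum(lt & !poor), n_good = sum(!poor))
}

#' Switch score (delta) from ordering counts
#'
#' The switch score of a pair is the absolute difference between the two
#' empirical class-conditional probabilities that `gene_a` is expressed
#' below `gene_b`:
#' `delta = | n_lt_poor/n_poor - n_lt_good/n_good |`, which lies in
#' `[0, 1]` and equals 1 exactly when the ordering is perfectly reversed
#' between the classes.
#'
#' @param counts named vector as returned by [ordering_counts()].
#' @return delta in `[0, 1]`.
#' @export
pair_delta <- function(counts) {
  counts <- counts[c("n_lt_poor", "n_poor", "n_lt_good", "n_good")]
  if (any(is.na(counts))) {
    stop_ktsp("counts must contain n_lt_poor, n_poor, n_lt_good, n_good",
              "ktsp_input_error")
  }
  if (counts[["n_poor"]] <= 0 || counts[["n_good"]] <= 0) {
    stop_ktsp("class totals must be positive", "ktsp_degenerate_error")
  }
  abs(counts[["n_lt_poor"]] / counts[["n_poor"]] -
        counts[["n_lt_good"]] / counts[["n_good"]])
}

#' Secondary rank score (gamma) for one gene pair
#'
#' Tie-break score used to order pairs with equal delta: ranks are computed
#' within each sample profile (average ranks for ties), and gamma is the
#' absolute difference between the class means of `rank(gene_a) -
#' rank(gene_b)`. Larger gamma means the pair's rank gap shifts more
#' between classes.
#'
#' @inheritParams ordering_counts
#' @return gamma, a non-negative real.
#' @export
pair_gamma <- function(cohort, gene_a, gene_b) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  check_two_classes(cohort)
  missing <- setdiff(c(gene_a, gene_b), rownames(cohort$values))
  if (length(missing)) {
    stop_ktsp(sprintf("unknown gene identifier(s): %s",
                      paste(missing, collapse = ", ")),
              "ktsp_identifier_error")
  }
  ranks <- apply(cohort$values, 2, rank)
  d <- ranks[gene_a, ] - ranks[gene_b, ]
  poor <- cohort$labels == "poor"
  # class-mean rank gaps are rationals with denominator 2 * n_poor * n_good;
  # rounding to 9 decimals makes mathematically equal scores compare equal
  # regardless of summation order, so tie-breaking is reproducible
  round(abs(mean(d[poor]) - mean(d[!poor])), 9)
}

#' Score every gene pair of a cohort
#'
#' Computes delta and gamma for all unordered gene pairs and returns them in
#' a deterministic total order: delta descending, then gamma descending,
#' then lexicographic gene identifiers (C locale). Each pair's orientation
#' records which strict ordering votes poor: the ordering observed more
#' frequently in the poor class. When the class-conditional proportions are
#' exactly equal (delta = 0) the orientation is `"none"` and the pair
#' always votes good.
#'
#' Because scores read only within-sample orderings, the returned ranking
#' is invariant under any strictly increasing transformation applied per
#' sample profile -- the property that makes top-scoring-pair signatures
#' robust to normalization choices.
#'
#' @param cohort a [ktsp_cohort()] with at least 2 genes and both classes
#'   non-empty.
#' @return `data.frame` with one row per unordered pair (`gene_a` <
#'   `gene_b` lexicographically) and columns `gene_a`, `gene_b`, `delta`,
#'   `gamma`, `orientation`.
#' @examples
#' cohort <- generate_cohort(n_genes = 10, n_poor = 15, n_good = 15,
#'                           planted = data.frame(pair = 1, p_poor = 1,
#'                                                p_good = 0),
#'                           seed = 1)
#' head(score_all_pairs(cohort))
#' @export
score_all_pairs <- function(cohort) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  sizes <- check_two_classes(cohort)
  x <- cohort$values
  if (nrow(x) < 2L) {
    stop_ktsp("need at least 2 genes to form pairs", "ktsp_degenerate_error")
  }
  # canonical lexicographic gene order (C locale, independent of input order)
  genes <- rownames(x)[order(rownames(x), method = "radix")]
  x <- x[genes, , drop = FALSE]
  poor <- cohort$labels == "poor"

  # n_lt[a, b] per class = #samples with expr(a) < expr(b), via one outer
  # comparison per sample
  g <- length(genes)
  lt_poor <- matrix(0L, g, g)
  lt_good <- matrix(0L, g, g)
  for (j in seq_len(ncol(x))) {
    cmp <- outer(x[, j], x[, j], "<")
    if (poor[j]) lt_poor <- lt_poor + cmp else lt_good <- lt_good + cmp
  }
  p_poor <- lt_poor / sizes[["poor"]]
  p_good <- lt_good / sizes[["good"]]

  # gamma from per-sample within-profile ranks: the class-mean rank gap
  # difference factorizes through per-gene mean ranks
  ranks <- apply(x, 2, rank)
  mean_poor <- rowMeans(ranks[, poor, drop = FALSE])
  mean_good <- rowMeans(ranks[, !poor, drop = FALSE])

  idx <- which(upper.tri(p_poor), arr.ind = TRUE)  # row < col: gene_a < gene_b
  a <- idx[, 1]
  b <- idx[, 2]
  delta <- abs(p_poor[idx] - p_good[idx])
  # rounded as in pair_gamma so exact rational ties stay exact ties
  gamma <- round(abs((mean_poor[a] - mean_poor[b]) -
                       (mean_good[a] - mean_good[b])), 9)
  orientation <- ifelse(p_poor[idx] > p_good[idx], "lt",
                        ifelse(p_poor[idx] < p_good[idx], "gt", "none"))
  out <- data.frame(gene_a = genes[a], gene_b = genes[b],
                    delta = delta, gamma = gamma,
                    orientation = orientation,
                    stringsAsFactors = FALSE)
  ord <- order(-out$delta, -out$gamma, out$gene_a, out$gene_b,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
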