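# Applying a trained K-TSP model to new expression profiles. Only the
# within-sample ordering of the two genes in each pair is read, so calls
# are invariant to any strictly increasing per-sample transformation.

#' Vote of one pair on one expression profile
#'
#' A pair votes poor exactly when the observed strict ordering of its two
#' genes matches the pair's poor orientation. Tied expression values vote
#' good: a tie is the absence of the poor-indicating ordering.
#'
#' @param profile named numeric vector of per-gene expression values for
#'   one sample (may contain extra genes).
#' @param pair one scored pair (single-row `data.frame` or list with
#'   `gene_a`, `gene_b`, `orientation`).
#' @return `"poor"` or `"good"`.
#' @export
pair_vote <- function(profile, pair) {
  missing <- setdiff(c(pair$gene_a, pair$gene_b), names(profile))
  if (length(missing)) {
    stop_ktsp(sprintf("gene(s) absent from profile: %s",
                      paste(missing, collapse = ", ")),
              "ktsp_identifier_error")
  }
  a <- profile[[pair$gene_a]]
  b <- profile[[pair$gene_b]]
  poor <- switch(pair$orientation,
                 lt = a < b,
                 gt = a > b,
                 none = FALSE,
                 stop_ktsp("orientation must be 'lt', 'gt' or 'none'",
                           "ktsp_input_error"))
  if (poor) "poor" else "good"
}

#' Predict prognosis with a trained K-TSP model
#'
#' Computes each sample's vote score (number of pairs voting poor) and
#' calls a sample poor prognosis when the score reaches the model's vote
#' threshold tau. The matrix may contain genes beyond the model's (real
#' assay exports carry the full signature); prediction subsets to the
#' model's genes and errors if any are absent.
#'
#' @param object a [ktsp_model()].
#' @param newdata a [ktsp_cohort()] or gene-by-sample expression matrix.
#' @param ... unused.
#' @return `data.frame` with columns `sample_id`, `score` (integer in
#'   `[0, K]`) and `label` (`"poor"` / `"good"`).
#' @export
predict.ktsp_model <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "ktsp_cohort")) newdata$values else newdata
  validate_expression_matrix(values)
  scores <- prognostic_scores(values, object$pairs)
  data.frame(sample_id = colnames(values),
             score = as.integer(scores),
             label = ifelse(scores >= object$threshold, "poor", "good"),
             stringsAsFactors = FALSE)
}
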