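# Core domain types: expression matrix, labeled cohort, scored pairs, model.
# All classifier stages read only the within-sample ordering of expression
# values, so the matrix may be on any scale whose per-sample ordering is
# meaningful (log-ratios, intensities, ranks, ...).

#' Signal a classed ktsp error
#'
#' @param msg message
#' @param class condition subclass, e.g. "ktsp_identifier_error"
#' @noRd
stop_ktsp <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ktsp_error", "error")))
}

#' Validate a gene-by-sample expression matrix
#'
#' Checks the contract every downstream stage relies on: a numeric matrix
#' with unique, non-empty gene identifiers as row names and sample
#' identifiers as column names, and every value finite. Missing values are
#' an error, never imputed: silent imputation would alter within-sample
#' rankings, which are the only information the classifier uses.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @return `values`, invisibly, if valid.
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_ktsp("expression values must be a numeric matrix (genes x samples)",
              "ktsp_input_error")
  }
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || any(!nzchar(genes))) {
    stop_ktsp("expression matrix must have gene identifiers as row names",
              "ktsp_input_error")
  }
  if (is.null(samples) || any(!nzchar(samples))) {
    stop_ktsp("expression matrix must have sample identifiers as column names",
              "ktsp_input_error")
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop_ktsp(sprintf("duplicate gene identifier(s): %s",
                      paste(dup, collapse = ", ")), "ktsp_input_error")
  }
  if (anyDuplicated(samples)) {
    dup <- unique(samples[duplicated(samples)])
    stop_ktsp(sprintf("duplicate sample identifier(s): %s",
                      paste(dup, collapse = ", ")), "ktsp_input_error")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_ktsp(sprintf(
      "expression matrix contains non-finite value(s), e.g. gene '%s', sample '%s'",
      genes[bad[1]], samples[bad[2]]), "ktsp_input_error")
  }
  invisible(values)
}

#' Construct a labeled cohort
#'
#' Bundles an expression matrix with per-sample binary prognosis labels and,
#' optionally, survival records. The positive class is fixed as `"poor"`
#' (recurrence / event) throughout the package.
#'
#' @param values numeric gene-by-sample matrix with row and column names
#'   (see [validate_expression_matrix()]).
#' @param labels character vector of `"poor"` / `"good"`, one per sample.
#'   If named, names must match the sample identifiers (any order);
#'   otherwise it is taken in column order.
#' @param survival optional `data.frame` with columns `sample_id`,
#'   `time_months` (non-negative) and `event` (0 = censored, 1 = event),
#'   covering exactly the cohort's samples.
#' @return An object of class `ktsp_cohort`: a list with elements `values`,
#'   `labels` (named, in column order) and `survival` (or `NULL`).
#' @examples
#' x <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' ktsp_cohort(x, c("poor", "poor", "good", "good", "good"))
#' @export
ktsp_cohort <- function(values, labels, survival = NULL) {
  validate_expression_matrix(values)
  samples <- colnames(values)
  labels <- stats::setNames(as.character(labels), names(labels))
  if (!is.null(names(labels))) {
    if (!setequal(names(labels), samples) || length(labels) != length(samples)) {
      extra <- setdiff(names(labels), samples)
      missing <- setdiff(samples, names(labels))
      stop_ktsp(sprintf(
        "labels do not cover the samples exactly once (missing: %s; extra: %s)",
        paste(missing, collapse = ", "), paste(extra, collapse = ", ")),
        "ktsp_alignment_error")
    }
    labels <- labels[samples]
  } else {
    if (length(labels) != length(samples)) {
      stop_ktsp(sprintf("expected %d labels, got %d",
                        length(samples), length(labels)),
                "ktsp_alignment_error")
    }
    names(labels) <- samples
  }
  bad <- setdiff(unique(labels), c("poor", "good"))
  if (length(bad)) {
    stop_ktsp(sprintf("labels must be 'poor' or 'good'; found: %s",
                      paste(bad, collapse = ", ")), "ktsp_input_error")
  }
  if (!is.null(survival)) {
    survival <- validate_survival(survival, samples)
  }
  structure(list(values = values, labels = labels, survival = survival),
            class = "ktsp_cohort")
}

#' @noRd
validate_survival <- function(survival, samples) {
  need <- c("sample_id", "time_months", "event")
  if (!is.data.frame(survival) || !all(need %in% names(survival))) {
    stop_ktsp(
      "survival records need columns sample_id, time_months, event",
      "ktsp_input_error")
  }
  survival$sample_id <- as.character(survival$sample_id)
  if (anyDuplicated(survival$sample_id) ||
      !setequal(survival$sample_id, samples)) {
    stop_ktsp("survival records must cover each cohort sample exactly once",
              "ktsp_alignment_error")
  }
  if (any(!is.finite(survival$time_months)) || any(survival$time_months < 0)) {
    stop_ktsp("survival times must be finite and >= 0", "ktsp_input_error")
  }
  if (!all(survival$event %in% c(0, 1))) {
    stop_ktsp("event indicator must be 0 (censored) or 1 (event)",
              "ktsp_input_error")
  }
  survival$event <- as.integer(survival$event)
  survival <- survival[match(samples, survival$sample_id),
                       need, drop = FALSE]
  rownames(survival) <- NULL
  survival
}

#' Attach survival records to a cohort
#'
#' @param cohort a [ktsp_cohort()].
#' @param survival survival records (see [ktsp_cohort()]).
#' @return The cohort with `survival` attached.
#' @export
with_survival <- function(cohort, survival) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  cohort$survival <- validate_survival(survival, colnames(cohort$values))
  cohort
}

#' @noRd
check_two_classes <- function(cohort) {
  n_poor <- sum(cohort$labels == "poor")
  n_good <- sum(cohort$labels == "good")
  if (n_poor == 0L || n_good == 0L) {
    stop_ktsp(sprintf(
      "both prognostic classes must be non-empty (poor: %d, good: %d)",
      n_poor, n_good), "ktsp_degenerate_error")
  }
  c(poor = n_poor, good = n_good)
}

#' @export
print.ktsp_cohort <- function(x, ...) {
  cat(sprintf("ktsp_cohort: %d genes x %d samples (%d poor, %d good)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == "poor"), sum(x$labels == "good"),
              if (is.null(x$survival)) "" else ", with survival records"))
  invisible(x)
}

#' Construct a K-TSP model
#'
#' A K-TSP model is an ordered list of K gene-disjoint scored pairs plus an
#' integer vote threshold tau: a sample is called poor prognosis when at
#' least tau of the K pairs vote poor.
#'
#' @param pairs `data.frame` with columns `gene_a`, `gene_b`, `delta`,
#'   `gamma`, `orientation` (one of `"lt"`, `"gt"`, `"none"`: which strict
#'   ordering of `gene_a` vs `gene_b` votes poor; `"none"` never votes poor).
#' @param threshold integer vote threshold tau in `[1, K]`.
#' @param metadata optional named list of training provenance (seed, k
#'   range, software version, ...); stored verbatim and serialized with the
#'   model.
#' @return Object of class `ktsp_model` with elements `pairs`, `k`,
#'   `threshold`, `metadata`.
#' @export
ktsp_model <- function(pairs, threshold, metadata = list()) {
  need <- c("gene_a", "gene_b", "delta", "gamma", "orientation")
  if (!is.data.frame(pairs) || !all(need %in% names(pairs)) ||
      nrow(pairs) < 1L) {
    stop_ktsp("pairs must be a non-empty data.frame with columns gene_a, gene_b, delta, gamma, orientation",
              "ktsp_input_error")
  }
  pairs <- as.data.frame(pairs)[, need]
  pairs$gene_a <- as.character(pairs$gene_a)
  pairs$gene_b <- as.character(pairs$gene_b)
  pairs$delta <- as.numeric(pairs$delta)
  pairs$gamma <- as.numeric(pairs$gamma)
  pairs$orientation <- as.character(pairs$orientation)
  rownames(pairs) <- NULL
  genes <- c(pairs$gene_a, pairs$gene_b)
  if (any(pairs$gene_a == pairs$gene_b)) {
    stop_ktsp("a pair cannot use the same gene twice", "ktsp_input_error")
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop_ktsp(sprintf("pairs must be gene-disjoint; reused gene(s): %s",
                      paste(dup, collapse = ", ")), "ktsp_input_error")
  }
  if (any(pairs$delta < 0 | pairs$delta > 1)) {
    stop_ktsp("delta must lie in [0, 1]", "ktsp_input_error")
  }
  if (!all(pairs$orientation %in% c("lt", "gt", "none"))) {
    stop_ktsp("orientation must be 'lt', 'gt' or 'none'", "ktsp_input_error")
  }
  k <- nrow(pairs)
  threshold <- as.integer(threshold)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 1L || threshold > k) {
    stop_ktsp(sprintf("threshold must be an integer in [1, %d]", k),
              "ktsp_input_error")
  }
  structure(list(pairs = pairs, k = k, threshold = threshold,
                 metadata = metadata),
            class = "ktsp_model")
}

#' @export
print.ktsp_model <- function(x, ...) {
  cat(sprintf("%d-TSP model (vote threshold tau = %d)\n", x$k, x$threshold))
  ori <- ifelse(x$pairs$orientation == "lt", "<",
                ifelse(x$pairs$orientation == "gt", ">", "~"))
  for (i in seq_len(x$k)) {
    cat(sprintf("  %d. %s %s %s votes poor  (delta = %.3f, gamma = %.2f)\n",
                i, x$pairs$gene_a[i], ori[i], x$pairs$gene_b[i],
                x$pairs$delta[i], x$pairs$gamma[i]))
  }
  invisible(x)
}

#' Genes used by a K-TSP model
#'
#' @param model a [ktsp_model()].
#' @return Character vector of the 2K distinct gene identifiers, in pair order.
#' @export
model_genes <- function(model) {
  stopifnot(inherits(model, "ktsp_model"))
  as.vector(rbind(model$pairs$gene_a, model$pairs$gene_b))
}
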