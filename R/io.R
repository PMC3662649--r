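# File formats: tab-delimited expression matrices (genes in rows, samples
# in columns), CSV phenotype/survival tables, JSON model files.

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers (with or without a leading
#' cell for the gene-id column) and one row per gene, first field the gene
#' identifier, remaining fields numeric. Ragged rows, non-numeric cells and
#' duplicate identifiers are parse errors reported with their line number.
#'
#' @param path file path.
#' @param transpose set `TRUE` if the file has samples in rows and genes
#'   in columns.
#' @return Validated numeric gene-by-sample matrix.
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) {
    stop_ktsp(sprintf("file not found: %s", path), "ktsp_io_error")
  }
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0L))]  # drop trailing blanks
  if (length(lines) < 2L) {
    stop_ktsp("expression file needs a header row and at least one gene row",
              "ktsp_parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  body_len <- lengths(fields[-1])
  if (length(unique(body_len)) > 1L) {
    bad <- 1L + which(body_len != stats::median(body_len))
    stop_ktsp(sprintf("ragged row(s) at line(s): %s",
                      paste(bad, collapse = ", ")), "ktsp_parse_error")
  }
  ncol_body <- body_len[1]
  header <- fields[[1]]
  samples <- if (length(header) == ncol_body) header[-1]
             else if (length(header) == ncol_body - 1L) header
             else stop_ktsp(sprintf(
               "header has %d field(s) but data rows have %d",
               length(header), ncol_body), "ktsp_parse_error")
  ids <- vapply(fields[-1], `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_ktsp(sprintf("duplicate gene identifier(s): %s (line %s)",
                      paste(dup, collapse = ", "),
                      paste(1L + which(ids %in% dup), collapse = ", ")),
              "ktsp_parse_error")
  }
  if (anyDuplicated(samples)) {
    stop_ktsp(sprintf("duplicate sample identifier(s) in header: %s",
                      paste(unique(samples[duplicated(samples)]),
                            collapse = ", ")), "ktsp_parse_error")
  }
  body <- vapply(fields[-1], function(f) {
    suppressWarnings(as.numeric(f[-1]))
  }, numeric(ncol_body - 1L))
  # body is samples x genes after vapply; transpose to genes x samples
  values <- t(matrix(body, nrow = ncol_body - 1L))
  bad <- which(is.na(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_ktsp(sprintf(
      "non-numeric value at line %d (gene '%s', sample '%s')",
      1L + bad[1, 1], ids[bad[1, 1]], samples[bad[1, 2]]),
      "ktsp_parse_error")
  }
  dimnames(values) <- list(ids, samples)
  if (transpose) values <- t(values)
  validate_expression_matrix(values)
  values
}

#' Write a tab-delimited expression matrix
#'
#' Values are printed with 17 significant digits so a write-read round
#' trip reproduces them exactly.
#'
#' @param x a [ktsp_cohort()] or gene-by-sample matrix.
#' @param path output path.
#' @export
write_expression_matrix <- function(x, path) {
  values <- if (inherits(x, "ktsp_cohort")) x$values else x
  validate_expression_matrix(values)
  body <- apply(values, 1:2, function(v) sprintf("%.17g", v))
  lines <- c(paste(c("gene_id", colnames(values)), collapse = "\t"),
             paste(rownames(values), apply(body, 1, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with required columns `sample_id` and `label` (values `poor` /
#' `good`) and optional survival columns `time_months` and `event` (0/1).
#'
#' @param path file path.
#' @return List with `labels` (named character vector) and `survival`
#'   (`data.frame` or `NULL`).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    stop_ktsp(sprintf("file not found: %s", path), "ktsp_io_error")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(tab))) {
    stop_ktsp("phenotype file needs columns sample_id and label",
              "ktsp_parse_error")
  }
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) {
    stop_ktsp(sprintf("duplicate sample identifier(s): %s",
                      paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
                            collapse = ", ")), "ktsp_parse_error")
  }
  bad <- setdiff(unique(tab$label), c("poor", "good"))
  if (length(bad)) {
    stop_ktsp(sprintf("unknown label token(s): %s (expected 'poor'/'good')",
                      paste(bad, collapse = ", ")), "ktsp_parse_error")
  }
  labels <- stats::setNames(tab$label, tab$sample_id)
  survival <- NULL
  if (all(c("time_months", "event") %in% names(tab))) {
    survival <- tab[, c("sample_id", "time_months", "event")]
  }
  list(labels = labels, survival = survival)
}

#' Write a phenotype table
#'
#' @param cohort a labeled [ktsp_cohort()]; survival columns are included
#'   when present.
#' @param path output path.
#' @export
write_phenotypes <- function(cohort, path) {
  stopifnot(inherits(cohort, "ktsp_cohort"))
  tab <- data.frame(sample_id = names(cohort$labels),
                    label = unname(cohort$labels),
                    stringsAsFactors = FALSE)
  if (!is.null(cohort$survival)) {
    tab$time_months <- cohort$survival$time_months[
      match(tab$sample_id, cohort$survival$sample_id)]
    tab$event <- cohort$survival$event[
      match(tab$sample_id, cohort$survival$sample_id)]
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a cohort from an expression matrix and phenotypes
#'
#' Aligns phenotype records to the matrix's sample identifiers and reports
#' any mismatch (samples present on only one side) as an alignment error
#' listing the identifiers.
#'
#' @param values gene-by-sample matrix (e.g. from
#'   [read_expression_matrix()]).
#' @param phenotypes list as returned by [read_phenotypes()].
#' @return A [ktsp_cohort()].
#' @export
build_cohort <- function(values, phenotypes) {
  samples <- colnames(values)
  known <- names(phenotypes$labels)
  if (!setequal(samples, known)) {
    stop_ktsp(sprintf(
      "samples differ between matrix and phenotypes (matrix only: %s; phenotypes only: %s)",
      paste(setdiff(samples, known), collapse = ", "),
      paste(setdiff(known, samples), collapse = ", ")),
      "ktsp_alignment_error")
  }
  ktsp_cohort(values, phenotypes$labels[samples],
              survival = phenotypes$survival)
}

#' Serialize a K-TSP model to JSON
#'
#' The model file is plain JSON -- human-auditable and diff-able --
#' containing the ordered pairs with their scores and orientations, K, the
#' vote threshold and the training metadata.
#'
#' @param model a [ktsp_model()].
#' @param path output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ktsp_model"))
  obj <- list(format = "ktsp-model",
              pairs = model$pairs,
              k = model$k,
              threshold = model$threshold,
              metadata = model$metadata)
  # digits = I(17) guarantees doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a K-TSP model from JSON
#'
#' @param path model file written by [write_model()] (or hand-authored to
#'   the same schema).
#' @return A [ktsp_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    stop_ktsp(sprintf("file not found: %s", path), "ktsp_io_error")
  }
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_ktsp(sprintf("not valid JSON: %s", conditionMessage(e)),
                              "ktsp_model_format_error")
                  })
  need <- c("pairs", "k", "threshold")
  missing <- setdiff(need, names(obj))
  if (length(missing)) {
    stop_ktsp(sprintf("model file missing field(s): %s",
                      paste(missing, collapse = ", ")),
              "ktsp_model_format_error")
  }
  pairs <- as.data.frame(obj$pairs, stringsAsFactors = FALSE)
  pair_cols <- c("gene_a", "gene_b", "delta", "gamma", "orientation")
  if (!all(pair_cols %in% names(pairs)) || nrow(pairs) != obj$k) {
    stop_ktsp("model file pairs do not match the declared k or lack required columns",
              "ktsp_model_format_error")
  }
  metadata <- if (is.null(obj$metadata)) list() else obj$metadata
  for (field in c("auc_curve", "candidates")) {
    if (!is.null(metadata[[field]])) {
      metadata[[field]] <- as.data.frame(metadata[[field]],
                                         stringsAsFactors = FALSE)
    }
  }
  tryCatch(ktsp_model(pairs, threshold = obj$threshold, metadata = metadata),
           ktsp_error = function(e) {
             stop_ktsp(sprintf("invalid model file: %s", conditionMessage(e)),
                       "ktsp_model_format_error")
           })
}
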