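# The published 8-pair breast-cancer prognostic signature: the 16 member
# genes, drawn from the 70-gene MammaPrint panel. The published pairing
# diagram is not available in machine-readable form, so pairings are
# shipped as unknown rather than guessed; only the membership and the
# vote threshold (tau = 2) are public knowledge.

#' Published 8-TSP signature gene list
#'
#' Returns the 16 genes of the published 8-pair prognostic signature for
#' 5-year breast-cancer recurrence, drawn from the 70-gene MammaPrint
#' panel. Four pairs mix a gene originally associated with good prognosis
#' with a poor-prognosis gene (`pair_group = "mixed"`); the other four
#' pairs use poor-prognosis genes only (`pair_group = "poor_only"`). Pair
#' partners are recorded as `"unknown"`: the published pairing diagram is
#' not machine-readable and this package does not guess it.
#'
#' @return `data.frame` with columns `gene_id`, `original_association`,
#'   `pair_group`, `pair_partner`.
#' @export
published_signature_genes <- function() {
  path <- system.file("extdata", "published_8tsp_signature_genes.tsv",
                      package = "ktsp", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Pair slots of the published signature
#'
#' Assembles the published gene list into its eight pair slots: each mixed
#' pair consumes one good-associated and one poor-associated gene, each
#' poor-only pair two poor-associated genes. The within-slot pairing is
#' unknown; this accessor exists to reason about signature size (8 pairs,
#' 16 distinct genes) and assay gene requirements.
#'
#' @return List with `n_pairs`, `genes` (distinct gene identifiers) and
#'   `slots` (list of per-slot candidate gene sets).
#' @export
published_signature_pairs <- function() {
  genes <- published_signature_genes()
  mixed_good <- genes$gene_id[genes$pair_group == "mixed" &
                                genes$original_association == "good"]
  mixed_poor <- genes$gene_id[genes$pair_group == "mixed" &
                                genes$original_association == "poor"]
  poor_only <- genes$gene_id[genes$pair_group == "poor_only"]
  slots <- c(
    lapply(seq_along(mixed_good), function(i) {
      list(group = "mixed", good_candidates = mixed_good,
           poor_candidates = mixed_poor)
    }),
    lapply(seq_len(length(poor_only) %/% 2L), function(i) {
      list(group = "poor_only", poor_candidates = poor_only)
    }))
  list(n_pairs = length(slots),
       genes = unique(genes$gene_id),
       slots = slots)
}
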