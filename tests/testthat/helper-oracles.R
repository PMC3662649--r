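# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, no shared code paths with
# the package implementation) so agreement is a real check.

# Random unstructured cohort: iid normal values, arbitrary labels.
random_cohort <- function(n_genes, n_poor, n_good, seed) {
  withr::with_seed(seed, {
    n <- n_poor + n_good
    x <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n))))
    ktsp_cohort(x, sample(rep(c("poor", "good"), c(n_poor, n_good))))
  })
}

# Score every unordered pair by explicit per-sample loops.
oracle_score_pairs <- function(cohort) {
  x <- cohort$values
  genes <- sort(rownames(x), method = "radix")
  poor <- which(cohort$labels == "poor")
  good <- which(cohort$labels == "good")
  ranks <- matrix(NA_real_, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) ranks[, j] <- rank(x[, j])
  rows <- list()
  for (ia in seq_len(length(genes) - 1L)) {
    for (ib in (ia + 1L):length(genes)) {
      a <- genes[ia]; b <- genes[ib]
      n_lt_poor <- 0L; n_lt_good <- 0L
      for (j in poor) if (x[a, j] < x[b, j]) n_lt_poor <- n_lt_poor + 1L
      for (j in good) if (x[a, j] < x[b, j]) n_lt_good <- n_lt_good + 1L
      p_poor <- n_lt_poor / length(poor)
      p_good <- n_lt_good / length(good)
      d_poor <- numeric(0); d_good <- numeric(0)
      for (j in poor) d_poor <- c(d_poor, ranks[a, j] - ranks[b, j])
      for (j in good) d_good <- c(d_good, ranks[a, j] - ranks[b, j])
      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b,
        delta = abs(p_poor - p_good),
        gamma = round(abs(mean(d_poor) - mean(d_good)), 9),
        orientation = if (p_poor > p_good) "lt"
                      else if (p_poor < p_good) "gt" else "none",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta, -out$gamma, out$gene_a, out$gene_b,
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}

# Greedy rank-remove-rescore selection via the oracle scorer.
oracle_select_disjoint <- function(cohort, k) {
  current <- cohort
  picked <- list()
  for (i in seq_len(k)) {
    ranked <- oracle_score_pairs(current)
    top <- ranked[1L, , drop = FALSE]
    picked[[i]] <- top
    keep <- setdiff(rownames(current$values), c(top$gene_a, top$gene_b))
    current$values <- current$values[keep, , drop = FALSE]
  }
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

# Per-sample vote score by looping pair_vote-style comparisons explicitly.
oracle_vote_scores <- function(values, pairs) {
  scores <- integer(ncol(values))
  for (j in seq_len(ncol(values))) {
    s <- 0L
    for (i in seq_len(nrow(pairs))) {
      a <- values[pairs$gene_a[i], j]
      b <- values[pairs$gene_b[i], j]
      hit <- switch(pairs$orientation[i],
                    lt = a < b, gt = a > b, none = FALSE)
      if (hit) s <- s + 1L
    }
    scores[j] <- s
  }
  names(scores) <- colnames(values)
  scores
}

# AUC by explicit pairwise comparison counting (wins + half-ties).
oracle_auc_pairwise <- function(scores, labels) {
  sp <- scores[labels == "poor"]
  sg <- scores[labels == "good"]
  total <- 0
  for (p in sp) {
    for (g in sg) {
      total <- total + if (p > g) 1 else if (p == g) 0.5 else 0
    }
  }
  total / (length(sp) * length(sg))
}

# Exhaustive (K, tau) grid search: every K in k_min..k_max, every tau in
# 1..K, keep combinations with training sensitivity 1, maximize
# specificity; ties -> smallest K, then largest tau. Returns NULL when no
# combination is admissible.
oracle_grid_select <- function(cohort, k_min, k_max) {
  pairs <- oracle_select_disjoint(cohort, k_max)
  poor <- cohort$labels == "poor"
  best <- NULL
  for (k in k_min:k_max) {
    s <- oracle_vote_scores(cohort$values, pairs[seq_len(k), , drop = FALSE])
    for (tau in 1:k) {
      sens <- mean(s[poor] >= tau)
      spec <- mean(s[!poor] < tau)
      if (sens == 1) {
        better <- is.null(best) || spec > best$spec ||
          (spec == best$spec && (k < best$k ||
                                   (k == best$k && tau > best$tau)))
        if (better) best <- list(k = k, tau = tau, spec = spec)
      }
    }
  }
  best
}

# Product-limit estimate from an explicit d_i / n_i table.
oracle_km <- function(time, event) {
  times <- sort(unique(time))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    n_i <- sum(time >= times[i])
    d_i <- sum(time == times[i] & event == 1)
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  data.frame(time = times, surv = surv)
}
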