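# A tiny 2-gene, 8-sample cohort with a perfect switch: gA < gB in every
# poor sample, gA > gB in every good sample.
perfect_switch_cohort <- function() {
  x <- rbind(gA = c(1, 2, 3, 4, 9, 9, 9, 9),
             gB = c(5, 6, 7, 8, 1, 2, 3, 4))
  colnames(x) <- sprintf("s%d", 1:8)
  ktsp_cohort(x, rep(c("poor", "good"), each = 4))
}

test_that("ordering_counts counts strict within-sample orderings per class", {
  expect_identical(ordering_counts(perfect_switch_cohort(), "gA", "gB"),
                   c(n_lt_poor = 4L, n_poor = 4L, n_lt_good = 0L,
                     n_good = 4L))

  # ties are 'not less than' under the strict comparison
  x <- rbind(gA = rep(1, 5), gB = rep(1, 5))
  colnames(x) <- sprintf("s%d", 1:5)
  tied <- ktsp_cohort(x, c("poor", "poor", "good", "good", "good"))
  expect_identical(ordering_counts(tied, "gA", "gB"),
                   c(n_lt_poor = 0L, n_poor = 2L, n_lt_good = 0L,
                     n_good = 3L))

  expect_error(ordering_counts(tied, "gA", "gZ"),
               class = "ktsp_identifier_error")
})

test_that("ordering_counts matches direct enumeration on a toy matrix", {
  x <- rbind(gA = c(2.0, 1.5, 3.0, 0.5, 2.2, 2.2),
             gB = c(1.0, 2.5, 3.0, 1.5, 2.0, 2.3))
  colnames(x) <- sprintf("s%d", 1:6)
  labels <- c("poor", "poor", "poor", "good", "good", "good")
  cohort <- ktsp_cohort(x, labels)
  # explicit loop over samples
  n_lt_poor <- 0L; n_lt_good <- 0L
  for (j in 1:6) {
    if (x["gA", j] < x["gB", j]) {
      if (labels[j] == "poor") n_lt_poor <- n_lt_poor + 1L
      else n_lt_good <- n_lt_good + 1L
    }
  }
  expect_identical(ordering_counts(cohort, "gA", "gB"),
                   c(n_lt_poor = n_lt_poor, n_poor = 3L,
                     n_lt_good = n_lt_good, n_good = 3L))
})

test_that("pair_delta is the absolute difference of class proportions", {
  expect_equal(pair_delta(c(n_lt_poor = 4, n_poor = 4, n_lt_good = 0,
                            n_good = 4)), 1.0)
  expect_equal(pair_delta(c(n_lt_poor = 2, n_poor = 4, n_lt_good = 2,
                            n_good = 4)), 0.0)
  expect_equal(pair_delta(c(n_lt_poor = 3, n_poor = 4, n_lt_good = 1,
                            n_good = 4)), 0.5)  # |0.75 - 0.25|
  expect_error(pair_delta(c(n_lt_poor = 0, n_poor = 0, n_lt_good = 1,
                            n_good = 4)), class = "ktsp_degenerate_error")
})

test_that("pair_gamma uses within-sample average ranks", {
  # two constant, equal genes tie in every sample -> gamma 0
  x <- rbind(gA = rep(5, 4), gB = rep(5, 4), gC = c(1, 9, 2, 8))
  colnames(x) <- sprintf("s%d", 1:4)
  cohort <- ktsp_cohort(x, c("poor", "poor", "good", "good"))
  expect_equal(pair_gamma(cohort, "gA", "gB"), 0)

  # 2-sample toy, hand-computed: ranks within each profile
  y <- rbind(gA = c(1, 3), gB = c(2, 2), gC = c(3, 1))
  colnames(y) <- c("s1", "s2")
  toy <- ktsp_cohort(y, c("poor", "good"))
  # s1 ranks: gA=1 gB=2 gC=3; s2 ranks: gA=3 gB=2 gC=1
  # d = rank(gA) - rank(gC): poor -2, good +2 -> gamma 4
  expect_equal(pair_gamma(toy, "gA", "gC"), 4)

  # a planted switching pair outscores an exchangeable background pair
  cohort <- generate_cohort(n_genes = 10, n_poor = 25, n_good = 25,
                            planted = data.frame(pair = 1, p_poor = 1,
                                                 p_good = 0),
                            seed = 11)
  expect_gt(pair_gamma(cohort, "g001", "g002"),
            pair_gamma(cohort, "g005", "g006"))
})

test_that("score_all_pairs enumerates all pairs in a deterministic order", {
  cohort <- generate_cohort(seed = 3)
  ranked <- score_all_pairs(cohort)
  expect_identical(nrow(ranked), 2415L)  # choose(70, 2)
  expect_true(all(ranked$delta >= 0 & ranked$delta <= 1))
  expect_true(all(ranked$gamma >= 0))
  expect_true(all(ranked$gene_a < ranked$gene_b))
  # sorted by delta desc, gamma desc, then gene ids
  expect_true(all(diff(ranked$delta) <= 0))

  # permuting sample order leaves the ranking unchanged
  perm <- withr::with_seed(5, sample(ncol(cohort$values)))
  shuffled <- ktsp_cohort(cohort$values[, perm], cohort$labels[perm])
  expect_identical(score_all_pairs(shuffled), ranked)

  expect_error(
    score_all_pairs(ktsp_cohort(cohort$values[1, , drop = FALSE],
                                cohort$labels)),
    class = "ktsp_degenerate_error")
  expect_error(
    score_all_pairs(ktsp_cohort(cohort$values,
                                setNames(rep("poor", 78),
                                         colnames(cohort$values)))),
    class = "ktsp_degenerate_error")
})

test_that("score_all_pairs matches the brute-force oracle", {
  for (seed in 1:5) {
    cohort <- random_cohort(n_genes = 8, n_poor = 6, n_good = 7, seed = seed)
    expect_equal(score_all_pairs(cohort), oracle_score_pairs(cohort),
                 tolerance = 1e-12)
  }
})

test_that("delta vanishes when the classes hold identical profile multisets", {
  withr::with_seed(21, {
    half <- matrix(rnorm(6 * 10), 6, 10)
  })
  x <- cbind(half, half)
  dimnames(x) <- list(sprintf("g%d", 1:6), sprintf("s%02d", 1:20))
  cohort <- ktsp_cohort(x, rep(c("poor", "good"), each = 10))
  ranked <- score_all_pairs(cohort)
  expect_true(all(ranked$delta == 0))
  expect_true(all(ranked$orientation == "none"))
})

test_that("pair ranking is invariant to strictly increasing per-sample transforms", {
  cohort <- generate_cohort(n_genes = 15, n_poor = 12, n_good = 12, seed = 8)
  ranked <- score_all_pairs(cohort)
  for (f in list(function(x) exp(x), function(x) 2 * x + 7)) {
    transformed <- ktsp_cohort(f(cohort$values), cohort$labels)
    rescored <- score_all_pairs(transformed)
    expect_identical(rescored[, c("gene_a", "gene_b", "orientation")],
                     ranked[, c("gene_a", "gene_b", "orientation")])
    expect_equal(rescored$delta, ranked$delta)
  }
})
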