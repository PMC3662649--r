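# Synthetic cohorts with planted class-switching pairs. The generator
# emulates the structure of a two-class discovery set (by default 70
# signature genes, 34 poor and 44 good samples): an exchangeable Gaussian
# background in which any gene pair has expected switch score zero, plus
# planted pairs whose within-sample ordering is Bernoulli per sample with
# class-specific probabilities, so their population delta is
# |p_poor - p_good| by construction.

#' Generate a synthetic labeled cohort
#'
#' Background values are drawn i.i.d. from N(0, `noise_sd`), making all
#' background genes exchangeable. Planted pair `i` occupies genes
#' `2i-1` and `2i`: for each sample the orientation `a < b` is drawn with
#' the class-specific probability, and the pair's two already-drawn
#' Gaussian values are assigned to match it (sorted or reverse-sorted), so
#' `P(a < b | class)` is exact while marginal scales stay comparable to
#' the background.
#'
#' @param n_genes number of genes; default 70 (signature-sized panel).
#' @param n_poor,n_good samples per class; defaults 34 and 44 (a
#'   78-sample discovery cohort split).
#' @param planted `data.frame` (or list coercible to one) with columns
#'   `pair` (index; pair i uses genes 2i-1, 2i), `p_poor` and `p_good`
#'   (ordering probabilities in [0, 1]). Default: one strong switching
#'   pair at (0.95, 0.05).
#' @param noise_sd standard deviation of the Gaussian background
#'   (default 1); all values share this scale.
#' @param seed integer seed; the same seed reproduces the cohort
#'   bit-identically.
#' @return A [ktsp_cohort()] with genes `g001..`, samples `s001..` and
#'   labels poor-first.
#' @export
generate_cohort <- function(n_genes = 70L, n_poor = 34L, n_good = 44L,
                            planted = data.frame(pair = 1L, p_poor = 0.95,
                                                 p_good = 0.05),
                            noise_sd = 1, seed) {
  if (missing(seed) || is.null(seed)) {
    stop_ktsp("a seed is required", "ktsp_input_error")
  }
  n_genes <- as.integer(n_genes)
  n_poor <- as.integer(n_poor)
  n_good <- as.integer(n_good)
  if (n_genes < 1L || n_poor < 1L || n_good < 1L) {
    stop_ktsp("n_genes, n_poor and n_good must be positive",
              "ktsp_input_error")
  }
  if (noise_sd < 0) {
    stop_ktsp("noise_sd must be >= 0", "ktsp_input_error")
  }
  if (is.null(planted)) planted <- data.frame(pair = integer(),
                                              p_poor = numeric(),
                                              p_good = numeric())
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    need <- c("pair", "p_poor", "p_good")
    if (!all(need %in% names(planted))) {
      stop_ktsp("planted needs columns pair, p_poor, p_good",
                "ktsp_input_error")
    }
    planted$pair <- as.integer(planted$pair)
    if (anyDuplicated(planted$pair) || any(planted$pair < 1L)) {
      stop_ktsp("planted pair indices must be distinct positive integers",
                "ktsp_input_error")
    }
    if (2L * max(planted$pair) > n_genes) {
      stop_ktsp(sprintf(
        "planted pair %d needs gene %d but the matrix has %d genes",
        max(planted$pair), 2L * max(planted$pair), n_genes),
        "ktsp_capacity_error")
    }
    if (any(planted$p_poor < 0 | planted$p_poor > 1 |
              planted$p_good < 0 | planted$p_good > 1)) {
      stop_ktsp("planted probabilities must lie in [0, 1]",
                "ktsp_input_error")
    }
  }
  n <- n_poor + n_good
  labels <- rep(c("poor", "good"), c(n_poor, n_good))
  values <- withr::with_seed(as.integer(seed), {
    x <- matrix(stats::rnorm(n_genes * n, sd = noise_sd), n_genes, n)
    for (i in seq_len(nrow(planted))) {
      a <- 2L * planted$pair[i] - 1L
      b <- a + 1L
      p <- ifelse(labels == "poor", planted$p_poor[i], planted$p_good[i])
      a_below_b <- stats::runif(n) < p
      lo <- pmin(x[a, ], x[b, ])
      hi <- pmax(x[a, ], x[b, ])
      x[a, ] <- ifelse(a_below_b, lo, hi)
      x[b, ] <- ifelse(a_below_b, hi, lo)
    }
    x
  })
  width_g <- max(3L, nchar(n_genes))
  width_s <- max(3L, nchar(n))
  rownames(values) <- sprintf(paste0("g%0", width_g, "d"), seq_len(n_genes))
  colnames(values) <- sprintf(paste0("s%0", width_s, "d"), seq_len(n))
  ktsp_cohort(values, labels)
}

#' Gene identifiers of a planted pair
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param pair planted pair index.
#' @return Character vector of the pair's two gene identifiers.
#' @export
planted_pair_genes <- function(cohort, pair = 1L) {
  rownames(cohort$values)[c(2L * pair - 1L, 2L * pair)]
}

#' Generate synthetic survival records
#'
#' Event times are exponential with hazard `baseline_rate` for the good
#' class and `baseline_rate * hazard_ratio` for the poor class;
#' censoring times are independent exponential with rate `censor_rate`
#' (0 means no censoring).
#'
#' @param labels named `"poor"`/`"good"` vector (names are sample ids), or
#'   a [ktsp_cohort()] whose labels are used.
#' @param hazard_ratio poor-class hazard multiplier (> 0); default 1.
#' @param baseline_rate good-class event rate per month (> 0);
#'   default 0.01.
#' @param censor_rate censoring rate per month (>= 0); default 0.
#' @param seed integer seed.
#' @return `data.frame` with `sample_id`, `time_months`, `event`.
#' @export
generate_survival <- function(labels, hazard_ratio = 1,
                              baseline_rate = 0.01, censor_rate = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop_ktsp("a seed is required", "ktsp_input_error")
  }
  if (inherits(labels, "ktsp_cohort")) labels <- labels$labels
  if (is.null(names(labels))) {
    stop_ktsp("labels must be named by sample identifier",
              "ktsp_input_error")
  }
  if (hazard_ratio <= 0 || baseline_rate <= 0 || censor_rate < 0) {
    stop_ktsp("hazard_ratio and baseline_rate must be > 0, censor_rate >= 0",
              "ktsp_input_error")
  }
  n <- length(labels)
  rate <- baseline_rate * ifelse(labels == "poor", hazard_ratio, 1)
  withr::with_seed(as.integer(seed), {
    t_event <- stats::rexp(n, rate = rate)
    t_censor <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate) else
      rep(Inf, n)
    data.frame(sample_id = names(labels),
               time_months = pmin(t_event, t_censor),
               event = as.integer(t_event <= t_censor),
               stringsAsFactors = FALSE)
  })
}
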