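#' Configuration for synthetic null-result corpora
#'
#' Describes a population of two-arm trials with the structure of a sample
#' of published null results: per-arm sizes and control-arm event rates
#' drawn log-uniformly over wide ranges, an optional risk difference added
#' to the treatment arm, and a nonsignificance screen that keeps only
#' studies whose chi-square p-value is at or above `alpha_filter` —
#' emulating how a corpus of published "no effect" claims is selected.
#'
#' The defaults describe 43 studies spanning per-arm sizes 15 to 5000
#' (total sample sizes from a few dozen to about ten thousand) and
#' control-arm event probabilities 0.01 to 0.5, with no true effect.
#'
#' @param n_studies Number of studies to generate (default 43).
#' @param n_per_arm_range Integer pair: log-uniform bounds for the per-arm
#'   sample size.
#' @param base_rate_range Pair in (0, 1): log-uniform bounds for the
#'   control-arm event probability.
#' @param effect Risk difference added to the treatment arm (default 0,
#'   an exact null). `base_rate + effect` must stay inside (0, 1) over the
#'   whole rate range.
#' @param alpha_filter Significance level of the nonsignificance screen,
#'   or `NULL` to disable screening.
#' @param filter_test Which p-value screens: `"uncorrected"` (default) or
#'   `"yates"`.
#' @param seed Integer seed; every study derives its own substream from
#'   it, so increasing `n_studies` extends a corpus without reshuffling
#'   earlier studies.
#' @return A validated list of class `"synthetic_config"`.
#' @examples
#' synthetic_config(seed = 7)
#' @export
synthetic_config <- function(n_studies = 43,
                             n_per_arm_range = c(15, 5000),
                             base_rate_range = c(0.01, 0.5),
                             effect = 0,
                             alpha_filter = 0.05,
                             filter_test = c("uncorrected", "yates"),
                             seed = 1) {
  filter_test <- match.arg(filter_test)
  if (!is.numeric(n_studies) || length(n_studies) != 1 || n_studies < 1 ||
      n_studies != round(n_studies)) {
    stop_input("`n_studies` must be a positive integer.")
  }
  if (length(n_per_arm_range) != 2 || any(n_per_arm_range < 2) ||
      n_per_arm_range[1] > n_per_arm_range[2] ||
      any(n_per_arm_range != round(n_per_arm_range))) {
    stop_input("`n_per_arm_range` must be an ordered pair of integers >= 2.")
  }
  if (length(base_rate_range) != 2 || any(base_rate_range <= 0) ||
      any(base_rate_range >= 1) || base_rate_range[1] > base_rate_range[2]) {
    stop_input("`base_rate_range` must be an ordered pair inside (0, 1).")
  }
  if (!is.numeric(effect) || length(effect) != 1 ||
      base_rate_range[1] + effect <= 0 || base_rate_range[2] + effect >= 1) {
    stop_input(
      "`effect` must keep the treatment rate inside (0, 1) over the whole base-rate range."
    )
  }
  if (!is.null(alpha_filter)) {
    if (!is.numeric(alpha_filter) || length(alpha_filter) != 1 ||
        alpha_filter < 0 || alpha_filter >= 1) {
      stop_input("`alpha_filter` must be in [0, 1) or NULL.")
    }
    if (alpha_filter == 0) alpha_filter <- NULL
  }
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed)) {
    stop_input("`seed` must be an integer.")
  }
  structure(
    list(
      n_studies = as.integer(n_studies),
      n_per_arm_range = as.integer(n_per_arm_range),
      base_rate_range = as.numeric(base_rate_range),
      effect = as.numeric(effect),
      alpha_filter = alpha_filter,
      filter_test = filter_test,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<synthetic_config: %d two-arm studies, seed %d>\n",
      "  n per arm: log-uniform %d..%d; control rate: log-uniform %.3g..%.3g\n",
      "  risk difference: %g; nonsignificance screen: %s\n"
    ),
    x$n_studies, x$seed,
    x$n_per_arm_range[1], x$n_per_arm_range[2],
    x$base_rate_range[1], x$base_rate_range[2],
    x$effect,
    if (is.null(x$alpha_filter)) "off"
    else sprintf("p >= %g (%s)", x$alpha_filter, x$filter_test)
  ))
  invisible(x)
}

# Deterministic per-study substream seed; keeps earlier studies fixed when
# n_studies grows and stays inside 32-bit integer range.
study_seed <- function(seed, i) {
  as.integer(((seed %% 100000) * 20011 + 7919 * i) %% 2147483647)
}

#' Generate a synthetic corpus of two-arm trials
#'
#' Draws each study independently under the configuration: per-arm size
#' and control rate log-uniform, binomial event counts per arm, 2 x 2
#' table of events vs non-events. Tables with a zero column total (no
#' events, or no non-events, in either arm) are redrawn — such a trial has
#' no defined proportion comparison. With the nonsignificance screen on, a
#' study is also redrawn until its screening p-value reaches
#' `alpha_filter`; a study exceeding 1000 attempts raises a generation
#' error (the configuration is then effectively infeasible).
#'
#' @param config A [synthetic_config()].
#' @return A corpus tibble (as from [read_corpus()]) with study ids
#'   `"S001"`, `"S002"`, ...
#' @examples
#' generate_corpus(synthetic_config(n_studies = 5, seed = 42))
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    stop_input("`config` must come from synthetic_config().")
  }
  tabs <- lapply(seq_len(config$n_studies), function(i) {
    withr::with_seed(study_seed(config$seed, i), draw_study(config, i))
  })
  names(tabs) <- sprintf("S%03d", seq_len(config$n_studies))
  as_corpus(tabs)
}

draw_study <- function(config, i) {
  ln <- log(config$n_per_arm_range)
  lr <- log(config$base_rate_range)
  for (attempt in seq_len(1000L)) {
    n <- as.integer(round(exp(runif(1, ln[1], ln[2]))))
    p0 <- exp(runif(1, lr[1], lr[2]))
    p1 <- p0 + config$effect
    e_ctl <- rbinom(1, n, p0)
    e_trt <- rbinom(1, n, p1)
    tab <- matrix(c(e_trt, n - e_trt, e_ctl, n - e_ctl), nrow = 2, byrow = TRUE)
    if (any(colSums(tab) == 0)) next
    if (!is.null(config$alpha_filter)) {
      p <- pearson_chi_square(tab, yates = config$filter_test == "yates")$p_value
      if (p < config$alpha_filter) next
    }
    return(contingency_table(
      tab,
      row_labels = c("treatment", "control"),
      col_labels = c("event", "no event")
    ))
  }
  stop_generation(
    paste0(
      "study %d: no admissible table in 1000 attempts ",
      "(effect %g with screen at %s is effectively infeasible)."
    ),
    i, config$effect,
    if (is.null(config$alpha_filter)) "none" else format(config$alpha_filter)
  )
}

#' Idealized exact-null series at a fixed event rate
#'
#' Builds deterministic concordant tables `[[k, n - k], [k, n - k]]` with
#' `k = round(k_over_n * n)` for each requested per-arm size: both arms
#' observe exactly the same event proportion, the cleanest possible null
#' data. Along such a series the chi-square p-value is exactly 1 while
#' BF01 grows like the square root of the total sample size — the
#' mechanism by which large trials, but not small ones, can deliver
#' compelling evidence of absence.
#'
#' @param k_over_n Event rate in (0, 1).
#' @param n_values Integer per-arm sample sizes; each must round to an
#'   event count strictly between 0 and n.
#' @return A corpus tibble with study ids `"n<size>"`.
#' @examples
#' fixed_rate_series(0.1, c(10, 100, 1000))
#' @export
fixed_rate_series <- function(k_over_n, n_values) {
  if (!is.numeric(k_over_n) || length(k_over_n) != 1 ||
      k_over_n <= 0 || k_over_n >= 1) {
    stop_input("`k_over_n` must be a rate in (0, 1).")
  }
  if (!is.numeric(n_values) || length(n_values) == 0 ||
      any(n_values != round(n_values)) || any(n_values < 2)) {
    stop_input("`n_values` must be integers >= 2.")
  }
  tabs <- lapply(n_values, function(n) {
    k <- round(k_over_n * n)
    if (k < 1 || k >= n) {
      stop_input("k_over_n * n must round inside 1..(n - 1); n = %d fails.", n)
    }
    contingency_table(
      matrix(c(k, n - k, k, n - k), nrow = 2, byrow = TRUE),
      row_labels = c("arm1", "arm2"),
      col_labels = c("event", "no event")
    )
  })
  names(tabs) <- paste0("n", n_values)
  as_corpus(tabs)
}
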