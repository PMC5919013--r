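#' Pearson chi-square test of independence, with optional Yates correction
#'
#' The frequentist companion to [bf01()]: the classical test of association
#' in an m x c table. The statistic is
#' \eqn{\sum (|O - E| - \delta)^2 / E} with \eqn{\delta = 1/2} when Yates'
#' continuity correction is applied (2 x 2 tables only), otherwise 0; the
#' corrected deviation is floored at zero so the correction can only shrink
#' the statistic. The p-value is the upper tail of the chi-square
#' distribution on (m - 1)(c - 1) degrees of freedom.
#'
#' @inheritParams log_marginal_null
#' @param yates Apply Yates' continuity correction? Honored only for 2 x 2
#'   tables; requesting it for a larger table warns and computes the
#'   uncorrected statistic.
#' @return An object of class `"freq_test_result"`: list with `statistic`,
#'   `df`, `p_value`, `yates_applied`. `tidy()` gives a one-row tibble.
#' @examples
#' pearson_chi_square(contingency_2x2(347, 4686, 351, 4679))              # p = .90
#' pearson_chi_square(contingency_2x2(347, 4686, 351, 4679), yates = FALSE) # p = .87
#' @export
pearson_chi_square <- function(table, yates = TRUE) {
  y <- as_contab(table)
  rt <- rowSums(y)
  ct <- colSums(y)
  if (any(rt == 0) || any(ct == 0)) {
    stop_input(
      "degenerate table: a zero row or column total gives expected count 0."
    )
  }
  expected <- outer(rt, ct) / sum(y)
  is2x2 <- nrow(y) == 2 && ncol(y) == 2
  if (yates && !is2x2) {
    warn("Yates' correction applies only to 2 x 2 tables; not applied.")
    yates <- FALSE
  }
  dev <- abs(y - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  df <- (nrow(y) - 1L) * (ncol(y) - 1L)
  structure(
    list(
      statistic = stat,
      df = df,
      p_value = pchisq(stat, df, lower.tail = FALSE),
      yates_applied = yates
    ),
    class = "freq_test_result"
  )
}

#' @export
print.freq_test_result <- function(x, ...) {
  cat(sprintf(
    "Pearson chi-square test%s: X2 = %.4g, df = %d, p = %.4g\n",
    if (x$yates_applied) " (Yates-corrected)" else "",
    x$statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' @rdname pearson_chi_square
#' @param x A `freq_test_result`.
#' @param ... Unused.
#' @method tidy freq_test_result
#' @export
tidy.freq_test_result <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    yates_applied = x$yates_applied
  )
}
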