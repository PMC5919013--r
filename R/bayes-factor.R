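#' Log marginal likelihood of a table under the null hypothesis
#'
#' Under independent-multinomial sampling (each group's size fixed by
#' design), the null hypothesis states that every group shares one vector
#' of outcome probabilities. With a symmetric Dirichlet(a) prior on that
#' shared vector, the marginal likelihood has the closed form
#' \deqn{\prod_i \binom{n_i}{y_{i\cdot}} \frac{\Gamma(ca)}{\Gamma(a)^c}
#'       \frac{\prod_j \Gamma(y_{+j} + a)}{\Gamma(N + ca)}}
#' where \eqn{n_i} are row totals, \eqn{y_{+j}} column totals, \eqn{N} the
#' grand total and \eqn{c} the number of outcome columns. Everything is
#' evaluated in natural-log space through [lgamma()] so arbitrarily large
#' trials never overflow.
#'
#' @param table A [contingency_table()] or count matrix.
#' @param a Prior concentration of the symmetric Dirichlet prior; `a = 1`
#'   (the default) is the uniform prior, which favors no probability
#'   vector a priori.
#' @return The log marginal likelihood (natural log, always <= 0).
#' @seealso [log_marginal_alt()], [bf01()]
#' @examples
#' log_marginal_null(rbind(c(5, 14), c(4, 10)))
#' @export
log_marginal_null <- function(table, a = 1) {
  y <- as_contab(table)
  check_prior_a(a)
  k <- ncol(y)
  log_multinom_coefs(y) +
    lgamma(k * a) - k * lgamma(a) +
    sum(lgamma(colSums(y) + a)) - lgamma(sum(y) + k * a)
}

#' Log marginal likelihood of a table under the alternative hypothesis
#'
#' The alternative hypothesis gives each group its own outcome-probability
#' vector with independent symmetric Dirichlet(a) priors, so the marginal
#' likelihood is a product of per-row Dirichlet-multinomial marginals:
#' \deqn{\prod_i \binom{n_i}{y_{i\cdot}} \frac{\Gamma(ca)}{\Gamma(a)^c}
#'       \frac{\prod_j \Gamma(y_{ij} + a)}{\Gamma(n_i + ca)}.}
#' For two outcome columns and `a = 1` this collapses to
#' \eqn{\prod_i 1 / (n_i + 1)} regardless of the counts — the uniform prior
#' predicts every event count 0..n_i equally.
#'
#' @inheritParams log_marginal_null
#' @return The log marginal likelihood (natural log, always <= 0).
#' @examples
#' log_marginal_alt(rbind(c(5, 14), c(4, 10)))  # = -log(20 * 15)
#' @export
log_marginal_alt <- function(table, a = 1) {
  y <- as_contab(table)
  check_prior_a(a)
  k <- ncol(y)
  n_i <- rowSums(y)
  log_multinom_coefs(y) +
    nrow(y) * (lgamma(k * a) - k * lgamma(a)) +
    sum(lgamma(y + a)) - sum(lgamma(n_i + k * a))
}

# sum over rows of log multinomial coefficients n_i! / prod_j y_ij!
log_multinom_coefs <- function(y) {
  sum(lgamma(rowSums(y) + 1)) - sum(lgamma(y + 1))
}

#' Default Bayes factor for the null hypothesis of no association
#'
#' Computes BF01, the ratio of the marginal likelihood of the table under
#' the null hypothesis (shared outcome probabilities across groups) to that
#' under the alternative (independent probabilities per group), both with
#' symmetric Dirichlet(a) priors and group sizes fixed by design. BF01 = 10
#' means the observed counts are ten times more likely under the null than
#' under the alternative; BF01 = 1 means the data are perfectly ambiguous.
#'
#' The multinomial coefficients cancel in the ratio, but both marginals are
#' full log probabilities, so each is individually interpretable.
#'
#' @inheritParams log_marginal_null
#' @return An object of class `"bf01_result"`: a list with elements
#'   `bf01`, `log10_bf01`, `log_m0`, `log_m1`, `category` (see
#'   [classify_evidence()]), `a`, and the `table`. `tidy()` turns it into a
#'   one-row tibble.
#' @examples
#' bf01(contingency_2x2(347, 4686, 351, 4679))  # approx 77.7
#' bf01(contingency_2x2(5, 14, 4, 10))          # approx 2.7
#' @export
bf01 <- function(table, a = 1) {
  y <- as_contab(table)
  log_m0 <- log_marginal_null(y, a)
  log_m1 <- log_marginal_alt(y, a)
  if (!is.finite(log_m0) || !is.finite(log_m1)) {
    abort("non-finite log marginal likelihood; this is an internal error.",
      class = "bfnull_internal_error"
    )
  }
  bf <- exp(log_m0 - log_m1)
  structure(
    list(
      bf01 = bf,
      log10_bf01 = (log_m0 - log_m1) / log(10),
      log_m0 = log_m0,
      log_m1 = log_m1,
      category = classify_evidence(bf),
      a = a,
      table = y
    ),
    class = "bf01_result"
  )
}

#' @export
print.bf01_result <- function(x, ...) {
  side <- if (x$bf01 >= 1) "H0 (no association)" else "H1 (association)"
  cat(sprintf(
    paste0(
      "Default Bayes factor for a %d x %d contingency table (a = %g)\n",
      "  BF01 = %.4g  (log10 BF01 = %.3f)\n",
      "  evidence: %s, favoring %s\n"
    ),
    nrow(x$table), ncol(x$table), x$a, x$bf01, x$log10_bf01,
    x$category, side
  ))
  invisible(x)
}

#' @rdname bf01
#' @param x A `bf01_result`.
#' @param ... Unused.
#' @method tidy bf01_result
#' @export
tidy.bf01_result <- function(x, ...) {
  tibble(
    bf01 = x$bf01,
    log10_bf01 = x$log10_bf01,
    log_m0 = x$log_m0,
    log_m1 = x$log_m1,
    category = x$category,
    a = x$a,
    n_total = sum(x$table)
  )
}

#' @rdname bf01
#' @method glance bf01_result
#' @export
glance.bf01_result <- function(x, ...) tidy(x, ...)

#' Grade a Bayes factor on the Jeffreys evidence scale
#'
#' Maps BF01 onto the conventional evidential categories: anecdotal
#' (1 < BF <= 3), moderate (3 < BF <= 10), strong (10 < BF <= 30), very
#' strong (30 < BF <= 100) and extreme (BF > 100). Values below 1 are
#' graded on the reciprocal (mirrored bands for evidence favoring the
#' alternative); BF = 1 is anecdotal. Each boundary value belongs to the
#' lower band (BF = 3 is still anecdotal).
#'
#' @param bf01 A vector of positive Bayes factors (null over alternative).
#' @param direction If `TRUE`, append `" (H0)"` or `" (H1)"` so mirrored
#'   bands on either side of 1 remain distinguishable.
#' @return A character vector of category labels.
#' @examples
#' classify_evidence(c(2.42, 77.7, 560.9))
#' classify_evidence(1 / 40, direction = TRUE)
#' @export
classify_evidence <- function(bf01, direction = FALSE) {
  if (!is.numeric(bf01) || length(bf01) == 0 || anyNA(bf01) || any(bf01 <= 0)) {
    stop_input("Bayes factors must be positive numbers.")
  }
  band <- function(b) {
    if (b <= 3) "anecdotal"
    else if (b <= 10) "moderate"
    else if (b <= 30) "strong"
    else if (b <= 100) "very strong"
    else "extreme"
  }
  lab <- vapply(pmax(bf01, 1 / bf01), band, character(1))
  if (direction) {
    side <- ifelse(bf01 >= 1, " (H0)", " (H1)")
    lab <- paste0(lab, side)
  }
  lab
}

#' Posterior odds from a Bayes factor and prior odds
#'
#' The posterior odds of the null over the alternative are the prior odds
#' multiplied by the Bayes factor.
#'
#' @param bf01 A positive Bayes factor (or a [bf01()] result).
#' @param prior_odds Positive prior odds of the null over the alternative.
#' @return `bf01 * prior_odds`.
#' @examples
#' posterior_odds(77.7, prior_odds = 0.5)
#' @export
posterior_odds <- function(bf01, prior_odds) {
  if (inherits(bf01, "bf01_result")) bf01 <- bf01$bf01
  if (!is.numeric(bf01) || anyNA(bf01) || any(bf01 <= 0)) {
    stop_input("`bf01` must be positive.")
  }
  if (!is.numeric(prior_odds) || anyNA(prior_odds) || any(prior_odds <= 0)) {
    stop_input("`prior_odds` must be positive.")
  }
  bf01 * prior_odds
}
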