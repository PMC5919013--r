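#' Numerical-integration oracle for the default Bayes factor
#'
#' Approximates both marginal likelihoods by deterministic quadrature of
#' the product-multinomial likelihood over the Dirichlet(a) priors and
#' returns their ratio. It shares no code with the closed-form
#' [log_marginal_null()] / [log_marginal_alt()] route and exists to verify
#' it in tests; it is limited to small tables (at most 3 groups and 3
#' outcome columns).
#'
#' The Dirichlet prior is integrated in stick-breaking coordinates, where
#' it factorizes into independent Beta(a, (c - j) a) sticks, and each stick
#' is mapped through x = sin^2(u) so the integrand stays smooth even for
#' a = 1/2 (where the Beta density diverges at the endpoints). Nodes and
#' weights come from Gauss-Legendre quadrature on u.
#'
#' @inheritParams log_marginal_null
#' @param resolution Number of quadrature nodes per stick dimension
#'   (>= 64). For two outcome columns this is a one-dimensional rule; for
#'   three it is a tensor grid of `resolution^2` nodes.
#' @return The approximate BF01 (a positive number).
#' @examples
#' bf01_numeric_oracle(rbind(c(5, 14), c(4, 10)), resolution = 512)
#' @export
bf01_numeric_oracle <- function(table, a = 1, resolution = 1024) {
  y <- as_contab(table)
  check_prior_a(a)
  if (nrow(y) > 3 || ncol(y) > 3) {
    stop_input(
      "the quadrature oracle supports at most 3 x 3 tables (got %d x %d).",
      nrow(y), ncol(y)
    )
  }
  if (resolution < 64) stop_input("`resolution` must be at least 64.")

  m1 <- prod(vapply(
    seq_len(nrow(y)),
    function(i) quad_marginal(y[i, , drop = FALSE], a, resolution),
    numeric(1)
  ))
  m0 <- quad_marginal(y, a, resolution)
  m0 / m1
}

# Gauss-Legendre rules are expensive to build at high node counts; cache
# them per resolution (nodes on [0, pi/2] are reused by every stick).
gl_cache <- new.env(parent = emptyenv())

gauss_legendre_half_pi <- function(resolution) {
  key <- as.character(resolution)
  if (is.null(gl_cache[[key]])) {
    gl_cache[[key]] <- pracma::gaussLegendre(resolution, 0, pi / 2)
  }
  gl_cache[[key]]
}

# Marginal likelihood of rows sharing one probability vector theta,
# integrated over Dirichlet(a) by tensor Gauss-Legendre in transformed
# stick-breaking coordinates. rows: matrix with c columns.
quad_marginal <- function(rows, a, resolution) {
  k <- ncol(rows)
  gl <- gauss_legendre_half_pi(resolution)
  sticks <- lapply(seq_len(k - 1), function(j) {
    x <- sin(gl$x)^2
    # Beta(a, (k - j) a) density times dx/du = sin(2u)
    w <- gl$w * stats::dbeta(x, a, (k - j) * a) * sin(2 * gl$x)
    list(x = x, w = w)
  })

  if (k == 2) {
    theta <- cbind(sticks[[1]]$x, 1 - sticks[[1]]$x)
    w <- sticks[[1]]$w
  } else {
    g <- expand.grid(i = seq_len(resolution), j = seq_len(resolution))
    x1 <- sticks[[1]]$x[g$i]
    x2 <- sticks[[2]]$x[g$j]
    theta <- cbind(x1, (1 - x1) * x2, (1 - x1) * (1 - x2))
    w <- sticks[[1]]$w[g$i] * sticks[[2]]$w[g$j]
  }

  coef <- exp(log_multinom_coefs(rows))
  lik <- rep(1, nrow(theta))
  for (i in seq_len(nrow(rows))) {
    for (j in seq_len(k)) lik <- lik * theta[, j]^rows[i, j]
  }
  coef * sum(w * lik)
}
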