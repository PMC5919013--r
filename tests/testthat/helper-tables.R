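# Shared fixtures and independent oracles for the test suite.

# Published worked-example tables: rows = arms, cols = (event, no event).
jolly_table <- function() rbind(c(347L, 4686L), c(351L, 4679L))
carrier_table <- function() rbind(c(5L, 14L), c(4L, 10L))

# Enumerate every 2-column table with the given fixed row totals.
# Returns a list of matrices; used for conservation checks.
enumerate_tables_2col <- function(row_totals) {
  grids <- lapply(row_totals, function(n) 0:n)
  combos <- expand.grid(grids)
  lapply(seq_len(nrow(combos)), function(r) {
    k <- as.integer(combos[r, ])
    cbind(k, row_totals - k)
  })
}

# Independent factorial-based marginal likelihoods for tiny tables:
# plain products of choose()/beta(), no lgamma sums shared with the
# implementation. Only safe for small counts.
factorial_marginal_null_2col <- function(y, a = 1) {
  n_i <- rowSums(y)
  coef <- prod(choose(n_i, y[, 1]))
  k1 <- sum(y[, 1])
  k2 <- sum(y[, 2])
  coef * beta(k1 + a, k2 + a) / beta(a, a)
}

factorial_marginal_alt_2col <- function(y, a = 1) {
  prod(vapply(seq_len(nrow(y)), function(i) {
    choose(sum(y[i, ]), y[i, 1]) * beta(y[i, 1] + a, y[i, 2] + a) / beta(a, a)
  }, numeric(1)))
}

# A small deterministic pool of random-looking tables for property tests.
small_table_pool <- function() {
  list(
    rbind(c(0L, 3L), c(2L, 1L)),
    rbind(c(1L, 1L), c(1L, 1L)),
    rbind(c(4L, 0L), c(0L, 4L)),
    rbind(c(2L, 5L), c(3L, 2L)),
    rbind(c(6L, 1L), c(2L, 4L)),
    rbind(c(0L, 2L), c(0L, 3L)),
    rbind(c(3L, 3L), c(3L, 3L)),
    rbind(c(1L, 6L), c(5L, 1L)),
    rbind(c(2L, 2L), c(2L, 2L), c(2L, 2L)),
    rbind(c(1L, 0L, 2L), c(0L, 3L, 1L)),
    rbind(c(2L, 1L, 1L), c(1L, 2L, 2L), c(0L, 1L, 3L))
  )
}

local_corpus_csv <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  writeLines(lines, path)
  path
}
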