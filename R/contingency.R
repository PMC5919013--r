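#' Construct a contingency table of event counts
#'
#' Builds the basic data object of the package: an m x c table of
#' non-negative integer counts with rows as groups (treatment arms) and
#' columns as outcome categories. Row totals, column totals and the grand
#' total are derived, never stored.
#'
#' @param counts A numeric matrix (or object coercible to one, e.g. a
#'   data frame of counts) with at least 2 rows and 2 columns; every entry
#'   must be a non-negative integer and the grand total must be positive.
#' @param row_labels,col_labels Optional character vectors of dimension
#'   labels; default to existing dimnames or `"group1"`/`"outcome1"` style
#'   names.
#'
#' @return An integer matrix of class `"contingency_table"`.
#'
#' @examples
#' contingency_table(rbind(c(5, 14), c(4, 10)))
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_input("`counts` must be a numeric matrix of event counts.")
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop_input(
      "a contingency table needs at least 2 rows and 2 columns (got %d x %d).",
      nrow(counts), ncol(counts)
    )
  }
  if (anyNA(counts)) stop_input("counts must not contain missing values.")
  if (any(counts < 0)) stop_input("counts must be non-negative.")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    stop_input("counts must be integers (event tallies, not rates).")
  }
  if (sum(counts) < 1) stop_input("the table must contain at least one observation.")

  storage.mode(counts) <- "integer"
  if (!is.null(row_labels)) {
    stopifnot(length(row_labels) == nrow(counts))
    rownames(counts) <- row_labels
  } else if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("group", seq_len(nrow(counts)))
  }
  if (!is.null(col_labels)) {
    stopifnot(length(col_labels) == ncol(counts))
    colnames(counts) <- col_labels
  } else if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("outcome", seq_len(ncol(counts)))
  }
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Build a 2 x 2 table from four counts
#'
#' Convenience constructor in the row-major order used throughout:
#' (group 1 events, group 1 non-events, group 2 events, group 2 non-events).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-major.
#' @return A 2 x 2 [contingency_table()].
#' @examples
#' contingency_2x2(347, 4686, 351, 4679)
#' @export
contingency_2x2 <- function(a, b, c, d) {
  contingency_table(
    matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
    col_labels = c("event", "no event")
  )
}

as_contab <- function(x, arg = "table") {
  if (inherits(x, "contingency_table")) return(x)
  if (is.matrix(x) || is.data.frame(x)) return(contingency_table(x))
  stop_input("`%s` must be a contingency_table or a count matrix.", arg)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf(
    "<contingency_table: %d groups x %d outcomes, N = %d>\n",
    nrow(x), ncol(x), sum(x)
  ))
  y <- unclass(x)
  print(cbind(y, total = rowSums(y)))
  invisible(x)
}

check_prior_a <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    stop_input("the prior concentration `a` must be a single positive number.")
  }
  a
}
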