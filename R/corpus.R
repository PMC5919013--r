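#' Read a corpus of study tables from CSV
#'
#' A corpus is a tibble with one row per study: `study_id`, a list-column
#' `table` of [contingency_table()] objects, and `n_total`. The CSV dialect
#' is long format, one cell per line, with columns `study_id`,
#' `row_index` (0-based group index), `col_index` (0-based outcome index),
#' `count`, and optional `row_label` / `col_label`. Lines starting with `#`
#' are comments (the simulator records its seed that way).
#'
#' @param path Path to a CSV file (or a connection readr accepts).
#' @return A corpus tibble (classes `"study_corpus"`, `"tbl_df"`). A file
#'   with a header but no rows yields an empty corpus.
#' @examples
#' path <- system.file("extdata", "nejm_worked_examples.csv", package = "bfnull")
#' read_corpus(path)
#' @export
read_corpus <- function(path) {
  cells <- tryCatch(
    suppressWarnings(readr::read_csv(
      path,
      comment = "#",
      col_types = readr::cols(
        study_id = readr::col_character(),
        row_index = readr::col_integer(),
        col_index = readr::col_integer(),
        count = readr::col_double(),
        .default = readr::col_character()
      ),
      progress = FALSE
    )),
    error = function(e) stop_input("cannot read corpus CSV: %s", conditionMessage(e))
  )
  required <- c("study_id", "row_index", "col_index", "count")
  missing_cols <- setdiff(required, names(cells))
  if (length(missing_cols) > 0) {
    stop_input("corpus CSV is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  prob <- readr::problems(cells)
  if (nrow(prob) > 0) {
    stop_input(
      "malformed corpus CSV at line %d: expected %s, got '%s'.",
      prob$row[1] + 1L, prob$expected[1], prob$actual[1]
    )
  }
  if (nrow(cells) == 0) {
    return(new_corpus(tibble(
      study_id = character(), table = list(), n_total = integer()
    )))
  }
  if (anyNA(cells[required])) {
    bad <- which(!stats::complete.cases(cells[required]))[1]
    stop_input("missing value in corpus CSV data line %d.", bad)
  }
  if (any(cells$count < 0)) {
    bad <- cells$study_id[cells$count < 0][1]
    stop_input("negative count in study '%s'.", bad)
  }
  if (any(cells$count != round(cells$count))) {
    bad <- cells$study_id[cells$count != round(cells$count)][1]
    stop_input("non-integer count in study '%s'.", bad)
  }

  dup <- duplicated(cells[, c("study_id", "row_index", "col_index")])
  if (any(dup)) {
    d <- cells[dup, ][1, ]
    stop_input(
      "duplicate cell (row %d, col %d) in study '%s'.",
      d$row_index, d$col_index, d$study_id
    )
  }

  ids <- unique(cells$study_id)
  tabs <- lapply(ids, function(id) {
    cc <- cells[cells$study_id == id, ]
    m <- max(cc$row_index) + 1L
    k <- max(cc$col_index) + 1L
    if (nrow(cc) != m * k) {
      stop_input(
        "study '%s' is ragged: expected %d cells for a %d x %d table, got %d.",
        id, m * k, m, k, nrow(cc)
      )
    }
    counts <- matrix(NA_real_, m, k)
    counts[cbind(cc$row_index + 1L, cc$col_index + 1L)] <- cc$count
    row_labels <- col_labels <- NULL
    if ("row_label" %in% names(cc)) {
      lab <- unique(cc[, c("row_index", "row_label")])
      if (!anyNA(lab$row_label)) row_labels <- lab$row_label[order(lab$row_index)]
    }
    if ("col_label" %in% names(cc)) {
      lab <- unique(cc[, c("col_index", "col_label")])
      if (!anyNA(lab$col_label)) col_labels <- lab$col_label[order(lab$col_index)]
    }
    withCallingHandlers(
      contingency_table(counts, row_labels, col_labels),
      bfnull_input_error = function(e) {
        stop_input("invalid table for study '%s': %s", id, conditionMessage(e))
      }
    )
  })
  new_corpus(tibble(
    study_id = ids,
    table = tabs,
    n_total = vapply(tabs, sum, integer(1))
  ))
}

new_corpus <- function(x) {
  class(x) <- c("study_corpus", class(x))
  x
}

#' Assemble a corpus from a list of tables
#'
#' @param tables A (preferably named) list of count matrices or
#'   [contingency_table()] objects; names become study ids.
#' @return A corpus tibble, as from [read_corpus()].
#' @examples
#' as_corpus(list(
#'   jolly = rbind(c(347, 4686), c(351, 4679)),
#'   carrier = rbind(c(5, 14), c(4, 10))
#' ))
#' @export
as_corpus <- function(tables) {
  if (!is.list(tables)) stop_input("`tables` must be a list of count matrices.")
  ids <- names(tables)
  if (is.null(ids) || any(ids == "")) {
    ids <- sprintf("study%03d", seq_along(tables))
  }
  if (anyDuplicated(ids)) stop_input("study ids must be unique.")
  tabs <- lapply(tables, as_contab)
  new_corpus(tibble(
    study_id = ids,
    table = unname(tabs),
    n_total = unname(vapply(tabs, sum, integer(1)))
  ))
}

#' Write a corpus in the long CSV dialect
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @param comment_lines Optional character vector written as `#`-prefixed
#'   header comments (used by the simulator to record its seed).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, comment_lines = NULL) {
  stopifnot(inherits(corpus, "study_corpus"))
  rows <- purrr::map2(corpus$study_id, corpus$table, function(id, tab) {
    g <- expand.grid(
      row_index = seq_len(nrow(tab)) - 1L,
      col_index = seq_len(ncol(tab)) - 1L
    )
    tibble(
      study_id = id,
      row_index = g$row_index,
      col_index = g$col_index,
      count = as.integer(tab[cbind(g$row_index + 1L, g$col_index + 1L)]),
      row_label = rownames(tab)[g$row_index + 1L],
      col_label = colnames(tab)[g$col_index + 1L]
    )
  })
  out <- dplyr::bind_rows(rows)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment_lines)) {
    writeLines(paste0("# ", comment_lines), con)
  }
  writeLines(paste(names(out), collapse = ","), con)
  writeLines(
    do.call(paste, c(unname(as.list(out)), sep = ",")),
    con
  )
  invisible(path)
}

#' Reanalyze every study in a corpus
#'
#' Runs the default Bayes factor and both chi-square variants on each
#' study, producing the per-study evidence table that the corpus summaries
#' and plots build on.
#'
#' @param corpus A corpus tibble from [read_corpus()], [as_corpus()] or
#'   [generate_corpus()]; must be non-empty.
#' @inheritParams log_marginal_null
#' @return A tibble of class `"corpus_reanalysis"` with columns
#'   `study_id`, `n_total`, `p_yates`, `p_uncorrected`, `bf01`,
#'   `log10_bf01`, `category`.
#' @examples
#' corpus <- as_corpus(list(
#'   jolly = rbind(c(347, 4686), c(351, 4679)),
#'   carrier = rbind(c(5, 14), c(4, 10))
#' ))
#' reanalyze(corpus)
#' @export
reanalyze <- function(corpus, a = 1) {
  if (!inherits(corpus, "study_corpus")) {
    if (is.list(corpus) && !is.data.frame(corpus)) corpus <- as_corpus(corpus)
    else stop_input("`corpus` must be a study corpus (see read_corpus()).")
  }
  if (nrow(corpus) == 0) stop_input("cannot reanalyze an empty corpus.")
  if (anyDuplicated(corpus$study_id)) stop_input("study ids must be unique.")
  check_prior_a(a)

  rows <- purrr::map2(corpus$study_id, corpus$table, function(id, tab) {
    res <- tryCatch(
      {
        b <- bf01(tab, a = a)
        py <- pearson_chi_square(tab, yates = TRUE)
        pu <- pearson_chi_square(tab, yates = FALSE)
        tibble(
          study_id = id,
          n_total = sum(tab),
          p_yates = py$p_value,
          p_uncorrected = pu$p_value,
          bf01 = b$bf01,
          log10_bf01 = b$log10_bf01,
          category = b$category
        )
      },
      bfnull_input_error = function(e) {
        stop_input("study '%s': %s", id, conditionMessage(e))
      }
    )
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("corpus_reanalysis", class(out))
  attr(out, "a") <- a
  out
}

#' Corpus-level evidence summary
#'
#' Collapses a per-study reanalysis into the corpus-level quantities:
#' the range and median of BF01, counts per evidence category, the Pearson
#' correlation between the p-value and log10 BF01 (with its square reported
#' as a percentage of variance explained), and the correlation between
#' log10 total sample size and log10 BF01. Correlations need at least 3
#' studies; with fewer they are reported as `NA`, never fabricated.
#'
#' @param reanalysis A `corpus_reanalysis` tibble from [reanalyze()] (any
#'   tibble with the same columns works, which is convenient for testing).
#' @param p_value Which p-value enters the p-vs-evidence correlation:
#'   `"uncorrected"` (default) or `"yates"`.
#' @return A list of class `"corpus_summary"` with elements `n_studies`,
#'   `min_bf01`, `max_bf01`, `median_bf01`, `category_counts` (named
#'   integer vector), `r_p_logbf`, `r2_p_logbf` (percent), `r_logn_logbf`,
#'   `p_value_used`. `glance()` flattens it to one row.
#' @examples
#' corpus <- as_corpus(list(
#'   jolly = rbind(c(347, 4686), c(351, 4679)),
#'   carrier = rbind(c(5, 14), c(4, 10))
#' ))
#' summarize_corpus(reanalyze(corpus))
#' @export
summarize_corpus <- function(reanalysis, p_value = c("uncorrected", "yates")) {
  p_value <- match.arg(p_value)
  needed <- c("study_id", "n_total", "p_yates", "p_uncorrected", "bf01", "log10_bf01")
  if (!is.data.frame(reanalysis) || !all(needed %in% names(reanalysis))) {
    stop_input("`reanalysis` must be a per-study reanalysis table (see reanalyze()).")
  }
  if (nrow(reanalysis) == 0) stop_input("cannot summarize an empty reanalysis.")
  p <- if (p_value == "uncorrected") reanalysis$p_uncorrected else reanalysis$p_yates
  lbf <- reanalysis$log10_bf01
  n3 <- nrow(reanalysis) >= 3
  r_p <- if (n3) cor(p, lbf) else NA_real_
  r_n <- if (n3) cor(log10(reanalysis$n_total), lbf) else NA_real_
  cats <- if ("category" %in% names(reanalysis)) reanalysis$category
          else classify_evidence(reanalysis$bf01)
  levels <- c("anecdotal", "moderate", "strong", "very strong", "extreme")
  counts <- table(factor(cats, levels = levels))
  structure(
    list(
      n_studies = nrow(reanalysis),
      min_bf01 = min(reanalysis$bf01),
      max_bf01 = max(reanalysis$bf01),
      median_bf01 = median(reanalysis$bf01),
      category_counts = setNames(as.integer(counts), levels),
      r_p_logbf = r_p,
      r2_p_logbf = if (n3) 100 * r_p^2 else NA_real_,
      r_logn_logbf = r_n,
      p_value_used = p_value
    ),
    class = "corpus_summary"
  )
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Corpus of %d studies\n",
      "  BF01: min %.3g, median %.3g, max %.3g\n",
      "  categories: %s\n"
    ),
    x$n_studies, x$min_bf01, x$median_bf01, x$max_bf01,
    paste(sprintf("%s %d", names(x$category_counts), x$category_counts),
      collapse = ", "
    )
  ))
  if (is.na(x$r_p_logbf)) {
    cat("  correlations: undefined (fewer than 3 studies)\n")
  } else {
    cat(sprintf(
      paste0(
        "  r(p [%s], log10 BF01) = %.3f  (%.2f%% of variance)\n",
        "  r(log10 N, log10 BF01) = %.3f\n"
      ),
      x$p_value_used, x$r_p_logbf, x$r2_p_logbf, x$r_logn_logbf
    ))
  }
  invisible(x)
}

#' @rdname summarize_corpus
#' @param x A `corpus_summary`.
#' @param ... Unused.
#' @method glance corpus_summary
#' @export
glance.corpus_summary <- function(x, ...) {
  tibble(
    n_studies = x$n_studies,
    min_bf01 = x$min_bf01,
    max_bf01 = x$max_bf01,
    median_bf01 = x$median_bf01,
    r_p_logbf = x$r_p_logbf,
    r2_p_logbf = x$r2_p_logbf,
    r_logn_logbf = x$r_logn_logbf,
    p_value_used = x$p_value_used
  )
}

#' @rdname summarize_corpus
#' @method glance corpus_reanalysis
#' @export
glance.corpus_reanalysis <- function(x, ...) glance(summarize_corpus(x, ...))

#' @rdname summarize_corpus
#' @method tidy corpus_summary
#' @export
tidy.corpus_summary <- function(x, ...) {
  tibble(
    category = names(x$category_counts),
    n = x$category_counts
  )
}

#' Serialize a corpus summary to JSON
#'
#' All floats are written at full precision; category counts become a
#' nested object.
#'
#' @param summary A `corpus_summary`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
summary_to_json <- function(summary, path = NULL) {
  stopifnot(inherits(summary, "corpus_summary"))
  obj <- unclass(summary)
  obj$category_counts <- as.list(obj$category_counts)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
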