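test_that("the shipped worked-example corpus loads with the published totals", {
  corpus <- read_corpus(
    system.file("extdata", "nejm_worked_examples.csv", package = "bfnull")
  )
  expect_s3_class(corpus, "study_corpus")
  expect_identical(nrow(corpus), 2L)
  expect_identical(corpus$n_total, c(10063L, 33L))
  expect_identical(rownames(corpus$table[[2]]), c("screening plus CT", "screening only"))
})

test_that("corpus CSV validation names the offending study", {
  header <- "study_id,row_index,col_index,count"
  ok <- c("s1,0,0,1", "s1,0,1,2", "s1,1,0,3", "s1,1,1,4")

  empty <- read_corpus(local_corpus_csv(header))
  expect_identical(nrow(empty), 0L)
  expect_error(reanalyze(empty), class = "bfnull_input_error")

  expect_error(
    read_corpus(local_corpus_csv(c(header, sub("1$", "-1", ok[1]), ok[-1]))),
    "negative.*s1",
    class = "bfnull_input_error"
  )
  expect_error(
    read_corpus(local_corpus_csv(c(header, "s1,0,0,1.5", ok[-1]))),
    "non-integer.*s1",
    class = "bfnull_input_error"
  )
  expect_error(
    read_corpus(local_corpus_csv(c(header, ok[-4]))),
    "ragged.*expected 4 cells",
    class = "bfnull_input_error"
  )
  expect_error(
    read_corpus(local_corpus_csv(c(header, ok, "s1,1,1,9"))),
    "duplicate cell",
    class = "bfnull_input_error"
  )
  expect_error(
    read_corpus(local_corpus_csv(c(header, "s1,0,0,x", ok[-1]))),
    class = "bfnull_input_error"
  )
})

test_that("a corpus round-trips through the CSV dialect", {
  corpus <- as_corpus(list(
    jolly = jolly_table(),
    carrier = carrier_table(),
    wide = rbind(c(1, 2, 3), c(4, 5, 6))
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, path, comment_lines = "seed: 7")
  back <- read_corpus(path)
  expect_identical(back$study_id, corpus$study_id)
  expect_identical(back$n_total, corpus$n_total)
  for (i in seq_len(nrow(corpus))) {
    expect_equal(unclass(back$table[[i]]), unclass(corpus$table[[i]]),
      ignore_attr = TRUE
    )
  }
})

test_that("reanalysis reproduces the published per-study numbers and is pure", {
  corpus <- as_corpus(list(jolly = jolly_table(), carrier = carrier_table()))
  res <- reanalyze(corpus)
  expect_identical(nrow(res), 2L)
  expect_equal(round(res$bf01, 1), c(77.7, 2.7))
  expect_equal(round(res$p_yates, 2), c(0.90, 1))
  expect_equal(round(res$p_uncorrected, 2), c(0.87, 0.89))
  expect_identical(res$category, c("very strong", "anecdotal"))
  expect_equal(res$log10_bf01, log10(res$bf01))
  expect_identical(res, reanalyze(corpus))

  balanced <- reanalyze(as_corpus(list(b = rbind(c(10, 10), c(10, 10)))))
  expect_equal(balanced$p_uncorrected, 1)
  expect_gt(balanced$bf01, 1)
})

test_that("reanalysis aborts naming the failing study", {
  corpus <- as_corpus(list(ok = carrier_table(), bad = rbind(c(0, 2), c(0, 3))))
  expect_error(reanalyze(corpus), "bad", class = "bfnull_input_error")
})

test_that("summaries compute the corpus-level quantities", {
  # hand-checkable symmetric configuration: r(p, log BF) is exactly 0
  flat <- tibble::tibble(
    study_id = c("a", "b", "c"),
    n_total = c(100L, 200L, 400L),
    p_yates = c(0.2, 0.5, 0.8),
    p_uncorrected = c(0.2, 0.5, 0.8),
    bf01 = 10^c(0, 1, 0),
    log10_bf01 = c(0, 1, 0),
    category = classify_evidence(10^c(0, 1, 0))
  )
  s <- summarize_corpus(flat)
  expect_equal(s$r_p_logbf, 0, tolerance = 1e-12)
  expect_equal(s$r2_p_logbf, 0, tolerance = 1e-12)
  expect_identical(sum(s$category_counts), s$n_studies)
  expect_true(s$min_bf01 <= s$median_bf01 && s$median_bf01 <= s$max_bf01)

  # perfect log-linear dependence on sample size
  linear <- flat
  linear$log10_bf01 <- 0.5 * log10(linear$n_total)
  linear$bf01 <- 10^linear$log10_bf01
  expect_equal(summarize_corpus(linear)$r_logn_logbf, 1, tolerance = 1e-12)
})

test_that("correlations are base-invariant and r2 is the squared correlation in percent", {
  res <- reanalyze(generate_corpus(synthetic_config(n_studies = 12, seed = 3)))
  s <- summarize_corpus(res)
  r_natural <- cor(res$p_uncorrected, log(res$bf01))
  expect_equal(s$r_p_logbf, r_natural, tolerance = 1e-12)
  expect_equal(s$r2_p_logbf, 100 * s$r_p_logbf^2, tolerance = 1e-12)
  expect_true(abs(s$r_p_logbf) <= 1 && abs(s$r_logn_logbf) <= 1)

  # summarize never mutates the per-study rows
  before <- res
  invisible(summarize_corpus(res))
  expect_identical(res, before)

  # the p-value column switch changes only the p correlation inputs
  sy <- summarize_corpus(res, p_value = "yates")
  expect_identical(sy$p_value_used, "yates")
  expect_equal(sy$r_logn_logbf, s$r_logn_logbf)
})

test_that("fewer than 3 studies leaves correlations undefined", {
  corpus <- as_corpus(list(jolly = jolly_table(), carrier = carrier_table()))
  s <- summarize_corpus(reanalyze(corpus))
  expect_true(is.na(s$r_p_logbf))
  expect_true(is.na(s$r_logn_logbf))
  expect_true(is.na(s$r2_p_logbf))
  expect_equal(round(s$min_bf01, 2), 2.66)
  expect_equal(round(s$max_bf01, 1), 77.7)
})

test_that("glance and JSON serialization expose the summary fields", {
  res <- reanalyze(generate_corpus(synthetic_config(n_studies = 10, seed = 2)))
  g <- glance(res)
  expect_s3_class(g, "tbl_df")
  expect_identical(nrow(g), 1L)
  expect_true(all(c("min_bf01", "r_logn_logbf", "r2_p_logbf") %in% names(g)))

  js <- jsonlite::fromJSON(summary_to_json(summarize_corpus(res)))
  expect_equal(js$n_studies, 10)
  expect_equal(sum(unlist(js$category_counts)), 10)
  expect_equal(js$min_bf01, min(res$bf01), tolerance = 1e-12)
})
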