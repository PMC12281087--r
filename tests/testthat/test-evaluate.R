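# Fit-based tests share one small simulated study (fast to refit).
study <- small_study(seed = 5)

test_that("build_sentence_table joins records, metrics and controls", {
  tab <- study$table
  expect_equal(nrow(tab), nrow(study$records))
  expect_true(all(c("log_speed", "mean_word_length", "mean_log_word_freq",
                    "surprisal", "relevance") %in% names(tab)))
  expect_equal(tab$log_speed, log(tab$reading_speed))
  # spot-check the response transform
  i <- which.min(abs(tab$reading_speed - 2.5))[1]
  expect_equal(tab$log_speed[i], log(tab$reading_speed[i]))

  # partial metric coverage: inner join drops and reports
  surp8 <- study$surprisal[-(1:2), ]
  expect_message(
    tab8 <- build_sentence_table(study$records, study$corpus, study$freqs,
                                 surprisal = surp8),
    "dropped"
  )
  n_per_sent <- nrow(study$records) / nrow(study$corpus)
  expect_equal(nrow(tab8), nrow(study$records) - 2 * n_per_sent)
  expect_error(
    build_sentence_table(study$records[0, ], study$corpus, study$freqs),
    "empty join"
  )
})

test_that("delta AIC identities: self-comparison is exactly zero, sign is full minus base", {
  tab <- study$table
  cmp0 <- compare_models(tab, base_metrics = "surprisal",
                         full_metrics = "surprisal")
  expect_identical(cmp0$delta_aic, 0)
  cmp <- compare_models(tab, full_metrics = "surprisal")
  expect_equal(cmp$delta_aic, cmp$full$aic - cmp$base$aic)
  expect_equal(cmp$base$n, cmp$full$n)
  expect_error(compare_models(tab, base_metrics = "relevance",
                              full_metrics = "surprisal"), "superset")
  g <- glance(cmp)
  expect_equal(g$delta_aic, cmp$delta_aic)
})

test_that("fitting is deterministic given fixed data", {
  f1 <- fit_reading_gamm(study$table, metrics = "surprisal")
  f2 <- fit_reading_gamm(study$table, metrics = "surprisal")
  expect_identical(coef(f1$gam), coef(f2$gam))
  expect_identical(f1$aic, f2$aic)
})

test_that("fit errors are diagnostic, never silent", {
  tab <- study$table
  one_p <- tab[tab$participant == tab$participant[1], ]
  expect_error(fit_reading_gamm(one_p), ">= 2 participants")
  tab2 <- tab
  tab2$surprisal <- 1
  expect_error(fit_reading_gamm(tab2, metrics = "surprisal"),
               "constant predictor")
  expect_error(fit_reading_gamm(tab, metrics = "nope"), "missing column")
})

test_that("a noiseless linear truth is recovered as a straight partial effect", {
  tab <- study$table
  tab$log_speed <- 0.7 - 0.2 * tab$mean_word_length
  # zero residual variance makes the REML step search complain; the fit
  # itself is well defined
  fit <- suppressWarnings(fit_reading_gamm(tab))
  pe <- partial_effects(fit, terms = "mean_word_length", n_grid = 100)
  interior <- pe[6:95, ]
  # centered curve differs from the generating line only by a constant
  offset <- interior$fit - (-0.2) * interior$x
  expect_lt(max(offset) - min(offset), 1e-3)
  expect_equal(partial_effect_slope(fit, "mean_word_length"), -0.2,
               tolerance = 1e-3)
  # the other smooth carries (essentially) nothing
  expect_lt(abs(partial_effect_slope(fit, "mean_log_word_freq")), 1e-3)
})

test_that("tidy and glance expose per-term significance and fit summaries", {
  fit <- fit_reading_gamm(study$table, metrics = c("surprisal", "relevance"))
  td <- tidy(fit)
  expect_true(all(c("s(mean_word_length)", "s(mean_log_word_freq)",
                    "s(surprisal)", "s(relevance)", "s(participant)") %in%
                    td$term))
  expect_true(all(td$p.value >= 0 & td$p.value <= 1, na.rm = TRUE))
  expect_identical(td$significant, td$p.value < 0.01)
  g <- glance(fit)
  expect_equal(g$n, nrow(study$table))
  expect_true(is.finite(g$AIC))
})

test_that("partial-effect export writes one TSV per term and round-trips", {
  fit <- fit_reading_gamm(study$table, metrics = c("surprisal", "relevance"))
  dir <- withr::local_tempdir()
  paths <- export_partial_effects(fit, dir)
  expect_length(paths, 4L) # two controls + two metrics
  pe <- partial_effects(fit, terms = "surprisal")
  back <- readr::read_tsv(file.path(dir, "partial_effect_surprisal.tsv"),
                          col_types = "ddddd", progress = FALSE)
  expect_equal(back$fit, pe$fit)
  expect_equal(back$lower, pe$lower)
  expect_error(partial_effects(fit, terms = "nope"), "unknown term")
  expect_error(export_partial_effects(fit, dir, terms = "nope"),
               "unknown term")
})

test_that("Spearman correlation endpoints and degenerate input", {
  tab <- tibble::tibble(a = 1:10, b = (1:10)^3, c = -(1:10), d = rep(1, 10))
  expect_equal(correlate_metrics(tab, "a", "b"), 1.0)
  expect_equal(correlate_metrics(tab, "a", "c"), -1.0)
  expect_error(correlate_metrics(tab, "a", "d"), "undefined correlation")
  expect_error(correlate_metrics(tab[1:2, ], "a", "b"))
})

test_that("autoplot and profile plots build without error", {
  fit <- fit_reading_gamm(study$table)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  p2 <- plot_metric_profile(study$surprisal[study$surprisal$doc_id ==
                                              study$surprisal$doc_id[1], ])
  expect_s3_class(p2, "ggplot")
})
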