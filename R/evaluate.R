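#' Join reading records with sentence metrics and control predictors
#'
#' Builds the modelling table: one row per participant x sentence with the
#' response (natural log of reading speed in words/second), the control
#' predictors (mean word length, mean log word frequency) and any number
#' of per-sentence metric columns. Joins are inner joins on
#' `(doc_id, sentence_index)`; unmatched record rows are counted and
#' reported via a message.
#'
#' @param records Reading-record tibble (see [read_reading_table()]).
#' @param corpus Corpus tibble.
#' @param freqs Frequency table.
#' @param ... Named metric profiles, e.g. `surprisal = <tibble>`,
#'   `relevance = <tibble>`; each must carry `doc_id`, `sentence_index`,
#'   `value`. The name becomes the column name.
#' @return A sentence table: tibble with columns `language`,
#'   `participant`, `doc_id`, `sentence_index`, `word_count`,
#'   `reading_speed`, `log_speed`, `mean_word_length`,
#'   `mean_log_word_freq` and one column per metric.
#' @export
build_sentence_table <- function(records, corpus, freqs, ...) {
  metrics <- list(...)
  if (length(metrics) > 0L && is.null(names(metrics))) {
    stop("metric profiles must be named", call. = FALSE)
  }
  preds <- sentence_predictors(corpus, freqs)
  tab <- dplyr::inner_join(
    records,
    dplyr::select(preds, "doc_id", "sentence_index", "mean_word_length",
                  "mean_log_word_freq"),
    by = c("doc_id", "sentence_index")
  )
  for (nm in names(metrics)) {
    m <- metrics[[nm]]
    stopifnot(all(c("doc_id", "sentence_index", "value") %in% names(m)))
    m <- dplyr::select(m, "doc_id", "sentence_index", "value")
    names(m)[names(m) == "value"] <- nm
    tab <- dplyr::inner_join(tab, m, by = c("doc_id", "sentence_index"))
  }
  dropped <- nrow(records) - nrow(tab)
  if (dropped > 0L) {
    message(dropped, " record(s) had no matching sentence and were dropped")
  }
  if (nrow(tab) == 0L) stop("empty join: no record matches a sentence",
                            call. = FALSE)
  tab$reading_speed <- compute_reading_speed(tab$word_count,
                                             tab$total_fixation_duration_ms)
  tab$log_speed <- log(tab$reading_speed)
  tab
}

#' Fit the additive reading-speed model
#'
#' A generalized additive mixed model of log reading speed: penalized
#' thin-plate spline smooths for the control predictors (mean word length,
#' mean log word frequency) and each supplied metric, language as a
#' parametric fixed factor (dropped automatically when only one language
#' is present), and a participant random intercept (`bs = "re"`). Fitted
#' with `mgcv::gam` under REML smoothing-parameter selection. The reported
#' AIC is the conditional AIC of the fitted `gam` object.
#'
#' @param table Sentence table from [build_sentence_table()].
#' @param metrics Character vector of metric column names to add as
#'   smooth terms (the base model uses none).
#' @param k Spline basis dimension per smooth (default 9).
#' @param response Response column (default `"log_speed"`).
#' @return A `reading_gamm` object: the `mgcv` fit plus metadata. Access
#'   the raw fit via `$gam`; see [tidy.reading_gamm()],
#'   [glance.reading_gamm()], [partial_effects()].
#' @export
fit_reading_gamm <- function(table, metrics = character(), k = 9,
                             response = "log_speed") {
  needed <- c(response, "mean_word_length", "mean_log_word_freq",
              "language", "participant", metrics)
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0L) {
    stop("sentence table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(unique(table$participant)) < 2L) {
    stop("need >= 2 participants for a random intercept", call. = FALSE)
  }
  dat <- as.data.frame(table[needed])
  dat$language <- factor(dat$language)
  dat$participant <- factor(dat$participant)
  smooth_vars <- c("mean_word_length", "mean_log_word_freq", metrics)
  const <- smooth_vars[vapply(smooth_vars,
                              function(v) stats::var(dat[[v]]) == 0,
                              logical(1))]
  if (length(const) > 0L) {
    stop("constant predictor(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }
  terms <- sprintf("s(%s, k = %d)", smooth_vars, k)
  if (nlevels(dat$language) > 1L) terms <- c(terms, "language")
  terms <- c(terms, 's(participant, bs = "re")')
  form <- stats::as.formula(paste(response, "~", paste(terms, collapse = " + ")))
  fit <- tryCatch(
    mgcv::gam(form, data = dat, method = "REML"),
    error = function(e) stop("GAMM fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (!fit$converged) stop("GAMM fit did not converge", call. = FALSE)
  structure(list(
    gam = fit, metrics = metrics, k = k, response = response,
    smooth_vars = smooth_vars, n = nrow(dat),
    aic = stats::AIC(fit), formula = form, data = dat
  ), class = "reading_gamm")
}

#' @export
print.reading_gamm <- function(x, ...) {
  cat("<reading_gamm>", deparse(x$formula), "\n")
  cat("  n =", x$n, " AIC =", format(x$aic), "\n")
  invisible(x)
}

#' Tidy the terms of a fitted reading model
#'
#' Broom-style per-term summary: smooth terms with effective degrees of
#' freedom, F statistic and p-value, and parametric terms with their
#' coefficients. `significant` applies the p < .01 convention.
#'
#' @param x A `reading_gamm`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `edf`, `statistic`,
#'   `p.value`, `significant`.
#' @export
tidy.reading_gamm <- function(x, ...) {
  s <- summary(x$gam)
  st <- s$s.table
  smooth <- tibble::tibble(
    term = rownames(st), type = "smooth", edf = st[, "edf"],
    statistic = st[, "F"], p.value = st[, "p-value"]
  )
  pt <- s$p.table
  param <- tibble::tibble(
    term = rownames(pt), type = "parametric", edf = NA_real_,
    statistic = pt[, "t value"], p.value = pt[, "Pr(>|t|)"]
  )
  out <- dplyr::bind_rows(smooth, param)
  out$significant <- out$p.value < 0.01
  out
}

#' One-row summary of a fitted reading model
#'
#' @param x A `reading_gamm`.
#' @param ... Unused.
#' @return Tibble with `AIC`, `n`, `r.squared`, `deviance.explained`,
#'   `reml`.
#' @export
glance.reading_gamm <- function(x, ...) {
  s <- summary(x$gam)
  tibble::tibble(
    AIC = x$aic, n = x$n, r.squared = s$r.sq,
    deviance.explained = s$dev.expl,
    reml = as.numeric(x$gam$gcv.ubre)
  )
}

#' Generic tidy/glance (broom-compatible)
#'
#' Thin generics so `tidy()`/`glance()` work without attaching broom.
#' @param x Object to summarise.
#' @param ... Method arguments.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Partial-effect curves of the fitted smooths
#'
#' Evaluates each (non-random-effect) smooth term's centered contribution
#' to log reading speed on an equally spaced grid over the observed range
#' of its predictor, with pointwise confidence bounds.
#'
#' @param fit A `reading_gamm`.
#' @param terms Predictor names (default: all smooth predictors).
#' @param n_grid Grid points per term (default 100).
#' @param level Confidence level for the pointwise interval (default
#'   0.99, matching the p < .01 significance convention).
#' @return Tibble with columns `term`, `x`, `fit`, `se`, `lower`,
#'   `upper`.
#' @export
partial_effects <- function(fit, terms = NULL, n_grid = 100, level = 0.99) {
  stopifnot(inherits(fit, "reading_gamm"))
  terms <- terms %||% fit$smooth_vars
  unknown <- setdiff(terms, fit$smooth_vars)
  if (length(unknown) > 0L) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  dat <- fit$data
  purrr::map_dfr(terms, function(v) {
    grid <- data.frame(x = seq(min(dat[[v]]), max(dat[[v]]),
                               length.out = n_grid))
    nd <- dat[rep(1L, n_grid), , drop = FALSE]
    nd[[v]] <- grid$x
    sm_label <- sprintf("s(%s)", v)
    pr <- stats::predict(fit$gam, newdata = nd, type = "terms",
                         terms = sm_label, se.fit = TRUE)
    eff <- as.numeric(pr$fit[, sm_label])
    se <- as.numeric(pr$se.fit[, sm_label])
    tibble::tibble(term = v, x = grid$x, fit = eff, se = se,
                   lower = eff - z * se, upper = eff + z * se)
  })
}

#' Average slope of a fitted smooth
#'
#' Least-squares slope of the partial-effect curve over its grid — a
#' one-number summary of a smooth's direction, used to check that fitted
#' effects carry the generating sign (and, for a linear truth, recover
#' the generating coefficient).
#'
#' @param fit A `reading_gamm`.
#' @param term Predictor name of the smooth.
#' @param n_grid Grid resolution.
#' @return Slope (response units per predictor unit).
#' @export
partial_effect_slope <- function(fit, term, n_grid = 100) {
  pe <- partial_effects(fit, terms = term, n_grid = n_grid)
  unname(stats::coef(stats::lm(fit ~ x, data = pe))[2])
}

#' Export partial-effect curves as TSV files
#'
#' Writes one TSV per term (`partial_effect_<term>.tsv`: columns `x`,
#' `fit`, `se`, `lower`, `upper`).
#'
#' @param fit A `reading_gamm`.
#' @param out_dir Output directory (created if needed).
#' @param terms Terms to export (default: all smooth predictors).
#' @param n_grid,level Passed to [partial_effects()].
#' @return Character vector of file paths, invisibly.
#' @export
export_partial_effects <- function(fit, out_dir, terms = NULL, n_grid = 100,
                                   level = 0.99) {
  pe <- partial_effects(fit, terms = terms, n_grid = n_grid, level = level)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_chr(unique(pe$term), function(v) {
    p <- file.path(out_dir, paste0("partial_effect_", v, ".tsv"))
    readr::write_tsv(pe[pe$term == v, c("x", "fit", "se", "lower", "upper")],
                     p, progress = FALSE)
    p
  })
  invisible(paths)
}

#' Compare base and full additive models by AIC
#'
#' Fits the base model (controls only) and the full model (controls plus
#' the given metrics) on exactly the same rows and reports
#' `delta_aic = AIC(full) - AIC(base)`. A negative value means the metric
#' improves the fit beyond the controls; the more negative, the stronger
#' the improvement.
#'
#' @param table Sentence table from [build_sentence_table()].
#' @param base_metrics Metric columns in the base model (usually none).
#' @param full_metrics Metric columns in the full model; must be a
#'   superset of `base_metrics`.
#' @param k Basis dimension passed to [fit_reading_gamm()].
#' @return A `sentread_comparison`: list with `delta_aic`, `base`,
#'   `full` (both `reading_gamm` objects), and `n`.
#' @export
compare_models <- function(table, base_metrics = character(),
                           full_metrics, k = 9) {
  if (!all(base_metrics %in% full_metrics)) {
    stop("full model terms must be a superset of the base model's",
         call. = FALSE)
  }
  cols <- unique(c("log_speed", "mean_word_length", "mean_log_word_freq",
                   "language", "participant", base_metrics, full_metrics))
  keep <- stats::complete.cases(as.data.frame(table[cols]))
  tab <- table[keep, , drop = FALSE]
  base <- fit_reading_gamm(tab, metrics = base_metrics, k = k)
  full <- fit_reading_gamm(tab, metrics = full_metrics, k = k)
  if (base$n != full$n) stop("base and full models fit different rows",
                             call. = FALSE)
  structure(list(
    delta_aic = full$aic - base$aic,
    base = base, full = full, n = base$n
  ), class = "sentread_comparison")
}

#' @export
print.sentread_comparison <- function(x, ...) {
  cat("<model comparison> n =", x$n, "\n")
  cat("  AIC base:", format(x$base$aic), " full:", format(x$full$aic), "\n")
  cat("  delta AIC (full - base):", format(x$delta_aic), "\n")
  invisible(x)
}

#' @export
glance.sentread_comparison <- function(x, ...) {
  tibble::tibble(delta_aic = x$delta_aic, aic_base = x$base$aic,
                 aic_full = x$full$aic, n = x$n)
}

#' @export
tidy.sentread_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$base), model = "base"),
    dplyr::mutate(tidy(x$full), model = "full")
  )
}

#' Rank correlation between two metric columns
#'
#' Spearman's rank correlation (average ranks on ties) between two
#' columns of a sentence table — used to check that surprisal and
#' relevance measure complementary, largely independent aspects of a
#' sentence.
#'
#' @param table Data frame holding both columns.
#' @param metric_a,metric_b Column names.
#' @return Correlation in [-1, 1].
#' @export
correlate_metrics <- function(table, metric_a, metric_b) {
  a <- table[[metric_a]]; b <- table[[metric_b]]
  stopifnot(length(a) >= 3L)
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  stats::cor(a, b, method = "spearman")
}

#' Plot partial-effect curves
#'
#' One panel per smooth term: centered partial effect on log reading
#' speed with its pointwise confidence band.
#'
#' @param object A `reading_gamm`.
#' @param ... Passed to [partial_effects()].
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.reading_gamm <- function(object, ...) {
  pe <- partial_effects(object, ...)
  ggplot2::ggplot(pe, ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "darkseagreen", alpha = 0.5) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "partial effect on log reading speed")
}

#' Plot a surprisal or relevance profile along a document
#'
#' @param profile Metric tibble with `doc_id`, `sentence_index`, `value`.
#' @return A ggplot object.
#' @export
plot_metric_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$sentence_index,
                                        y = .data$value)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(~doc_id, scales = "free_y") +
    ggplot2::labs(x = "sentence index", y = "metric value")
}
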