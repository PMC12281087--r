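#' Configuration for the synthetic reading study
#'
#' Bundles every knob of the synthetic multilingual reading study: corpus
#' shape, Zipfian vocabulary, and the generative model for sentence
#' reading speed. The generative link is log-linear:
#' \deqn{\log(speed) = \beta_0 + \beta_{len} len + \beta_{freq} freq +
#'   \beta_{surp} surp + \beta_{rel} rel + lang_l + b_p + \epsilon}
#' with participant random intercepts `b_p ~ N(0, sigma_p^2)`, per-language
#' baseline offsets `lang_l ~ N(0, sigma_lang^2)` drawn once per run, and
#' residual noise `epsilon ~ N(0, sigma_e^2)`. Default effect signs follow
#' the empirical pattern for naturalistic reading: longer words and higher
#' surprisal slow reading, frequent words and contextually relevant
#' sentences speed it up.
#'
#' Defaults give 3 languages x 20 participants x (12 documents x 10
#' sentences) = 7,200 participant-sentence records per run.
#'
#' @param n_languages,n_participants,n_documents,sentences_per_document
#'   Study shape (all >= 1); participants and documents are per language.
#' @param vocabulary_size Words per language vocabulary.
#' @param zipf_exponent Zipf rank exponent `s` (word `r` has weight
#'   `1/r^s`; 0 = uniform).
#' @param sentence_length_mean Poisson mean for words per sentence
#'   (floored at `sentence_length_min`).
#' @param sentence_length_min Minimum words per sentence.
#' @param beta Named numeric vector of generative coefficients:
#'   `intercept`, `len`, `freq`, `surp`, `rel` (log words/second scale).
#' @param sigma_p Participant random-intercept SD.
#' @param sigma_lang Language baseline-offset SD.
#' @param sigma_e Residual SD.
#' @param seed Integer seed fixing the full simulation stream.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_languages = 3L, n_participants = 20L,
                       n_documents = 12L, sentences_per_document = 10L,
                       vocabulary_size = 250L, zipf_exponent = 1,
                       sentence_length_mean = 12, sentence_length_min = 3L,
                       beta = c(intercept = 1.0, len = -0.05, freq = 0.05,
                                surp = -0.1, rel = 0.1),
                       sigma_p = 0.1, sigma_lang = 0.1, sigma_e = 0.2,
                       seed = 1L) {
  stopifnot(n_languages >= 1, n_participants >= 1, n_documents >= 1,
            sentences_per_document >= 1, vocabulary_size >= 1,
            sigma_p >= 0, sigma_lang >= 0, sigma_e >= 0,
            all(c("intercept", "len", "freq", "surp", "rel") %in% names(beta)))
  if (vocabulary_size < sentence_length_min) {
    stop("vocabulary_size smaller than the sentence length floor",
         call. = FALSE)
  }
  structure(list(
    n_languages = as.integer(n_languages),
    n_participants = as.integer(n_participants),
    n_documents = as.integer(n_documents),
    sentences_per_document = as.integer(sentences_per_document),
    vocabulary_size = as.integer(vocabulary_size),
    zipf_exponent = zipf_exponent,
    sentence_length_mean = sentence_length_mean,
    sentence_length_min = as.integer(sentence_length_min),
    beta = beta, sigma_p = sigma_p, sigma_lang = sigma_lang,
    sigma_e = sigma_e, seed = as.integer(seed)
  ), class = "sim_config")
}

# Random unique word forms; frequent ranks get shorter words on average,
# echoing the brevity of high-frequency vocabulary.
make_vocabulary <- function(n) {
  lens <- pmin(12L, pmax(1L, 1L + stats::rpois(n, 1 + 3 * log1p(seq_len(n)) /
                                                 log1p(n))))
  words <- vapply(lens, function(L) {
    paste(sample(letters, L, replace = TRUE), collapse = "")
  }, character(1))
  while (anyDuplicated(words)) {
    d <- which(duplicated(words))
    words[d] <- vapply(lens[d] + 1L, function(L) {
      paste(sample(letters, L, replace = TRUE), collapse = "")
    }, character(1))
  }
  words
}

#' Generate a synthetic multilingual corpus
#'
#' Draws, per language, a Zipfian vocabulary of random word forms and
#' builds documents of sentences whose lengths follow a floored Poisson.
#' The returned frequency table holds the generating Zipf counts (so
#' frequency lookups reflect the true sampling distribution, not an
#' empirical estimate). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `corpus` (corpus tibble; `doc_id` is
#'   `<language>_d<nn>`) and `freqs` (frequency table over all languages).
#' @export
simulate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  langs <- sprintf("l%d", seq_len(config$n_languages))
  zipf_w <- 1 / seq_len(config$vocabulary_size)^config$zipf_exponent
  vocabs <- stats::setNames(
    purrr::map(langs, ~ make_vocabulary(config$vocabulary_size)), langs)
  rows <- list()
  for (lang in langs) {
    vocab <- vocabs[[lang]]
    for (d in seq_len(config$n_documents)) {
      doc_id <- sprintf("%s_d%02d", lang, d)
      for (s in seq_len(config$sentences_per_document)) {
        len <- max(config$sentence_length_min,
                   stats::rpois(1, config$sentence_length_mean))
        words <- sample(vocab, len, replace = TRUE, prob = zipf_w)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          doc_id = doc_id, language = lang, sentence_index = s - 1L,
          text = paste0(paste(words, collapse = " "), "."),
          words = list(words)
        )
      }
    }
  }
  corpus <- dplyr::bind_rows(rows)
  # generating counts: Zipf weights scaled to integers, identical across
  # a language's documents
  counts <- round(zipf_w / sum(zipf_w) * 1e6)
  counts[counts < 1] <- 1
  freqs <- frequency_table(unlist(vocabs), rep(counts, config$n_languages))
  list(corpus = corpus, freqs = freqs)
}

#' Generate synthetic reading records with known ground truth
#'
#' Turns per-sentence predictors into participant-level reading records
#' under the log-linear generative model of [sim_config()]. Reading
#' speeds are drawn on the log scale; total fixation durations are then
#' back-computed as `word_count / speed * 1000` ms, so recomputing speed
#' from the records recovers the generated value exactly.
#'
#' @param corpus Corpus tibble from [simulate_corpus()].
#' @param surprisal Surprisal profile tibble (one row per sentence).
#' @param relevance Relevance profile tibble (one row per sentence).
#' @param freqs Frequency table for the control predictor.
#' @param config The same [sim_config()] used for the corpus.
#' @return List with `records` (reading-record tibble, one row per
#'   participant x sentence) and `truth` (generative coefficients,
#'   participant intercepts, language offsets, and the per-sentence
#'   predictor table).
#' @export
simulate_reading_records <- function(corpus, surprisal, relevance, freqs,
                                     config) {
  stopifnot(inherits(config, "sim_config"))
  preds <- sentence_predictors(corpus, freqs)
  preds <- dplyr::inner_join(
    preds,
    dplyr::select(surprisal, "doc_id", "sentence_index", surp = "value"),
    by = c("doc_id", "sentence_index")
  )
  preds <- dplyr::inner_join(
    preds,
    dplyr::select(relevance, "doc_id", "sentence_index", rel = "value"),
    by = c("doc_id", "sentence_index")
  )
  if (nrow(preds) < nrow(corpus)) {
    stop("metrics do not cover every sentence in the corpus", call. = FALSE)
  }
  if (!all(is.finite(preds$surp)) || !all(is.finite(preds$rel))) {
    stop("non-finite metric value in simulation input", call. = FALSE)
  }
  # separate sub-stream so corpus and records are independently reproducible
  set.seed(config$seed + 1000003L)
  langs <- sprintf("l%d", seq_len(config$n_languages))
  lang_off <- stats::setNames(stats::rnorm(length(langs), 0, config$sigma_lang),
                              langs)
  participants <- tidyr::expand_grid(
    language = langs, p = seq_len(config$n_participants))
  participants$participant <- sprintf("%s_p%02d", participants$language,
                                      participants$p)
  participants$b <- stats::rnorm(nrow(participants), 0, config$sigma_p)
  b <- config$beta
  tab <- dplyr::inner_join(
    dplyr::select(participants, "language", "participant", "b"),
    preds, by = "language", relationship = "many-to-many")
  eta <- b[["intercept"]] + b[["len"]] * tab$mean_word_length +
    b[["freq"]] * tab$mean_log_word_freq + b[["surp"]] * tab$surp +
    b[["rel"]] * tab$rel + unname(lang_off[tab$language]) + tab$b
  eps <- stats::rnorm(nrow(tab), 0, config$sigma_e)
  speed <- exp(eta + eps)
  records <- tibble::tibble(
    language = tab$language, participant = tab$participant,
    doc_id = tab$doc_id, sentence_index = tab$sentence_index,
    word_count = tab$word_count,
    total_fixation_duration_ms = tab$word_count / speed * 1000
  )
  truth <- list(
    beta = as.list(b), sigma_p = config$sigma_p, sigma_e = config$sigma_e,
    sigma_lang = config$sigma_lang,
    language_offsets = as.list(lang_off),
    participant_intercepts = stats::setNames(as.list(participants$b),
                                             participants$participant),
    linear_predictor = eta, seed = config$seed,
    predictors = preds
  )
  list(records = records, truth = truth)
}

#' Per-sentence control predictors of a corpus
#'
#' Mean word length and mean natural-log relative word frequency for every
#' sentence, plus the word count.
#'
#' @param corpus Corpus tibble.
#' @param freqs Frequency table.
#' @return Tibble keyed by `doc_id`, `sentence_index` with columns
#'   `language`, `word_count`, `mean_word_length`, `mean_log_word_freq`.
#' @export
sentence_predictors <- function(corpus, freqs) {
  tibble::tibble(
    doc_id = corpus$doc_id,
    language = corpus$language,
    sentence_index = corpus$sentence_index,
    word_count = lengths(corpus$words),
    mean_word_length = purrr::map_dbl(corpus$words, mean_word_length),
    mean_log_word_freq = purrr::map_dbl(corpus$words, mean_log_word_frequency,
                                        freqs = freqs)
  )
}

#' Simulate a full synthetic reading study
#'
#' Convenience wrapper chaining corpus generation, metric computation with
#' the bundled toy backends (bigram negative log-likelihood for surprisal,
#' bag-of-words embeddings for relevance), and reading-record generation.
#'
#' @param config A [sim_config()].
#' @param surprisal_method Method passed to [surprisal_profile()].
#' @param bigram_alpha Laplace smoothing for the corpus-trained bigram
#'   backend.
#' @return List with `corpus`, `freqs`, `surprisal`, `relevance`,
#'   `records`, `truth`.
#' @export
simulate_study <- function(config = sim_config(), surprisal_method = "nll",
                           bigram_alpha = 0.1) {
  sim <- simulate_corpus(config)
  backend <- backend_bigram_from_corpus(sim$corpus, alpha = bigram_alpha)
  surp <- surprisal_profile(sim$corpus, backend, method = surprisal_method)
  embedder <- backend_bow(unique(unlist(sim$corpus$words)))
  rel <- relevance_profile(sim$corpus, embedder)
  rr <- simulate_reading_records(sim$corpus, surp, rel, sim$freqs, config)
  list(corpus = sim$corpus, freqs = sim$freqs, surprisal = surp,
       relevance = rel, records = rr$records, truth = rr$truth)
}
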