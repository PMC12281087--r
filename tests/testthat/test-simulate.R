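test_that("corpus generation is deterministic and has the configured shape", {
  cfg <- sim_config(n_languages = 2, n_documents = 2,
                    sentences_per_document = 10, vocabulary_size = 50,
                    seed = 1)
  s1 <- simulate_corpus(cfg)
  s2 <- simulate_corpus(cfg)
  expect_identical(s1, s2)
  # 2 languages x 2 documents x 10 sentences
  expect_equal(nrow(s1$corpus), 40L)
  expect_equal(length(unique(s1$corpus$doc_id)), 4L)
  expect_true(all(lengths(s1$corpus$words) >= cfg$sentence_length_min))
  # frequency table covers every generated word
  expect_true(all(tolower(unlist(s1$corpus$words)) %in% s1$freqs$word))
})

test_that("zipf exponent 0 gives approximately uniform empirical frequencies", {
  cfg <- sim_config(n_languages = 1, n_documents = 30,
                    sentences_per_document = 20, vocabulary_size = 20,
                    zipf_exponent = 0, seed = 2)
  corp <- simulate_corpus(cfg)$corpus
  tokens <- unlist(corp$words)
  obs <- table(factor(tokens, levels = unique(tokens)))
  chisq <- sum((obs - mean(obs))^2 / mean(obs))
  # df = 19; far below an extreme-tail bound
  expect_lt(chisq, qchisq(1 - 1e-6, df = length(obs) - 1))
  # and a steep exponent concentrates mass on top ranks
  cfg2 <- sim_config(n_languages = 1, n_documents = 30,
                     sentences_per_document = 20, vocabulary_size = 20,
                     zipf_exponent = 1.5, seed = 2)
  corp2 <- simulate_corpus(cfg2)$corpus
  top_share <- function(tok) max(table(tok)) / length(tok)
  expect_gt(top_share(unlist(corp2$words)), top_share(tokens) * 3)
})

test_that("degenerate generative settings give closed-form reading speeds", {
  cfg <- sim_config(n_languages = 1, n_participants = 2, n_documents = 1,
                    sentences_per_document = 5,
                    beta = c(intercept = log(2), len = 0, freq = 0,
                             surp = 0, rel = 0),
                    sigma_p = 0, sigma_lang = 0, sigma_e = 0, seed = 3)
  st <- simulate_study(cfg)
  speed <- compute_reading_speed(st$records$word_count,
                                 st$records$total_fixation_duration_ms)
  expect_equal(speed, rep(2.0, nrow(st$records)))
})

test_that("a pure surprisal effect exponentiates into the speed ratio", {
  cfg <- sim_config(n_languages = 1, n_participants = 1, n_documents = 1,
                    sentences_per_document = 2,
                    beta = c(intercept = 0, len = 0, freq = 0,
                             surp = -0.1, rel = 0),
                    sigma_p = 0, sigma_lang = 0, sigma_e = 0, seed = 4)
  sim <- simulate_corpus(cfg)
  # metric tables with surprisal 0 and 10 for the two sentences
  surp <- tibble::tibble(doc_id = sim$corpus$doc_id,
                         sentence_index = sim$corpus$sentence_index,
                         value = c(0, 10))
  rel <- tibble::tibble(doc_id = sim$corpus$doc_id,
                        sentence_index = sim$corpus$sentence_index,
                        value = c(0, 0))
  rr <- simulate_reading_records(sim$corpus, surp, rel, sim$freqs, cfg)
  speed <- compute_reading_speed(rr$records$word_count,
                                 rr$records$total_fixation_duration_ms)
  expect_equal(speed[1] / speed[2], exp(1), tolerance = 1e-9)
})

test_that("record generation is deterministic and validates its inputs", {
  cfg <- sim_config(n_languages = 1, n_participants = 3, n_documents = 2,
                    sentences_per_document = 4, seed = 5)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$records, st2$records)
  expect_identical(st1$truth$participant_intercepts,
                   st2$truth$participant_intercepts)
  # metrics must cover every sentence
  expect_error(
    simulate_reading_records(st1$corpus, st1$surprisal[-1, ], st1$relevance,
                             st1$freqs, cfg),
    "cover every sentence"
  )
  bad <- st1$surprisal
  bad$value[1] <- NaN
  expect_error(
    simulate_reading_records(st1$corpus, bad, st1$relevance, st1$freqs, cfg),
    "non-finite"
  )
})

test_that("simulated log speeds match the generative moments at scale", {
  cfg <- sim_config(n_languages = 2, n_participants = 25, n_documents = 10,
                    sentences_per_document = 10, sigma_p = 0.1,
                    sigma_lang = 0, sigma_e = 0.2, seed = 6)
  st <- simulate_study(cfg) # 2 x 25 x 100 = 5,000 records
  expect_gte(nrow(st$records), 5000)
  log_speed <- log(compute_reading_speed(
    st$records$word_count, st$records$total_fixation_duration_ms))
  # centered on the linear predictor: residual mean ~ 0, sd ~ sqrt(sp^2+se^2)
  resid <- log_speed - st$truth$linear_predictor
  expect_lt(abs(mean(resid)), 3 * cfg$sigma_e / sqrt(nrow(st$records)) * 2)
  expect_equal(sd(resid), cfg$sigma_e, tolerance = 0.05)
})

test_that("generated tables survive the reader round-trip unchanged", {
  cfg <- sim_config(n_languages = 1, n_participants = 2, n_documents = 2,
                    sentences_per_document = 3, seed = 7)
  st <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reading_table(st$records, path)
  back <- read_reading_table(path)
  expect_equal(nrow(back), nrow(st$records))
  expect_equal(back$total_fixation_duration_ms,
               st$records$total_fixation_duration_ms)
  cpath <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(st$corpus, cpath)
  expect_equal(read_corpus(cpath)$words, st$corpus$words)
})
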