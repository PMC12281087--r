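# Shared fixtures: tiny corpora and independent oracles.
# Oracles recompute quantities from first principles (explicit products,
# all-pairs cosines) so they never share code with the implementation.

make_corpus <- function(sent_words, doc_id = "d1", language = "en") {
  tibble::tibble(
    doc_id = doc_id, language = language,
    sentence_index = seq_along(sent_words) - 1L,
    text = purrr::map_chr(sent_words, paste, collapse = " "),
    words = sent_words
  )
}

# Laplace bigram conditional computed directly from the raw count table.
oracle_bigram_prob <- function(counts, vocab, alpha, prev, w) {
  V <- length(vocab)
  if (is.na(prev)) return(1 / V)
  tot <- sum(counts$count[counts$prev == prev])
  if (tot == 0) return(1 / V)
  c_pair <- sum(counts$count[counts$prev == prev & counts$word == w])
  (c_pair + alpha) / (tot + alpha * V)
}

# Joint sentence probability by explicit multiplication of conditionals,
# then -log; the brute-force chain-rule oracle.
oracle_bigram_cr <- function(counts, vocab, alpha, context, target) {
  seq_tokens <- c(context, target)
  start <- length(context) + 1L
  p <- 1
  for (k in start:length(seq_tokens)) {
    prev <- if (k == 1L) NA_character_ else seq_tokens[k - 1L]
    p <- p * oracle_bigram_prob(counts, vocab, alpha, prev, seq_tokens[k])
  }
  -log(p)
}

# All-pairs-cosine relevance oracle for short documents: embeds every
# sentence as term frequencies, computes the full cosine matrix directly,
# then assembles each target's weighted sum from scratch.
oracle_relevance <- function(sent_words, vocab, weights) {
  n <- length(sent_words)
  emb <- sapply(sent_words, function(w) {
    as.numeric(table(factor(w, levels = vocab)))
  })
  cosmat <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cosmat[i, j] <- sum(emb[, i] * emb[, j]) /
      (sqrt(sum(emb[, i]^2)) * sqrt(sum(emb[, j]^2)))
  }
  vapply(seq_len(n), function(t) {
    val <- 0
    if (t - 1 >= 1) val <- val + weights[["c1"]] * cosmat[t, t - 1]
    if (t - 2 >= 1) val <- val + weights[["c2"]] * cosmat[t, t - 2]
    if (t + 1 <= n) val <- val + weights[["n1"]] * cosmat[t, t + 1]
    val
  }, numeric(1))
}

random_sentences <- function(n_sent, vocab, len_range = 2:6) {
  lapply(seq_len(n_sent), function(i) {
    sample(vocab, sample(len_range, 1), replace = TRUE)
  })
}

# Small simulated study for evaluation tests (a couple of seconds to fit).
small_study <- function(seed = 5, beta = c(intercept = 1, len = -0.05,
                                           freq = 0.05, surp = -0.1,
                                           rel = 0.1), ...) {
  cfg <- sim_config(n_languages = 2, n_participants = 5, n_documents = 3,
                    sentences_per_document = 6, beta = beta, seed = seed, ...)
  st <- simulate_study(cfg)
  st$table <- build_sentence_table(st$records, st$corpus, st$freqs,
                                   surprisal = st$surprisal,
                                   relevance = st$relevance)
  st
}
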