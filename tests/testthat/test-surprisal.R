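test_that("uniform and certainty limits of the surprisal estimators", {
  b4 <- backend_uniform(c("a", "b", "c", "d"))
  s3 <- c("a", "b", "a")
  expect_equal(chain_rule_surprisal(b4, character(), s3)$value, 3 * log(4))
  expect_equal(nll_surprisal(b4, character(), s3)$value, log(4))
  expect_equal(nll_surprisal(b4, c("c", "d"), c("a", "b", "c", "d", "a"))$value,
               log(4)) # normalization removes length
  b1 <- backend_constant(1)
  expect_equal(chain_rule_surprisal(b1, "x", s3)$value, 0)
  expect_equal(nll_surprisal(b1, "x", s3)$value, 0)
  expect_error(chain_rule_surprisal(b4, "a", character()), "empty target")
})

test_that("chain-rule surprisal matches the brute-force product oracle", {
  set.seed(11)
  vocab <- letters[1:5]
  counts <- expand.grid(prev = vocab, word = vocab, stringsAsFactors = FALSE)
  counts$count <- sample(1:20, nrow(counts), replace = TRUE)
  counts <- counts[sample(nrow(counts), 18), ]
  alpha <- 0.5
  b <- backend_bigram(counts, vocabulary = vocab, alpha = alpha)
  for (i in 1:100) {
    ctx <- sample(vocab, sample(0:4, 1), replace = TRUE)
    target <- sample(vocab, sample(1:6, 1), replace = TRUE)
    expect_equal(chain_rule_surprisal(b, ctx, target)$value,
                 oracle_bigram_cr(counts, vocab, alpha, ctx, target),
                 tolerance = 1e-9)
  }
})

test_that("chain rule decomposes over concatenation and NLL = CR/n on causal backends", {
  set.seed(12)
  vocab <- letters[1:5]
  counts <- expand.grid(prev = vocab, word = vocab, stringsAsFactors = FALSE)
  counts$count <- sample(1:9, nrow(counts), replace = TRUE)
  b <- backend_bigram(counts, alpha = 0.1)
  for (i in 1:25) {
    ctx <- sample(vocab, 3, replace = TRUE)
    s1 <- sample(vocab, sample(1:5, 1), replace = TRUE)
    s2 <- sample(vocab, sample(1:5, 1), replace = TRUE)
    joint <- chain_rule_surprisal(b, ctx, c(s1, s2))$value
    split <- chain_rule_surprisal(b, ctx, s1)$value +
      chain_rule_surprisal(b, c(ctx, s1), s2)$value
    expect_equal(joint, split, tolerance = 1e-9)
    cr <- chain_rule_surprisal(b, ctx, s1)
    expect_equal(nll_surprisal(b, ctx, s1)$value, cr$value / cr$n_tokens)
  }
})

test_that("NSP surprisal is -log next-sentence probability with finite boundary", {
  expect_equal(nsp_surprisal(backend_constant(0.5), "a", "b")$value, log(2))
  bj <- backend_nsp_jaccard(eps = 0.01)
  s <- c("the", "cat")
  expect_equal(nsp_surprisal(bj, s, s)$value, 0)
  expect_equal(nsp_surprisal(bj, s, c("dog", "ran"))$value, -log(0.01))
  # document-initial: empty previous sentence still yields a finite value
  v <- nsp_surprisal(bj, character(), s)$value
  expect_true(is.finite(v) && v >= 0)
  expect_error(nsp_surprisal(backend_uniform("a"), "a", "b"), "nsp")
})

test_that("document profiles have one row per sentence with sliding context", {
  b2 <- backend_uniform(c("a", "b"))
  corp1 <- make_corpus(list(c("a", "b", "a", "b", "a")))
  expect_equal(surprisal_profile(corp1, b2, "cr")$value, 5 * log(2))

  corp <- make_corpus(random_sentences(7, c("a", "b")), doc_id = "dA")
  prof <- surprisal_profile(corp, b2, "nll")
  expect_equal(nrow(prof), 7L)
  expect_equal(prof$sentence_index, 0:6)
  expect_true(all(prof$value >= 0 & is.finite(prof$value)))
  expect_equal(prof$n_tokens, lengths(corp$words))

  # profile respects the context window: with bigram scoring, context only
  # matters through preceding tokens, so an identical corpus gives an
  # identical (deterministic) profile
  set.seed(3)
  counts <- data.frame(prev = c("a", "a", "b"), word = c("a", "b", "a"),
                       count = c(2, 6, 4))
  bb <- backend_bigram(counts, alpha = 0.2)
  p1 <- surprisal_profile(corp, bb, "cr", context_sentences = 2)
  p2 <- surprisal_profile(corp, bb, "cr", context_sentences = 2)
  expect_identical(p1, p2)

  # NSP profile over a document: first sentence scored against empty context
  pn <- surprisal_profile(corp, backend_nsp_jaccard(), "nsp")
  expect_equal(nrow(pn), 7L)
  expect_true(all(is.finite(pn$value)))
})

test_that("context conditioning changes CR scores but never their sign", {
  counts <- data.frame(prev = c("a", "a", "b"), word = c("a", "b", "a"),
                       count = c(1, 9, 5))
  b <- backend_bigram(counts, alpha = 0.1)
  # same target, different context token: p(a|a) != p(a|b)
  v_a <- chain_rule_surprisal(b, "a", c("a", "b"))$value
  v_b <- chain_rule_surprisal(b, "b", c("a", "b"))$value
  expect_false(isTRUE(all.equal(v_a, v_b)))
  expect_true(v_a >= 0 && v_b >= 0)
})

test_that("raising every conditional probability weakly decreases surprisal", {
  # parameterized uniform backends: larger vocabulary = lower per-token p
  sizes <- c(2, 4, 8, 16)
  vals <- vapply(sizes, function(V) {
    chain_rule_surprisal(backend_uniform(sprintf("w%d", 1:V)),
                         character(), c("w1", "w2"))$value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # and constant backends with increasing p
  ps <- c(0.1, 0.3, 0.6, 1)
  vals <- vapply(ps, function(p) {
    chain_rule_surprisal(backend_constant(p), character(), c("x", "y"))$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0) && vals[4] == 0)
})

test_that("bits conversion divides nat values by log(2)", {
  b <- backend_uniform(c("a", "b", "c", "d"))
  corp <- make_corpus(list(c("a", "b")))
  expect_equal(surprisal_profile(corp, b, "cr", log_base = "bits")$value,
               surprisal_profile(corp, b, "cr")$value / log(2))
  expect_equal(surprisal_profile(corp, b, "cr", log_base = "bits")$value, 4)
})
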