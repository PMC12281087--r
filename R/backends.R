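#' Scoring-backend contract
#'
#' A scoring backend supplies the probabilistic primitives every
#' sentence-level metric is built from: token conditional probabilities
#' (for surprisal), a next-sentence probability (for NSP surprisal), and
#' sentence embeddings (for semantic relevance). Real multilingual
#' language models (e.g. a masked or autoregressive transformer) can be
#' wrapped behind this same contract; the bundled backends are small,
#' deterministic and fully enumerable, so every downstream metric is
#' testable offline.
#'
#' A backend is a list with class `sentread_backend` carrying:
#' \describe{
#'   \item{id}{short identifier recorded in metric provenance}
#'   \item{capabilities}{character subset of `causal_scoring`,
#'     `masked_scoring`, `nsp`, `embedding`}
#'   \item{vocabulary}{finite token set (toy backends)}
#'   \item{max_context_tokens}{context limit; older tokens are
#'     left-truncated beyond it}
#' }
#'
#' @param backend A backend object.
#' @param capability Capability flag to query.
#' @name scoring-backend
NULL

new_backend <- function(id, class, capabilities, vocabulary = character(),
                        max_context_tokens = 512L, ...) {
  structure(
    list(id = id, capabilities = capabilities, vocabulary = vocabulary,
         max_context_tokens = as.integer(max_context_tokens), ...),
    class = c(class, "sentread_backend")
  )
}

#' @rdname scoring-backend
#' @return `backend_supports()`: logical scalar.
#' @export
backend_supports <- function(backend, capability) {
  capability %in% backend$capabilities
}

#' @export
print.sentread_backend <- function(x, ...) {
  cat("<sentread backend:", x$id, "| capabilities:",
      paste(x$capabilities, collapse = ", "), ">\n")
  invisible(x)
}

#' Uniform toy backend
#'
#' Assigns every token probability `1/|V|` regardless of context. The
#' maximum-entropy reference point: chain-rule surprisal of an n-token
#' sentence is exactly `n * log(|V|)` nats.
#'
#' @param vocabulary Character vector of tokens (the finite vocabulary).
#' @param max_context_tokens Context limit.
#' @return A scoring backend with causal scoring and bag-of-words
#'   embedding.
#' @export
backend_uniform <- function(vocabulary, max_context_tokens = 512L) {
  vocabulary <- unique(as.character(vocabulary))
  stopifnot(length(vocabulary) >= 1L)
  new_backend("uniform", "sentread_backend_uniform",
              capabilities = c("causal_scoring", "embedding"),
              vocabulary = vocabulary,
              max_context_tokens = max_context_tokens)
}

#' Constant-probability stub backend
#'
#' Returns a fixed probability `p` for every token and every next-sentence
#' query. With `p = 1` all surprisals are exactly 0 (the certainty limit);
#' with `p = 0.5` NSP surprisal is `log 2`. Deliberately unnormalised — a
#' stub for exercising metric arithmetic, not a probability model.
#'
#' @param p Constant probability in (0, 1].
#' @return A scoring backend supporting causal scoring and NSP.
#' @export
backend_constant <- function(p = 1) {
  stopifnot(p > 0, p <= 1)
  new_backend(paste0("constant:", format(p)), "sentread_backend_constant",
              capabilities = c("causal_scoring", "nsp"), p = p)
}

#' Bigram toy backend
#'
#' Conditional token probabilities estimated from a bigram count table,
#' with optional Laplace smoothing:
#' `p(w | prev) = (c(prev, w) + alpha) / (c(prev, .) + alpha * |V|)`.
#' A previous token with no outgoing counts (including the empty context)
#' falls back to the uniform distribution over the vocabulary. With
#' `alpha = 0` the estimates are maximum-likelihood and unseen transitions
#' from a seen token have probability zero; use `alpha > 0` whenever the
#' scored text may contain transitions absent from the counts.
#'
#' @param counts Data frame with columns `prev`, `word`, `count`
#'   (positive counts of observed bigrams).
#' @param vocabulary Token set; defaults to all tokens in `counts`.
#' @param alpha Laplace smoothing constant (>= 0).
#' @param max_context_tokens Context limit.
#' @return A causal scoring backend.
#' @examples
#' b <- backend_bigram(data.frame(prev = c("a", "a"), word = c("b", "c"),
#'                                count = c(3, 1)))
#' token_logprob(b, "a", "b") # log(0.75)
#' @export
backend_bigram <- function(counts, vocabulary = NULL, alpha = 0,
                           max_context_tokens = 512L) {
  stopifnot(all(c("prev", "word", "count") %in% names(counts)),
            all(counts$count > 0), alpha >= 0)
  counts <- dplyr::summarise(
    dplyr::group_by(counts, prev = as.character(.data$prev),
                    word = as.character(.data$word)),
    count = sum(.data$count), .groups = "drop"
  )
  vocabulary <- unique(as.character(
    vocabulary %||% c(counts$prev, counts$word)
  ))
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$prev),
                             total = sum(.data$count), .groups = "drop")
  new_backend("bigram", "sentread_backend_bigram",
              capabilities = c("causal_scoring", "embedding"),
              vocabulary = vocabulary, max_context_tokens = max_context_tokens,
              counts = counts, totals = totals, alpha = alpha)
}

#' Train a bigram backend from a corpus tibble
#'
#' Counts within-sentence transitions plus a transition from each
#' sentence-initial position's preceding token (the last word of the
#' previous sentence, when present).
#'
#' @param corpus Corpus tibble (see [segment_document()]).
#' @param alpha Laplace smoothing constant passed to [backend_bigram()].
#' @return A bigram scoring backend.
#' @export
backend_bigram_from_corpus <- function(corpus, alpha = 0.1) {
  toks <- dplyr::group_split(corpus, .data$doc_id)
  pairs <- purrr::map(toks, function(d) {
    w <- unlist(d$words[order(d$sentence_index)])
    if (length(w) < 2L) return(NULL)
    tibble::tibble(prev = w[-length(w)], word = w[-1L])
  })
  pairs <- dplyr::bind_rows(pairs)
  counts <- dplyr::summarise(dplyr::group_by(pairs, .data$prev, .data$word),
                             count = dplyr::n(), .groups = "drop")
  backend_bigram(counts, vocabulary = unique(unlist(corpus$words)),
                 alpha = alpha)
}

#' Bag-of-words embedding backend
#'
#' Embeds a sentence as its term-frequency vector over a fixed vocabulary
#' ordering. Order-invariant and deterministic.
#'
#' @param vocabulary Token set fixing the embedding dimension and order.
#' @return An embedding backend.
#' @export
backend_bow <- function(vocabulary) {
  vocabulary <- unique(as.character(vocabulary))
  stopifnot(length(vocabulary) >= 1L)
  new_backend("bow", "sentread_backend_bow",
              capabilities = "embedding", vocabulary = vocabulary)
}

#' Jaccard next-sentence toy backend
#'
#' Next-sentence probability as a deterministic monotone function of
#' bag-of-words overlap: `p = eps + (1 - eps) * jaccard(prev, next)`.
#' Bounded away from zero so NSP surprisal stays finite; identical
#' sentences give p = 1 (zero surprisal), disjoint sentences give p = eps.
#'
#' @param eps Lower endpoint of the probability mapping (default 0.01).
#' @return An NSP backend.
#' @export
backend_nsp_jaccard <- function(eps = 0.01) {
  stopifnot(eps > 0, eps < 1)
  new_backend("nsp-jaccard", "sentread_backend_nsp_jaccard",
              capabilities = "nsp", eps = eps)
}

#' Conditional log-probability of a token given its left context
#'
#' Returns `log p(target | context)` in nats (always <= 0). Context beyond
#' the backend's `max_context_tokens` is left-truncated (oldest tokens
#' dropped). Out-of-vocabulary handling is backend policy; the toy
#' backends fall back to uniform mass over their vocabulary.
#'
#' @param backend A scoring backend supporting causal scoring.
#' @param context Character vector of context tokens (possibly empty).
#' @param target Single target token.
#' @return Log-probability in nats.
#' @export
token_logprob <- function(backend, context, target) {
  if (!backend_supports(backend, "causal_scoring")) {
    stop("backend '", backend$id, "' does not support causal scoring",
         call. = FALSE)
  }
  stopifnot(length(target) == 1L)
  n <- length(context)
  limit <- backend$max_context_tokens
  if (n > limit) context <- context[(n - limit + 1L):n]
  UseMethod("token_logprob")
}

#' @export
token_logprob.sentread_backend_uniform <- function(backend, context, target) {
  -log(length(backend$vocabulary))
}

#' @export
token_logprob.sentread_backend_constant <- function(backend, context, target) {
  log(backend$p)
}

#' @export
token_logprob.sentread_backend_bigram <- function(backend, context, target) {
  V <- length(backend$vocabulary)
  prev <- if (length(context) > 0L) context[length(context)] else NA_character_
  tot <- if (is.na(prev)) NA_real_ else {
    i <- match(prev, backend$totals$prev)
    if (is.na(i)) NA_real_ else backend$totals$total[i]
  }
  if (is.na(tot)) return(-log(V)) # unseen or empty context: uniform
  j <- which(backend$counts$prev == prev & backend$counts$word == target)
  c_pair <- if (length(j) == 1L) backend$counts$count[j] else 0
  log((c_pair + backend$alpha) / (tot + backend$alpha * V))
}

#' Next-sentence probability
#'
#' Probability in (0, 1] that `next_words` follows `prev_words`, from a
#' backend with the `nsp` capability. An empty previous sentence (the
#' document-initial boundary) is allowed.
#'
#' @param backend An NSP-capable scoring backend.
#' @param prev_words Word tokens of the preceding sentence (may be empty).
#' @param next_words Word tokens of the candidate next sentence.
#' @return Probability in (0, 1].
#' @export
next_sentence_prob <- function(backend, prev_words, next_words) {
  if (!backend_supports(backend, "nsp")) {
    stop("nsp unsupported by backend '", backend$id, "'", call. = FALSE)
  }
  UseMethod("next_sentence_prob")
}

#' @export
next_sentence_prob.sentread_backend_constant <- function(backend, prev_words,
                                                         next_words) {
  backend$p
}

#' @export
next_sentence_prob.sentread_backend_nsp_jaccard <- function(backend,
                                                            prev_words,
                                                            next_words) {
  a <- unique(tolower(prev_words))
  b <- unique(tolower(next_words))
  u <- length(union(a, b))
  jac <- if (u == 0L) 0 else length(intersect(a, b)) / u
  backend$eps + (1 - backend$eps) * jac
}

#' Embed a sentence
#'
#' Deterministic fixed-dimension embedding of a sentence's word tokens.
#' The toy embedders are bag-of-words term-frequency vectors over the
#' backend vocabulary; out-of-vocabulary words are dropped.
#'
#' @param backend An embedding-capable backend.
#' @param words Word tokens of the sentence (non-empty).
#' @return Numeric vector of fixed dimension.
#' @export
embed_sentence <- function(backend, words) {
  if (!backend_supports(backend, "embedding")) {
    stop("embedding unsupported by backend '", backend$id, "'", call. = FALSE)
  }
  if (length(words) == 0L) stop("cannot embed an empty sentence", call. = FALSE)
  UseMethod("embed_sentence")
}

#' @export
embed_sentence.sentread_backend <- function(backend, words) {
  v <- backend$vocabulary
  tab <- table(factor(words, levels = v))
  as.numeric(tab)
}

#' Construct a backend from a name
#'
#' Resolves the command-line backend spelling: `uniform:<V>` (uniform over
#' a V-token vocabulary), `bigram:<counts.tsv>` (TSV columns prev, word,
#' count), `bow:<V>` or `bow:<vocab.txt>`, `nsp-jaccard`, `constant:<p>`.
#'
#' @param name Backend specifier string.
#' @return A scoring backend.
#' @export
backend_from_name <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  arg <- if (length(parts) > 1L) parts[2] else NA_character_
  or_default <- function(x, d) if (is.na(x)) d else x
  synth_vocab <- function(n) sprintf("w%04d", seq_len(as.integer(n)))
  switch(kind,
    uniform = backend_uniform(synth_vocab(or_default(arg, 100))),
    bigram = {
      tbl <- readr::read_tsv(arg, col_types = "ccd", progress = FALSE)
      backend_bigram(tbl, alpha = 0.1)
    },
    bow = {
      if (!is.na(arg) && file.exists(arg)) {
        backend_bow(readLines(arg, warn = FALSE))
      } else {
        backend_bow(synth_vocab(or_default(arg, 100)))
      }
    },
    `nsp-jaccard` = backend_nsp_jaccard(),
    constant = backend_constant(as.numeric(or_default(arg, 1))),
    stop("unknown backend: ", name, call. = FALSE)
  )
}
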