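#' Chain-rule sentence surprisal
#'
#' The joint negative log-probability of a sentence given its discourse
#' context, factorised by the chain rule over the backend's tokens:
#' `-sum_k log p(t_k | context, t_1..t_{k-1})` in nats. Context tokens are
#' the concatenated words of the preceding sentences; they condition the
#' score but are not themselves scored.
#'
#' @param backend Causal scoring backend.
#' @param context_words Character vector of context tokens (may be empty
#'   at the document start).
#' @param target_words Word tokens of the target sentence (non-empty).
#' @return One-row tibble with `value` (nats, >= 0) and `n_tokens`.
#' @export
chain_rule_surprisal <- function(backend, context_words, target_words) {
  if (length(target_words) == 0L) stop("empty target sentence", call. = FALSE)
  lp <- vapply(seq_along(target_words), function(k) {
    token_logprob(backend,
                  c(context_words, target_words[seq_len(k - 1L)]),
                  target_words[k])
  }, numeric(1))
  tibble::tibble(value = -sum(lp), n_tokens = length(target_words))
}

#' Length-normalised negative log-likelihood surprisal
#'
#' Per-token negative log-likelihood of the sentence given its context:
#' the summed token surprisals divided by the token count. On a causal
#' backend this equals the chain-rule surprisal divided by `n_tokens`
#' exactly; a bidirectional backend would instead score each token with
#' the remaining sentence visible (pseudo-log-likelihood).
#'
#' @inheritParams chain_rule_surprisal
#' @return One-row tibble with `value` (nats/token, >= 0) and `n_tokens`.
#' @export
nll_surprisal <- function(backend, context_words, target_words) {
  cr <- chain_rule_surprisal(backend, context_words, target_words)
  tibble::tibble(value = cr$value / cr$n_tokens, n_tokens = cr$n_tokens)
}

#' Next-sentence-prediction surprisal
#'
#' `-log p(target follows prev)` from an NSP-capable backend, in nats.
#' The document-initial sentence uses an empty previous sentence.
#'
#' @param backend NSP-capable backend.
#' @param prev_words Word tokens of the preceding sentence (may be empty).
#' @param target_words Word tokens of the target sentence (non-empty).
#' @return One-row tibble with `value` (nats, >= 0) and `n_tokens`.
#' @export
nsp_surprisal <- function(backend, prev_words, target_words) {
  if (length(target_words) == 0L) stop("empty target sentence", call. = FALSE)
  p <- next_sentence_prob(backend, prev_words, target_words)
  tibble::tibble(value = -log(p), n_tokens = length(target_words))
}

#' Per-sentence surprisal profile of a corpus
#'
#' Computes one surprisal value per sentence with a sliding discourse
#' context of up to `context_sentences` immediately preceding sentences
#' (fewer near the document start; the first sentence has none). The NSP
#' method always operates on a two-sentence window (the single preceding
#' sentence).
#'
#' @param corpus Corpus tibble (see [segment_document()]).
#' @param backend Scoring backend with the capability the method needs.
#' @param method `"cr"` (joint chain-rule surprisal), `"nll"`
#'   (per-token negative log-likelihood), or `"nsp"`.
#' @param context_sentences Number of preceding sentences of context for
#'   CR/NLL (default 3).
#' @param log_base `"nats"` (natural log, default) or `"bits"`.
#' @return Tibble with columns `doc_id`, `sentence_index`, `method`,
#'   `backend`, `n_tokens`, `value`, one row per sentence in index order.
#' @examples
#' corp <- segment_document("A cat sat. A dog ran.", "d1", "en")
#' surprisal_profile(corp, backend_uniform(c("A", "cat", "sat", "dog", "ran")))
#' @export
surprisal_profile <- function(corpus, backend, method = c("cr", "nll", "nsp"),
                              context_sentences = 3L,
                              log_base = c("nats", "bits")) {
  method <- match.arg(method)
  log_base <- match.arg(log_base)
  stopifnot(context_sentences >= 0L)
  docs <- dplyr::group_split(dplyr::arrange(corpus, .data$doc_id,
                                            .data$sentence_index),
                             .data$doc_id)
  out <- purrr::map(docs, function(d) {
    purrr::map(seq_len(nrow(d)), function(i) {
      res <- tryCatch({
        if (method == "nsp") {
          prev <- if (i > 1L) d$words[[i - 1L]] else character()
          nsp_surprisal(backend, prev, d$words[[i]])
        } else {
          lo <- max(1L, i - context_sentences)
          ctx <- if (i > 1L) unlist(d$words[lo:(i - 1L)]) else character()
          if (method == "cr") {
            chain_rule_surprisal(backend, ctx, d$words[[i]])
          } else {
            nll_surprisal(backend, ctx, d$words[[i]])
          }
        }
      }, error = function(e) {
        stop("surprisal failed for ", d$doc_id[i], " sentence ",
             d$sentence_index[i], ": ", conditionMessage(e), call. = FALSE)
      })
      tibble::tibble(doc_id = d$doc_id[i], sentence_index = d$sentence_index[i],
                     method = method, backend = backend$id,
                     n_tokens = res$n_tokens, value = res$value)
    })
  })
  prof <- dplyr::bind_rows(out)
  if (log_base == "bits") prof$value <- prof$value / log(2)
  prof
}
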