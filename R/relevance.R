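#' Cosine similarity between two embeddings
#'
#' @param a,b Numeric vectors of equal dimension; neither may be the zero
#'   vector.
#' @return Cosine similarity in [-1, 1]; symmetric.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined cosine: zero vector", call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Default memory-aware relevance weights
#'
#' Fixed recency-decay weights on the contextual sentences of the
#' four-sentence window around a target: the immediately preceding
#' sentence (`c1`), the sentence before that (`c2`), and the following
#' sentence (`n1`). The `"recency"` preset (default) assigns the largest
#' weight to the nearest preceding sentence, mirroring working-memory
#' recency effects; `"as_published"` keeps the literal published vector
#' order `[1, 0.5, 0.3]` mapped to `(c2, c1, n1)`.
#'
#' @param preset `"recency"` or `"as_published"`.
#' @return Named numeric vector with entries `c1`, `c2`, `n1`.
#' @export
relevance_weights <- function(preset = c("recency", "as_published")) {
  preset <- match.arg(preset)
  switch(preset,
    recency = c(c1 = 1.0, c2 = 0.5, n1 = 0.3),
    as_published = c(c2 = 1.0, c1 = 0.5, n1 = 0.3)[c("c1", "c2", "n1")]
  )
}

check_weights <- function(weights) {
  stopifnot(all(c("c1", "c2", "n1") %in% names(weights)))
  w <- weights[c("c1", "c2", "n1")]
  if (any(w < 0) || all(w == 0)) {
    stop("weights must be >= 0 with at least one positive", call. = FALSE)
  }
  w
}

#' Memory-aware sentence relevance for one window
#'
#' The weighted sum of cosine similarities between the target sentence's
#' embedding and the embeddings of its windowed neighbours: up to two
#' preceding sentences (`c1` at distance 1, `c2` at distance 2) and one
#' following sentence (`n1`). The target's self-similarity is excluded.
#' Absent neighbours (document boundaries) contribute zero; weights are
#' never renormalised, so `|value| <= sum(weights present)`.
#'
#' @param target_words Word tokens of the target sentence.
#' @param c1_words,c2_words,n1_words Word tokens of the neighbours, or
#'   `NULL` when absent.
#' @param embedder Embedding-capable backend.
#' @param weights Named weights for `c1`, `c2`, `n1`
#'   (default [relevance_weights()]).
#' @return One-row tibble with `sim_c1`, `sim_c2`, `sim_n1` (NA when the
#'   neighbour is absent) and `value`.
#' @export
sentence_relevance <- function(target_words, c1_words = NULL, c2_words = NULL,
                               n1_words = NULL, embedder,
                               weights = relevance_weights()) {
  w <- check_weights(weights)
  et <- embed_sentence(embedder, target_words)
  sim_to <- function(words) {
    if (is.null(words) || length(words) == 0L) return(NA_real_)
    cosine_similarity(et, embed_sentence(embedder, words))
  }
  sims <- c(c1 = sim_to(c1_words), c2 = sim_to(c2_words), n1 = sim_to(n1_words))
  contrib <- ifelse(is.na(sims), 0, sims) * w
  tibble::tibble(sim_c1 = sims[["c1"]], sim_c2 = sims[["c2"]],
                 sim_n1 = sims[["n1"]], value = sum(contrib))
}

#' Per-sentence relevance profile of a corpus
#'
#' Slides the four-sentence window over each document and computes the
#' memory-aware relevance of every sentence. Windows truncate at document
#' boundaries: the first sentence has only a following neighbour, the
#' last only preceding ones; a single-sentence document scores 0.
#'
#' @param corpus Corpus tibble (see [segment_document()]).
#' @param embedder Embedding-capable backend.
#' @param weights Named weights for `c1`, `c2`, `n1`.
#' @return Tibble with columns `doc_id`, `sentence_index`, `sim_c1`,
#'   `sim_c2`, `sim_n1`, `value`, `backend`.
#' @examples
#' corp <- segment_document("A cat sat. A cat ran. A dog ran.", "d1", "en")
#' relevance_profile(corp, backend_bow(c("A", "cat", "sat", "ran", "dog")))
#' @export
relevance_profile <- function(corpus, embedder,
                              weights = relevance_weights()) {
  check_weights(weights)
  docs <- dplyr::group_split(dplyr::arrange(corpus, .data$doc_id,
                                            .data$sentence_index),
                             .data$doc_id)
  out <- purrr::map(docs, function(d) {
    n <- nrow(d)
    at <- function(i) if (i >= 1L && i <= n) d$words[[i]] else NULL
    purrr::map(seq_len(n), function(i) {
      res <- tryCatch(
        sentence_relevance(d$words[[i]], c1_words = at(i - 1L),
                           c2_words = at(i - 2L), n1_words = at(i + 1L),
                           embedder = embedder, weights = weights),
        error = function(e) {
          stop("relevance failed for ", d$doc_id[i], " sentence ",
               d$sentence_index[i], ": ", conditionMessage(e), call. = FALSE)
        }
      )
      dplyr::bind_cols(
        tibble::tibble(doc_id = d$doc_id[i],
                       sentence_index = d$sentence_index[i]),
        res, tibble::tibble(backend = embedder$id)
      )
    })
  })
  dplyr::bind_rows(out)
}
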