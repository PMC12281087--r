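#' Segment a document into sentences and word tokens
#'
#' Splits raw text into sentences on terminal punctuation (`.`, `!`, `?` and
#' their CJK equivalents) followed by whitespace or end-of-text, then
#' tokenizes each sentence on whitespace, stripping leading and trailing
#' punctuation from each word. Sentence indices are 0-based and contiguous.
#'
#' Languages without whitespace word boundaries (e.g. Chinese, Japanese)
#' must be supplied pre-tokenized, with words separated by spaces.
#'
#' @param text Document text (single UTF-8 string, non-empty).
#' @param doc_id Document identifier.
#' @param language Language code (BCP-47-style string, e.g. `"en"`).
#'
#' @return A tibble with one row per sentence and columns `doc_id`,
#'   `language`, `sentence_index` (0-based), `text` (the raw sentence) and
#'   `words` (list-column of word tokens).
#' @examples
#' segment_document("A cat. A dog!", "d1", "en")
#' @export
segment_document <- function(text, doc_id, language = "und") {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) {
    stop("empty document: '", doc_id, "'", call. = FALSE)
  }
  # Latin terminators split only before whitespace or end-of-text; CJK
  # terminators split unconditionally (CJK text carries no spaces).
  pieces <- stringr::str_split(text, "(?<=[.!?])(?:\\s+|$)|(?<=[。！？])\\s*")[[1]]
  pieces <- pieces[nzchar(trimws(pieces))]
  sents <- tibble::tibble(
    doc_id = as.character(doc_id),
    language = as.character(language),
    sentence_index = seq_along(pieces) - 1L,
    text = trimws(pieces),
    words = purrr::map(pieces, tokenize_words)
  )
  keep <- lengths(sents$words) > 0L
  sents <- sents[keep, , drop = FALSE]
  if (nrow(sents) == 0L) stop("empty document: '", doc_id, "'", call. = FALSE)
  sents$sentence_index <- seq_len(nrow(sents)) - 1L
  sents
}

#' @keywords internal
#' @noRd
tokenize_words <- function(sentence_text) {
  raw <- stringr::str_split(trimws(sentence_text), "\\s+")[[1]]
  w <- stringr::str_remove_all(raw, "^[[:punct:]。！？，、]+|[[:punct:]。！？，、]+$")
  w[nzchar(w)]
}

#' Read a corpus from plain text or JSONL
#'
#' Plain-text files become a single document whose `doc_id` is the file name
#' (without extension). JSONL files carry one document per line, as either
#' `{"doc_id":..., "language":..., "text":...}` (segmented here) or
#' `{"doc_id":..., "language":..., "sentences":[...]}` (pre-segmented; each
#' element is one sentence string).
#'
#' @param path File path (`.jsonl`/`.json` treated as JSONL; anything else
#'   as plain text).
#' @param language Language code used for plain-text input.
#' @return A corpus tibble (rows = sentences; see [segment_document()]).
#' @export
read_corpus <- function(path, language = "und") {
  stopifnot(file.exists(path))
  if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    docs <- purrr::map(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      lang <- rec$language %||% language
      if (!is.null(rec$sentences)) {
        txt <- paste(unlist(rec$sentences), collapse = " ")
        out <- segment_document(txt, rec$doc_id, lang)
      } else {
        out <- segment_document(rec$text, rec$doc_id, lang)
      }
      out
    })
    dplyr::bind_rows(docs)
  } else {
    txt <- paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    segment_document(txt, tools::file_path_sans_ext(basename(path)), language)
  }
}

#' Write a corpus tibble as JSONL
#'
#' One line per document with pre-segmented sentences, re-readable by
#' [read_corpus()].
#'
#' @param corpus Corpus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  docs <- dplyr::group_split(corpus, .data$doc_id)
  lines <- purrr::map_chr(docs, function(d) {
    jsonlite::toJSON(list(
      doc_id = d$doc_id[1], language = d$language[1],
      sentences = d$text
    ), auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Build a word-frequency table
#'
#' @param words Character vector of words (tokens).
#' @param counts Positive counts, recycled against `words`.
#' @return A frequency table: tibble with columns `word` (lower-cased) and
#'   `count`, plus attribute `total` (the normalizer).
#' @export
frequency_table <- function(words, counts) {
  stopifnot(length(words) >= 1L, all(counts > 0))
  tbl <- tibble::tibble(word = tolower(as.character(words)), count = as.numeric(counts))
  tbl <- dplyr::summarise(dplyr::group_by(tbl, .data$word), count = sum(.data$count), .groups = "drop")
  attr(tbl, "total") <- sum(tbl$count)
  class(tbl) <- c("sentread_freqs", class(tbl))
  tbl
}

#' Read a two-column word-frequency TSV (word, count)
#'
#' @param path TSV path with header columns `word` and `count`.
#' @return A frequency table (see [frequency_table()]).
#' @export
read_frequency_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    word = readr::col_character(), count = readr::col_double()
  ), progress = FALSE)
  if (!all(c("word", "count") %in% names(tbl))) {
    stop("frequency table must have columns 'word' and 'count'", call. = FALSE)
  }
  frequency_table(tbl$word, tbl$count)
}

#' Write a frequency table as TSV
#' @param freqs Frequency table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(freqs, path) {
  readr::write_tsv(freqs[, c("word", "count")], path, progress = FALSE)
  invisible(path)
}

#' Mean word length of a sentence
#'
#' Arithmetic mean of the character counts of a sentence's
#' (punctuation-stripped) word tokens — a standard control predictor for
#' sentence reading measures.
#'
#' @param words Character vector of word tokens (non-empty).
#' @return Mean characters per word.
#' @examples
#' mean_word_length(c("a", "bb", "ccc", "dddd")) # 2.5
#' @export
mean_word_length <- function(words) {
  if (length(words) == 0L) stop("sentence has no words", call. = FALSE)
  mean(nchar(words))
}

#' Mean natural-log relative word frequency of a sentence
#'
#' For each word, the natural log of `count / total` from the frequency
#' table (case-insensitive lookup); the sentence value is the mean over its
#' words. Out-of-vocabulary words default to a Laplace floor count of 1,
#' which keeps the log finite.
#'
#' @param words Character vector of word tokens (non-empty).
#' @param freqs Frequency table from [frequency_table()].
#' @param oov_count Count assigned to out-of-vocabulary words (default 1).
#' @return Mean log relative frequency (a negative number in practice).
#' @export
mean_log_word_frequency <- function(words, freqs, oov_count = 1) {
  if (length(words) == 0L) stop("sentence has no words", call. = FALSE)
  if (nrow(freqs) == 0L) stop("empty frequency table", call. = FALSE)
  total <- attr(freqs, "total")
  idx <- match(tolower(words), freqs$word)
  cnt <- freqs$count[idx]
  cnt[is.na(cnt)] <- oov_count
  mean(log(cnt / total))
}

#' Sentence reading speed in words per second
#'
#' Reading speed is the number of words in the sentence divided by the total
#' fixation duration on that sentence; durations are supplied in
#' milliseconds and converted to seconds here.
#'
#' @param word_count Words in the sentence (>= 1).
#' @param total_fixation_duration_ms Total fixation duration in ms (> 0).
#' @return Reading speed, words/second. Vectorised.
#' @examples
#' compute_reading_speed(10, 4000) # 2.5 words/s
#' @export
compute_reading_speed <- function(word_count, total_fixation_duration_ms) {
  if (any(word_count < 1)) stop("word_count must be >= 1", call. = FALSE)
  if (any(total_fixation_duration_ms <= 0)) {
    stop("total_fixation_duration_ms must be > 0", call. = FALSE)
  }
  word_count / (total_fixation_duration_ms / 1000)
}

reading_table_cols <- c(
  "language", "participant", "doc_id", "sentence_index",
  "word_count", "total_fixation_duration_ms"
)

#' Read a reading-behaviour table
#'
#' Expects a delimited file with header columns `language`, `participant`,
#' `doc_id`, `sentence_index` (0-based), `word_count`,
#' `total_fixation_duration_ms`. Rows violating the invariants
#' (`word_count >= 1`, duration > 0, non-missing fields) are rejected with
#' their line numbers.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return Tibble of valid reading records, one row per participant x
#'   sentence observation.
#' @export
read_reading_table <- function(path, delim = "\t") {
  tbl <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    language = readr::col_character(),
    participant = readr::col_character(),
    doc_id = readr::col_character(),
    sentence_index = readr::col_integer(),
    word_count = readr::col_integer(),
    total_fixation_duration_ms = readr::col_double()
  ), progress = FALSE)
  missing <- setdiff(reading_table_cols, names(tbl))
  if (length(missing) > 0L) {
    stop("reading table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tbl <- tbl[reading_table_cols]
  bad <- is.na(tbl$word_count) | is.na(tbl$total_fixation_duration_ms) |
    tbl$word_count < 1 | tbl$total_fixation_duration_ms <= 0 |
    is.na(tbl$sentence_index) | tbl$sentence_index < 0
  if (any(bad)) {
    # +1 for the header line
    warning("rejected ", sum(bad), " invalid row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "), call. = FALSE)
    tbl <- tbl[!bad, , drop = FALSE]
  }
  tbl
}

#' Write a reading-behaviour table as TSV
#' @param records Reading-record tibble (see [read_reading_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reading_table <- function(records, path) {
  readr::write_tsv(records[reading_table_cols], path, progress = FALSE)
  invisible(path)
}

#' Write a per-sentence metric table as TSV
#'
#' Column order is fixed: `doc_id`, `sentence_index`, then the metric
#' columns present in `metrics`.
#'
#' @param metrics Metric tibble keyed by `doc_id`, `sentence_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(metrics, path) {
  lead <- c("doc_id", "sentence_index")
  stopifnot(all(lead %in% names(metrics)))
  readr::write_tsv(metrics[c(lead, setdiff(names(metrics), lead))], path,
                   progress = FALSE)
  invisible(path)
}

#' Read a per-sentence metric table written by [write_metric_table()]
#' @param path TSV path.
#' @return Metric tibble.
#' @export
read_metric_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    doc_id = readr::col_character(),
    sentence_index = readr::col_integer(),
    .default = readr::col_guess()
  ), progress = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
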