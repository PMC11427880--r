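#' Flesch Reading Ease score
#'
#' Computes 206.835 - 1.015 * (words / sentences) - 84.6 * (syllables /
#' words) on a tokenized text. The score typically falls between 0 and
#' 100 (higher = easier to read) but is reported unclamped; extreme
#' texts legitimately fall outside that range.
#'
#' @param tokens An `hq_tokens` object with at least one token.
#' @return The readability score, or `NA_real_` (with a warning) for an
#'   empty text.
#' @examples
#' flesch_reading_ease(hq_tokenize("Go."))  # 206.835 - 1.015 - 84.6
#' @export
flesch_reading_ease <- function(tokens) {
  hq_assert(inherits(tokens, "hq_tokens"), "tokens must be hq_tokens")
  nw <- n_tokens(tokens)
  ns <- n_sentences(tokens)
  if (nw == 0L || ns == 0L) {
    warning("empty text: readability is undefined, returning NA")
    return(NA_real_)
  }
  206.835 - 1.015 * (nw / ns) - 84.6 * (sum(tokens$syllables) / nw)
}

#' Clarity score of a question
#'
#' The percentage of tokens that are interrogative words (who, what,
#' where, when, why, how, ...), including contracted forms such as
#' "what's". A higher share of interrogative words signals a more
#' explicitly articulated information need; a question that never uses
#' one scores zero.
#'
#' @param tokens An `hq_tokens` object.
#' @param interrogatives An `hq_lexicon` of interrogative words;
#'   defaults to the packaged closed set.
#' @return Percentage in \[0, 100\]; 0 for an empty text.
#' @examples
#' clarity(hq_tokenize("Why?"))
#' @export
clarity <- function(tokens,
                    interrogatives = attr(default_lexicons(),
                                          "interrogative")) {
  hq_assert(inherits(tokens, "hq_tokens"), "tokens must be hq_tokens")
  nw <- n_tokens(tokens)
  if (nw == 0L) return(0)
  100 * match_category(tokens, interrogatives) / nw
}

#' Dictionary-based language features
#'
#' For every category in the lexicon set, the percentage of tokens
#' matching that category (the word-count convention of dictionary
#' tools such as LIWC), plus `word_count` and `words_per_sentence`.
#'
#' @param tokens An `hq_tokens` object.
#' @param lexicons An `hq_lexicon_set`; defaults to the packaged set.
#' @return A named numeric vector: `word_count`, `words_per_sentence`,
#'   then one percentage per category.
#' @export
language_features <- function(tokens, lexicons = default_lexicons()) {
  hq_assert(inherits(tokens, "hq_tokens"), "tokens must be hq_tokens")
  hq_assert(inherits(lexicons, "hq_lexicon_set"),
            "lexicons must be an hq_lexicon_set")
  missing_cats <- setdiff(hq_category_names(), names(lexicons))
  if (length(missing_cats)) {
    hq_stop("lexicon set is missing categories: ",
            paste(missing_cats, collapse = ", "),
            class = "healthqq_config_error")
  }
  nw <- n_tokens(tokens)
  ns <- n_sentences(tokens)
  contractions <- attr(lexicons, "contractions")
  cats <- vapply(lexicons[hq_category_names()], function(lex) {
    if (nw == 0L) 0 else 100 * sum(hq_match_mask(tokens$lower, lex,
                                                 contractions)) / nw
  }, numeric(1))
  c(word_count = as.numeric(nw),
    words_per_sentence = if (ns > 0L) nw / ns else 0,
    cats)
}

#' Extract quality indicators and language features from a corpus
#'
#' Tokenizes each question (title and body concatenated by default) and
#' computes readability, clarity and all dictionary-based language
#' features. Records whose combined text is empty receive `NA`
#' readability and zero for all percentages, and are reported in a
#' warning; downstream clustering excludes them.
#'
#' @param corpus A data frame with columns `id`, `title`, `body` and
#'   optionally `platform` (carried through).
#' @param lexicons An `hq_lexicon_set`; defaults to the packaged set.
#' @param text Which text to analyze: `"title_body"` (default,
#'   concatenated with a space) or `"body"`.
#' @return A data frame, one row per record in input order: `id`,
#'   `platform` (if present), `readability`, `clarity`, `word_count`,
#'   `words_per_sentence` and one column per language category.
#' @examples
#' corpus <- read_corpus(system.file("extdata", "examples",
#'   "sample_questions.csv", package = "healthqq"))
#' featurize(corpus)[, c("id", "readability", "clarity")]
#' @export
featurize <- function(corpus, lexicons = default_lexicons(),
                      text = c("title_body", "body")) {
  text <- match.arg(text)
  hq_assert(is.data.frame(corpus), "corpus must be a data frame")
  for (col in c("id", "title", "body")) {
    hq_assert(col %in% names(corpus), "corpus is missing column '", col, "'")
  }
  combined <- if (text == "body") as.character(corpus$body) else
    hq_squish(paste(as.character(corpus$title), as.character(corpus$body)))
  combined[is.na(combined)] <- ""

  interrog <- attr(lexicons, "interrogative")
  rows <- vector("list", nrow(corpus))
  n_empty <- 0L
  for (i in seq_len(nrow(corpus))) {
    tk <- tryCatch(hq_tokenize(combined[i]), error = function(e) {
      hq_stop("record '", corpus$id[i], "': ", conditionMessage(e))
    })
    if (n_tokens(tk) == 0L) {
      n_empty <- n_empty + 1L
      feats <- c(readability = NA_real_, clarity = 0,
                 suppressWarnings(language_features(tk, lexicons)))
    } else {
      feats <- c(readability = flesch_reading_ease(tk),
                 clarity = clarity(tk, interrog),
                 language_features(tk, lexicons))
    }
    rows[[i]] <- feats
  }
  if (n_empty > 0L) {
    warning(sprintf("%d record(s) with empty text: readability recorded as NA",
                    n_empty))
  }
  feat <- as.data.frame(do.call(rbind, rows))
  out <- data.frame(id = as.character(corpus$id), stringsAsFactors = FALSE)
  if ("platform" %in% names(corpus)) out$platform <- as.character(corpus$platform)
  cbind(out, feat)
}
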