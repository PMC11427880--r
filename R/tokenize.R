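#' Tokenize a question text
#'
#' Splits a text into word tokens, sentence spans and per-token syllable
#' counts. Tokens are maximal runs of letters, digits and apostrophes, so
#' contractions ("what's") stay single tokens while hyphenated compounds
#' split. Sentence boundaries are runs of `.`, `!` or `?` followed by
#' whitespace or end of text; a packaged abbreviation stoplist ("dr.",
#' "e.g.", ...) suppresses spurious splits, and trailing text without
#' terminal punctuation counts as one sentence.
#'
#' @param text A length-1 character string (may be empty).
#' @return An object of class `hq_tokens`: a list with elements
#'   `tokens` (surface forms), `lower` (lowercased forms), `sentence`
#'   (integer sentence index per token, partitioning the tokens), and
#'   `syllables` (positive integer per token).
#' @examples
#' tk <- hq_tokenize("What happens next? Ask your doctor.")
#' tk$tokens
#' n_sentences(tk)
#' @export
hq_tokenize <- function(text) {
  hq_assert(is.character(text) && length(text) == 1L && !is.na(text),
            "text must be a single non-NA character string")
  empty <- structure(list(tokens = character(0), lower = character(0),
                          sentence = integer(0), syllables = integer(0)),
                     class = "hq_tokens")
  if (!nzchar(text)) return(empty)

  m <- gregexpr("[A-Za-z0-9']+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  toks <- regmatches(text, list(m))[[1]]
  # strip apostrophes at token edges ('tis, rock' -> tis, rock)
  keep_ofs <- regexpr("[A-Za-z0-9]", toks)
  toks_clean <- gsub("^'+|'+$", "", toks)
  ok <- nzchar(toks_clean)
  toks <- toks_clean[ok]
  starts <- (starts + pmax(keep_ofs - 1L, 0L))[ok]
  if (!length(toks)) return(empty)

  # candidate boundaries: punctuation runs followed by whitespace or EOS
  bm <- gregexpr("[.!?]+(?=[[:space:]]|$)", text, perl = TRUE)[[1]]
  bpos <- integer(0)
  if (bm[1] != -1L) {
    bpos <- as.integer(bm)
    bstr <- regmatches(text, list(bm))[[1]]
    abbrev <- hq_abbreviations()
    drop <- logical(length(bpos))
    for (i in seq_along(bpos)) {
      if (bstr[i] != ".") next  # only bare periods can be abbreviations
      prev <- which(starts < bpos[i])
      if (length(prev)) {
        last_tok <- tolower(toks[max(prev)])
        # "e.g." style internal dots arrive as separate tokens ("e", "g")
        if (last_tok %in% abbrev || nchar(last_tok) == 1L) drop[i] <- TRUE
      }
    }
    bpos <- bpos[!drop]
  }

  sentence <- findInterval(starts, bpos) + 1L
  # renumber consecutively (a boundary with no following tokens adds nothing)
  sentence <- match(sentence, unique(sentence))

  lower <- tolower(toks)
  structure(list(tokens = toks, lower = lower, sentence = sentence,
                 syllables = vapply(lower, hq_count_syllables, integer(1),
                                    USE.NAMES = FALSE)),
            class = "hq_tokens")
}

#' @export
print.hq_tokens <- function(x, ...) {
  cat(sprintf("<hq_tokens: %d tokens, %d sentences, %d syllables>\n",
              n_tokens(x), n_sentences(x), sum(x$syllables)))
  invisible(x)
}

#' Token and sentence counts
#' @param x An `hq_tokens` object.
#' @return An integer count.
#' @export
n_tokens <- function(x) length(x$tokens)

#' @rdname n_tokens
#' @export
n_sentences <- function(x) if (length(x$sentence)) max(x$sentence) else 0L

#' Reassemble tokens into plain text
#'
#' Joins tokens with single spaces, terminating each sentence with a
#' period. Round-tripping through [hq_tokenize()] preserves the token
#' sequence for ordinary texts.
#' @param x An `hq_tokens` object.
#' @return A character string.
#' @export
hq_detokenize <- function(x) {
  if (!n_tokens(x)) return("")
  parts <- vapply(split(x$tokens, x$sentence),
                  function(s) paste0(paste(s, collapse = " "), "."),
                  character(1))
  paste(parts, collapse = " ")
}

#' Count syllables in a word token
#'
#' Looks the word up in the packaged syllable dictionary first; unknown
#' words fall back to a vowel-group heuristic (runs of `aeiouy` count
#' one syllable each, a final silent "e" is subtracted unless the word
#' ends in a consonant + "le", minimum one). Tokens with no letters
#' (e.g. "55") count one syllable.
#'
#' @param token A single word token (character).
#' @return A positive integer syllable count.
#' @examples
#' hq_count_syllables("kidney")
#' hq_count_syllables("dialysis")
#' @export
hq_count_syllables <- function(token) {
  hq_assert(is.character(token) && length(token) == 1L,
            "token must be a single string")
  w <- gsub("[^a-z]", "", tolower(token))
  if (!nchar(w)) return(1L)
  dict <- hq_syllable_dict()
  hit <- dict[[w]]
  if (!is.null(hit)) return(hit)
  hq_heuristic_syllables(w)
}

# vowel-group heuristic; `w` is lowercase letters only, nonempty
hq_heuristic_syllables <- function(w) {
  groups <- gregexpr("[aeiouy]+", w)[[1]]
  n <- if (groups[1] == -1L) 0L else length(groups)
  if (n > 1L && grepl("[^aeiouy]e$", w) && !grepl("[^aeiouy]le$", w)) {
    n <- n - 1L
  }
  max(n, 1L)
}

hq_syllable_dict <- function() {
  if (is.null(.hq_cache$syll)) {
    tab <- utils::read.delim(hq_extdata("syllables.tsv"),
                             header = TRUE, stringsAsFactors = FALSE,
                             comment.char = "#")
    env <- new.env(parent = emptyenv(), size = nrow(tab) * 2L)
    for (i in seq_len(nrow(tab))) {
      assign(tab$word[i], as.integer(tab$syllables[i]), envir = env)
    }
    .hq_cache$syll <- env
  }
  .hq_cache$syll
}

hq_abbreviations <- function() {
  if (is.null(.hq_cache$abbrev)) {
    lines <- readLines(hq_extdata("abbreviations.txt"), warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- tolower(hq_squish(lines))
    .hq_cache$abbrev <- lines[nzchar(lines)]
  }
  .hq_cache$abbrev
}
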