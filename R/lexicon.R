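#' Create a lexicon
#'
#' A lexicon is a named set of lowercase entries used to count tokens
#' belonging to a psycholinguistic category. Entries ending in `*` are
#' prefix wildcards (the dictionary-file convention of word-count
#' tools): `diagnos*` matches "diagnosis", "diagnosed", ... . Exact
#' entries match whole tokens only.
#'
#' @param name Category identifier (single string, unique within a set).
#' @param terms Character vector of lowercase, whitespace-free entries;
#'   a trailing `*` marks a prefix entry.
#' @param match_mode `"wildcard"` (default; trailing `*` entries match
#'   prefixes) or `"exact"` (entries taken literally, `*` disallowed).
#' @return An object of class `hq_lexicon`.
#' @export
hq_lexicon <- function(name, terms, match_mode = c("wildcard", "exact")) {
  if (is.character(match_mode) && length(match_mode) == 1L &&
      !match_mode %in% c("wildcard", "exact")) {
    hq_stop("unknown match_mode: '", match_mode, "'",
            class = "healthqq_config_error")
  }
  match_mode <- match.arg(match_mode)
  hq_assert(is.character(name) && length(name) == 1L && nzchar(name),
            "lexicon name must be a nonempty string")
  terms <- unique(as.character(terms))
  bad <- terms[!nzchar(terms) | grepl("[[:space:]]", terms) |
                 terms != tolower(terms)]
  if (length(bad)) {
    hq_stop("invalid lexicon entries (must be nonempty, lowercase, ",
            "whitespace-free): ", paste(utils::head(bad, 5), collapse = ", "),
            class = "healthqq_config_error")
  }
  is_prefix <- endsWith(terms, "*")
  if (match_mode == "exact" && any(is_prefix)) {
    hq_stop("exact-mode lexicon '", name, "' contains wildcard entries",
            class = "healthqq_config_error")
  }
  structure(list(name = name,
                 exact = terms[!is_prefix],
                 prefixes = sub("\\*$", "", terms[is_prefix]),
                 match_mode = match_mode),
            class = "hq_lexicon")
}

#' @export
print.hq_lexicon <- function(x, ...) {
  cat(sprintf("<hq_lexicon '%s': %d exact, %d prefix entries>\n",
              x$name, length(x$exact), length(x$prefixes)))
  invisible(x)
}

#' Read a lexicon from a plain-text file
#'
#' One entry per line; `#` starts a comment; a trailing `*` marks a
#' prefix wildcard.
#'
#' @param path Path to the lexicon file.
#' @param name Category name; defaults to the file name without extension.
#' @inheritParams hq_lexicon
#' @return An `hq_lexicon`.
#' @export
read_lexicon <- function(path, name = NULL,
                         match_mode = c("wildcard", "exact")) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- hq_squish(lines)
  hq_lexicon(name %||% sub("\\.[^.]*$", "", basename(path)),
             lines[nzchar(lines)], match_mode)
}

# the categories every feature vector carries, in reporting order
hq_category_names <- function() {
  c("total_pronouns", "personal_pronouns", "impersonal_pronouns",
    "social", "family", "friend", "female_refs", "male_refs",
    "past_focus", "present_focus", "future_focus",
    "body", "health",
    "affect", "positive_emotion", "negative_emotion",
    "anxiety", "anger", "sadness")
}

#' Packaged default lexicons
#'
#' Loads the lexicon set shipped with the package: the interrogative
#' lexicon used for clarity, the contraction-expansion table, and one
#' open lexicon per language category (pronouns, social, time
#' orientation, biological, affect). These are documented open word
#' lists, editable as plain-text files.
#'
#' @param dir Directory of lexicon files; defaults to the packaged set.
#' @return An object of class `hq_lexicon_set`: a named list of
#'   `hq_lexicon` objects with attributes `interrogative` (lexicon) and
#'   `contractions` (named character vector mapping contraction to its
#'   head word).
#' @export
default_lexicons <- function(dir = NULL) {
  packaged <- is.null(dir)
  if (packaged && !is.null(.hq_cache$lexset)) return(.hq_cache$lexset)
  if (packaged) dir <- hq_extdata("lexicons")
  cats <- hq_category_names()
  lex <- lapply(cats, function(nm) {
    read_lexicon(file.path(dir, paste0(nm, ".txt")), name = nm)
  })
  names(lex) <- cats
  out <- structure(lex, class = "hq_lexicon_set",
                   interrogative = read_lexicon(
                     file.path(dir, "interrogative.txt")),
                   contractions = hq_read_contractions(
                     file.path(dir, "contractions.tsv")))
  if (packaged) .hq_cache$lexset <- out
  out
}

#' @export
print.hq_lexicon_set <- function(x, ...) {
  cat(sprintf("<hq_lexicon_set: %d categories + interrogative lexicon>\n",
              length(x)))
  invisible(x)
}

hq_read_contractions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  stats::setNames(tolower(tab$head), tolower(tab$contraction))
}

#' Count tokens matching a lexicon category
#'
#' Case-insensitive. A token matches if its lowercase form is an exact
#' entry, starts with a prefix entry, or its contraction head word
#' (from the packaged expansion table, e.g. "what's" -> "what") does.
#' Each token counts at most once per category.
#'
#' @param tokens An `hq_tokens` object.
#' @param lexicon An `hq_lexicon`.
#' @param contractions Named character vector mapping contractions to
#'   head words; defaults to the packaged table. Use `NULL` to disable
#'   contraction expansion.
#' @return Integer count of matching tokens.
#' @examples
#' lex <- attr(default_lexicons(), "interrogative")
#' match_category(hq_tokenize("What's next and when?"), lex)
#' @export
match_category <- function(tokens, lexicon,
                           contractions = attr(default_lexicons(),
                                               "contractions")) {
  hq_assert(inherits(tokens, "hq_tokens"), "tokens must be hq_tokens")
  hq_assert(inherits(lexicon, "hq_lexicon"), "lexicon must be hq_lexicon")
  sum(hq_match_mask(tokens$lower, lexicon, contractions))
}

# logical mask over lowercase tokens; shared by match_category and features
hq_match_mask <- function(lower, lexicon, contractions) {
  if (!length(lower)) return(logical(0))
  expanded <- lower
  if (!is.null(contractions)) {
    has_apo <- grepl("'", lower, fixed = TRUE)
    if (any(has_apo)) {
      heads <- contractions[lower[has_apo]]
      got <- !is.na(heads)
      expanded[has_apo][got] <- heads[got]
    }
  }
  hit <- lower %in% lexicon$exact | expanded %in% lexicon$exact
  if (length(lexicon$prefixes)) {
    for (p in lexicon$prefixes) {
      if (all(hit)) break
      hit <- hit | startsWith(lower, p) | startsWith(expanded, p)
    }
  }
  hit
}
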