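sample_path <- system.file("extdata", "examples", "sample_questions.csv",
                           package = "healthqq")

test_that("tokenizer handles the packaged sample questions and edge cases", {
  corpus <- read_corpus(sample_path)
  q1 <- hq_tokenize(corpus$title[corpus$id == "q1"])
  expect_equal(n_tokens(q1), 36L)
  expect_equal(q1$tokens[1], "What's")  # contraction stays one token

  expect_equal(n_tokens(hq_tokenize("")), 0L)
  expect_equal(n_sentences(hq_tokenize("")), 0L)

  go <- hq_tokenize("Go.")
  expect_equal(n_tokens(go), 1L)
  expect_equal(n_sentences(go), 1L)

  expect_equal(hq_tokenize("self-test kit")$tokens,
               c("self", "test", "kit"))       # hyphens split
  expect_equal(n_tokens(hq_tokenize("I am 55 now")), 4L)  # digits tokenize
})

test_that("sentence segmentation respects abbreviations, ? runs and trailing text", {
  expect_equal(n_sentences(hq_tokenize("Dr. Smith said no. Ask again.")), 2L)
  expect_equal(n_sentences(hq_tokenize("What?? Really? Fine.")), 3L)
  expect_equal(n_sentences(hq_tokenize("no terminal punctuation here")), 1L)
  # sentence indices partition the tokens with no gaps
  tk <- hq_tokenize("One two. Three! Four five? Six")
  expect_equal(tk$sentence, c(1L, 1L, 2L, 3L, 3L, 4L))
})

test_that("tokenization is idempotent through detokenization", {
  texts <- c("What's the dose for dialysis?",
             "My doctor said: start treatment now. Ask why!",
             "kidney disease affects blood pressure")
  for (tx in texts) {
    tk <- hq_tokenize(tx)
    again <- hq_tokenize(hq_detokenize(tk))
    expect_equal(again$tokens, tk$tokens)
  }
})

test_that("syllable counting uses the dictionary then the heuristic", {
  expect_equal(hq_count_syllables("a"), 1L)
  expect_equal(hq_count_syllables("kidney"), 2L)
  expect_equal(hq_count_syllables("dialysis"), 4L)
  expect_equal(hq_count_syllables("55"), 1L)    # no letters -> 1
  expect_equal(hq_count_syllables("Go"), 1L)
  # silent-e and -le endings in the fallback
  expect_equal(hq_count_syllables("mistake"), 2L)
  expect_equal(hq_count_syllables("trifle"), 2L)
  expect_true(all(hq_tokenize("some words here")$syllables >= 1L))
})

test_that("heuristic fallback agrees with the dictionary on >= 90% of its words", {
  dict <- read.delim(system.file("extdata", "syllables.tsv",
                                 package = "healthqq"), comment.char = "#")
  heur <- vapply(dict$word, healthqq:::hq_heuristic_syllables, integer(1))
  expect_gte(nrow(dict), 200L)
  expect_gte(mean(heur == dict$syllables), 0.90)
})

test_that("category matching counts each token once, with contractions expanded", {
  interrog <- attr(default_lexicons(), "interrogative")
  corpus <- read_corpus(sample_path)
  q1 <- hq_tokenize(corpus$title[corpus$id == "q1"])
  expect_equal(match_category(q1, interrog), 7L)

  expect_equal(match_category(hq_tokenize("who who who"),
                              hq_lexicon("w", "who")), 3L)
  expect_equal(match_category(q1, hq_lexicon("none", "zebra")), 0L)
  # prefix wildcard
  expect_equal(match_category(hq_tokenize("diagnosed diagnosis dialysis"),
                              hq_lexicon("dx", "diagnos*")), 2L)
})

test_that("union matching is subadditive with equality on disjoint lexicons", {
  set.seed(42)
  pool <- c("what", "when", "doctor", "kidney", "pain", "who", "test", "why")
  for (i in 1:20) {
    tk <- hq_tokenize(paste(sample(pool, 12, TRUE), collapse = " "))
    l1 <- hq_lexicon("a", c("what", "when", "doctor"))
    l2 <- hq_lexicon("b", c("who", "why", "doctor"))
    lu <- hq_lexicon("u", c("what", "when", "doctor", "who", "why"))
    m1 <- match_category(tk, l1); m2 <- match_category(tk, l2)
    expect_lte(match_category(tk, lu), m1 + m2)
    # disjoint pair: equality
    l2d <- hq_lexicon("bd", c("who", "why"))
    lud <- hq_lexicon("ud", c("what", "when", "doctor", "who", "why"))
    expect_equal(match_category(tk, lud),
                 m1 + match_category(tk, l2d))
  }
})

test_that("lexicon validation rejects malformed entries and modes", {
  expect_error(hq_lexicon("x", "Upper"), "lowercase")
  expect_error(hq_lexicon("x", "two words"), "whitespace")
  expect_error(hq_lexicon("x", "ok", match_mode = "fuzzy"), "unknown match_mode")
  expect_error(hq_lexicon("x", "pre*", match_mode = "exact"), "wildcard")
})

test_that("packaged pronoun sub-lexicons are subsets of the total lexicon", {
  lx <- default_lexicons()
  expect_true(all(lx$personal_pronouns$exact %in% lx$total_pronouns$exact))
  expect_true(all(lx$impersonal_pronouns$exact %in% lx$total_pronouns$exact))
  # and disjoint from each other, so percentages can add
  expect_length(intersect(lx$personal_pronouns$exact,
                          lx$impersonal_pronouns$exact), 0)
})
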