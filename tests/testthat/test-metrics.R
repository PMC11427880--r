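sample_path <- system.file("extdata", "examples", "sample_questions.csv",
                           package = "healthqq")

test_that("Flesch Reading Ease matches the closed form on constructed texts", {
  fre <- function(w, s, syl) 206.835 - 1.015 * (w / s) - 84.6 * (syl / w)
  # words with dictionary-known syllable counts
  mono <- c("go", "run", "eat", "rest", "walk", "drink", "need", "know",
            "day", "week", "test", "blood")
  cases <- list(
    # one-word extreme
    list(text = "Go.", w = 1, s = 1, syl = 1),
    list(text = "Go now.", w = 2, s = 1, syl = 2),
    list(text = "Run. Eat. Rest.", w = 3, s = 3, syl = 3),
    list(text = "The kidney test.", w = 3, s = 1, syl = 4),
    list(text = "Dialysis helps. Medication helps.", w = 4, s = 2, syl = 10),
    list(text = "Doctor doctor doctor.", w = 3, s = 1, syl = 6),
    list(text = "Hospital medical therapy.", w = 3, s = 1, syl = 9),
    list(text = paste(paste(mono[1:10], collapse = " "), "."), w = 10,
         s = 1, syl = 10),
    list(text = "Blood test day. Kidney doctor week.", w = 6, s = 2,
         syl = 8),
    list(text = "Know the treatment. Ask the doctor. Check the dose.",
         w = 9, s = 3, syl = 11),
    # 10 words, 15 syllables in one sentence -> 69.785
    list(text = "Dialysis doctor blood test day week walk run eat pressure.",
         w = 10, s = 1, syl = 15))
  for (cs in cases) {
    tk <- hq_tokenize(cs$text)
    expect_equal(n_tokens(tk), cs$w)
    expect_equal(n_sentences(tk), cs$s)
    expect_equal(sum(tk$syllables), cs$syl)
    expect_equal(flesch_reading_ease(tk), fre(cs$w, cs$s, cs$syl),
                 tolerance = 1e-12)
  }
  expect_equal(flesch_reading_ease(hq_tokenize("Go.")), 121.22)
  expect_equal(flesch_reading_ease(hq_tokenize(
    "Dialysis doctor blood test day week walk run eat pressure.")), 69.785)
})

test_that("readability is invariant under repeating a text", {
  base <- "What is dialysis? The doctor can explain the treatment."
  one <- flesch_reading_ease(hq_tokenize(base))
  four <- flesch_reading_ease(hq_tokenize(paste(rep(base, 4), collapse = " ")))
  expect_equal(one, four, tolerance = 1e-12)
})

test_that("readability decreases in both formula arguments", {
  fre <- function(w, s, syl) 206.835 - 1.015 * (w / s) - 84.6 * (syl / w)
  # more syllables per word at fixed sentence length
  expect_true(all(diff(sapply(seq(1, 4, 0.5),
                              function(asw) fre(10, 1, 10 * asw))) < 0))
  # longer sentences at fixed syllable rate
  expect_true(all(diff(sapply(seq(5, 40, 5),
                              function(w) fre(w, 1, w * 1.5))) < 0))
})

test_that("clarity reproduces the worked sample questions", {
  corpus <- read_corpus(sample_path)
  f <- featurize(corpus)
  expect_equal(f$clarity[f$id == "q1"], 100 * 7 / 36)
  expect_equal(round(f$clarity[f$id == "q1"], 2), 19.44)
  expect_equal(f$clarity[f$id == "q2"], 0)
  expect_equal(clarity(hq_tokenize("Why?")), 100)
  expect_equal(clarity(hq_tokenize("")), 0)
})

test_that("clarity is invariant under proportional extension", {
  tk1 <- hq_tokenize("What dose now?")            # 1 of 3
  tk2 <- hq_tokenize("What dose now? When blood test?")  # 2 of 6
  expect_equal(clarity(tk1), clarity(tk2))
})

test_that("language features match hand counts on a fixture sentence", {
  tx <- paste("I was sad when my doctor told me the kidney test results",
              "and my family called my friend to help me feel good today",
              "again")
  tk <- hq_tokenize(tx)
  expect_equal(n_tokens(tk), 25L)
  lf <- language_features(tk)
  pct <- function(n) 100 * n / 25
  expect_equal(lf[["word_count"]], 25)
  expect_equal(lf[["words_per_sentence"]], 25)
  expect_equal(lf[["personal_pronouns"]], pct(6))   # I me me my my my
  expect_equal(lf[["impersonal_pronouns"]], pct(0))
  expect_equal(lf[["total_pronouns"]], pct(6))
  expect_equal(lf[["social"]], pct(5))      # family friend called told help
  expect_equal(lf[["family"]], pct(1))
  expect_equal(lf[["friend"]], pct(1))
  expect_equal(lf[["female_refs"]], 0)
  expect_equal(lf[["male_refs"]], 0)
  expect_equal(lf[["past_focus"]], pct(2))          # was told
  expect_equal(lf[["present_focus"]], pct(1))       # today
  expect_equal(lf[["future_focus"]], 0)
  expect_equal(lf[["body"]], pct(1))                # kidney
  expect_equal(lf[["health"]], pct(1))              # doctor
  expect_equal(lf[["affect"]], pct(2))              # sad good
  expect_equal(lf[["positive_emotion"]], pct(1))    # good
  expect_equal(lf[["negative_emotion"]], pct(1))    # sad
  expect_equal(lf[["sadness"]], pct(1))
  expect_equal(lf[["anxiety"]], 0)
  expect_equal(lf[["anger"]], 0)
})

test_that("all-category and no-hit extremes behave", {
  expect_equal(language_features(hq_tokenize("I me my"))[["personal_pronouns"]],
               100)
  lf <- language_features(hq_tokenize("zzz qqq xxx"))
  expect_true(all(lf[healthqq:::hq_category_names()] == 0))
})

test_that("pronoun sub-category percentages never exceed the total", {
  set.seed(7)
  pool <- c("i", "me", "it", "this", "doctor", "what", "they", "kidney",
            "something", "you", "her", "test")
  for (i in 1:25) {
    tk <- hq_tokenize(paste(sample(pool, 15, TRUE), collapse = " "))
    lf <- language_features(tk)
    expect_lte(lf[["personal_pronouns"]] + lf[["impersonal_pronouns"]],
               lf[["total_pronouns"]] + 1e-9)
    expect_true(all(lf[healthqq:::hq_category_names()] >= 0 &
                      lf[healthqq:::hq_category_names()] <= 100))
  }
})

test_that("featurize is deterministic, order-preserving and flags empty text", {
  corpus <- make_corpus(c("What is dialysis?", "", "Kidney pain why?"))
  expect_warning(f1 <- featurize(corpus), "empty text")
  expect_warning(f2 <- featurize(corpus), "empty text")
  expect_identical(f1, f2)
  expect_equal(f1$id, corpus$id)
  expect_true(is.na(f1$readability[2]))
  expect_equal(f1$clarity[2], 0)
  expect_equal(f1$word_count[2], 0)
  # per-record calls agree with the batch call
  f_one <- featurize(corpus[3, ])
  expect_equal(f_one$readability, f1$readability[3])
  expect_equal(f_one$clarity, f1$clarity[3])
})

test_that("missing lexicon categories raise a configuration error naming them", {
  lx <- default_lexicons()
  broken <- lx[setdiff(names(lx), "anger")]
  class(broken) <- "hq_lexicon_set"
  attributes(broken)$interrogative <- attr(lx, "interrogative")
  attributes(broken)$contractions <- attr(lx, "contractions")
  expect_error(language_features(hq_tokenize("some text"), broken), "anger")
})
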