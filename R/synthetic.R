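# Word banks for synthetic question texts, stratified by syllable count
# (every word's count is validated against the package syllable counter
# in the test suite). Category-tagged monosyllable banks let the
# generator plant platform differences in pronoun/affect/social rates.
hq_word_banks <- function() {
  list(
    interrogative = c("what", "who", "when", "why", "how", "which", "where"),
    mono_pronoun = c("i", "me", "my", "we", "us", "you", "your", "he",
                     "she", "it", "they", "them", "this", "that"),
    mono_affect = c("good", "bad", "sad", "mad", "glad", "fear", "hurt",
                    "worse", "worst", "nice", "safe", "love", "joy", "cry"),
    mono_social = c("friend", "mom", "dad", "wife", "son", "pal", "guy",
                    "man", "men", "kid", "kids", "talk", "call", "meet",
                    "help", "group"),
    mono_neutral = c("blood", "skin", "head", "arm", "leg", "back", "test",
                     "drug", "pill", "dose", "flu", "day", "week", "month",
                     "year", "stage", "sign", "cell", "scan", "stone",
                     "salt", "food", "sleep", "rest", "walk", "run", "eat",
                     "drink", "need", "know", "go", "get", "the", "and"),
    di = c("kidney", "doctor", "body", "pressure", "treatment", "symptom",
           "chronic", "stable", "fever", "cancer", "patient", "stomach",
           "muscle", "liver", "bladder", "organ", "tissue", "damage",
           "function", "failure", "dosage", "tablet", "protein", "answer",
           "question", "water", "level"),
    tri = c("hospital", "medical", "medicine", "condition", "infection",
            "insulin", "nutrition", "exercise", "therapy", "vitamin",
            "sodium", "calcium", "disorder", "surgery", "unstable",
            "history", "biopsy", "ultrasound", "appointment", "specialist",
            "referral", "prescription", "filtration", "abnormal"),
    quad = c("dialysis", "diabetes", "diabetic", "medication",
             "hypertension", "nephrology", "nephrologist", "potassium",
             "preventative", "recovery", "anemia", "creatinine",
             "emergency", "inflammation", "complication", "dietitian",
             "nutritionist", "glomerular"))
}

#' Specification for a synthetic question corpus
#'
#' Defines the conditions a generated corpus emulates: two platform
#' subpopulations (a community site with longer, more personal
#' questions; an expert site with shorter, more medical ones), three
#' planted quality tiers separated in (readability, clarity) space, and
#' content codes whose planted multinomial coefficients drive tier
#' membership. Tier text targets are words-per-sentence, syllable-
#' stratum mix (fractions of 1/2/3/4-syllable words) and interrogative
#' rate; the defaults put the tiers near Flesch scores of roughly 67 /
#' 48 / 11 and clarity of roughly 35 / 5 / 1 percent, mirroring the
#' ordering high > average > low on both indicators.
#'
#' @param n_per_platform Named integer vector: questions per platform.
#' @param tiers Named list of per-tier generators, each with
#'   `words_per_sentence`, `syllable_mix` (fractions over 1-4 syllable
#'   strata, summing to 1) and `interrogative_rate` in \[0, 1\].
#' @param platforms Named list of per-platform shifts: `word_count_mean`,
#'   `word_count_sd`, `pronoun_rate`, `affect_rate`, `social_rate`
#'   (per-word probabilities), code prevalences `demographic`,
#'   `diagnostic`, `treatment_prevention`, `medical_extra`, and
#'   categorical probabilities `stage_probs` (none/preventative/
#'   diagnosis/treatment) and `chronic_probs` (none/when_chronic/
#'   stable/unstable).
#' @param beta Planted multinomial-logit coefficient matrix (terms x
#'   2 contrasts, "average vs high" and "low vs high") applied to the
#'   content codes to draw tiers; `NULL` draws tiers independently with
#'   probabilities `tier_props`.
#' @param tier_props Tier proportions (sum to 1) used when `beta` is
#'   `NULL`; defaults to the 101/169/354 cluster-size split.
#' @param seed Default integer seed recorded in the spec.
#' @return A validated object of class `hq_synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_platform = c(community = 400, expert = 400),
                           tiers = NULL, platforms = NULL, beta = NULL,
                           tier_props = c(high = 101, average = 169,
                                          low = 354) / 624,
                           seed = 1L) {
  tiers <- tiers %||% list(
    high = list(words_per_sentence = 9,
                syllable_mix = c(0.60, 0.28, 0.09, 0.03),
                interrogative_rate = 0.35),
    average = list(words_per_sentence = 15,
                   syllable_mix = c(0.55, 0.25, 0.15, 0.05),
                   interrogative_rate = 0.05),
    low = list(words_per_sentence = 22,
               syllable_mix = c(0.38, 0.30, 0.21, 0.11),
               interrogative_rate = 0.01))
  platforms <- platforms %||% list(
    community = list(word_count_mean = 60, word_count_sd = 10,
                     pronoun_rate = 0.14, affect_rate = 0.030,
                     social_rate = 0.066,
                     demographic = 0.32, diagnostic = 0.35,
                     treatment_prevention = 0.25, medical_extra = 0.10,
                     stage_probs = c(none = 0.10, preventative = 0.04,
                                     stage_diagnosis = 0.55,
                                     stage_treatment = 0.31),
                     chronic_probs = c(none = 0.30, when_chronic = 0.28,
                                       stable = 0.12, unstable = 0.30)),
    expert = list(word_count_mean = 42, word_count_sd = 10,
                  pronoun_rate = 0.11, affect_rate = 0.018,
                  social_rate = 0.033,
                  demographic = 0.19, diagnostic = 0.50,
                  treatment_prevention = 0.31, medical_extra = 0.10,
                  stage_probs = c(none = 0.06, preventative = 0.04,
                                  stage_diagnosis = 0.44,
                                  stage_treatment = 0.46),
                  chronic_probs = c(none = 0.35, when_chronic = 0.08,
                                    stable = 0.05, unstable = 0.52)))
  if (is.null(beta)) beta <- hq_default_beta()
  spec <- structure(list(n_per_platform = n_per_platform, tiers = tiers,
                         platforms = platforms, beta = beta,
                         tier_props = tier_props, seed = as.integer(seed)),
                    class = "hq_synthetic_spec")
  hq_validate_spec(spec)
  spec
}

# planted log-odds effects of the content codes on tier membership
# (reference = high); directions echo the observed contrasts: diagnosis-
# stage, chronic and unstable questions skew away from high quality,
# demographic/diagnostic/treatment information skews toward it.
hq_default_beta <- function() {
  terms <- c("(Intercept)", "preventative", "stage_diagnosis",
             "stage_treatment", "when_chronic", "stable", "unstable",
             "demographic_info", "diagnostic_info",
             "treatment_prevention_info")
  matrix(c(-0.3, 0.5, 1.0, -0.6, 0.5, -0.3, 1.0, -0.8, 1.0, 0.3,
           0.9, -0.5, 0.2, -0.5, 1.0, 0.2, 0.9, -1.2, -1.0, -1.1),
         ncol = 2, dimnames = list(terms, c("average vs high",
                                            "low vs high")))
}

hq_validate_spec <- function(spec) {
  hq_assert(all(spec$n_per_platform >= 1), "n per platform must be >= 1")
  hq_assert(abs(sum(spec$tier_props) - 1) < 1e-8,
            "tier proportions must sum to 1")
  hq_assert(sum(spec$n_per_platform) >= 9,
            "need n >= 3 * k records for clustering")
  for (nm in names(spec$tiers)) {
    t <- spec$tiers[[nm]]
    hq_assert(abs(sum(t$syllable_mix) - 1) < 1e-8,
              "tier '", nm, "': syllable mix must sum to 1")
    if (t$interrogative_rate < 0 || t$interrogative_rate > 1) {
      hq_stop("tier '", nm, "': interrogative rate must be in [0, 1]",
              class = "healthqq_spec_error")
    }
    if (t$interrogative_rate > t$syllable_mix[1]) {
      hq_stop("tier '", nm, "': interrogative rate exceeds the ",
              "monosyllable share; infeasible text target",
              class = "healthqq_spec_error")
    }
    hq_assert(t$words_per_sentence >= 1, "words per sentence must be >= 1")
  }
  for (nm in names(spec$platforms)) {
    p <- spec$platforms[[nm]]
    rates <- c(p$pronoun_rate, p$affect_rate, p$social_rate,
               p$demographic, p$diagnostic, p$treatment_prevention,
               p$medical_extra)
    hq_assert(all(rates >= 0 & rates <= 1),
              "platform '", nm, "': rates must be in [0, 1]")
    hq_assert(abs(sum(p$stage_probs) - 1) < 1e-8 &&
                abs(sum(p$chronic_probs) - 1) < 1e-8,
              "platform '", nm, "': stage probabilities must sum to 1")
  }
  invisible(spec)
}

#' Generate a synthetic question corpus with planted structure
#'
#' Synthesizes question texts from a packaged health-domain word bank so
#' that each planted quality tier hits its readability and clarity
#' targets, draws content codes with platform-specific prevalences, and
#' assigns tiers either from the planted multinomial coefficients
#' applied to the codes (default) or independently from `tier_props`.
#' Fully reproducible from the seed.
#'
#' @param spec An [synthetic_spec()] object.
#' @param seed Integer seed; defaults to the seed recorded in the spec.
#' @return A list of class `hq_synthetic_corpus`: `corpus` (data frame
#'   `id`, `platform`, `title`, `body`), `tiers` (planted quality level
#'   per record, 1 = high / 2 = average / 3 = low), `codes` (data frame
#'   of binary content codes), `seed`.
#' @export
generate_corpus <- function(spec = synthetic_spec(), seed = spec$seed) {
  hq_assert(inherits(spec, "hq_synthetic_spec"), "spec must be hq_synthetic_spec")
  hq_validate_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  codes <- generate_codes(spec)
  tiers <- hq_plant_tiers(codes, spec)
  banks <- hq_word_banks()
  tier_names <- c("high", "average", "low")

  n <- nrow(codes)
  title <- body <- character(n)
  for (i in seq_len(n)) {
    pf <- spec$platforms[[codes$platform[i]]]
    tr <- spec$tiers[[tier_names[tiers[i]]]]
    txt <- hq_make_text(tr, pf, banks)
    title[i] <- txt$title
    body[i] <- txt$body
  }
  corpus <- data.frame(id = sprintf("s%04d", seq_len(n)),
                       platform = codes$platform,
                       title = title, body = body,
                       stringsAsFactors = FALSE)
  structure(list(corpus = corpus, tiers = tiers,
                 codes = cbind(id = corpus$id,
                               codes[, setdiff(names(codes), "platform")],
                               platform = codes$platform),
                 seed = as.integer(seed)),
            class = "hq_synthetic_corpus")
}

#' @export
print.hq_synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic corpus: %d questions, seed %d>\n",
              nrow(x$corpus), x$seed))
  print(table(platform = x$corpus$platform, tier = x$tiers))
  invisible(x)
}

#' Draw content codes only (no text synthesis)
#'
#' Used directly for regression-recovery simulations where the texts
#' are not needed.
#' @inheritParams generate_corpus
#' @return Data frame of binary content codes plus `platform`.
#' @export
generate_codes <- function(spec = synthetic_spec()) {
  pieces <- lapply(names(spec$n_per_platform), function(pl) {
    np <- spec$n_per_platform[[pl]]
    p <- spec$platforms[[pl]]
    stage <- sample(names(p$stage_probs), np, TRUE, p$stage_probs)
    chronic <- sample(names(p$chronic_probs), np, TRUE, p$chronic_probs)
    diag_info <- stats::rbinom(np, 1, p$diagnostic)
    treat_info <- stats::rbinom(np, 1, p$treatment_prevention)
    medical <- pmax(diag_info, treat_info,
                    stats::rbinom(np, 1, p$medical_extra))
    data.frame(platform = pl,
               medical_info = medical,
               demographic_info = stats::rbinom(np, 1, p$demographic),
               diagnostic_info = diag_info,
               treatment_prevention_info = treat_info,
               preventative = 1L * (stage == "preventative"),
               stage_diagnosis = 1L * (stage == "stage_diagnosis"),
               stage_treatment = 1L * (stage == "stage_treatment"),
               when_chronic = 1L * (chronic == "when_chronic"),
               stable = 1L * (chronic == "stable"),
               unstable = 1L * (chronic == "unstable"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

# tier per record: softmax of planted coefficients on the codes, or iid
# draws from tier_props when no coefficients are planted
hq_plant_tiers <- function(codes, spec) {
  n <- nrow(codes)
  if (is.null(spec$beta)) {
    return(sample(1:3, n, TRUE, spec$tier_props))
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(codes[, rownames(spec$beta)[-1], drop = FALSE]))
  eta <- cbind(0, X %*% spec$beta)   # high, average, low
  e <- exp(eta - apply(eta, 1, max))
  P <- e / rowSums(e)
  vapply(seq_len(n), function(i) sample.int(3L, 1L, prob = P[i, ]),
         integer(1))
}

# one question text meeting the tier's composition targets
hq_make_text <- function(tier, platform, banks) {
  wps <- tier$words_per_sentence
  nw <- max(3 * wps, round(stats::rnorm(1, platform$word_count_mean,
                                        platform$word_count_sd)))
  ns <- max(1L, round(nw / wps))
  nw <- as.integer(ns * wps)

  q <- round(tier$interrogative_rate * nw)
  c4 <- round(tier$syllable_mix[4] * nw)
  c3 <- round(tier$syllable_mix[3] * nw)
  c2 <- round(tier$syllable_mix[2] * nw)
  c1 <- nw - q - c2 - c3 - c4
  if (c1 < 0) { c2 <- c2 + c1; c1 <- 0L }  # rounding guard

  n_pron <- min(c1, stats::rbinom(1, nw, platform$pronoun_rate))
  n_aff <- min(c1 - n_pron, stats::rbinom(1, nw, platform$affect_rate))
  n_soc <- min(c1 - n_pron - n_aff, stats::rbinom(1, nw, platform$social_rate))
  n_neu <- c1 - n_pron - n_aff - n_soc

  fill <- c(sample(banks$mono_pronoun, n_pron, TRUE),
            sample(banks$mono_affect, n_aff, TRUE),
            sample(banks$mono_social, n_soc, TRUE),
            sample(banks$mono_neutral, n_neu, TRUE),
            sample(banks$di, c2, TRUE),
            sample(banks$tri, c3, TRUE),
            sample(banks$quad, c4, TRUE))
  fill <- fill[sample.int(length(fill))]
  interrog <- sample(banks$interrogative, q, TRUE)

  # spread interrogatives across sentences, sentence-initial where possible
  per_sent <- tabulate(rep_len(seq_len(ns), q), ns)
  sentences <- character(ns)
  pos <- 0L
  for (s in seq_len(ns)) {
    take <- wps - per_sent[s]
    words <- c(interrog[seq_len(per_sent[s]) + sum(per_sent[seq_len(s - 1L)])],
               fill[seq_len(take) + pos])
    pos <- pos + take
    # a single-letter word before "." would read as an abbreviation and
    # merge sentences; keep such words away from sentence-final position
    nlast <- length(words)
    if (nchar(words[nlast]) == 1L && any(nchar(words) > 1L)) {
      swap <- which(nchar(words) > 1L)[1]
      words[c(swap, nlast)] <- words[c(nlast, swap)]
    }
    words[1] <- paste0(toupper(substring(words[1], 1, 1)),
                       substring(words[1], 2))
    sentences[s] <- paste0(paste(words, collapse = " "),
                           if (per_sent[s] > 0) "?" else ".")
  }
  list(title = sentences[1],
       body = if (ns > 1L) paste(sentences[-1], collapse = " ") else "")
}

#' Generate judge ratings from planted tiers
#'
#' Each judge independently reports the planted quality level, flipped
#' with probability `noise` to one of the other two levels chosen
#' uniformly.
#'
#' @param tiers Integer vector of planted quality levels (1/2/3).
#' @param judges Number of judges.
#' @param noise Flip probability in \[0, 1).
#' @param seed Integer seed.
#' @return A records-by-judges matrix of quality levels, suitable for
#'   [panel_kappa()].
#' @export
generate_ratings <- function(tiers, judges = 3L, noise = 0.1, seed = 1L) {
  hq_assert(noise >= 0 && noise < 1, "noise must be in [0, 1)")
  hq_assert(judges >= 1L, "need at least 1 judge")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- length(tiers)
  out <- matrix(0L, n, judges,
                dimnames = list(names(tiers) %||% seq_len(n),
                                paste0("judge", seq_len(judges))))
  for (j in seq_len(judges)) {
    flip <- stats::runif(n) < noise
    r <- as.integer(tiers)
    if (any(flip)) {
      r[flip] <- vapply(r[flip], function(v) {
        sample(setdiff(1:3, v), 1L)
      }, integer(1))
    }
    out[, j] <- r
  }
  out
}
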