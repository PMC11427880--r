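---
title: "Measuring the quality of consumer health questions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the quality of consumer health questions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthqq)
```

## The measurement problem

Laypeople post health questions to Q&A communities, and what they get
back depends heavily on how well the question is posed. `healthqq`
measures question quality from the text alone, using two automated
indicators:

* **Readability** — the Flesch Reading Ease score,
  $206.835 - 1.015\,\frac{\text{words}}{\text{sentences}} -
  84.6\,\frac{\text{syllables}}{\text{words}}$. Higher is easier to
  read. The score is reported unclamped: a one-word question scores
  121.22, and dense clinical prose can go below zero; both are
  legitimate values of the formula, not errors.
* **Clarity** — the percentage of tokens that are interrogative words
  (*who, whom, whose, what, which, where, when, why, how*, plus
  contracted forms such as *what's*). A question that never uses an
  interrogative word scores zero however informative its background
  is; an explicit information need shows up as a high share of
  question words.

Questions are then grouped into three overall quality tiers — high
(1), average (2), low (3) — by k-means on the two indicators, the
tiers are validated against human judges (Cohen's kappa between
judges, Pearson correlation between consensus ratings and tiers), and
a multinomial logistic regression relates content codes and language
features to tier membership.

## Text decomposition choices

Every metric sits on the tokenizer, so its rules are fixed and
documented:

* Tokens are maximal runs of letters, digits and apostrophes.
  Contractions (*what's*) are single tokens; a packaged
  contraction-expansion table maps them to a head word (*what*) for
  lexicon matching. Hyphenated compounds split; digit runs (*55*) are
  their own tokens and count one syllable.
* Sentence boundaries are runs of `.`, `!`, `?` followed by whitespace
  or end of text, so *What??* ends one sentence. A packaged
  abbreviation stoplist (*dr., e.g., ...*) suppresses false breaks,
  and trailing text without terminal punctuation counts as one
  sentence — postings in question sections are treated as questions
  whether or not they end with a question mark.
* Syllables come from a packaged plain-text dictionary of health
  vocabulary and common words, with a vowel-group heuristic fallback
  (runs of `aeiouy` count one each; a final silent *e* is subtracted
  unless the word ends in consonant + *le*; minimum one). The fallback
  agrees with the dictionary on over 90% of the dictionary's own
  words; genuinely irregular words (*dialysis*, *diabetes*) are the
  reason the dictionary exists.

Question title and body are concatenated with a space before analysis
(the body alone can be selected with `text = "body"`); a question's
information need is routinely split across the two fields, so
analyzing either alone discards signal.

The psycholinguistic categories (pronouns, social processes, time
orientation, biological words, affect and its sub-scales) are open,
editable word lists shipped as plain-text files, one entry per line
with `#` comments and a trailing `*` as a prefix wildcard. They are
deliberately small, documented approximations in the word-count
tradition — they are not, and do not claim to be, any proprietary
dictionary. Feature values are percentages of tokens matching each
category; the personal and impersonal pronoun lists are disjoint
subsets of the total-pronoun list, so their percentages add.

## Clustering and tier labels

Readability and clarity live on incommensurate scales (roughly 0–120
versus 0–100 with most mass near zero), so the indicators are
z-standardized before clustering; unstandardized k-means would be
dominated by readability variance. A `standardize = FALSE` escape
hatch exists.

`fit_kmeans()` is Lloyd's algorithm with k-means++ seeding, best of
`n_restarts` (default 20) by SSE, empty-cluster repair by reseeding at
the farthest point, and convergence when assignments stabilize. On
small point sets this reliably reaches the global optimum found by
exhaustive partition enumeration, which the test suite checks
directly.

The reference pipeline fixes `k = 3` — high, average, low is the
coding human judges can apply reliably — and reports the elbow
diagnostic alongside. The elbow is formalized as the largest second
difference of **log** SSE over the candidate range. The raw-SSE second
difference was rejected deliberately: it is dominated by the absolute
size of the first drop, and on three well-separated tiers it
systematically prefers k = 2. On the log scale the criterion measures
relative bend, is invariant to the overall scale of the data, and is
exactly zero under geometric SSE decay. A bend must exceed log 2 (the
shrinkage factor entering the bend at least twice the factor leaving
it) to count; below that the curve is treated as structureless and the
smallest candidate k is returned. On planted three-tier corpora the
bend at k = 3 is about 4.7; on a single Gaussian cluster the largest
bend stayed below 0.3 across 40 simulations, so the floor separates
the two regimes by an order of magnitude.

Clusters are ranked by composite score (mean standardized readability
plus mean standardized clarity); the highest composite becomes high
quality. Exact composite ties break by the higher clarity mean, then
the lower cluster id, and are logged. The 10% per-cluster validation
sample uses `round(fraction * n)` with a floor of one per nonempty
cluster, and the pooled sample order is randomized.

## Validation statistics

`cohen_kappa()` is the unweighted statistic by default — the plain
Cohen coefficient — with a linear-weights option since the levels are
ordinal. The degenerate case where every rating is identical across
both raters has `p_e = 1`; kappa is defined as 1 there with a warning,
since observed agreement is perfect. Panels of three or more judges
are summarized by all pairwise kappas and their unweighted mean; a
pair with too few shared ratings fails alone without aborting the
rest.

Consensus ratings are an explicit input: the package never silently
synthesizes them. `majority_consensus()` exists for convenience but
raises an error on tied votes, because ties were resolved by
discussion among judges, which software should not simulate.
Agreement between consensus and tiers is the Pearson correlation on
the 1/2/3 codes; zero variance raises an error rather than returning
a silent 0.

## Determinant regression

`fit_multinomial()` is maximum-likelihood softmax regression fitted by
Newton–Raphson with step halving (the penalized log-likelihood is
monotone by construction), standard errors from the inverse observed
information, and the high-quality tier as the default reference, so
coefficients read as "average vs high" and "low vs high" log-odds.
Predictors enter untransformed — binary content codes and percentage
features as-is.

Quasi-complete separation — a predictor that perfectly splits tiers —
drives coefficients toward infinity while the likelihood plateaus.
The fit stops at the plateau, flags every coefficient above 10 in
absolute value, and warns; an optional ridge penalty (`ridge =
lambda`, intercepts unpenalized, strength reported) gives stabilized
estimates when wanted. Flag-and-report is the default because real
coding data does produce such cells, and hiding them behind automatic
shrinkage misrepresents the evidence. Raw p-values are reported
without multiple-testing correction by default, matching common
reporting practice for this design; Benjamini–Hochberg adjustment is
a one-liner with `p.adjust` on the tidy coefficient table.

Group contrasts between the two platforms use a continuity-corrected
chi-square test for binary codes and Welch's t-test for numeric
features — the standard defaults when the source analysis does not
name its tests. Zero-variance variables are skipped with a reason.

The content-code schema keeps three merged questioning-stage
indicators (preventative / diagnosis-related / treatment-related) and
three chronic-stage indicators (when chronic / stable / unstable),
each with an implicit "none" baseline so the one-hot design stays full
rank.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` stands in for the original two-platform corpus
(400 questions from a community site, 400 from an expert site), which
is not redistributable. It emulates:

* two platform subpopulations differing in question length (means 60
  vs 42 words), pronoun/affect/social word rates, and
  information-sharing prevalences (the expert-like platform richer in
  diagnostic and treatment information, the community-like platform
  richer in demographic information and pronouns);
* three quality tiers with distinct (readability, clarity) targets —
  about (67, 35%), (48, 5%) and (11, 1%) — produced constructively:
  per-question word counts are drawn, then the syllable-stratum mix,
  words-per-sentence and interrogative count are fixed to the tier
  target, so tier separation is large relative to within-tier spread
  and the planted partition is recoverable;
* tier membership driven by planted multinomial-logit coefficients on
  the content codes, so the regression stage has a known truth to
  recover;
* judge ratings as planted tiers flipped with a given probability to a
  uniformly random other level.

Texts are template-free draws from a health-domain word bank, not a
language model. They are not fluent English, their vocabulary
distribution is nothing like real postings, and the language-feature
correlations with quality are whatever the bank mixture implies —
so a passing pipeline demonstrates that the *machinery* (tokenizing,
counting, clustering, labeling, regression) recovers planted
structure, not that the indicators capture quality in real postings.
Corpus-scale descriptive values from the original study (cluster
sizes, indicator ranges, coefficient tables) are consequently not
reproduction targets; only directions and structural behaviour are.

## Numerical and reproducibility choices

* Every stochastic stage (k-means restarts, sampling, generation)
  takes an explicit integer seed; nothing seeds from the clock. The
  generator restores the caller's RNG state.
* Newton iterations stop at relative log-likelihood change below
  1e-10 or gradient norm below 1e-8; near-singular information
  matrices fall back to an SVD pseudo-inverse.
* The elbow's log curve floors SSE at `1e-9 * max(SSE)` so a k that
  already fits perfectly stays defined.
* Percentages are stored at full float precision; two-decimal rounding
  happens only at the presentation layer.
* Test problem sizes are chosen to make the checked properties sharp
  but cheap: enumeration oracles run at n ≤ 8, elbow/tier recovery at
  300 questions over 50 seeds, regression coverage at n = 2000 over
  100 seeds.

## Limitations

The clarity lexicon is a closed set; rhetorical questions without
interrogative words score zero by design. The syllable counter is
English-only. The language-feature lexicons are small open word lists,
so absolute category percentages are not comparable to values from
proprietary dictionaries — only contrasts computed with the same
lexicons are meaningful. And the quality construct itself is
two-dimensional by design; content depth beyond readability and
clarity enters only through the regression stage, not the tiers.
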