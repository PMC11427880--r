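Package: healthqq
Title: Quality Measurement of Consumer Health Questions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the quality of consumer health questions posted to
    question-and-answer communities from the text alone. Computes
    Flesch Reading Ease readability and an interrogative-word clarity
    score, dictionary-based psycholinguistic language features, groups
    questions into high/average/low quality tiers by k-means clustering
    with elbow-based model selection, provides human-validation
    statistics (Cohen's kappa, rating-cluster correlation), and fits
    multinomial logistic regressions relating content and language
    variables to question quality. Includes a synthetic corpus
    generator with planted quality structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet,
    mclust,
    yaml
Config/testthat/edition: 3
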