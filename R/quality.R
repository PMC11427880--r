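#' Fit the question-quality model to a corpus
#'
#' The end-to-end quality measurement: featurizes every question
#' (readability and clarity plus dictionary language features), groups
#' the questions by k-means on the standardized (readability, clarity)
#' indicators, and labels the clusters as high (1), average (2) and low
#' (3) quality by their composite indicator means. The number of
#' clusters is fixed at `k = 3` in the reference pipeline; the elbow
#' criterion over `k_range` is computed alongside as an advisory
#' diagnostic. Records with empty text are excluded from clustering
#' (reported via message) but retained with `NA` quality.
#'
#' @param corpus Data frame with columns `id`, `title`, `body` and
#'   optionally `platform`; see [read_corpus()].
#' @param k Number of quality clusters (default 3).
#' @param k_range Candidate k values for the advisory elbow diagnostic;
#'   `NULL` skips it.
#' @param seed Integer seed for clustering restarts.
#' @param n_restarts k-means++ restarts.
#' @param lexicons An `hq_lexicon_set`.
#' @param standardize Z-standardize indicators before clustering.
#' @param text Which text to featurize (see [featurize()]).
#' @return An object of class `question_quality`: `features` (the
#'   feature table), `model` (`hq_kmeans`), `labels` (cluster to
#'   quality-level map), `assignments` (data frame `id`, `cluster`,
#'   `quality`), `elbow` (advisory `k` and `sse_curve`, or `NULL`),
#'   `seed`, `call`. Methods: `print`, `summary`, `predict`, `plot`,
#'   `fitted`.
#' @examples
#' sim <- generate_corpus(synthetic_spec(n_per_platform =
#'   c(community = 30, expert = 30)), seed = 7)
#' fit <- question_quality(sim$corpus, seed = 7)
#' table(fitted(fit), sim$tiers)
#' @export
question_quality <- function(corpus, k = 3L, k_range = 1:8, seed = 1L,
                             n_restarts = 20L,
                             lexicons = default_lexicons(),
                             standardize = TRUE,
                             text = c("title_body", "body")) {
  feats <- featurize(corpus, lexicons = lexicons, text = match.arg(text))
  usable <- !is.na(feats$readability)
  if (any(!usable)) {
    message(sum(!usable), " record(s) excluded from clustering (empty text)")
  }
  pts <- as.matrix(feats[usable, c("readability", "clarity")])
  if (nrow(pts) < k) {
    hq_stop("cannot form ", k, " clusters from ", nrow(pts),
            " usable records", class = "healthqq_sizing_error")
  }
  elbow <- NULL
  if (!is.null(k_range) && length(k_range) >= 3L &&
      max(k_range) <= nrow(pts)) {
    sel <- select_k_elbow(pts, k_range = k_range, seed = seed,
                          n_restarts = n_restarts,
                          standardize = standardize)
    elbow <- list(k = sel$k, sse_curve = sel$sse_curve)
  }
  model <- fit_kmeans(pts, k = k, seed = seed, n_restarts = n_restarts,
                      standardize = standardize)
  labels <- if (k == 3L) label_clusters(model) else
    stats::setNames(seq_len(k), as.character(seq_len(k)))
  assignments <- data.frame(id = feats$id, cluster = NA_integer_,
                            quality = NA_integer_,
                            stringsAsFactors = FALSE)
  assignments$cluster[usable] <- model$cluster
  assignments$quality[usable] <- unname(labels[as.character(model$cluster)])
  structure(list(features = feats, model = model, labels = labels,
                 assignments = assignments, elbow = elbow,
                 seed = as.integer(seed), call = match.call()),
            class = "question_quality")
}

#' @export
print.question_quality <- function(x, ...) {
  cat("Question-quality model (k-means on readability and clarity)\n")
  cat(sprintf("  %d questions, k = %d, seed = %d\n",
              nrow(x$features), x$model$k, x$seed))
  tiers <- factor(x$assignments$quality, levels = 1:3,
                  labels = c("high", "average", "low"))
  print(table(quality = tiers, useNA = "ifany"))
  if (!is.null(x$elbow)) {
    cat(sprintf("  advisory elbow selection: k = %d\n", x$elbow$k))
  }
  invisible(x)
}

#' @export
summary.question_quality <- function(object, ...) {
  a <- object$assignments
  f <- object$features
  stats_by <- function(v) {
    do.call(rbind, lapply(1:3, function(q) {
      x <- f[[v]][which(a$quality == q)]
      data.frame(quality = c("high", "average", "low")[q], n = length(x),
                 mean = mean(x), sd = stats::sd(x),
                 min = if (length(x)) min(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_)
    }))
  }
  out <- list(readability = stats_by("readability"),
              clarity = stats_by("clarity"),
              elbow = object$elbow, sse = object$model$sse)
  class(out) <- "summary.question_quality"
  out
}

#' @export
print.summary.question_quality <- function(x, ...) {
  cat("Readability by quality tier:\n")
  print(x$readability, row.names = FALSE, digits = 4)
  cat("Clarity by quality tier:\n")
  print(x$clarity, row.names = FALSE, digits = 4)
  if (!is.null(x$elbow)) {
    cat(sprintf("Advisory elbow k: %d\nSSE curve: %s\n", x$elbow$k,
                paste(sprintf("k=%s: %.1f", names(x$elbow$sse_curve),
                              x$elbow$sse_curve), collapse = ", ")))
  }
  invisible(x)
}

#' @param object,newdata A fitted `question_quality` model and a new
#'   corpus data frame (same schema as `corpus`).
#' @param ... Unused.
#' @rdname question_quality
#' @export
predict.question_quality <- function(object, newdata, ...) {
  feats <- featurize(newdata)
  usable <- !is.na(feats$readability)
  out <- data.frame(id = feats$id, cluster = NA_integer_,
                    quality = NA_integer_, stringsAsFactors = FALSE)
  if (any(usable)) {
    cl <- predict(object$model,
                  feats[usable, c("readability", "clarity")])
    out$cluster[usable] <- cl
    out$quality[usable] <- unname(object$labels[as.character(cl)])
  }
  out
}

#' @export
fitted.question_quality <- function(object, ...) {
  factor(object$assignments$quality, levels = 1:3,
         labels = c("high", "average", "low"))
}

#' @param x A `question_quality` object.
#' @rdname question_quality
#' @export
plot.question_quality <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, if (is.null(x$elbow)) 1 else 2))
  on.exit(graphics::par(op))
  if (!is.null(x$elbow)) {
    graphics::plot(as.integer(names(x$elbow$sse_curve)), x$elbow$sse_curve,
                   type = "b", xlab = "k", ylab = "SSE",
                   main = "Elbow diagnostic")
    graphics::abline(v = x$elbow$k, lty = 2)
  }
  keep <- !is.na(x$assignments$quality)
  cols <- c("#1b7837", "#fdae61", "#d73027")
  graphics::plot(x$features$readability[keep], x$features$clarity[keep],
                 col = cols[x$assignments$quality[keep]], pch = 19,
                 xlab = "Readability (Flesch Reading Ease)",
                 ylab = "Clarity (% interrogative words)",
                 main = "Quality tiers")
  graphics::legend("topleft", legend = c("high", "average", "low"),
                   col = cols, pch = 19, bty = "n")
  invisible(x)
}
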