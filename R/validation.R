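#' Cohen's kappa between two raters
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` where
#' `p_o` is observed agreement and `p_e` the expected agreement from the
#' raters' marginal distributions. Pairs with a missing rating on either
#' side are dropped. When every rating is identical across both raters
#' and categories (`p_e = 1`), kappa is defined as 1 with a warning.
#'
#' @param ratings_a,ratings_b Vectors of category codes (e.g. quality
#'   levels 1/2/3); `NA`s allowed.
#' @param weights `"unweighted"` (default, the bare Cohen statistic) or
#'   `"linear"` for ordinal levels.
#' @return The kappa statistic (numeric scalar) with attributes `p_o`,
#'   `p_e` and `n` (complete pairs).
#' @examples
#' cohen_kappa(c(1, 1, 2, 2), c(1, 2, 1, 2))  # chance-level: 0
#' @export
cohen_kappa <- function(ratings_a, ratings_b,
                        weights = c("unweighted", "linear")) {
  weights <- match.arg(weights)
  hq_assert(length(ratings_a) == length(ratings_b),
            "rating vectors must have equal length")
  ok <- !is.na(ratings_a) & !is.na(ratings_b)
  a <- ratings_a[ok]
  b <- ratings_b[ok]
  if (length(a) < 2L) {
    hq_stop("need at least 2 complete rating pairs, got ", length(a),
            class = "healthqq_insufficient_data")
  }
  lev <- sort(unique(c(a, b)))
  a <- factor(a, levels = lev)
  b <- factor(b, levels = lev)
  n <- length(a)
  tab <- table(a, b) / n
  w <- if (weights == "unweighted") {
    diag(length(lev))
  } else {
    1 - abs(outer(seq_along(lev), seq_along(lev), "-")) / (length(lev) - 1)
  }
  p_o <- sum(w * tab)
  p_e <- sum(w * outer(rowSums(tab), colSums(tab)))
  kappa <- if (isTRUE(all.equal(p_e, 1))) {
    warning("all ratings identical across raters and categories; kappa = 1")
    1
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(kappa, p_o = p_o, p_e = p_e, n = n)
}

#' Pairwise kappas for a panel of judges
#'
#' Computes Cohen's kappa for every pair of judges on their shared
#' complete cases, plus the unweighted mean across pairs. A pair that
#' cannot be computed (too few shared ratings) is reported as `NA` with
#' the error message, without aborting the other pairs.
#'
#' @param ratings A records-by-judges matrix/data frame of quality
#'   levels (rows = questions, columns = judges; `NA` = not rated), or a
#'   long data frame with columns `record_id`, `judge_id`, `rating`.
#' @inheritParams cohen_kappa
#' @return A list of class `hq_panel_kappa`: `pairs` (data frame with
#'   `judge_a`, `judge_b`, `kappa`, `n`, `note`) and `mean_kappa`.
#' @export
panel_kappa <- function(ratings, weights = c("unweighted", "linear")) {
  weights <- match.arg(weights)
  mat <- hq_ratings_matrix(ratings)
  hq_assert(ncol(mat) >= 2L, "need at least 2 judges")
  judges <- colnames(mat)
  combs <- utils::combn(seq_len(ncol(mat)), 2L)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    ja <- combs[1, i]; jb <- combs[2, i]
    res <- tryCatch(cohen_kappa(mat[, ja], mat[, jb], weights = weights),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(judge_a = judges[ja], judge_b = judges[jb],
                 kappa = NA_real_, n = NA_integer_,
                 note = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(judge_a = judges[ja], judge_b = judges[jb],
                 kappa = as.numeric(res), n = attr(res, "n"),
                 note = "", stringsAsFactors = FALSE)
    }
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs,
                 mean_kappa = mean(pairs$kappa, na.rm = TRUE)),
            class = "hq_panel_kappa")
}

#' @export
print.hq_panel_kappa <- function(x, ...) {
  cat("Pairwise Cohen's kappa:\n")
  print(x$pairs, row.names = FALSE)
  cat(sprintf("Mean kappa: %.3f\n", x$mean_kappa))
  invisible(x)
}

# accepts wide matrix/df or long (record_id, judge_id, rating)
hq_ratings_matrix <- function(ratings) {
  if (is.data.frame(ratings) &&
      all(c("record_id", "judge_id", "rating") %in% names(ratings))) {
    recs <- unique(as.character(ratings$record_id))
    judges <- unique(as.character(ratings$judge_id))
    mat <- matrix(NA_real_, length(recs), length(judges),
                  dimnames = list(recs, judges))
    mat[cbind(match(as.character(ratings$record_id), recs),
              match(as.character(ratings$judge_id), judges))] <-
      as.numeric(ratings$rating)
    return(mat)
  }
  mat <- as.matrix(ratings)
  if (is.null(colnames(mat))) {
    colnames(mat) <- paste0("judge", seq_len(ncol(mat)))
  }
  storage.mode(mat) <- "double"
  mat
}

#' Correlation between judge ratings and cluster quality levels
#'
#' Pearson product-moment correlation between the consensus human
#' ratings and the cluster-derived quality levels, both on the 1 = high,
#' 2 = average, 3 = low coding.
#'
#' @param consensus,assignment Paired numeric vectors of quality levels.
#' @return Pearson r.
#' @export
rating_cluster_correlation <- function(consensus, assignment) {
  hq_assert(length(consensus) == length(assignment),
            "vectors must be paired (equal length)")
  ok <- !is.na(consensus) & !is.na(assignment)
  x <- as.numeric(consensus[ok])
  y <- as.numeric(assignment[ok])
  hq_assert(length(x) >= 3L, "need at least 3 paired ratings")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    hq_stop("correlation undefined: a rating vector has zero variance",
            class = "healthqq_degenerate_error")
  }
  stats::cor(x, y)
}

#' Majority consensus from a judge panel
#'
#' Synthesizes a consensus rating per record by strict majority across
#' judges. Records with a tied vote raise an error: ties require
#' adjudication by discussion, which the package does not simulate.
#'
#' @param ratings See [panel_kappa()].
#' @return Named numeric vector of consensus levels per record.
#' @export
majority_consensus <- function(ratings) {
  mat <- hq_ratings_matrix(ratings)
  out <- apply(mat, 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(NA_real_)
    tab <- sort(table(r), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) return(Inf)  # tie marker
    as.numeric(names(tab)[1])
  })
  if (any(is.infinite(out))) {
    hq_stop("tied votes for record(s): ",
            paste(utils::head(names(out)[is.infinite(out)], 5), collapse = ", "),
            "; adjudication required",
            class = "healthqq_adjudication_error")
  }
  out
}
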