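#' Fit k-means on quality indicators
#'
#' Lloyd's algorithm with k-means++ seeding, run `n_restarts` times and
#' keeping the restart with the lowest sum of squared errors (SSE).
#' Indicators are z-standardized by default because readability and
#' clarity live on incommensurate scales. Empty clusters are repaired by
#' reseeding at the point farthest from its centroid; iteration stops
#' when assignments stabilize or after `max_iter` sweeps.
#'
#' @param x Numeric matrix or data frame of points (rows = questions,
#'   columns = indicators, typically readability and clarity). Must be
#'   finite.
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Integer seed controlling all restarts.
#' @param n_restarts Number of independent k-means++ restarts.
#' @param standardize Z-standardize columns before clustering (default
#'   `TRUE`); centers/scales are stored for prediction.
#' @param max_iter Maximum Lloyd sweeps per restart.
#' @param init Optional matrix of starting centroids (in standardized
#'   space) used as one additional restart.
#' @return An object of class `hq_kmeans`: `k`, `centers` (standardized
#'   space), `standardizer` (`center`, `scale`), `cluster` (assignment
#'   per row), `sse`, `sse_trace` (per accepted iteration of the best
#'   restart), `iter`, `seed`, `n_restarts`.
#' @export
fit_kmeans <- function(x, k, seed = 1L, n_restarts = 20L,
                       standardize = TRUE, max_iter = 300L, init = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  hq_assert(all(is.finite(x)), "indicators must be finite")
  n <- nrow(x)
  hq_assert(k >= 1L, "k must be >= 1")
  if (n < k) {
    hq_stop("cannot form ", k, " clusters from ", n, " points",
            class = "healthqq_sizing_error")
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  if (!standardize) {
    ctr[] <- 0
    scl[] <- 1
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (k > 1L && nrow(unique(z)) == 1L) {
    hq_stop("all points are identical; cannot form ", k, " > 1 clusters",
            class = "healthqq_degenerate_error")
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  best <- NULL
  starts <- c(lapply(seq_len(n_restarts), function(i) NULL),
              if (!is.null(init)) list(as.matrix(init)))
  for (s in starts) {
    res <- hq_lloyd(z, k, start = s %||% hq_kmeanspp(z, k),
                    max_iter = max_iter)
    if (is.null(best) || res$sse < best$sse) best <- res
  }
  structure(list(k = k, centers = best$centers,
                 standardizer = list(center = ctr, scale = scl),
                 cluster = best$cluster, sse = best$sse,
                 sse_trace = best$trace, iter = best$iter,
                 seed = seed, n_restarts = n_restarts),
            class = "hq_kmeans")
}

# squared Euclidean distances from every row of z to every centroid
hq_dist2 <- function(z, centers) {
  d2 <- outer(rowSums(z^2), rep(1, nrow(centers))) -
    2 * z %*% t(centers) +
    outer(rep(1, nrow(z)), rowSums(centers^2))
  pmax(d2, 0)
}

hq_kmeanspp <- function(z, k) {
  n <- nrow(z)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- hq_dist2(z, z[idx[1], , drop = FALSE])[, 1]
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        idx[j] <- sample.int(n, 1L)
      } else {
        idx[j] <- sample.int(n, 1L, prob = d2)
      }
      d2 <- pmin(d2, hq_dist2(z, z[idx[j], , drop = FALSE])[, 1])
    }
  }
  z[idx, , drop = FALSE]
}

hq_lloyd <- function(z, k, start, max_iter) {
  centers <- start
  assign_prev <- rep(0L, nrow(z))
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- hq_dist2(z, centers)
    cl <- max.col(-d2, ties.method = "first")
    # empty-cluster repair: reseed at the point farthest from its centroid
    for (j in seq_len(k)) {
      if (!any(cl == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(z)), cl)])
        cl[far] <- j
        d2[far, ] <- 0  # do not pick the same point twice
      }
    }
    sse <- sum(hq_dist2(z, centers)[cbind(seq_len(nrow(z)), cl)])
    trace <- c(trace, sse)
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(z[cl == j, , drop = FALSE])
    }
    if (identical(cl, assign_prev) || iter >= max_iter) break
    assign_prev <- cl
  }
  sse <- sum(hq_dist2(z, centers)[cbind(seq_len(nrow(z)), cl)])
  list(centers = centers, cluster = cl, sse = sse,
       trace = c(trace, sse), iter = iter)
}

#' @export
print.hq_kmeans <- function(x, ...) {
  cat(sprintf("k-means quality model: k = %d, SSE = %.4f (%d restarts, seed %d)\n",
              x$k, x$sse, x$n_restarts, x$seed))
  cat("Cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  invisible(x)
}

#' @param object,newdata An `hq_kmeans` model and a matrix/data frame of
#'   points on the original indicator scale.
#' @param ... Unused.
#' @return `predict.hq_kmeans`: integer cluster ids.
#' @rdname fit_kmeans
#' @export
predict.hq_kmeans <- function(object, newdata, ...) {
  z <- sweep(sweep(as.matrix(newdata), 2, object$standardizer$center),
             2, object$standardizer$scale, "/")
  max.col(-hq_dist2(z, object$centers), ties.method = "first")
}

#' Choose the number of clusters by the elbow method
#'
#' Fits k-means for every k in `k_range`, records the SSE curve, and
#' returns the k with the largest discrete second difference of the
#' log-SSE curve, `log sse[k-1] - 2 log sse[k] + log sse[k+1]` (the
#' sharpest relative bend; on the log scale the criterion is invariant
#' to the overall scale of the data and is exactly zero under geometric
#' SSE decay, so it isolates the k where the marginal gain collapses).
#' A bend only counts as an elbow if it exceeds `log(2)` -- i.e. the
#' SSE shrinkage factor entering the bend must be at least twice the
#' factor leaving it; when no bend reaches that, the curve is treated
#' as structureless and the smallest candidate k is returned. Ties
#' break toward the smallest k. To keep the SSE curve nonincreasing,
#' each fit at k also tries a start derived from the best (k-1)
#' solution plus the farthest point.
#'
#' @inheritParams fit_kmeans
#' @param k_range Integer vector of at least 3 consecutive candidate
#'   values, within `[1, nrow(x)]`.
#' @return A list: `k` (selected), `sse_curve` (named numeric over
#'   `k_range`), `models` (fitted `hq_kmeans` per k).
#' @export
select_k_elbow <- function(x, k_range = 1:8, seed = 1L, n_restarts = 20L,
                           standardize = TRUE) {
  k_range <- sort(unique(as.integer(k_range)))
  hq_assert(length(k_range) >= 3L,
            "k_range must contain at least 3 values to locate an elbow")
  hq_assert(min(k_range) >= 1L && max(k_range) <= nrow(as.matrix(x)),
            "k_range must lie within [1, n_points]")
  models <- vector("list", length(k_range))
  names(models) <- as.character(k_range)
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    init <- NULL
    if (!is.null(prev) && k == prev$k + 1L) {
      # warm start: previous centroids plus the worst-fit point
      z <- sweep(sweep(as.matrix(x), 2, prev$standardizer$center),
                 2, prev$standardizer$scale, "/")
      resid <- hq_dist2(z, prev$centers)[cbind(seq_len(nrow(z)), prev$cluster)]
      init <- rbind(prev$centers, z[which.max(resid), ])
    }
    models[[i]] <- fit_kmeans(x, k, seed = seed + k, n_restarts = n_restarts,
                              standardize = standardize, init = init)
    prev <- models[[i]]
  }
  sse <- vapply(models, `[[`, numeric(1), "sse")
  names(sse) <- as.character(k_range)
  # relative second difference on interior ks only; the floor keeps the
  # log defined when a k already fits perfectly (SSE = 0)
  lsse <- log(pmax(sse, max(sse, 1) * 1e-9))
  d2 <- lsse[-c(1, length(lsse))]
  for (j in 2:(length(lsse) - 1L)) {
    d2[j - 1L] <- lsse[j - 1L] - 2 * lsse[j] + lsse[j + 1L]
  }
  k_sel <- if (max(d2) < log(2)) {
    k_range[1]  # no discernible elbow: stay at the smallest candidate
  } else {
    k_range[which(d2 == max(d2))[1] + 1L]  # ties toward smallest k
  }
  list(k = k_sel, sse_curve = sse, models = models)
}

#' Label clusters as quality tiers
#'
#' Ranks the three clusters by composite score (mean standardized
#' readability + mean standardized clarity of the centroid) and maps the
#' highest composite to high quality (1), the middle to average (2) and
#' the lowest to low (3). Composite ties break by higher clarity mean,
#' then lower cluster id (logged via message).
#'
#' @param model A fitted `hq_kmeans` with `k = 3` whose columns are
#'   (readability, clarity).
#' @return Named integer vector mapping cluster id to quality level; a
#'   bijection onto `c(1, 2, 3)`.
#' @export
label_clusters <- function(model) {
  hq_assert(inherits(model, "hq_kmeans"), "model must be hq_kmeans")
  hq_assert(model$k == 3L, "quality labeling requires k = 3")
  composite <- rowSums(model$centers)
  clar <- model$centers[, 2]
  if (anyDuplicated(composite)) {
    message("composite ties between clusters; breaking by clarity, then id")
  }
  ord <- order(-composite, -clar, seq_len(3L))
  labels <- integer(3L)
  labels[ord] <- 1:3
  stats::setNames(labels, as.character(seq_len(3L)))
}

#' Stratified sample of questions per quality cluster
#'
#' Draws `round(fraction * n_cluster)` questions (at least 1) from each
#' nonempty cluster and returns the pooled ids in randomized order, the
#' procedure used to select questions for human judging.
#'
#' @param assignments Data frame with columns `id` and `cluster` (or
#'   `quality`).
#' @param fraction Sampling fraction in (0, 1].
#' @param seed Integer seed.
#' @return Character vector of sampled record ids, shuffled.
#' @export
stratified_sample <- function(assignments, fraction = 0.1, seed = 1L) {
  hq_assert(is.data.frame(assignments) && nrow(assignments) > 0L,
            "assignments must be a nonempty data frame")
  hq_assert(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  strat <- if ("cluster" %in% names(assignments)) assignments$cluster
           else assignments$quality
  hq_assert(!is.null(strat), "assignments need a 'cluster' or 'quality' column")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  ids <- unlist(lapply(split(as.character(assignments$id), strat), function(g) {
    size <- max(1L, round(fraction * length(g)))
    g[sample.int(length(g), size)]
  }), use.names = FALSE)
  ids[sample.int(length(ids))]
}
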