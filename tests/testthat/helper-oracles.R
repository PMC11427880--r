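# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: the k-means oracle enumerates every
# assignment, the ARI is computed straight from the contingency-table
# formula.

# global SSE optimum over all assignments of n points to k nonempty
# clusters (feasible up to ~k^n = a few thousand combinations)
brute_force_kmeans_sse <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(k^n <= 4e5)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    a <- grid[r, ]
    if (length(unique(a)) < k) next
    sse <- 0
    for (j in unique(a)) {
      pts <- x[a == j, , drop = FALSE]
      ctr <- colMeans(pts)
      sse <- sse + sum(sweep(pts, 2, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# adjusted Rand index from the pair-counting formula
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# tiny corpus data frame builder for io/metrics tests
make_corpus <- function(titles, bodies = rep("", length(titles)),
                        platform = "community") {
  data.frame(id = paste0("r", seq_along(titles)), platform = platform,
             title = titles, body = bodies, stringsAsFactors = FALSE)
}
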