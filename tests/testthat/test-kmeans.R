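test_that("k-means attains the enumerated global optimum on small fixtures", {
  # 1-D structure embedded in 2-D: optimum pairs the close points
  x1 <- cbind(c(0, 0.1, 10, 10.1, 20, 20.2), 0)
  fit <- fit_kmeans(x1, k = 3, seed = 1, n_restarts = 20, standardize = FALSE)
  expect_equal(fit$sse, brute_force_kmeans_sse(x1, 3), tolerance = 1e-12)
  part <- split(seq_len(6), fit$cluster)
  expect_setequal(lapply(part, sort), list(1:2, 3:4, 5:6))

  set.seed(11)
  fixtures <- list(
    list(x = matrix(rnorm(10), 5, 2), k = 2),
    list(x = matrix(rnorm(14), 7, 2), k = 3),
    list(x = matrix(rnorm(16), 8, 2), k = 3),
    list(x = matrix(runif(16, 0, 5), 8, 2), k = 2))
  for (fx in fixtures) {
    fit <- fit_kmeans(fx$x, fx$k, seed = 3, n_restarts = 25,
                      standardize = FALSE)
    expect_equal(fit$sse, brute_force_kmeans_sse(fx$x, fx$k),
                 tolerance = 1e-9)
  }
})

test_that("k = 1 and k = n closed forms hold", {
  set.seed(2)
  x <- matrix(rnorm(20), 10, 2)
  f1 <- fit_kmeans(x, 1, seed = 1, standardize = FALSE)
  expect_equal(as.vector(f1$centers), colMeans(x), tolerance = 1e-12)
  expect_equal(f1$sse, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-12)
  fn <- fit_kmeans(x, 10, seed = 1, standardize = FALSE)
  expect_equal(fn$sse, 0, tolerance = 1e-12)
})

test_that("SSE never increases across Lloyd iterations", {
  set.seed(4)
  for (s in 1:5) {
    x <- rbind(matrix(rnorm(40), 20, 2), matrix(rnorm(40, 4), 20, 2))
    fit <- fit_kmeans(x, 3, seed = s, n_restarts = 5)
    expect_true(all(diff(fit$sse_trace) <= 1e-10))
  }
})

test_that("sizing and degeneracy errors are raised", {
  expect_error(fit_kmeans(matrix(rnorm(4), 2, 2), 3), class = "healthqq_sizing_error")
  same <- matrix(1, 5, 2)
  expect_error(fit_kmeans(same, 2), class = "healthqq_degenerate_error")
})

test_that("elbow selection finds planted structure and stays low without it", {
  # three tight, well-separated clusters
  set.seed(9)
  x <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
             matrix(rnorm(60, 5, 0.1), ncol = 2),
             cbind(rnorm(30, 10, 0.1), rnorm(30, 0, 0.1)))
  sel <- select_k_elbow(x, 1:8, seed = 5)
  expect_equal(sel$k, 3)
  expect_true(all(diff(sel$sse_curve) <= 1e-8))  # nonincreasing curve
  # structureless cloud: no elbow, smallest candidate returned
  set.seed(10)
  noise <- matrix(rnorm(400), 200, 2)
  expect_lte(select_k_elbow(noise, 1:8, seed = 5)$k, 2)
  expect_error(select_k_elbow(x, 1:2, seed = 1), "at least 3")
})

test_that("cluster labeling ranks composites with documented tie-breaks", {
  fake <- function(centers) {
    structure(list(k = 3L, centers = centers,
                   standardizer = list(center = c(0, 0), scale = c(1, 1))),
              class = "hq_kmeans")
  }
  lab <- label_clusters(fake(rbind(c(1, 1), c(0, 0), c(-1, -1))))
  expect_equal(unname(lab), c(1L, 2L, 3L))
  # composite ties -> higher clarity wins high
  expect_message(
    lab2 <- label_clusters(fake(rbind(c(1, -1), c(-1, 1), c(0, 0)))),
    "ties")
  expect_equal(unname(lab2[c("2", "3", "1")]), c(1L, 2L, 3L))
  expect_setequal(unname(lab2), 1:3)  # bijection
})

test_that("labeling is invariant to cluster index permutation", {
  set.seed(21)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 3, 0.3), 20, 2),
             matrix(rnorm(40, 6, 0.3), 20, 2))
  fit <- fit_kmeans(x, 3, seed = 2)
  lab <- label_clusters(fit)
  perm <- c(3L, 1L, 2L)
  fit2 <- fit
  fit2$centers <- fit$centers[order(perm), ]
  fit2$cluster <- perm[fit$cluster]
  lab2 <- label_clusters(fit2)
  expect_equal(unname(lab[as.character(fit$cluster)]),
               unname(lab2[as.character(fit2$cluster)]))
})

test_that("stratified sampling uses round(fraction * n) with a floor of 1", {
  assignments <- data.frame(
    id = sprintf("q%03d", 1:(101 + 169 + 354)),
    cluster = rep(1:3, c(101, 169, 354)))
  ids <- stratified_sample(assignments, 0.10, seed = 8)
  got <- table(assignments$cluster[match(ids, assignments$id)])
  expect_equal(as.vector(got), c(10L, 17L, 35L))
  # fraction 1 returns everything, shuffled
  all_ids <- stratified_sample(assignments, 1, seed = 8)
  expect_setequal(all_ids, assignments$id)
  expect_false(identical(all_ids, assignments$id))
  # determinism
  expect_identical(stratified_sample(assignments, 0.1, seed = 3),
                   stratified_sample(assignments, 0.1, seed = 3))
  # tiny cluster still contributes one
  tiny <- data.frame(id = c("a", "b", "c"), cluster = c(1, 2, 2))
  expect_true(any(c("a") %in% stratified_sample(tiny, 0.1, seed = 1)))
  expect_error(stratified_sample(tiny[0, ], 0.1), "nonempty")
})

test_that("prediction assigns new points to the nearest learned centroid", {
  set.seed(30)
  x <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 5, 0.2), 20, 2))
  fit <- fit_kmeans(x, 2, seed = 1)
  pr <- predict(fit, x)
  expect_equal(pr, fit$cluster)
})
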