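test_that("intercept-only coefficients equal log count ratios", {
  d <- data.frame(quality = factor(rep(c("high", "average", "low"),
                                       c(101, 169, 354)),
                                   levels = c("high", "average", "low")))
  fit <- fit_multinomial(quality ~ 1, d, reference = "high")
  expect_equal(unname(coef(fit)[1, ]),
               c(log(169 / 101), log(354 / 101)), tolerance = 1e-6)
  expect_equal(colnames(coef(fit)), c("average vs high", "low vs high"))
})

test_that("a two-level outcome reduces to binary logistic regression", {
  set.seed(31)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  eta <- -0.4 + 0.9 * d$x1 - 0.7 * d$x2
  d$y <- factor(ifelse(runif(n) < plogis(eta), "case", "control"),
                levels = c("control", "case"))
  fit <- fit_multinomial(y ~ x1 + x2, d)
  ref <- glm(y ~ x1 + x2, binomial(), d)
  expect_equal(unname(coef(fit)[, 1]), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(as.vector(fit$se)),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
})

test_that("three-level fits agree with an independent multinomial solver", {
  set.seed(32)
  n <- 400
  d <- data.frame(x = rnorm(n), b = rbinom(n, 1, 0.5))
  eta2 <- 0.3 + 0.8 * d$x - 0.5 * d$b
  eta3 <- -0.2 - 0.6 * d$x + 0.9 * d$b
  p <- cbind(1, exp(eta2), exp(eta3))
  p <- p / rowSums(p)
  d$y <- factor(apply(p, 1, function(pr) sample(c("high", "avg", "low"),
                                                1, prob = pr)),
                levels = c("high", "avg", "low"))
  fit <- fit_multinomial(y ~ x + b, d, reference = "high")
  ref <- nnet::multinom(y ~ x + b, d, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(coef(fit)), unname(t(coef(ref))), tolerance = 1e-4)
})

test_that("fitted probabilities sum to one and the log-likelihood is monotone", {
  set.seed(33)
  d <- data.frame(x = rnorm(150),
                  y = factor(sample(c("a", "b", "c"), 150, TRUE)))
  fit <- fit_multinomial(y ~ x, d)
  expect_true(all(abs(rowSums(fit$fitted) - 1) < 1e-10))
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_equal(as.numeric(logLik(fit)),
               sum(log(fit$fitted[cbind(seq_len(150),
                                        as.integer(d$y))])),
               tolerance = 1e-8)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  d <- data.frame(y = factor(rep(c("a", "b", "c"), 10)),
                  x1 = rnorm(30))
  d$x2 <- 2 * d$x1
  expect_error(fit_multinomial(y ~ x1 + x2, d), "x2")
})

test_that("quasi-complete separation is detected, flagged and ridge-stabilized", {
  d <- data.frame(x = c(1, 2, 3, 4, 5, 6),
                  y = factor(rep(c("lo", "hi"), each = 3)))
  expect_warning(fit <- fit_multinomial(y ~ x, d), "separation")
  expect_true(length(fit$separation) > 0)
  expect_gt(abs(coef(fit)["x", 1]), 10)
  # ridge tames the fit; shrinking lambda lets the coefficient diverge
  lams <- c(1, 0.1, 0.01)
  coefs <- vapply(lams, function(l) {
    suppressWarnings(suppressMessages(
      abs(coef(fit_multinomial(y ~ x, d, ridge = l))["x", 1])))
  }, numeric(1))
  expect_true(all(diff(coefs) > 0))
  expect_lt(coefs[1], abs(coef(fit)["x", 1]))
})

test_that("planted coefficients are recovered with nominal Wald coverage", {
  spec <- synthetic_spec(n_per_platform = c(community = 1000, expert = 1000))
  preds <- rownames(spec$beta)[-1]
  fml <- reformulate(preds, response = "quality")
  n_seeds <- 30
  inside <- total <- 0
  sign_ok <- sign_tot <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    codes <- generate_codes(spec)
    tiers <- healthqq:::hq_plant_tiers(codes, spec)
    codes$quality <- factor(c("high", "average", "low")[tiers],
                            levels = c("high", "average", "low"))
    fit <- fit_multinomial(fml, codes, reference = "high")
    ci <- confint(fit)
    truth <- as.vector(spec$beta)
    inside <- inside + sum(ci[, 1] <= truth & truth <= ci[, 2])
    total <- total + length(truth)
    big <- abs(spec$beta) >= 0.5 & rownames(spec$beta) != "(Intercept)"
    sign_ok <- sign_ok + sum(sign(coef(fit))[big] == sign(spec$beta)[big])
    sign_tot <- sign_tot + sum(big)
  }
  expect_gte(inside / total, 0.90)
  expect_gte(sign_ok / sign_tot, 0.95)
})

test_that("model methods: predict, simulate, residuals, confint", {
  set.seed(34)
  d <- data.frame(x = rnorm(200),
                  y = factor(sample(c("a", "b", "c"), 200, TRUE,
                                    prob = c(0.5, 0.3, 0.2))))
  fit <- fit_multinomial(y ~ x, d)
  P <- predict(fit)
  expect_equal(dim(P), c(200L, 3L))
  expect_equal(predict(fit, d), P, tolerance = 1e-12, ignore_attr = TRUE)
  cls <- predict(fit, type = "class")
  expect_s3_class(cls, "factor")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(200L, 2L))
  r <- residuals(fit)
  expect_equal(rowSums(r), rep(0, 200), tolerance = 1e-10)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < ci[, 2]))
  s <- summary(fit)
  expect_true(all(c("contrast", "term", "estimate", "se", "z", "p") %in%
                    names(s$coefficients)))
})
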