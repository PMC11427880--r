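#' Multinomial logistic regression of question quality
#'
#' Maximum-likelihood softmax regression fitted by Newton-Raphson with
#' step halving, expressing every non-reference quality level as a
#' log-odds contrast against the reference level (high quality by
#' convention, so coefficients read as "average vs high" and "low vs
#' high"). Standard errors come from the inverse observed information.
#' Quasi-complete separation -- a predictor that perfectly splits
#' outcome levels, driving its coefficient to infinity while the
#' likelihood plateaus -- is detected and the affected terms flagged;
#' an optional ridge penalty stabilizes such fits.
#'
#' @param formula Model formula, e.g. `quality ~ demographic_info +
#'   word_count`.
#' @param data Data frame containing the outcome and predictors.
#' @param reference Outcome level used as the reference; defaults to
#'   the first factor level (level `1` = high quality under the 1/2/3
#'   coding).
#' @param ridge Ridge penalty strength `lambda >= 0` on non-intercept
#'   coefficients (0 = plain maximum likelihood). A nonzero value is
#'   reported in the fit summary.
#' @param max_iter Maximum Newton iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param sep_threshold Absolute coefficient size beyond which a term
#'   is flagged as separation-affected.
#' @return An object of class `hq_multinom` with components
#'   `coefficients` (terms x contrasts matrix), `se`, `vcov`,
#'   `logLik`, `loglik_trace`, `converged`, `separation` (character
#'   vector of flagged "contrast:term" entries), `levels`, `reference`,
#'   `fitted` (n x K probability matrix), and the usual `coef`,
#'   `summary`, `predict`, `vcov`, `logLik`, `confint`, `simulate`,
#'   `residuals` methods.
#' @examples
#' d <- data.frame(quality = factor(rep(c("high", "average", "low"),
#'                                      c(30, 40, 50))))
#' coef(fit_multinomial(quality ~ 1, d))  # log(n_j / n_ref)
#' @export
fit_multinomial <- function(formula, data, reference = NULL, ridge = 0,
                            max_iter = 200L, tol = 1e-10,
                            sep_threshold = 10) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- droplevels(as.factor(stats::model.response(mf)))
  if (!is.null(reference)) {
    hq_assert(as.character(reference) %in% levels(y),
              "reference level '", reference, "' not present in outcome")
    y <- stats::relevel(y, ref = as.character(reference))
  }
  K <- nlevels(y)
  hq_assert(K >= 2L, "outcome must have at least 2 observed levels")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    hq_stop("design matrix is rank deficient; collinear columns: ",
            paste(bad, collapse = ", "))
  }
  hq_assert(n > p, "need more observations (", n, ") than parameters per ",
            "contrast (", p, ")")

  Ymat <- 1 * outer(as.integer(y), 2:K, "==")      # n x (K-1)
  is_intercept <- colnames(X) == "(Intercept)"
  pen_mask <- rep(!is_intercept, K - 1L)           # ridge skips intercepts

  B <- matrix(0, p, K - 1L)
  softmax <- function(B) {
    eta <- cbind(0, X %*% B)
    eta <- eta - apply(eta, 1, max)
    e <- exp(eta)
    e / rowSums(e)
  }
  pen_ll <- function(B, P) {
    sum(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-300))) -
      ridge / 2 * sum((as.vector(B)[pen_mask])^2)
  }

  P <- softmax(B)
  ll <- pen_ll(B, P)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    G <- crossprod(X, Ymat - P[, -1, drop = FALSE])          # p x (K-1)
    g <- as.vector(G)
    g[pen_mask] <- g[pen_mask] - ridge * as.vector(B)[pen_mask]
    H <- hq_multinom_info(X, P, K)                           # observed info
    diag(H)[pen_mask] <- diag(H)[pen_mask] + ridge
    step <- tryCatch(solve(H, g), error = function(e) hq_pinv(H) %*% g)
    # step halving keeps the (penalized) log-likelihood nondecreasing
    alpha <- 1
    repeat {
      Bnew <- B + alpha * matrix(step, p, K - 1L)
      Pnew <- softmax(Bnew)
      llnew <- pen_ll(Bnew, Pnew)
      if (llnew >= ll - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    rel <- abs(llnew - ll) / (abs(ll) + 1e-10)
    B <- Bnew; P <- Pnew; ll <- llnew
    trace <- c(trace, ll)
    if (rel < tol || max(abs(g)) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    cond <- structure(
      class = c("healthqq_nonconvergence", "error", "condition"),
      list(message = paste0("multinomial fit did not converge in ",
                            max_iter, " iterations"),
           call = sys.call(-1),
           coefficients = B, logLik = ll, trace = trace))
    stop(cond)
  }

  H <- hq_multinom_info(X, P, K)
  diag(H)[pen_mask] <- diag(H)[pen_mask] + ridge
  V <- tryCatch(solve(H), error = function(e) hq_pinv(H))
  se <- matrix(sqrt(pmax(diag(V), 0)), p, K - 1L)

  contrasts <- paste(levels(y)[-1], "vs", levels(y)[1])
  dimnames(B) <- dimnames(se) <- list(colnames(X), contrasts)
  param_names <- as.vector(outer(colnames(X), contrasts,
                                 function(t, c) paste0(c, ":", t)))
  dimnames(V) <- list(param_names, param_names)

  sep <- param_names[abs(as.vector(B)) > sep_threshold]
  if (length(sep)) {
    warning("possible quasi-complete separation; inflated coefficients: ",
            paste(sep, collapse = ", "),
            if (ridge == 0) " (consider a ridge penalty)" else "")
  }
  if (ridge > 0) {
    message(sprintf("ridge penalty applied: lambda = %g", ridge))
  }

  structure(list(coefficients = B, se = se, vcov = V,
                 logLik = ll + if (ridge > 0)
                   ridge / 2 * sum((as.vector(B)[pen_mask])^2) else 0,
                 loglik_trace = trace, converged = converged,
                 iterations = it, separation = sep, ridge = ridge,
                 levels = levels(y), reference = levels(y)[1],
                 fitted = P, y = y, terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 call = match.call(), n = n),
            class = "hq_multinom")
}

# observed information of the multinomial log-likelihood (block matrix)
hq_multinom_info <- function(X, P, K) {
  p <- ncol(X)
  H <- matrix(0, p * (K - 1L), p * (K - 1L))
  for (j in 2:K) {
    for (k in j:K) {
      w <- if (j == k) P[, j] * (1 - P[, j]) else -P[, j] * P[, k]
      blk <- crossprod(X, X * w)
      rj <- ((j - 2L) * p + 1L):((j - 1L) * p)
      rk <- ((k - 2L) * p + 1L):((k - 1L) * p)
      H[rj, rk] <- blk
      if (j != k) H[rk, rj] <- t(blk)
    }
  }
  H
}

# Moore-Penrose pseudo-inverse via SVD (for near-singular information)
hq_pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
coef.hq_multinom <- function(object, ...) object$coefficients

#' @export
vcov.hq_multinom <- function(object, ...) object$vcov

#' @export
logLik.hq_multinom <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
print.hq_multinom <- function(x, ...) {
  cat("Multinomial logistic regression (reference level: ",
      x$reference, ")\n", sep = "")
  cat(sprintf("n = %d, log-likelihood = %.4f, %d iterations%s\n",
              x$n, x$logLik, x$iterations,
              if (x$ridge > 0) sprintf(", ridge lambda = %g", x$ridge) else ""))
  print(round(x$coefficients, 4))
  if (length(x$separation)) {
    cat("Separation-flagged terms:", paste(x$separation, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.hq_multinom <- function(object, ...) {
  B <- object$coefficients
  se <- object$se
  z <- B / se
  pval <- 2 * stats::pnorm(-abs(z))
  tidy <- do.call(rbind, lapply(colnames(B), function(ct) {
    data.frame(contrast = ct, term = rownames(B),
               estimate = B[, ct], se = se[, ct], z = z[, ct],
               p = pval[, ct],
               flag = ifelse(paste0(ct, ":", rownames(B)) %in%
                               object$separation, "separation", ""),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  structure(list(coefficients = tidy, logLik = object$logLik,
                 reference = object$reference, n = object$n,
                 ridge = object$ridge, separation = object$separation),
            class = "summary.hq_multinom")
}

#' @export
print.summary.hq_multinom <- function(x, ...) {
  cat("Multinomial logistic regression (reference level: ",
      x$reference, "), n = ", x$n, "\n", sep = "")
  df <- x$coefficients
  df$estimate <- sprintf("%.4f", df$estimate)
  df$se <- sprintf("%.4f", df$se)
  df$z <- sprintf("%.2f", df$z)
  df$p <- format.pval(df$p, digits = 3, eps = 1e-16)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
predict.hq_multinom <- function(object, newdata = NULL,
                                type = c("probs", "class"), ...) {
  type <- match.arg(type)
  P <- if (is.null(newdata)) {
    object$fitted
  } else {
    Terms <- stats::delete.response(object$terms)
    X <- stats::model.matrix(Terms, stats::model.frame(
      Terms, newdata, xlev = object$xlevels))
    eta <- cbind(0, X %*% object$coefficients)
    eta <- eta - apply(eta, 1, max)
    e <- exp(eta)
    e / rowSums(e)
  }
  colnames(P) <- object$levels
  if (type == "probs") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' @export
residuals.hq_multinom <- function(object, ...) {
  Y <- 1 * outer(as.integer(object$y), seq_along(object$levels), "==")
  colnames(Y) <- object$levels
  Y - object$fitted
}

#' @export
confint.hq_multinom <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  B <- as.vector(object$coefficients)
  se <- as.vector(object$se)
  out <- cbind(B - zq * se, B + zq * se)
  rownames(out) <- rownames(object$vcov)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
simulate.hq_multinom <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- object$fitted
  out <- as.data.frame(replicate(nsim, {
    idx <- apply(P, 1, function(pr) sample.int(length(pr), 1L, prob = pr))
    factor(object$levels[idx], levels = object$levels)
  }, simplify = FALSE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
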