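# Single-SNP scans and joint multi-SNP fits supplying (b, V) to the
# proportional test.

#' Single-SNP association scan
#'
#' Fits one univariate regression per SNP (logistic for a binary trait,
#' linear for a quantitative trait), each with an intercept, and reports
#' Wald p-values. The most-associated SNP is the one with the smallest
#' p-value, ties broken by SNP order. Monomorphic SNPs get p = 1 with a
#' warning; logistic fits showing separation or non-convergence fall back
#' to the score test and are flagged.
#'
#' @param g a fully observed [genotype_matrix()].
#' @param y the paired [trait_vector()].
#' @return A `scan_result`: data frame with columns `snp`, `estimate`,
#'   `se`, `p`, `flag`, plus attribute `top` (index of the most-associated
#'   SNP).
#' @export
single_snp_scan <- function(g, y) {
  check_paired(g, y)
  d <- g$dosages
  if (anyNA(d)) stop_validation("genotypes must be imputed before scanning")
  p <- ncol(d)
  yy <- y$values
  mono <- apply(d, 2, stats::var) == 0
  if (y$kind == "quantitative") {
    res <- scan_quantitative(d, yy)
  } else {
    res <- scan_binary(d, yy)
  }
  if (any(mono)) {
    warning("monomorphic SNP(s), p set to 1: ",
            paste(snp_ids(g)[mono], collapse = ", "))
    res$estimate[mono] <- 0
    res$se[mono] <- NA_real_
    res$p[mono] <- 1
    res$flag[mono] <- "monomorphic"
  }
  res$p[res$p <= 0] <- .Machine$double.xmin
  tab <- data.frame(snp = snp_ids(g), estimate = res$estimate, se = res$se,
                    p = res$p, flag = res$flag, stringsAsFactors = FALSE)
  structure(tab, top = unname(which.min(res$p)),
            class = c("scan_result", "data.frame"))
}

# Closed-form simple linear regression across all SNPs at once.
scan_quantitative <- function(d, y) {
  n <- length(y)
  xc <- sweep(d, 2, colMeans(d))
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  beta <- ifelse(sxx > 0, sxy / sxx, 0)
  rss <- sum(yc^2) - beta^2 * sxx
  sigma2 <- rss / (n - 2)
  se <- sqrt(ifelse(sxx > 0, sigma2 / sxx, NA))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  list(estimate = beta, se = se, p = pval,
       flag = rep("", ncol(d)))
}

# Univariate logistic IRLS run for all SNPs simultaneously: each SNP's
# 2 x 2 weighted normal equations have a closed form, so the whole scan is
# elementwise matrix arithmetic (epsilon 1e-8, maxit 50, as in the joint
# fits). Separation or non-convergence falls back to the score test.
scan_binary <- function(d, y, epsilon = 1e-12, maxit = 50) {
  n <- nrow(d); p <- ncol(d)
  a <- rep(stats::qlogis(mean(y)), p)   # intercepts
  b <- rep(0, p)                        # slopes
  dev_old <- rep(Inf, p)
  converged <- rep(FALSE, p)
  for (it in seq_len(maxit)) {
    eta <- sweep(d * rep(b, each = n), 2, a, "+")
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / pmax(w, 1e-12)
    s0 <- colSums(w); s1 <- colSums(w * d); s2 <- colSums(w * d^2)
    t0 <- colSums(w * z); t1 <- colSums(w * d * z)
    det <- s0 * s2 - s1^2
    ok <- det > 1e-12 * pmax(s0 * s2, 1e-300)
    a[ok] <- ((s2 * t0 - s1 * t1) / det)[ok]
    b[ok] <- ((s0 * t1 - s1 * t0) / det)[ok]
    dev <- -2 * colSums(y * log(pmax(mu, 1e-300)) +
                          (1 - y) * log(pmax(1 - mu, 1e-300)))
    converged <- abs(dev - dev_old) / (abs(dev) + 0.1) < epsilon
    if (all(converged)) break
    dev_old <- dev
  }
  eta <- sweep(d * rep(b, each = n), 2, a, "+")
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  s0 <- colSums(w); s1 <- colSums(w * d); s2 <- colSums(w * d^2)
  det <- s0 * s2 - s1^2
  se <- sqrt(ifelse(det > 0, s0 / det, NA))
  separated <- apply(mu, 2, function(m) any(m > 1 - 1e-8 | m < 1e-8))
  bad <- !converged | separated | !is.finite(se) | abs(b) > 50
  pv <- 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
  flag <- rep("", p)
  if (any(bad)) {
    for (j in which(bad)) pv[j] <- logistic_score_test(d[, j], y)
    se[bad] <- NA_real_
    flag[bad] <- "score_fallback"
  }
  list(estimate = b, se = se, p = pv, flag = flag)
}

# IRLS logistic regression; returns ok = FALSE on separation or
# non-convergence so callers can fall back to a score test.
logistic_fit <- function(X, y, epsilon = 1e-8, maxit = 50) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon, maxit = maxit)))
  mu <- fit$fitted.values
  separated <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
  k <- fit$rank
  p1 <- seq_len(k)
  V <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  b <- fit$coefficients
  list(b = b, se = sqrt(diag(V))[seq_along(b)], V = V,
       loglik = k - fit$aic / 2, rank = k,
       ok = fit$converged && !separated, qr = fit$qr)
}

logistic_score_test <- function(x, y) {
  ybar <- mean(y)
  u <- sum(x * (y - ybar))
  v <- ybar * (1 - ybar) * sum((x - mean(x))^2)
  if (v <= 0) return(1)
  stats::pchisq(u^2 / v, df = 1, lower.tail = FALSE)
}

#' Joint multi-SNP (or multi-component) regression fit
#'
#' Maximum-likelihood multiple regression of a trait on a set of SNP
#' dosages or principal-component scores, with an intercept. The returned
#' coefficient vector and covariance exclude the intercept; these are the
#' `(b, V)` pairs consumed by the proportional test. Aliased (linearly
#' dependent) columns are dropped with a warning.
#'
#' @param x a [genotype_matrix()], or a numeric matrix of regressor scores
#'   with column names.
#' @param y the paired [trait_vector()].
#' @param ids identifiers of the columns to include (default: all).
#' @return A `regression_fit`: list with `ids`, `b`, `V`, `kind`, `n`,
#'   `loglik`, `bic` (computed as `-2 loglik + (q + 1) log n`).
#' @export
fit_joint <- function(x, y, ids = NULL) {
  scores <- if (inherits(x, "genotype_matrix")) x$dosages else as.matrix(x)
  if (inherits(x, "genotype_matrix") && anyNA(scores))
    stop_validation("genotypes must be imputed before fitting")
  if (is.null(ids)) ids <- colnames(scores)
  ids <- as.character(ids)
  miss <- setdiff(ids, colnames(scores))
  if (length(miss) > 0)
    stop_validation("unknown regressor id(s): ", paste(miss, collapse = ", "))
  if (length(y$values) != nrow(scores))
    stop_validation("trait length does not match sample count")
  X <- scores[, ids, drop = FALSE]
  # drop duplicated ids and aliased columns via pivoted QR of [1 X]
  if (anyDuplicated(ids)) {
    warning("duplicated regressor id(s) dropped")
    keep <- !duplicated(ids)
    ids <- ids[keep]; X <- X[, keep, drop = FALSE]
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    aliased <- setdiff(colnames(Xd)[qrd$pivot[-seq_len(qrd$rank)]], "(Intercept)")
    warning("aliased column(s) dropped: ", paste(aliased, collapse = ", "))
    ids <- setdiff(ids, aliased)
    if (length(ids) == 0) stop_validation("no regressors left after dropping aliased columns")
    X <- X[, ids, drop = FALSE]
    Xd <- cbind(`(Intercept)` = 1, X)
  }
  n <- nrow(Xd)
  q <- length(ids)
  if (y$kind == "quantitative") {
    fit <- stats::lm.fit(Xd, y$values)
    rss <- sum(fit$residuals^2)
    k <- fit$rank
    sigma2 <- rss / (n - k)
    R <- qr.R(fit$qr)
    Vfull <- chol2inv(R) * sigma2
    b <- fit$coefficients
    loglik <- -n / 2 * (log(2 * pi * rss / n) + 1)
  } else {
    lf <- logistic_fit(Xd, y$values)
    b <- lf$b
    Vfull <- lf$V
    loglik <- lf$loglik
  }
  keep <- seq_along(b)[-1]
  V <- Vfull[keep, keep, drop = FALSE]
  V <- (V + t(V)) / 2
  bic <- -2 * loglik + (q + 1) * log(n)
  structure(list(ids = ids, b = unname(b[-1]), V = unname(V),
                 trait_kind = y$kind, n = n, loglik = loglik, bic = bic),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: %s trait, n = %d, q = %d, BIC = %.2f\n",
              x$trait_kind, x$n, length(x$b), x$bic))
  invisible(x)
}

#' Randomly partition a shared control set in two
#'
#' Proportional testing assumes `Cov(b1, b2) = 0`, which fails when two
#' case-control cohorts share controls. This utility splits a shared
#' control set into two disjoint halves, one per cohort.
#'
#' @param control_ids character vector of control sample identifiers.
#' @param seed integer seed.
#' @return A list of two disjoint identifier vectors covering the input.
#' @export
split_controls <- function(control_ids, seed = 1) {
  control_ids <- unique(as.character(control_ids))
  with_seed(seed, {
    n <- length(control_ids)
    first <- sample(n, floor(n / 2))
    list(group1 = control_ids[first], group2 = control_ids[-first])
  })
}
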