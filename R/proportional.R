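# Proportional colocalisation core: Fieller statistic, profile test,
# theta-posterior, posterior predictive p-value and eta credible interval.
#
# The null of colocalisation states that the joint regression coefficients
# for the two traits are proportional: beta1 = beta2 / eta. The test
# statistic derives from Fieller's theorem,
#   T(eta)^2 = u' V^-1 u,  u = b1 - b2 / eta,  V = V1 + V2 / eta^2,
# which is chi-squared on q degrees of freedom for known eta. Everything
# here works in the angular parametrisation theta = atan(eta), where
#   u(theta) = b1 sin(theta) - b2 cos(theta),
#   V(theta) = V1 sin^2(theta) + V2 cos^2(theta),
# algebraically identical to the eta-form (multiply u by sin(theta)) but
# finite at eta = 0 and eta = +/- infinity, and periodic with period pi.

# Simultaneous diagonalisation: W with W' B W = I and W' A W = diag(lam).
# Lets the whole theta grid be evaluated in O(q) per point.
gen_eigen <- function(A, B) {
  R <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Linv <- function(x) forwardsolve(t(R), x)
  M <- Linv(t(Linv(A)))
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  W <- backsolve(R, e$vectors)
  list(W = W, lambda = e$values)
}

fieller_decomp <- function(b1, V1, b2, V2) {
  b1 <- as.numeric(b1); b2 <- as.numeric(b2)
  V1 <- as.matrix(V1); V2 <- as.matrix(V2)
  q <- length(b1)
  if (length(b2) != q || any(dim(V1) != q) || any(dim(V2) != q))
    stop_validation("dimension mismatch between coefficient vectors and covariances")
  ge <- gen_eigen(V1, V2)
  if (!is.null(ge)) {
    # den(theta) = lambda sin^2 + cos^2
    return(list(a = drop(crossprod(ge$W, b1)), d = drop(crossprod(ge$W, b2)),
                lambda = ge$lambda, swapped = FALSE, q = q))
  }
  ge <- gen_eigen(V2, V1)
  if (is.null(ge))
    stop_numeric("V1 + V2 not positive definite (condition numbers: ",
                 format(kappa(V1), digits = 3), ", ",
                 format(kappa(V2), digits = 3), ")")
  list(a = drop(crossprod(ge$W, b1)), d = drop(crossprod(ge$W, b2)),
       lambda = ge$lambda, swapped = TRUE, q = q)
}

fieller_stat_decomp <- function(dec, theta) {
  s <- sin(theta); cth <- cos(theta)
  u <- outer(dec$a, s) - outer(dec$d, cth)       # q x n_theta
  den <- if (!dec$swapped) outer(dec$lambda, s^2) + rep(cth^2, each = dec$q)
         else outer(dec$lambda, cth^2) + rep(s^2, each = dec$q)
  if (any(den <= .Machine$double.eps * max(den)))
    stop_numeric("V(theta) numerically singular at some requested angle(s); ",
                 "condition of the generalized spectrum: ",
                 format(max(dec$lambda) / max(min(dec$lambda), 1e-300), digits = 3))
  colSums(u^2 / den)
}

#' Fieller proportionality statistic
#'
#' Evaluates `T(theta)^2 = u(theta)' V(theta)^-1 u(theta)` with
#' `u(theta) = b1 sin(theta) - b2 cos(theta)` and
#' `V(theta) = V1 sin^2(theta) + V2 cos^2(theta)`, the angular form of the
#' Fieller ratio statistic at `eta = tan(theta)`. Vectorised over `theta`.
#'
#' @param b1,b2 coefficient vectors of equal length `q`.
#' @param V1,V2 `q x q` coefficient covariance matrices; `V1 + V2` must be
#'   positive definite.
#' @param theta angle(s) in `(-pi/2, pi/2]` (any real value is accepted;
#'   the statistic has period `pi`).
#' @return Non-negative statistic value(s), one per `theta`.
#' @export
fieller_stat <- function(b1, V1, b2, V2, theta) {
  dec <- fieller_decomp(b1, V1, b2, V2)
  fieller_stat_decomp(dec, theta)
}

theta_grid_default <- function(n_grid) {
  h <- pi / n_grid
  seq(-pi / 2 + h, pi / 2, by = h)[seq_len(n_grid)]
}

check_fit_pair <- function(f1, f2) {
  if (!identical(f1$ids, f2$ids))
    stop_validation("the two fits must cover identical regressors in identical order")
  length(f1$b)
}

#' Profile Fieller test of proportionality
#'
#' Replaces `eta` by its maximum-likelihood estimate, which also minimises
#' `T(eta)^2`; the minimised statistic is referred to a chi-squared
#' distribution on `q - 1` degrees of freedom. The minimum is located on a
#' coarse `theta` grid and refined by golden-section search.
#'
#' @param f1,f2 `regression_fit` objects over identical regressors.
#' @param n_grid number of coarse grid points on `(-pi/2, pi/2]`.
#' @param tol golden-section convergence tolerance on `theta`.
#' @return List with `eta_hat`, `theta_hat`, `stat`, `df`, `p_profile`.
#' @export
profile_test <- function(f1, f2, n_grid = 1000, tol = 1e-8) {
  q <- check_fit_pair(f1, f2)
  dec <- fieller_decomp(f1$b, f1$V, f2$b, f2$V)
  if (q == 1) {
    warning("profile test undefined for q = 1 (statistic identically 0)")
    th <- atan2(f2$b, f1$b)
    return(list(eta_hat = tan(th), theta_hat = th, stat = 0, df = 0,
                p_profile = 1))
  }
  grid <- theta_grid_default(n_grid)
  vals <- fieller_stat_decomp(dec, grid)
  i <- which.min(vals)
  h <- pi / n_grid
  lo <- grid[i] - h
  hi <- grid[i] + h
  th <- golden_min(function(t) fieller_stat_decomp(dec, t), lo, hi, tol)
  th_wrapped <- th - pi * floor((th + pi / 2) / pi)  # back to (-pi/2, pi/2]
  if (th_wrapped <= -pi / 2) th_wrapped <- th_wrapped + pi
  stat <- fieller_stat_decomp(dec, th)
  list(eta_hat = tan(th_wrapped), theta_hat = th_wrapped, stat = stat,
       df = q - 1,
       p_profile = stats::pchisq(stat, df = q - 1, lower.tail = FALSE))
}

golden_min <- function(f, lo, hi, tol) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

# log prior on theta implied by a Cauchy(0, k) prior on eta = tan(theta):
# p(theta) = k / (pi (k^2 cos^2 + sin^2)); uniform when k = 1.
log_theta_prior <- function(theta, k) {
  log(k) - log(pi) - log(k^2 * cos(theta)^2 + sin(theta)^2)
}

#' Posterior distribution of the proportionality angle theta
#'
#' Under the null, `(b1; b2)` is Gaussian with mean
#' `(beta cos(theta); beta sin(theta))` and block covariance
#' `diag(V1, V2)`. The common coefficient vector `beta` is marginalised
#' analytically under a flat improper prior, leaving a marginal likelihood
#' for `theta` that is multiplied by the prior implied by a Cauchy(0,
#' `prior_scale`) prior on `eta` (`prior_scale = 1` gives a uniform prior
#' on `theta`) and normalised by the trapezoid rule on the grid.
#'
#' @param f1,f2 `regression_fit` objects over identical regressors.
#' @param prior_scale Cauchy scale `k` of the prior on `eta`; default 1.
#' @param n_grid number of grid points on `(-pi/2, pi/2]`; default 1001.
#' @return A `theta_posterior`: list with `grid`, `density`, `prior_scale`,
#'   `q`, plus the fit pair needed downstream.
#' @export
theta_posterior <- function(f1, f2, prior_scale = 1, n_grid = 1001) {
  q <- check_fit_pair(f1, f2)
  if (prior_scale <= 0) stop_validation("prior_scale must be positive")
  U1 <- chol2inv(chol(f1$V))
  U2 <- chol2inv(chol(f2$V))
  ge <- gen_eigen(U1, U2)
  if (is.null(ge)) stop_numeric("coefficient precision matrices not positive definite")
  g1 <- drop(crossprod(ge$W, U1 %*% f1$b))
  g2 <- drop(crossprod(ge$W, U2 %*% f2$b))
  log_unnorm <- function(theta) {
    s <- sin(theta); cth <- cos(theta)
    # A' Sigma^-1 A = cos^2 U1 + sin^2 U2 -> diagonal lam cos^2 + sin^2 in
    # the transformed basis; marginal log-likelihood per grid point:
    den <- outer(ge$lambda, cth^2) + rep(s^2, each = q)
    num <- (outer(g1, cth) + outer(g2, s))^2
    -colSums(log(den)) / 2 + colSums(num / den) / 2 +
      log_theta_prior(theta, prior_scale)
  }
  grid <- theta_grid_default(n_grid)
  logpost <- log_unnorm(grid)
  if (any(!is.finite(logpost)))
    stop_numeric("non-finite marginal likelihood on the theta grid")
  dens <- exp(logpost - max(logpost))
  # with very precise coefficients the posterior can be narrower than the
  # grid spacing; refine around the mode so quadrature stays accurate
  h <- pi / n_grid
  rc <- recentre_on_mode(grid, dens)
  w <- rc$density / sum(rc$density)
  mu <- sum(w * rc$theta)
  sigma <- sqrt(sum(w * (rc$theta - mu)^2))
  if (sigma < 5 * h) {
    fine <- seq(rc$mode - 10 * (sigma + h / 4), rc$mode + 10 * (sigma + h / 4),
                length.out = 2001)
    fine <- fine - pi * floor((fine + pi / 2) / pi)  # back into (-pi/2, pi/2]
    grid <- sort(unique(c(grid, fine)))
    logpost <- log_unnorm(grid)
    dens <- exp(logpost - max(logpost))
  }
  dens <- dens / trapz(grid, dens)
  structure(list(grid = grid, density = dens, prior_scale = prior_scale,
                 q = q), class = "theta_posterior")
}

#' Posterior predictive p-value for proportionality
#'
#' Averages the known-`eta` Fieller p-value `T*(theta)` -- the upper-tail
#' chi-squared(`q`) probability of `T(theta)^2` -- over the posterior of
#' `theta`: `ppp = integral of T*(theta) P(theta | b1, b2) d theta`.
#'
#' @param posterior a [theta_posterior()] built from the same fits.
#' @param f1,f2 the `regression_fit` pair.
#' @return A p-value in `[0, 1]`.
#' @export
ppp_value <- function(posterior, f1, f2) {
  q <- check_fit_pair(f1, f2)
  if (!inherits(posterior, "theta_posterior") || posterior$q != q)
    stop_validation("posterior was not built from fits of this dimension")
  dec <- fieller_decomp(f1$b, f1$V, f2$b, f2$V)
  tstar <- stats::pchisq(fieller_stat_decomp(dec, posterior$grid), df = q,
                         lower.tail = FALSE)
  min(max(trapz(posterior$grid, tstar * posterior$density), 0), 1)
}

# Rotate a periodic density grid so the mode sits centrally; returns
# strictly increasing theta values covering one full period around the
# mode. Works for non-uniform grids: the cut is made at the angle
# antipodal to the mode.
recentre_on_mode <- function(grid, density) {
  i_mode <- which.max(density)
  centre <- grid[i_mode]
  offset <- (grid - (centre - pi / 2)) %% pi    # position in [0, pi)
  o <- order(offset)
  list(theta = centre - pi / 2 + offset[o], density = density[o],
       mode = centre)
}

#' Credible interval for the proportionality coefficient eta
#'
#' Central credible interval from the theta-posterior: the grid is
#' recentred on the posterior mode (the density has period pi, so the
#' interval never straddles the artificial boundary at theta = +/- pi/2),
#' theta quantiles are read off the cumulative trapezoid distribution and
#' mapped through `tan`. `eta = 0` means no effect on trait 1 given an
#' effect on trait 2; `eta = 1` means equal effects.
#'
#' @param posterior a [theta_posterior()].
#' @param level interval mass, in `(0, 1)`; default 0.95.
#' @return List with `lower`, `upper` (on the eta scale), `theta_lower`,
#'   `theta_upper`, `contains_zero`, `contains_one`, `wraps` (`TRUE` if
#'   the theta interval crosses `pi/2`, in which case the eta set is the
#'   complement `(-Inf, upper] U [lower, Inf)`).
#' @export
eta_credible_interval <- function(posterior, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop_validation("level must be a probability in (0, 1)")
  rc <- recentre_on_mode(posterior$grid, posterior$density)
  cdf <- cumtrapz(rc$theta, rc$density)
  cdf <- cdf / cdf[length(cdf)]
  alpha <- (1 - level) / 2
  th_lo <- stats::approx(cdf, rc$theta, xout = alpha, ties = "ordered")$y
  th_hi <- stats::approx(cdf, rc$theta, xout = 1 - alpha, ties = "ordered")$y
  contains <- function(target) {
    # does any point congruent to target (mod pi) fall inside the interval?
    kk <- seq(floor((th_lo - target) / pi), ceiling((th_hi - target) / pi))
    any(target + kk * pi >= th_lo & target + kk * pi <= th_hi)
  }
  wraps <- contains(pi / 2)
  list(lower = tan(th_lo), upper = tan(th_hi),
       theta_lower = th_lo, theta_upper = th_hi,
       contains_zero = contains(0), contains_one = contains(pi / 4),
       wraps = wraps, level = level)
}

#' Full proportional colocalisation test from a pair of fits
#'
#' Runs the profile Fieller test, the theta-posterior, the posterior
#' predictive p-value and the eta credible interval in one call.
#'
#' @param f1,f2 `regression_fit` objects over identical regressors.
#' @param prior_scale Cauchy scale of the eta prior (1 = uniform theta).
#' @param n_grid posterior grid size.
#' @param level credible-interval mass.
#' @return A `prop_test_result`: `eta_hat`, `theta_hat`, `stat`, `df`,
#'   `p_profile`, `ppp`, `posterior`, `eta_ci`, `q`.
#' @export
prop_test <- function(f1, f2, prior_scale = 1, n_grid = 1001, level = 0.95) {
  prof <- profile_test(f1, f2)
  post <- theta_posterior(f1, f2, prior_scale = prior_scale, n_grid = n_grid)
  ppp <- ppp_value(post, f1, f2)
  ci <- eta_credible_interval(post, level = level)
  structure(list(eta_hat = prof$eta_hat, theta_hat = prof$theta_hat,
                 stat = prof$stat, df = prof$df, p_profile = prof$p_profile,
                 ppp = ppp, posterior = post, eta_ci = ci,
                 q = length(f1$b)),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat("Proportional colocalisation test\n")
  cat(sprintf("  regressors (q):     %d\n", x$q))
  cat(sprintf("  T(eta_hat)^2:       %.4g on %d df (profile p = %.4g)\n",
              x$stat, x$df, x$p_profile))
  cat(sprintf("  posterior pred. p:  %.4g\n", x$ppp))
  cat(sprintf("  eta_hat:            %.4g\n", x$eta_hat))
  ci <- x$eta_ci
  cat(sprintf("  %d%% credible int.:  [%.4g, %.4g]%s (eta=0 %s, eta=1 %s)\n",
              round(100 * ci$level), ci$lower, ci$upper,
              if (ci$wraps) " [wraps through infinity]" else "",
              if (ci$contains_zero) "inside" else "outside",
              if (ci$contains_one) "inside" else "outside"))
  invisible(x)
}

#' Serialise a proportional test result to a flat key-value record
#'
#' @param x a `prop_test_result`.
#' @param path output file; tab-delimited `key<TAB>value` lines.
#' @param extra named list of additional keys to record.
#' @return `path`, invisibly.
#' @export
write_prop_result <- function(x, path, extra = list()) {
  rec <- c(list(stat = x$stat, df = x$df, p_profile = x$p_profile,
                ppp = x$ppp, eta_hat = x$eta_hat,
                ci_low = x$eta_ci$lower, ci_high = x$eta_ci$upper,
                ci_level = x$eta_ci$level,
                contains_zero = x$eta_ci$contains_zero,
                contains_one = x$eta_ci$contains_one,
                n_grid = length(x$posterior$grid),
                prior_scale = x$posterior$prior_scale),
           extra)
  lines <- paste(names(rec), vapply(rec, function(v) format(v, digits = 10),
                                    character(1)), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
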