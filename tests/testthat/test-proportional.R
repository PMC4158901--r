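# The Fieller statistic, profile test, theta posterior, posterior
# predictive p-value and credible interval.

test_that("the statistic vanishes under exact proportionality", {
  expect_equal(fieller_stat(2, matrix(1), 1, matrix(1), atan(0.5)), 0,
               tolerance = 1e-12)
  # q = 2, b2 = 2 b1, arbitrary V: zero at theta = atan(2)
  V1 <- rand_pd(2); V2 <- rand_pd(2)
  expect_equal(fieller_stat(c(1, 3), V1, c(2, 6), V2, atan(2)), 0,
               tolerance = 1e-10)
})

test_that("orthogonal unit-variance instance gives a constant statistic", {
  # b1 = (1,0), b2 = (0,1), V1 = V2 = I: u(theta) = (sin, -cos),
  # V(theta) = I, so T^2 = sin^2 + cos^2 = 1 for every theta
  th <- seq(-1.5, 1.5, length.out = 31)
  expect_equal(fieller_stat(c(1, 0), diag(2), c(0, 1), diag(2), th),
               rep(1, 31), tolerance = 1e-12)
})

test_that("theta-form equals the eta-form of the Fieller statistic", {
  set.seed(101)
  for (rep in 1:20) {
    q <- sample(2:4, 1)
    b1 <- rnorm(q); b2 <- rnorm(q)
    V1 <- rand_pd(q); V2 <- rand_pd(q)
    th <- runif(5, 0.05, pi / 2 - 0.05)
    eta_form <- vapply(tan(th), function(eta) {
      u <- b1 - b2 / eta
      V <- V1 + V2 / eta^2
      drop(t(u) %*% solve(V) %*% u)
    }, numeric(1))
    expect_equal(fieller_stat(b1, V1, b2, V2, th), eta_form,
                 tolerance = 1e-8)
  }
})

test_that("the statistic has period pi", {
  set.seed(102)
  b1 <- rnorm(3); b2 <- rnorm(3); V1 <- rand_pd(3); V2 <- rand_pd(3)
  th <- runif(10, -pi / 2, pi / 2)
  expect_equal(fieller_stat(b1, V1, b2, V2, th),
               fieller_stat(b1, V1, b2, V2, th + pi), tolerance = 1e-10)
})

test_that("profile test recovers the null exactly when b2 is proportional to b1", {
  f1 <- make_fit(c(1, 2), rand_pd(2, 0.1))
  f2 <- make_fit(c(2, 4), rand_pd(2, 0.1))
  pr <- profile_test(f1, f2)
  expect_equal(pr$stat, 0, tolerance = 1e-10)
  expect_equal(pr$p_profile, 1, tolerance = 1e-8)
  expect_equal(pr$eta_hat, 2, tolerance = 1e-6)
  expect_equal(pr$df, 1L)
})

test_that("profile test on the constant-statistic instance hits the chi-square tail", {
  f1 <- make_fit(c(1, 0), diag(2))
  f2 <- make_fit(c(0, 1), diag(2))
  pr <- profile_test(f1, f2)
  expect_equal(pr$stat, 1, tolerance = 1e-8)
  expect_equal(pr$p_profile, pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("grid-plus-golden-section minimum matches a brute-force fine grid", {
  set.seed(103)
  for (rep in 1:20) {
    q <- sample(2:3, 1)
    f1 <- make_fit(rnorm(q), rand_pd(q))
    f2 <- make_fit(rnorm(q), rand_pd(q), ids = f1$ids)
    pr <- profile_test(f1, f2)
    fine <- theta_grid <- seq(-pi / 2 + pi / 1e6, pi / 2, length.out = 1e6)
    vals <- fieller_stat(f1$b, f1$V, f2$b, f2$V, fine)
    expect_lt(abs(pr$stat - min(vals)), 1e-6)
    expect_lt(min(abs(pr$theta_hat - fine[which.min(vals)]),
                  abs(abs(pr$theta_hat - fine[which.min(vals)]) - pi)), 1e-5)
  }
})

test_that("profile test is invariant to joint non-singular linear transforms", {
  set.seed(104)
  f1 <- make_fit(rnorm(3), rand_pd(3))
  f2 <- make_fit(rnorm(3), rand_pd(3), ids = f1$ids)
  A <- matrix(rnorm(9), 3)
  t1 <- make_fit(drop(A %*% f1$b), A %*% f1$V %*% t(A))
  t2 <- make_fit(drop(A %*% f2$b), A %*% f2$V %*% t(A), ids = t1$ids)
  pr <- profile_test(f1, f2)
  prT <- profile_test(t1, t2)
  expect_equal(pr$stat, prT$stat, tolerance = 1e-6)
  expect_equal(pr$eta_hat, prT$eta_hat, tolerance = 1e-4)
})

test_that("q = 1 profile test degenerates with a warning", {
  f1 <- make_fit(1, matrix(0.1))
  f2 <- make_fit(0.5, matrix(0.1))
  expect_warning(pr <- profile_test(f1, f2), "q = 1")
  expect_equal(pr$p_profile, 1)
})

test_that("the theta posterior is a proper density", {
  set.seed(105)
  for (rep in 1:5) {
    q <- sample(2:4, 1)
    f1 <- make_fit(rnorm(q), rand_pd(q))
    f2 <- make_fit(rnorm(q), rand_pd(q), ids = f1$ids)
    post <- theta_posterior(f1, f2)
    expect_true(all(post$density >= 0))
    expect_equal(propcoloc:::trapz(post$grid, post$density), 1,
                 tolerance = 1e-6)
    expect_true(all(diff(post$grid) > 0))
  }
})

test_that("swapping the two fits reflects the posterior about theta -> pi/2 - theta", {
  set.seed(106)
  # informative fits: posterior mass vanishes at the period boundary, so
  # the open-grid trapezoid normalisation is reflection-symmetric too
  f1 <- make_fit(rnorm(2) + 1, rand_pd(2, 0.02))
  f2 <- make_fit(rnorm(2) + 1, rand_pd(2, 0.02), ids = f1$ids)
  n <- 1000  # even grid so reflected points are grid points
  p12 <- theta_posterior(f1, f2, n_grid = n)
  p21 <- theta_posterior(f2, f1, n_grid = n)
  # grid_i = -pi/2 + i h; pi/2 - grid_i is the grid point with index
  # n/2 - i (mod n)
  i <- seq_len(n)
  j <- ((n / 2 - i - 1) %% n) + 1
  expect_equal(p12$density, p21$density[j], tolerance = 1e-6)
})

test_that("informative proportional data put the posterior mode at atan(eta0)", {
  for (eta0 in c(1, 0.5)) {
    b1 <- c(1, 2)
    f1 <- make_fit(b1, diag(2) * 1e-4)
    f2 <- make_fit(eta0 * b1, diag(2) * 1e-4, ids = f1$ids)
    post <- theta_posterior(f1, f2)
    mode <- post$grid[which.max(post$density)]
    expect_lt(abs(mode - atan(eta0)), pi / length(post$grid) + 1e-12)
  }
})

test_that("ppp equals the integrand when the statistic is constant in theta", {
  f1 <- make_fit(c(1, 0), diag(2))
  f2 <- make_fit(c(0, 1), diag(2))
  post <- theta_posterior(f1, f2)
  expect_equal(ppp_value(post, f1, f2), pchisq(1, 2, lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("under exact proportionality the ppp approaches its analytic limit", {
  # As V -> 0 the posterior is Gaussian around theta_hat with the same
  # curvature as the statistic (T^2 is the profile deviance), so
  # ppp -> E[P(chisq_2 > Z^2)] = E[exp(-Z^2/2)] = 1/sqrt(2) for q = 2.
  b1 <- c(1, 2)
  for (s in c(1e-4, 1e-6)) {
    f1 <- make_fit(b1, diag(2) * s)
    f2 <- make_fit(2 * b1, diag(2) * s, ids = f1$ids)
    post <- theta_posterior(f1, f2)
    ppp <- ppp_value(post, f1, f2)
    expect_lt(abs(ppp - 1 / sqrt(2)), 0.05)
    expect_equal(profile_test(f1, f2)$p_profile, 1, tolerance = 1e-4)
  }
})

test_that("credible intervals carry the stated mass and the right flags", {
  set.seed(107)
  f1 <- make_fit(c(1, 2), diag(2) * 0.01)
  f2 <- make_fit(c(1, 2) * 1.02, diag(2) * 0.01, ids = f1$ids)
  post <- theta_posterior(f1, f2)
  ci <- eta_credible_interval(post, level = 0.95)
  # independent mass recomputation on the recentred grid
  rc <- propcoloc:::recentre_on_mode(post$grid, post$density)
  cdf <- propcoloc:::cumtrapz(rc$theta, rc$density)
  cdf <- cdf / cdf[length(cdf)]
  mass <- approx(rc$theta, cdf, xout = ci$theta_upper)$y -
    approx(rc$theta, cdf, xout = ci$theta_lower)$y
  expect_equal(mass, 0.95, tolerance = 1e-6)
  expect_true(ci$contains_one)   # eta near 1.02
  expect_false(ci$contains_zero)
  expect_error(eta_credible_interval(post, level = 1.2), "probability")
})

test_that("a posterior concentrated just above eta = 0 contains zero but not one", {
  f1 <- make_fit(c(1, 0.5), diag(2) * 1e-4)
  f2 <- make_fit(c(0.004, 0.002), diag(2) * 1e-4, ids = f1$ids)
  post <- theta_posterior(f1, f2)
  ci <- eta_credible_interval(post)
  expect_true(ci$contains_zero)
  expect_false(ci$contains_one)
  expect_gt(post$grid[which.max(post$density)], 0)
})

test_that("a symmetric posterior centred at theta = pi/4 contains eta = 1", {
  f1 <- make_fit(c(2, 1), diag(2) * 0.05)
  f2 <- make_fit(c(2, 1), diag(2) * 0.05, ids = f1$ids)
  ci <- eta_credible_interval(theta_posterior(f1, f2))
  expect_true(ci$contains_one)
})

test_that("prop_test ties the pieces together consistently", {
  set.seed(108)
  f1 <- make_fit(rnorm(3), rand_pd(3))
  f2 <- make_fit(rnorm(3), rand_pd(3), ids = f1$ids)
  res <- prop_test(f1, f2)
  expect_s3_class(res, "prop_test_result")
  expect_gte(res$ppp, 0); expect_lte(res$ppp, 1)
  expect_equal(res$df, 2L)
  expect_identical(res$ppp, ppp_value(res$posterior, f1, f2))
  path <- tempfile()
  write_prop_result(res, path)
  rec <- read.delim(path, header = FALSE, col.names = c("key", "value"))
  expect_true(all(c("stat", "ppp", "eta_hat", "ci_low", "ci_high") %in%
                    rec$key))
  expect_equal(as.numeric(rec$value[rec$key == "ppp"]), res$ppp,
               tolerance = 1e-8)
})
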