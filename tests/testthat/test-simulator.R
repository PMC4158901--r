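test_that("rho = 0 panels have uncorrelated SNPs", {
  p <- make_panel(2000, 20, block_size = 10, rho = 0, dup_prob = 0,
                  seed = 501)
  r <- cor(p$haplotypes)
  diag(r) <- NA
  expect_lt(mean(abs(r), na.rm = TRUE), 2 / sqrt(2000))
})

test_that("LD is strong within blocks and broken across block boundaries", {
  p <- make_panel(2000, 40, block_size = 20, rho = 0.95, seed = 502)
  h <- p$haplotypes
  within <- sapply(c(2:20, 22:40), function(j) cor(h[, j - 1], h[, j])^2)
  across <- cor(h[, 20], h[, 21])^2
  expect_gt(mean(within), 0.3)
  expect_lt(across, 0.05)
  expect_equal(p$blocks, c(1, 21))
})

test_that("realised MAFs respect the floor and panels are reproducible", {
  p1 <- make_panel(1000, 50, seed = 503)
  expect_true(all(pmin(p1$maf, 1 - p1$maf) >= 0.05 - 1e-9))
  expect_true(all(p1$haplotypes %in% c(0L, 1L)))
  p2 <- make_panel(1000, 50, seed = 503)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_error(make_panel(999, 10), "even")
  expect_error(make_panel(100, 10, maf_floor = 0.6), "0.5")
})

test_that("admixture boundaries reproduce the pure panels", {
  pa <- make_panel(400, 15, seed = 504)
  pb <- make_panel(400, 15, seed = 505, population = "pop2")
  m0 <- admix_panels(pa, pb, 0, seed = 506)
  expect_true(all(m0$population == "pop1"))
  m1 <- admix_panels(pa, pb, 1, seed = 506)
  expect_true(all(m1$population == "pop2"))
  m <- admix_panels(pa, pb, 0.3, seed = 506)
  expect_equal(nrow(m$haplotypes), 400)
  expect_error(admix_panels(pa, make_panel(100, 5, seed = 1), 0.5), "same SNPs")
})

test_that("rr = 1 produces no case-control frequency shift", {
  p <- make_panel(800, 10, block_size = 5, seed = 507)
  d <- simulate_case_control(p, 4, 1, 1500, 1500, seed = 508)
  f_case <- mean(d$genotypes$dosages[d$trait$values == 1, 4]) / 2
  f_ctrl <- mean(d$genotypes$dosages[d$trait$values == 0, 4]) / 2
  se <- sqrt(f_ctrl * (1 - f_ctrl) * (1 / 3000 + 1 / 3000))
  expect_lt(abs(f_case - f_ctrl), 4 * se)
})

test_that("case allele frequency follows the multiplicative closed form", {
  p <- make_panel(800, 10, block_size = 5, seed = 509)
  for (rr in c(1.1, 1.2, 1.3)) {
    d <- simulate_case_control(p, 4, rr, 4000, 1000, seed = 510 + rr * 10)
    f <- p$maf[4]
    expected <- f * rr / (1 - f + f * rr)   # retrospective per-allele freq
    f_case <- mean(d$genotypes$dosages[d$trait$values == 1, 4]) / 2
    se <- sqrt(expected * (1 - expected) / (2 * 4000))
    expect_lt(abs(f_case - expected), 3.5 * se)
  }
})

test_that("case-control datasets are reproducible from their seed", {
  p <- make_panel(400, 10, block_size = 5, seed = 511)
  d1 <- simulate_case_control(p, 2, 1.3, 200, 200, seed = 512)
  d2 <- simulate_case_control(p, 2, 1.3, 200, 200, seed = 512)
  expect_identical(d1$genotypes$dosages, d2$genotypes$dosages)
})

test_that("quantitative traits explain the stated variance fraction", {
  p <- make_panel(1000, 10, block_size = 5, seed = 513)
  d <- simulate_quantitative(p, 3, 0.3, 10000, seed = 514)
  r2 <- summary(lm(d$trait$values ~ d$genotypes$dosages[, 3]))$r.squared
  expect_lt(abs(r2 - 0.30), 0.02)
})

test_that("correlated causal variants add a 2 b1 b2 cov term to explained variance", {
  p <- make_panel(1000, 10, block_size = 10, rho = 0.9, seed = 515)
  d <- simulate_quantitative(p, c(3, 4), c(0.1, 0.1), 20000, seed = 516)
  X <- d$genotypes$dosages[, 3:4]
  beta <- d$beta
  analytic <- drop(t(beta) %*% cov(X) %*% beta)       # includes 2 b1 b2 cov
  naive <- beta[1]^2 * var(X[, 1]) + beta[2]^2 * var(X[, 2])
  fitted_var <- var(X %*% beta)
  expect_equal(drop(fitted_var), analytic, tolerance = 1e-10)
  expect_gt(analytic, naive)   # positive LD inflates the joint contribution
  r2 <- summary(lm(d$trait$values ~ X))$r.squared
  expect_lt(abs(r2 - analytic / (analytic + (1 - 0.2))), 0.02)
})

test_that("tag thinning keeps the requested count deterministically", {
  p <- make_panel(400, 100, seed = 517)
  d <- simulate_quantitative(p, 1, 0.1, 50, seed = 518)$genotypes
  t1 <- tag_subset(d, 0.3, seed = 519)
  expect_equal(ncol(t1$dosages), 30L)
  expect_identical(colnames(t1$dosages),
                   colnames(tag_subset(d, 0.3, seed = 519)$dosages))
  expect_identical(tag_subset(d, 1, seed = 1), d)
  expect_error(tag_subset(d, 0, seed = 1), "\\(0, 1]")
})

test_that("the minimum-p screen keeps strong signals and everything at threshold 1", {
  p <- make_panel(400, 10, block_size = 5, seed = 520)
  strong <- simulate_quantitative(p, 2, 0.4, 500, seed = 521)
  expect_true(screen_min_p(strong$genotypes, strong$trait))
  null <- simulate_quantitative(p, 2, 1e-6, 100, seed = 522)
  expect_true(screen_min_p(null$genotypes, null$trait, threshold = 1))
})

test_that("run_study with zero replicates returns an empty, well-formed table", {
  st <- run_study(sim_scenario("s"), "PC", n_reps = 0, seed = 1)
  expect_equal(nrow(st$summary), 0)
  expect_named(st$summary, c("scenario_id", "method", "n_reps",
                             "rejections", "rate", "se"))
})

test_that("run_study is reproducible and records causal-pair r2 and redraws", {
  scen <- sim_scenario("qt", trait = "qt", causal = "distinct",
                       var_explained = 0.25, n_samples = 400, n_snp = 30,
                       r2_range = c(0, 0.4))
  st1 <- run_study(scen, "causal_pair", n_reps = 3, seed = 77, n_grid = 301)
  st2 <- run_study(scen, "causal_pair", n_reps = 3, seed = 77, n_grid = 301)
  expect_identical(st1$detail$p, st2$detail$p)
  expect_true(all(st1$detail$r2 >= 0 & st1$detail$r2 <= 0.4))
  expect_true(all(st1$detail$redraws >= 0))
})
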