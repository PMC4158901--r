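test_that("dosage tables round-trip through read_genotypes", {
  tab <- data.frame(sample = c("a", "b", "c"),
                    snp1 = c(0, 1, 2), snp2 = c(2, 0, 1))
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  g <- read_genotypes(path, "dosage_table")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(unname(g$dosages[, "snp1"]), c(0, 1, 2))
  expect_equal(unname(g$dosages[, "snp2"]), c(2, 0, 1))
  expect_false(any(missing_mask(g)))
})

test_that("VCF genotypes become alt-allele dosages with missing cells masked", {
  gts <- rbind(c("0/1", "1/1", "0/0"),
               c("./.", "0|1", "1|1"))
  path <- write_test_vcf(tempfile(fileext = ".vcf"), gts)
  g <- read_genotypes(path, "vcf")
  expect_equal(unname(g$dosages[, "rs1"]), c(1, 2, 0))
  expect_equal(unname(g$dosages[, "rs2"]), c(NA, 1, 2))
  expect_equal(unname(missing_mask(g)[, "rs2"]), c(TRUE, FALSE, FALSE))
  expect_equal(g$positions, c(100L, 200L))
})

test_that("SNPs are returned in position order and duplicates rejected", {
  gts <- rbind(c("0/0", "0/1"), c("1/1", "0/0"))
  path <- write_test_vcf(tempfile(fileext = ".vcf"), gts,
                         positions = c(500, 100))
  g <- read_genotypes(path, "vcf")
  expect_equal(snp_ids <- colnames(g$dosages), c("rs2", "rs1"))
  expect_error(genotype_matrix(matrix(0, 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("s", "s")))),
               "duplicate SNP")
  expect_error(genotype_matrix(matrix(3, 2, 2)), "0, 2")
})

test_that("imputation is a no-op on complete data and exact for r2 = 1", {
  set.seed(1)
  d <- matrix(sample(0:2, 30, TRUE), 10, 3)
  g <- genotype_matrix(d)
  expect_identical(impute_missing(g)$dosages, g$dosages)

  d2 <- cbind(a = d[, 1], b = d[, 1], c = d[, 2])  # a and b duplicates
  d2[4, "b"] <- NA
  g2 <- genotype_matrix(d2)
  imp <- impute_missing(g2)
  expect_equal(unname(imp$dosages[4, "b"]), unname(d[4, 1]))
  expect_false(any(missing_mask(imp)))
})

test_that("imputed value equals the normal-equations least-squares fit", {
  # 5 x 3 matrix, one missing cell in SNP 3, predictors = SNPs 1-2
  d <- cbind(s1 = c(0, 1, 2, 1, 0),
             s2 = c(2, 1, 0, 2, 1),
             s3 = c(0, 1, 2, 2, NA))
  g <- genotype_matrix(d)
  imp <- impute_missing(g, max_predictors = 2)
  obs <- 1:4
  X <- cbind(1, d[obs, 1:2])
  beta <- solve(crossprod(X), crossprod(X, d[obs, 3]))   # independent oracle
  expected <- min(max(drop(c(1, d[5, 1:2]) %*% beta), 0), 2)
  expect_equal(unname(imp$dosages[5, "s3"]), expected, tolerance = 1e-12)
})

test_that("imputation is idempotent and preserves dosage bounds", {
  set.seed(7)
  d <- matrix(sample(0:2, 200, TRUE), 20, 10)
  d[cbind(sample(20, 6), sample(10, 6, TRUE))] <- NA
  g <- genotype_matrix(d)
  once <- impute_missing(g)
  twice <- impute_missing(once)
  expect_identical(once$dosages, twice$dosages)
  expect_true(all(once$dosages >= 0 & once$dosages <= 2))
  # observed cells untouched
  obs <- !is.na(d)
  expect_equal(once$dosages[obs], d[obs])
})

test_that("imputation errors on hopeless missingness patterns", {
  d <- matrix(c(0, 1, NA, NA, NA, NA, 1, 2), 4, 2,
              dimnames = list(letters[1:4], c("s1", "s2")))
  expect_error(impute_missing(genotype_matrix(d)), "50%")
  d2 <- cbind(s1 = c(0, 1, 2), s2 = c(NA, NA, NA))
  expect_error(impute_missing(genotype_matrix(d2)), "all samples")
})

test_that("merging stacks cohorts over the SNP intersection", {
  set.seed(3)
  d1 <- matrix(sample(0:2, 50, TRUE), 5, 10,
               dimnames = list(paste0("a", 1:5), paste0("s", 1:10)))
  d2 <- matrix(sample(0:2, 64, TRUE), 8, 8,
               dimnames = list(paste0("b", 1:8), paste0("s", 1:8)))
  g1 <- genotype_matrix(d1)
  g2 <- genotype_matrix(d2)
  expect_warning(merge_cohorts(g1, g2), "dropped")
  m <- suppressWarnings(merge_cohorts(g1, g2))
  expect_equal(dim(m), c(13L, 8L))
  expect_equal(levels(attr(m, "cohort")), c("1", "2"))
  # identical panels: no warning, all columns kept
  m2 <- merge_cohorts(g1, g1_copy <- {
    tmp <- g1; rownames(tmp$dosages) <- paste0("c", 1:5); tmp
  })
  expect_equal(dim(m2), c(10L, 10L))
})

test_that("ref/alt swaps are recoded as 2 - dosage and mismatches rejected", {
  d <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(paste0("a", 1:3), c("s1", "s2")))
  g1 <- genotype_matrix(d, alleles = cbind(c("A", "C"), c("G", "T")))
  d2 <- d; rownames(d2) <- paste0("b", 1:3)
  g2 <- genotype_matrix(d2, alleles = cbind(c("G", "C"), c("A", "T")))
  m <- merge_cohorts(g1, g2)
  expect_equal(unname(m$dosages[4:6, "s1"]), unname(2 - d[, 1]))
  expect_equal(unname(m$dosages[4:6, "s2"]), unname(d[, 2]))
  g3 <- genotype_matrix(d2, alleles = cbind(c("C", "C"), c("T", "T")))
  expect_error(merge_cohorts(g1, g3), "allele mismatch")
})

test_that("merge then split recovers each cohort's dosages exactly", {
  set.seed(11)
  d1 <- matrix(sample(0:2, 40, TRUE), 4, 10,
               dimnames = list(paste0("a", 1:4), paste0("s", 1:10)))
  d2 <- matrix(sample(0:2, 60, TRUE), 6, 10,
               dimnames = list(paste0("b", 1:6), paste0("s", 1:10)))
  m <- merge_cohorts(genotype_matrix(d1), genotype_matrix(d2))
  coh <- attr(m, "cohort")
  expect_equal(m$dosages[coh == "1", ], d1)
  expect_equal(m$dosages[coh == "2", ], d2)
})

test_that("trait files are read and aligned to the genotype sample order", {
  g <- genotype_matrix(matrix(0:1, 2, 1, dimnames = list(c("b", "a"), "s1")))
  path <- tempfile()
  write.table(data.frame(sample = c("a", "b"), value = c(1, 0)), path,
              sep = "\t", row.names = FALSE, quote = FALSE)
  y <- read_trait(path, "binary", g = g)
  expect_equal(y$values, c(0, 1))  # reordered to (b, a)
  expect_error(trait_vector(c(0, 2), "binary"), "0 .* 1")
  expect_error(trait_vector(c(1, Inf), "quantitative"), "finite")
})
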