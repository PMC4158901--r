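# Shared fixture builders; everything is generated in code.

# A regression_fit with given coefficients/covariance, for exercising the
# proportional core without data.
make_fit <- function(b, V, ids = paste0("x", seq_along(b)),
                     kind = "quantitative", n = 1000) {
  b <- as.numeric(b)
  V <- as.matrix(V)
  structure(list(ids = ids, b = b, V = V, trait_kind = kind, n = n,
                 loglik = 0, bic = 0), class = "regression_fit")
}

# Random positive-definite matrix.
rand_pd <- function(q, scale = 1) {
  A <- matrix(stats::rnorm(q * q), q)
  crossprod(A) * scale / q + diag(q) * 0.1 * scale
}

# Small two-cohort dataset with a shared causal variant (quantitative).
make_shared_cohorts <- function(n = 500, n_snp = 20, v = 0.2, seed = 42,
                                causal = min(7, n_snp - 1)) {
  panel <- make_panel(600, n_snp, block_size = 10, seed = seed)
  d1 <- simulate_quantitative(panel, causal, v, n, seed = seed + 1)
  d2 <- simulate_quantitative(panel, causal, v, n, seed = seed + 2)
  rownames(d2$genotypes$dosages) <- paste0("t", seq_len(n))
  list(g1 = d1$genotypes, y1 = d1$trait, g2 = d2$genotypes, y2 = d2$trait,
       causal = d1$causal, panel = panel)
}

# Minimal single-sample VCF body used by the reader tests.
write_test_vcf <- function(path, gts, ids = NULL, positions = NULL) {
  # gts: matrix snps x samples of GT strings
  n_snp <- nrow(gts); n_sam <- ncol(gts)
  if (is.null(ids)) ids <- paste0("rs", seq_len(n_snp))
  if (is.null(positions)) positions <- seq_len(n_snp) * 100
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("s", seq_len(n_sam))),
                    collapse = "\t"))
  body <- vapply(seq_len(n_snp), function(i) {
    paste(c("1", positions[i], ids[i], "A", "G", ".", "PASS", ".", "GT",
            gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}
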