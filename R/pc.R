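# Principal-component summarisation of the combined genotype matrix.
#
# Summarising the region by the leading PCs of the *combined* (both-cohort)
# genotype matrix avoids trait-informed variable selection entirely: the
# basis depends only on genotypes, so the projected coefficients are
# unbiased and the proportional test keeps its nominal size.

#' Principal-component basis of a combined genotype matrix
#'
#' Centres and scales each SNP of the combined dosage matrix to unit
#' variance, then takes the singular value decomposition. Component signs
#' follow a deterministic convention (the largest-magnitude loading of each
#' component is positive).
#'
#' @param combined a fully observed [genotype_matrix()], normally the
#'   output of [merge_cohorts()].
#' @return A `pc_basis`: `loadings` (`n_snps x n_components`, orthonormal
#'   columns), `variance_fractions` (descending, summing to 1),
#'   `snp_means`, `snp_scales`, `snp_ids`.
#' @export
build_pc_basis <- function(combined) {
  d <- combined$dosages
  if (anyNA(d)) stop_validation("combined matrix must be fully imputed")
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  if (any(sdv == 0))
    stop_validation("zero-variance SNP(s) in combined data: ",
                    paste(snp_ids(combined)[sdv == 0], collapse = ", "))
  z <- scale(d, center = mu, scale = sdv)
  sv <- svd(z, nu = 0)
  loadings <- sv$v
  # deterministic sign: largest |loading| per component made positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  rownames(loadings) <- snp_ids(combined)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  structure(list(loadings = loadings,
                 variance_fractions = sv$d^2 / sum(sv$d^2),
                 snp_means = mu, snp_scales = sdv,
                 snp_ids = snp_ids(combined)),
            class = "pc_basis")
}

#' Select the leading components reaching a variance threshold
#'
#' @param basis a [build_pc_basis()] result.
#' @param threshold fraction of total genetic variance to capture, in
#'   `(0, 1]`; the smallest leading component set whose cumulative variance
#'   fraction reaches it is returned.
#' @return Integer vector of component indices `1..k`.
#' @export
select_components <- function(basis, threshold = 0.9) {
  if (threshold <= 0 || threshold > 1)
    stop_validation("threshold must be in (0, 1]")
  k <- which(cumsum(basis$variance_fractions) >= threshold - 1e-12)[1]
  if (is.na(k)) k <- length(basis$variance_fractions)
  seq_len(k)
}

#' Project a cohort onto a PC basis
#'
#' Uses the centering and scaling constants of the *combined* matrix, so
#' both cohorts land in the same component space.
#'
#' @param g a [genotype_matrix()] covering the basis SNPs.
#' @param basis a [build_pc_basis()] result.
#' @param components component indices (default: all).
#' @return Numeric score matrix, samples x components.
#' @export
project_cohort <- function(g, basis, components = NULL) {
  if (is.null(components)) components <- seq_along(basis$variance_fractions)
  m <- match(basis$snp_ids, snp_ids(g))
  if (anyNA(m)) stop_validation("cohort lacks basis SNP(s): ",
                                paste(basis$snp_ids[is.na(m)], collapse = ", "))
  z <- scale(g$dosages[, m, drop = FALSE], center = basis$snp_means,
             scale = basis$snp_scales)
  z %*% basis$loadings[, components, drop = FALSE]
}

#' PC-based proportional colocalisation test
#'
#' Merges the two cohorts, builds the combined PC basis, selects the
#' smallest leading component set capturing `threshold` of the genetic
#' variance, projects each cohort onto those components, fits each trait
#' jointly on its component scores, and runs the proportional test.
#'
#' @param g1,g2 fully observed [genotype_matrix()] objects for the two
#'   cohorts (SNP panels are intersected).
#' @param y1,y2 the paired [trait_vector()]s.
#' @param threshold variance fraction captured by the selected components
#'   (default 0.90).
#' @param prior_scale,n_grid,level passed to [prop_test()].
#' @return A `prop_test_result` with an extra field `n_components`.
#' @export
pc_test <- function(g1, y1, g2, y2, threshold = 0.9,
                    prior_scale = 1, n_grid = 1001, level = 0.95) {
  check_paired(g1, y1); check_paired(g2, y2)
  combined <- merge_cohorts(g1, g2)
  basis <- build_pc_basis(combined)
  comp <- select_components(basis, threshold)
  if (length(comp) >= min(nrow(g1$dosages), nrow(g2$dosages)) / 10)
    warning("selected ", length(comp), " components for cohort sizes ",
            nrow(g1$dosages), "/", nrow(g2$dosages),
            "; overfitting risk")
  s1 <- project_cohort(g1, basis, comp)
  s2 <- project_cohort(g2, basis, comp)
  f1 <- fit_joint(s1, y1)
  f2 <- fit_joint(s2, y2)
  res <- prop_test(f1, f2, prior_scale = prior_scale, n_grid = n_grid,
                   level = level)
  res$n_components <- length(comp)
  res$method <- "PC"
  res
}
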