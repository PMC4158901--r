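# Regional genotype containers: reading, validation, imputation, merging.

#' Construct a regional genotype matrix
#'
#' A `genotype_matrix` holds allele dosages for one genomic region in one
#' cohort: an `n_samples x n_snps` matrix of alt-allele counts in `[0, 2]`
#' (integer 0/1/2 before imputation, real afterwards), with per-SNP
#' positions and ref/alt alleles. Missing genotypes are stored as `NA`.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; dimnames
#'   give sample and SNP identifiers. Values in `[0, 2]` or `NA`.
#' @param positions integer vector of 1-based base-pair coordinates, one per
#'   SNP.
#' @param alleles two-column character matrix (ref, alt), one row per SNP.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages,
                            positions = seq_len(ncol(dosages)),
                            alleles = NULL) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("sample", seq_len(nrow(dosages)))
  if (is.null(alleles)) {
    alleles <- cbind(ref = rep("A", ncol(dosages)),
                     alt = rep("B", ncol(dosages)))
  }
  alleles <- as.matrix(alleles)
  colnames(alleles) <- c("ref", "alt")
  p <- ncol(dosages)
  if (length(positions) != p || nrow(alleles) != p)
    stop_validation("positions and alleles must have one entry per SNP")
  if (anyDuplicated(colnames(dosages)))
    stop_validation("duplicate SNP identifiers: ",
                    paste(unique(colnames(dosages)[duplicated(colnames(dosages))]),
                          collapse = ", "))
  if (anyDuplicated(rownames(dosages)))
    stop_validation("duplicate sample identifiers")
  rng <- suppressWarnings(range(dosages, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop_validation("dosages must lie in [0, 2]")
  structure(list(dosages = dosages,
                 positions = as.integer(positions),
                 alleles = alleles),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs, %d missing cells\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

snp_ids <- function(g) colnames(g$dosages)
sample_ids <- function(g) rownames(g$dosages)

#' Missing-genotype indicator
#' @param g a [genotype_matrix()].
#' @return Logical matrix, `TRUE` where the genotype is missing.
#' @export
missing_mask <- function(g) is.na(g$dosages)

#' Construct a trait vector paired with a genotype matrix
#'
#' @param values numeric vector, one value per sample, in the same sample
#'   order as the paired genotype matrix. Binary traits are coded 0 =
#'   control, 1 = case.
#' @param kind `"binary"` or `"quantitative"`.
#' @return An object of class `trait_vector`.
#' @export
trait_vector <- function(values, kind = c("binary", "quantitative")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "binary") {
    if (!all(values %in% c(0, 1)))
      stop_validation("binary trait values must be 0 (control) or 1 (case)")
  } else if (any(!is.finite(values))) {
    stop_validation("quantitative trait values must be finite")
  }
  structure(list(values = values, kind = kind), class = "trait_vector")
}

check_paired <- function(g, y) {
  if (length(y$values) != nrow(g$dosages))
    stop_validation("trait length (", length(y$values),
                    ") does not match sample count (", nrow(g$dosages), ")")
  invisible(TRUE)
}

#' Read regional genotypes from a VCF or dosage table
#'
#' VCF genotypes (`GT` field) are converted to alt-allele dosage counts;
#' `./.` becomes a missing cell. A dosage table is tab-delimited with a
#' header row of SNP identifiers and the sample identifier in the first
#' column. SNPs are returned in position order.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage_table"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage_table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop_validation("cannot parse VCF: ",
                                                      conditionMessage(e)))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  # count alt alleles; any "." in the call marks the cell missing
  count_alt <- function(s) {
    if (is.na(s)) return(NA_real_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == "." | a == "")) return(NA_real_)
    sum(a != "0")
  }
  dos <- t(apply(gt, 1, function(row) vapply(row, count_alt, numeric(1))))
  if (ncol(vcf@gt) - 1L == 1L) dos <- matrix(dos, nrow = nrow(gt),
                                             dimnames = list(NULL, colnames(vcf@gt)[-1]))
  dosages <- t(dos)  # samples x snps
  colnames(dosages) <- ids
  g <- genotype_matrix(dosages,
                       positions = as.integer(fix[, "POS"]),
                       alleles = cbind(ref = fix[, "REF"], alt = fix[, "ALT"]))
  sort_by_position(g)
}

read_genotypes_dosage <- function(path) {
  tab <- tryCatch(utils::read.delim(path, check.names = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e) stop_validation("cannot parse dosage table: ",
                                                      conditionMessage(e)))
  if (ncol(tab) < 2) stop_validation("dosage table needs >= 1 SNP column")
  samples <- as.character(tab[[1]])
  dosages <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(dosages) <- "double"
  rownames(dosages) <- samples
  genotype_matrix(dosages)  # positions default to column order
}

sort_by_position <- function(g) {
  o <- order(g$positions, snp_ids(g))
  genotype_matrix(g$dosages[, o, drop = FALSE], g$positions[o],
                  g$alleles[o, , drop = FALSE])
}

#' Impute missing genotypes by multiple regression
#'
#' Each missing cell is filled with the fitted value from a least-squares
#' regression of its SNP on the most-correlated complete SNPs in the region
#' (those with no missing values), then clipped to `[0, 2]`. Fractional
#' dosages are retained. If no complete predictor SNP exists, the SNP mean
#' is used.
#'
#' @param g a [genotype_matrix()].
#' @param max_predictors maximum number of predictor SNPs per target
#'   (default 5); ties in absolute correlation are broken by SNP order.
#' @return A fully observed [genotype_matrix()].
#' @export
impute_missing <- function(g, max_predictors = 5) {
  d <- g$dosages
  miss <- is.na(d)
  if (!any(miss)) return(g)
  if (any(rowSums(!miss) == 0))
    stop_validation("some samples have no observed genotypes")
  frac <- colMeans(miss)
  if (any(frac >= 1))
    stop_validation("SNP(s) missing in all samples: ",
                    paste(snp_ids(g)[frac >= 1], collapse = ", "))
  if (any(frac >= 0.5))
    stop_validation("SNP(s) with >= 50% missing genotypes: ",
                    paste(snp_ids(g)[frac >= 0.5], collapse = ", "))
  complete <- which(colSums(miss) == 0)
  for (j in which(colSums(miss) > 0)) {
    obs <- !miss[, j]
    target <- d[obs, j]
    preds <- integer(0)
    if (length(complete) > 0 && stats::sd(target) > 0) {
      r <- suppressWarnings(
        abs(stats::cor(d[obs, complete, drop = FALSE], target)))
      r[is.na(r)] <- 0
      ord <- order(-r, seq_along(r))
      preds <- complete[ord[seq_len(min(max_predictors, length(ord)))]]
      preds <- preds[r[ord[seq_len(length(preds))]] > 0]
    }
    if (length(preds) == 0) {
      fill <- mean(target)
      d[!obs, j] <- fill
    } else {
      X <- cbind(1, d[, preds, drop = FALSE])
      fit <- stats::lm.fit(X[obs, , drop = FALSE], target)
      coefs <- fit$coefficients
      coefs[is.na(coefs)] <- 0
      d[!obs, j] <- drop(X[!obs, , drop = FALSE] %*% coefs)
    }
  }
  d[d < 0] <- 0
  d[d > 2] <- 2
  genotype_matrix(d, g$positions, g$alleles)
}

is_allele_ambiguous <- function(ref, alt) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[ref]) & comp[ref] == alt
}

#' Merge two cohorts over their common SNPs
#'
#' Intersects the SNP panels by identifier, recodes SNPs whose ref/alt
#' alleles are swapped between cohorts as `2 - dosage`, and row-stacks the
#' dosage matrices. Strand-ambiguous (A/T, C/G) SNPs are flagged in a
#' warning but kept. Both inputs must be fully imputed.
#'
#' @param g1,g2 fully observed [genotype_matrix()] objects.
#' @return A [genotype_matrix()] over the common SNPs with an attribute
#'   `cohort` (factor `"1"`/`"2"` per sample).
#' @export
merge_cohorts <- function(g1, g2) {
  if (anyNA(g1$dosages) || anyNA(g2$dosages))
    stop_validation("cohorts must be imputed before merging")
  common <- intersect(snp_ids(g1), snp_ids(g2))
  if (length(common) == 0) stop_validation("no SNPs shared between cohorts")
  dropped <- setdiff(union(snp_ids(g1), snp_ids(g2)), common)
  if (length(dropped) > 0)
    warning(length(dropped), " SNP(s) absent from one cohort dropped: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
  i1 <- match(common, snp_ids(g1))
  i2 <- match(common, snp_ids(g2))
  a1 <- g1$alleles[i1, , drop = FALSE]
  a2 <- g2$alleles[i2, , drop = FALSE]
  d2 <- g2$dosages[, i2, drop = FALSE]
  same <- a1[, "ref"] == a2[, "ref"] & a1[, "alt"] == a2[, "alt"]
  swapped <- a1[, "ref"] == a2[, "alt"] & a1[, "alt"] == a2[, "ref"]
  if (any(!same & !swapped))
    stop_validation("allele mismatch (not a ref/alt swap) at: ",
                    paste(common[!same & !swapped], collapse = ", "))
  if (any(swapped)) d2[, swapped] <- 2 - d2[, swapped]
  amb <- is_allele_ambiguous(a1[, "ref"], a1[, "alt"])
  if (any(amb))
    warning("strand-ambiguous SNP(s) retained: ",
            paste(common[amb], collapse = ", "))
  d1 <- g1$dosages[, i1, drop = FALSE]
  s1 <- rownames(d1); s2 <- rownames(d2)
  if (any(s1 %in% s2)) {
    warning("sample identifiers shared between cohorts; prefixing")
    rownames(d1) <- paste0("c1.", s1)
    rownames(d2) <- paste0("c2.", s2)
  }
  merged <- genotype_matrix(rbind(d1, d2), g1$positions[i1], a1)
  attr(merged, "cohort") <- factor(rep(c("1", "2"), c(nrow(d1), nrow(d2))))
  merged
}

#' Read a two-column trait file (sample id, value)
#'
#' @param path tab-delimited file with columns sample id and trait value.
#' @param kind `"binary"` or `"quantitative"`.
#' @param g optional [genotype_matrix()]; if given, values are reordered to
#'   its sample order and checked for completeness.
#' @return A [trait_vector()].
#' @export
read_trait <- function(path, kind = c("binary", "quantitative"), g = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_validation("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_validation("trait file needs two columns")
  vals <- as.numeric(tab[[2]])
  names(vals) <- as.character(tab[[1]])
  if (!is.null(g)) {
    m <- match(sample_ids(g), names(vals))
    if (anyNA(m))
      stop_validation("trait file missing sample(s): ",
                      paste(sample_ids(g)[is.na(m)], collapse = ", "))
    vals <- vals[m]
  }
  trait_vector(vals, kind)
}
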