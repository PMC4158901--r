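# Biased comparison baselines: conditional testing, the Nica residual-rank
# score, and naive SNP-selection strategies for proportional testing.
#
# These are shipped for benchmarking only. Selecting SNPs for their
# observed association in the data being tested ("winner's curse") inflates
# the type 1 error of every method below; the PC and BMA tests exist to
# replace them.

#' Conditional colocalisation test (biased baseline)
#'
#' Tests association between the trait and SNP `k` conditional on SNP
#' `k_prime`: the Wald p-value of the `k` coefficient in the joint
#' regression of `y` on `(X_k_prime, X_k)`.
#'
#' @param g a fully observed [genotype_matrix()].
#' @param y the paired [trait_vector()].
#' @param k,k_prime SNP identifiers (or column indices); must differ.
#' @return A p-value. Collinear pairs (r^2 = 1) return 1 with a warning.
#' @export
conditional_test <- function(g, y, k, k_prime) {
  k <- resolve_snp(g, k); k_prime <- resolve_snp(g, k_prime)
  if (k == k_prime) stop_validation("test and conditioning SNP must differ")
  x_k <- g$dosages[, k]; x_kp <- g$dosages[, k_prime]
  if (stats::var(x_k) == 0 || stats::var(x_kp) == 0)
    stop_validation("monomorphic SNP in conditional test")
  if (abs(stats::cor(x_k, x_kp)) >= 1 - 1e-12) {
    warning("conditional test undefined for a collinear SNP pair; p = 1")
    return(1)
  }
  X <- cbind(1, x_kp, x_k)
  if (y$kind == "quantitative") {
    fit <- stats::lm.fit(X, y$values)
    rss <- sum(fit$residuals^2)
    sigma2 <- rss / (length(y$values) - 3)
    V <- chol2inv(qr.R(fit$qr)) * sigma2
    z <- fit$coefficients[3] / sqrt(V[3, 3])
    unname(2 * stats::pt(abs(z), df = length(y$values) - 3,
                         lower.tail = FALSE))
  } else {
    lf <- logistic_fit(X, y$values)
    if (!lf$ok) return(logistic_score_conditional(x_kp, x_k, y$values))
    unname(2 * stats::pnorm(abs(lf$b[3] / lf$se[3]), lower.tail = FALSE))
  }
}

# score-type fallback: test residual correlation after adjusting both
# genotype and trait for the conditioning SNP.
logistic_score_conditional <- function(x_kp, x_k, y) {
  rx <- stats::lm.fit(cbind(1, x_kp), x_k)$residuals
  ry <- y - stats::glm.fit(cbind(1, x_kp), y,
                           family = stats::binomial())$fitted.values
  u <- sum(rx * ry)
  v <- sum(rx^2) * mean(y) * (1 - mean(y))
  if (v <= 0) return(1)
  stats::pchisq(u^2 / v, df = 1, lower.tail = FALSE)
}

resolve_snp <- function(g, k) {
  if (is.character(k)) {
    i <- match(k, snp_ids(g))
    if (is.na(i)) stop_validation("unknown SNP: ", k)
    return(i)
  }
  as.integer(k)
}

#' Nica residual-rank colocalisation score
#'
#' For every SNP `j != k`, regresses the trait on `X_j`, tests the Spearman
#' correlation of the residuals with `X_k`, and reports the ascending rank
#' of the conditioning SNP's p-value `P_k_prime` among all `P_j`, divided
#' by their number. Scores near 1 are consistent with colocalisation;
#' under distinct unlinked causal variants the score is uniform on (0, 1].
#' The set of conditioning candidates excludes `j = k` and includes
#' `j = k_prime`. No formal null distribution is attached.
#'
#' @inheritParams conditional_test
#' @return A `nica_score`: list with `score`, `p_values` (named by SNP),
#'   `k`, `k_prime`.
#' @export
nica_score <- function(g, y, k, k_prime) {
  k <- resolve_snp(g, k); k_prime <- resolve_snp(g, k_prime)
  if (k == k_prime) stop_validation("test and conditioning SNP must differ")
  n <- nrow(g$dosages)
  x_k <- g$dosages[, k]
  js <- setdiff(seq_len(ncol(g$dosages)), k)
  pj <- vapply(js, function(j) {
    xj <- g$dosages[, j]
    r <- if (y$kind == "quantitative") stats::lm.fit(cbind(1, xj), y$values)$residuals
         else y$values - stats::glm.fit(cbind(1, xj), y$values,
                                        family = stats::binomial())$fitted.values
    suppressWarnings(stats::cor.test(r, x_k, method = "spearman",
                                     exact = n < 50)$p.value)
  }, numeric(1))
  names(pj) <- snp_ids(g)[js]
  rank_kp <- rank(pj, ties.method = "average")[match(k_prime, js)]
  structure(list(score = unname(rank_kp) / length(js), p_values = pj,
                 k = k, k_prime = k_prime),
            class = "nica_score")
}

#' Naive SNP selection for proportional testing (biased baselines)
#'
#' The three published selection strategies whose inflation motivates the
#' PC and BMA approaches: `top_pair` takes each cohort's most-associated
#' SNP; `lasso_union` takes the union of per-cohort lasso selections;
#' `lasso_two_stage` runs the lasso on cohort 1 and then on cohort 2 with
#' the cohort-1 selections unpenalised. Lasso penalties are chosen by
#' 10-fold cross-validation at the 1-SE rule with deterministic folds.
#' Selections of fewer than two SNPs fall back to `top_pair`, topped up
#' with the next-ranked SNP of cohort 1 where needed.
#'
#' @param g1,y1,g2,y2 the two cohorts over a common SNP panel.
#' @param strategy `"top_pair"`, `"lasso_union"` or `"lasso_two_stage"`.
#' @param seed seed for the cross-validation folds.
#' @return Character vector of at least two SNP identifiers.
#' @export
naive_select <- function(g1, y1, g2, y2,
                         strategy = c("top_pair", "lasso_union",
                                      "lasso_two_stage"),
                         seed = 1) {
  strategy <- match.arg(strategy)
  common <- intersect(snp_ids(g1), snp_ids(g2))
  if (length(common) < 2) stop_validation("need at least two common SNPs")
  top_pair <- function() {
    sc1 <- single_snp_scan(subset_snps(g1, common), y1)
    sc2 <- single_snp_scan(subset_snps(g2, common), y2)
    sel <- unique(c(common[attr(sc1, "top")], common[attr(sc2, "top")]))
    if (length(sel) < 2) {
      nxt <- common[order(sc1$p, seq_along(common))]
      sel <- unique(c(sel, nxt))[1:2]
    }
    sel
  }
  if (strategy == "top_pair") return(top_pair())
  sel <- tryCatch({
    if (strategy == "lasso_union") {
      union(lasso_select(g1, y1, common, seed = seed),
            lasso_select(g2, y2, common, seed = seed))
    } else {
      s1 <- lasso_select(g1, y1, common, seed = seed)
      union(s1, lasso_select(g2, y2, common, unpenalised = s1, seed = seed))
    }
  }, error = function(e) character(0))
  if (length(sel) < 2) {
    warning("lasso selected < 2 SNPs; falling back to top_pair")
    sel <- top_pair()
  }
  sel
}

lasso_select <- function(g, y, common, unpenalised = character(0), seed = 1) {
  X <- g$dosages[, common, drop = FALSE]
  fam <- if (y$kind == "binary") "binomial" else "gaussian"
  pf <- ifelse(common %in% unpenalised, 0, 1)
  n <- nrow(X)
  foldid <- with_seed(seed, sample(rep_len(1:10, n)))
  cv <- glmnet::cv.glmnet(X, y$values, family = fam, foldid = foldid,
                          penalty.factor = pf)
  co <- stats::coef(cv, s = "lambda.1se")
  common[as.vector(co[-1] != 0)]
}

subset_snps <- function(g, ids) {
  i <- match(ids, snp_ids(g))
  genotype_matrix(g$dosages[, i, drop = FALSE], g$positions[i],
                  g$alleles[i, , drop = FALSE])
}

#' Proportional test after a naive selection strategy (biased baseline)
#'
#' Feeds a [naive_select()] SNP set into [fit_joint()] for each cohort and
#' the proportional core. Reproduces the inflated strategies P1-P3; use
#' [pc_test()] or [bma_test()] for calibrated inference.
#'
#' @inheritParams naive_select
#' @param prior_scale,n_grid,level as in [prop_test()].
#' @return A `prop_test_result` with a `snps` field naming the selection.
#' @export
baseline_test <- function(g1, y1, g2, y2,
                          strategy = c("top_pair", "lasso_union",
                                       "lasso_two_stage"),
                          seed = 1, prior_scale = 1, n_grid = 1001,
                          level = 0.95) {
  strategy <- match.arg(strategy)
  sel <- naive_select(g1, y1, g2, y2, strategy, seed = seed)
  f1 <- fit_joint(g1, y1, sel)
  f2 <- fit_joint(g2, y2, sel)
  res <- prop_test(f1, f2, prior_scale = prior_scale, n_grid = n_grid,
                   level = level)
  res$snps <- sel
  res$method <- strategy
  res
}
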