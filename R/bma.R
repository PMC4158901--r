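# Bayesian model averaging over two- and three-SNP models.
#
# Rather than selecting SNPs, treat the SNP model itself as a nuisance
# parameter: enumerate every subset of fixed size, weight each model by its
# BIC-approximated posterior probability (prior uniform over the model
# universe), and average the per-model posterior predictive p-values:
#   ppp = sum over models m of P*(m) P(m).
# Because the two cohorts are independent (Cov(b1, b2) = 0), a model's
# joint weight is the product of its per-trait marginal likelihood
# approximations, i.e. exp(-(BIC1 + BIC2)/2) up to normalisation.

#' Enumerate all SNP models of a fixed size
#'
#' @param snp_ids character vector of SNP identifiers.
#' @param size model size, 2 or 3 (100 SNPs give 4,950 two-SNP models but
#'   161,700 three-SNP models; four-SNP universes are deliberately not
#'   supported).
#' @return A `model_space`: `models` (integer matrix, one row per model,
#'   columns the SNP indices in lexicographic order), `snp_ids`, `size`,
#'   and placeholder `bic1`, `bic2`, `posterior`, `pruned` columns.
#' @export
enumerate_models <- function(snp_ids, size) {
  size <- as.integer(size)
  if (!size %in% c(2L, 3L)) stop_validation("model size must be 2 or 3")
  p <- length(snp_ids)
  if (size > p) stop_validation("model size exceeds SNP count")
  models <- t(utils::combn(p, size))
  n <- nrow(models)
  structure(list(models = models, snp_ids = as.character(snp_ids),
                 size = size,
                 bic1 = rep(NA_real_, n), bic2 = rep(NA_real_, n),
                 posterior = rep(NA_real_, n), pruned = rep(FALSE, n)),
            class = "model_space")
}

#' @export
print.model_space <- function(x, ...) {
  cat(sprintf("model_space: %d models of size %d over %d SNPs (%d pruned)\n",
              nrow(x$models), x$size, length(x$snp_ids), sum(x$pruned)))
  invisible(x)
}

# Fast per-model BIC for one cohort; X is the dosage matrix restricted to
# the model-space SNPs, models an index matrix into its columns.
model_bics <- function(X, y, models) {
  n <- nrow(X)
  nm <- nrow(models)
  size <- ncol(models)
  bics <- numeric(nm)
  if (y$kind == "quantitative") {
    yy <- y$values
    for (m in seq_len(nm)) {
      fit <- stats::lm.fit(cbind(1, X[, models[m, ], drop = FALSE]), yy)
      rss <- sum(fit$residuals^2)
      ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
      bics[m] <- -2 * ll + (size + 1) * log(n)
    }
  } else {
    yy <- y$values
    for (m in seq_len(nm)) {
      lf <- logistic_fit(cbind(1, X[, models[m, ], drop = FALSE]), yy)
      bics[m] <- -2 * lf$loglik + (size + 1) * log(n)
    }
  }
  bics
}

#' BIC-approximated posterior model probabilities
#'
#' Fits every model in the space to both cohorts, forms normalised weights
#' `exp(-(BIC1 + BIC2 - min)/2)` under a uniform model prior, and prunes
#' the improbable tail: models are ranked by weight and the minimal prefix
#' reaching cumulative mass `prune_mass` is retained, with weights
#' renormalised over the retained set.
#'
#' @param space a [enumerate_models()] result.
#' @param g1,y1,g2,y2 the two cohorts; both must contain every SNP of the
#'   space.
#' @param prune_mass cumulative posterior mass to retain (default 0.9999;
#'   1 keeps everything).
#' @return The space with `bic1`, `bic2`, `posterior`, `pruned` filled in.
#' @export
model_posteriors <- function(space, g1, y1, g2, y2, prune_mass = 0.9999) {
  if (prune_mass <= 0 || prune_mass > 1)
    stop_validation("prune_mass must be in (0, 1]")
  i1 <- match(space$snp_ids, snp_ids(g1))
  i2 <- match(space$snp_ids, snp_ids(g2))
  if (anyNA(i1) || anyNA(i2))
    stop_validation("both cohorts must contain every SNP of the model space")
  space$bic1 <- model_bics(g1$dosages[, i1, drop = FALSE], y1, space$models)
  space$bic2 <- model_bics(g2$dosages[, i2, drop = FALSE], y2, space$models)
  bsum <- space$bic1 + space$bic2
  w <- exp(-(bsum - min(bsum)) / 2)
  w <- w / sum(w)
  ord <- order(-w)
  keep_n <- which(cumsum(w[ord]) >= prune_mass - 1e-12)[1]
  retained <- ord[seq_len(keep_n)]
  space$pruned <- rep(TRUE, length(w))
  space$pruned[retained] <- FALSE
  w[space$pruned] <- 0
  space$posterior <- w / sum(w)
  space
}

#' BMA proportional colocalisation test
#'
#' Runs the proportional test under every retained model (each model is a
#' single SNP subset used for both traits, as the test needs a common
#' regressor set), then averages: the returned posterior predictive
#' p-value is `sum of P*(m) P(m)`, and the returned theta-posterior is the
#' posterior-weighted mixture of per-model posteriors, from which the
#' mixture-mode `eta` estimate and credible interval are taken.
#'
#' @param g1,y1,g2,y2 the two cohorts (SNP panels intersected by id).
#' @param size model size, 2 or 3.
#' @param prune_mass cumulative model mass retained before testing.
#' @param prior_scale,n_grid,level as in [prop_test()].
#' @return A `prop_test_result` with extra fields `model_table` (retained
#'   models: SNPs, bic1, bic2, weight, ppp) and `n_models`; `stat`, `df`
#'   and `p_profile` refer to the highest-weight model.
#' @export
bma_test <- function(g1, y1, g2, y2, size = 2, prune_mass = 0.9999,
                     prior_scale = 1, n_grid = 1001, level = 0.95) {
  check_paired(g1, y1); check_paired(g2, y2)
  common <- intersect(snp_ids(g1), snp_ids(g2))
  if (length(common) < size)
    stop_validation("fewer common SNPs than the model size")
  space <- enumerate_models(common, size)
  space <- model_posteriors(space, g1, y1, g2, y2, prune_mass)
  retained <- which(!space$pruned)
  grid <- theta_grid_default(n_grid)
  mix_dens <- numeric(n_grid)
  ppp_m <- numeric(length(retained))
  weights <- space$posterior[retained]
  best <- retained[which.max(weights)]
  best_prof <- NULL
  ok <- rep(TRUE, length(retained))
  for (k in seq_along(retained)) {
    m <- retained[k]
    ids_m <- space$snp_ids[space$models[m, ]]
    res_k <- tryCatch({
      f1 <- fit_joint(g1, y1, ids_m)
      f2 <- fit_joint(g2, y2, ids_m)
      post <- theta_posterior(f1, f2, prior_scale = prior_scale,
                              n_grid = n_grid)
      list(ppp = ppp_value(post, f1, f2), dens = post$density,
           prof = if (m == best) profile_test(f1, f2) else NULL)
    }, error = function(e) NULL)
    if (is.null(res_k)) {
      warning("model ", paste(ids_m, collapse = "+"),
              " failed to fit and was pruned")
      ok[k] <- FALSE
      next
    }
    ppp_m[k] <- res_k$ppp
    mix_dens <- mix_dens + weights[k] * res_k$dens
    if (!is.null(res_k$prof)) best_prof <- res_k$prof
  }
  if (!any(ok)) stop_numeric("all models failed to fit")
  if (is.null(best_prof))
    best_prof <- list(stat = NA_real_, df = size - 1L, p_profile = NA_real_)
  if (!all(ok)) {
    weights <- weights[ok] / sum(weights[ok])
    ppp_m <- ppp_m[ok]
    mix_dens <- mix_dens / sum(space$posterior[retained][ok])
    retained <- retained[ok]
  }
  mix_dens <- mix_dens / trapz(grid, mix_dens)
  posterior <- structure(list(grid = grid, density = mix_dens,
                              prior_scale = prior_scale, q = size),
                         class = "theta_posterior")
  ci <- eta_credible_interval(posterior, level = level)
  theta_hat <- grid[which.max(mix_dens)]
  model_table <- data.frame(
    model = apply(space$models[retained, , drop = FALSE], 1,
                  function(i) paste(space$snp_ids[i], collapse = "+")),
    bic1 = space$bic1[retained], bic2 = space$bic2[retained],
    weight = weights, ppp = ppp_m, stringsAsFactors = FALSE)
  structure(list(eta_hat = tan(theta_hat), theta_hat = theta_hat,
                 stat = best_prof$stat, df = best_prof$df,
                 p_profile = best_prof$p_profile,
                 ppp = min(max(sum(weights * ppp_m), 0), 1),
                 posterior = posterior, eta_ci = ci, q = size,
                 model_table = model_table[order(-model_table$weight), ],
                 n_models = nrow(space$models), method = paste0("BMA", size)),
            class = "prop_test_result")
}
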