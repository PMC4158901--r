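# Synthetic haplotype panels and trait simulation for type-1-error and
# power studies.
#
# The panel generator emulates the features of real phased reference
# haplotypes that matter to regional colocalisation testing: block LD
# (Gaussian-copula latent process with within-block autocorrelation),
# minor allele frequencies above a floor, and optional population
# admixture for equal-LD sensitivity analyses. Case-control samples follow
# a multiplicative per-allele relative-risk model via rejection sampling;
# quantitative traits fix the variance explained per causal variant.

#' Generate a synthetic phased haplotype panel with block LD
#'
#' Each haplotype's alleles come from thresholding a latent Gaussian
#' process with within-block AR(1) correlation `rho` at per-SNP quantiles.
#' Target minor allele frequencies share a block-level base frequency
#' (drawn uniformly on `(maf_floor, 0.5)`) with small per-SNP jitter:
#' SNPs in strong LD have similar frequencies in real panels, and without
#' this the thresholded (binary) r^2 between neighbours never approaches
#' 1. SNPs whose realised MAF falls below the floor are re-thresholded
#' (same latent values, so LD is preserved).
#'
#' @param n_hap number of haplotypes (must be even).
#' @param n_snp number of SNPs.
#' @param block_size SNPs per LD block (default 25).
#' @param rho latent within-block autocorrelation in `[0, 1)` (default
#'   0.95).
#' @param maf_floor minimum minor allele frequency (default 0.05).
#' @param seed integer seed.
#' @param population label attached to every haplotype.
#' @param dup_prob probability that a SNP is a near-copy of its
#'   predecessor (latent correlation 0.997) rather than an ordinary AR
#'   step; dense regional panels contain many such near-perfect proxies,
#'   and without them the genotype r^2 spectrum never reaches the
#'   `[0.8, 1]` range (default 0.3).
#' @return A `haplotype_panel`: `haplotypes` (`n_hap x n_snp` 0/1 matrix),
#'   `maf` (realised), `blocks` (first SNP index of each block),
#'   `population`.
#' @export
make_panel <- function(n_hap, n_snp, block_size = 25, rho = 0.95,
                       maf_floor = 0.05, seed = 1, population = "pop1",
                       dup_prob = 0.3) {
  if (n_hap <= 0 || n_snp <= 0 || block_size <= 0)
    stop_validation("panel dimensions must be positive")
  if (n_hap %% 2 != 0) stop_validation("n_hap must be even")
  if (rho < 0 || rho >= 1) stop_validation("rho must be in [0, 1)")
  if (maf_floor >= 0.5) stop_validation("maf_floor must be below 0.5")
  with_seed(seed, {
    z <- matrix(stats::rnorm(n_hap * n_snp), n_hap, n_snp)
    step_rho <- ifelse(stats::runif(n_snp) < dup_prob, 0.997, rho)
    for (j in seq_len(n_snp)[-1]) {
      if ((j - 1) %% block_size != 0)  # block boundaries reset the process
        z[, j] <- step_rho[j] * z[, j - 1] +
          sqrt(1 - step_rho[j]^2) * z[, j]
    }
    block_of <- (seq_len(n_snp) - 1) %/% block_size
    base_maf <- stats::runif(max(block_of) + 1, maf_floor, 0.5)
    maf_target <- pmin(pmax(base_maf[block_of + 1] +
                              stats::runif(n_snp, -0.05, 0.05),
                            maf_floor), 0.5)
    # near-copies track their predecessor's frequency closely, as real
    # proxies do; a frequency mismatch alone caps the attainable r^2
    jit <- stats::runif(n_snp, -0.01, 0.01)
    for (j in seq_len(n_snp)[-1]) {
      if ((j - 1) %% block_size != 0 && step_rho[j] > rho)
        maf_target[j] <- pmin(pmax(maf_target[j - 1] + jit[j], maf_floor), 0.5)
    }
    hap <- sweep(z, 2, stats::qnorm(maf_target), "<") * 1L
    # re-threshold SNPs whose realised MAF dropped under the floor
    for (iter in 1:20) {
      f <- colMeans(hap)
      low <- which(pmin(f, 1 - f) < maf_floor)
      if (length(low) == 0) break
      maf_target[low] <- stats::runif(length(low),
                                      pmin(maf_target[low] + 0.05, 0.45), 0.5)
      hap[, low] <- sweep(z[, low, drop = FALSE], 2,
                          stats::qnorm(maf_target[low]), "<") * 1L
    }
    f <- colMeans(hap)
    low <- which(pmin(f, 1 - f) < maf_floor)
    if (length(low) > 0) {
      # deterministic fallback: threshold at the empirical quantile
      for (j in low)
        hap[, j] <- (z[, j] < stats::quantile(z[, j], probs = 0.25)) * 1L
    }
    colnames(hap) <- paste0("snp", seq_len(n_snp))
    structure(list(haplotypes = hap, maf = colMeans(hap),
                   blocks = seq(1, n_snp, by = block_size),
                   population = rep(population, n_hap)),
              class = "haplotype_panel")
  })
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d SNPs (%s)\n",
              nrow(x$haplotypes), ncol(x$haplotypes),
              paste(unique(x$population), collapse = "+")))
  invisible(x)
}

#' Admix two haplotype panels
#'
#' Builds a panel of the same size as `panel_a` in which each haplotype is
#' drawn (with replacement) from `panel_b` with probability `pi` and from
#' `panel_a` otherwise, emulating population admixture in one cohort.
#'
#' @param panel_a,panel_b `haplotype_panel`s over the same SNP count.
#' @param pi admixture fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return A `haplotype_panel`.
#' @export
admix_panels <- function(panel_a, panel_b, pi, seed = 1) {
  if (ncol(panel_a$haplotypes) != ncol(panel_b$haplotypes))
    stop_validation("panels must cover the same SNPs")
  if (pi < 0 || pi > 1) stop_validation("pi must be in [0, 1]")
  n <- nrow(panel_a$haplotypes)
  with_seed(seed, {
    from_b <- stats::runif(n) < pi
    ia <- sample(nrow(panel_a$haplotypes), n, replace = TRUE)
    ib <- sample(nrow(panel_b$haplotypes), n, replace = TRUE)
    hap <- panel_a$haplotypes[ia, , drop = FALSE]
    hap[from_b, ] <- panel_b$haplotypes[ib[from_b], , drop = FALSE]
    pop <- ifelse(from_b, panel_b$population[ib], panel_a$population[ia])
    structure(list(haplotypes = hap, maf = colMeans(hap),
                   blocks = panel_a$blocks, population = pop),
              class = "haplotype_panel")
  })
}

panel_to_genotypes <- function(hap_idx_mat, panel, prefix = "s") {
  g <- panel$haplotypes[hap_idx_mat[, 1], , drop = FALSE] +
       panel$haplotypes[hap_idx_mat[, 2], , drop = FALSE]
  rownames(g) <- paste0(prefix, seq_len(nrow(g)))
  genotype_matrix(g)
}

#' Simulate a case-control dataset under a multiplicative risk model
#'
#' Controls are random haplotype pairs from the panel; cases are pairs
#' accepted by rejection sampling with probability proportional to
#' `rr ^ (causal allele count)`. Genotypes are the allele-count sums.
#'
#' @param panel a `haplotype_panel`.
#' @param causal_snp causal SNP name or column index.
#' @param rr per-allele relative risk (> 0).
#' @param n_case,n_control sample sizes.
#' @param seed integer seed.
#' @return List with `genotypes` (a [genotype_matrix()], cases first) and
#'   `trait` (binary [trait_vector()]).
#' @export
simulate_case_control <- function(panel, causal_snp, rr, n_case, n_control,
                                  seed = 1) {
  if (rr <= 0) stop_validation("relative risk must be positive")
  ci <- if (is.character(causal_snp)) match(causal_snp, colnames(panel$haplotypes))
        else as.integer(causal_snp)
  if (is.na(ci) || ci < 1 || ci > ncol(panel$haplotypes))
    stop_validation("causal SNP not in panel")
  nh <- nrow(panel$haplotypes)
  with_seed(seed, {
    ctrl <- cbind(sample(nh, n_control, TRUE), sample(nh, n_control, TRUE))
    rmax <- max(rr^2, 1)
    case <- matrix(0L, 0, 2)
    tried <- 0; accepted <- 0
    while (nrow(case) < n_case) {
      batch <- max(2L * (n_case - nrow(case)), 100L)
      h1 <- sample(nh, batch, TRUE); h2 <- sample(nh, batch, TRUE)
      gvals <- panel$haplotypes[h1, ci] + panel$haplotypes[h2, ci]
      acc <- stats::runif(batch) < rr^gvals / rmax
      tried <- tried + batch; accepted <- accepted + sum(acc)
      case <- rbind(case, cbind(h1[acc], h2[acc]))
      if (tried > 1000 && accepted / tried < 1e-4)
        stop_numeric("case acceptance rate below 1e-4; reduce rr")
    }
    case <- case[seq_len(n_case), , drop = FALSE]
    g <- panel_to_genotypes(rbind(case, ctrl), panel)
    y <- trait_vector(rep(c(1, 0), c(n_case, n_control)), "binary")
    list(genotypes = g, trait = y, causal = colnames(panel$haplotypes)[ci])
  })
}

#' Simulate a quantitative trait with fixed variance explained
#'
#' Draws `n` genotypes as random haplotype pairs and generates
#' `y = sum of beta_c X_c + e`, with `beta_c = sqrt(v_c / (2 f_c (1 -
#' f_c)))` (Hardy-Weinberg genotype variance) and Gaussian noise of
#' variance `1 - sum(v_c)`, so each causal variant explains its stated
#' fraction of a total variance of about 1.
#'
#' @param panel a `haplotype_panel`.
#' @param causal_snps causal SNP names or indices.
#' @param var_fractions per-variant variance fractions (each > 0, sum < 1).
#' @param n sample size.
#' @param seed integer seed.
#' @return List with `genotypes` and `trait` (quantitative).
#' @export
simulate_quantitative <- function(panel, causal_snps, var_fractions, n,
                                  seed = 1) {
  ci <- if (is.character(causal_snps))
          match(causal_snps, colnames(panel$haplotypes))
        else as.integer(causal_snps)
  if (anyNA(ci)) stop_validation("causal SNP(s) not in panel")
  if (any(var_fractions <= 0) || sum(var_fractions) >= 1)
    stop_validation("variance fractions must be positive and sum below 1")
  if (length(ci) != length(var_fractions))
    stop_validation("one variance fraction per causal SNP required")
  nh <- nrow(panel$haplotypes)
  with_seed(seed, {
    pairs <- cbind(sample(nh, n, TRUE), sample(nh, n, TRUE))
    g <- panel_to_genotypes(pairs, panel)
    f <- panel$maf[ci]
    beta <- sqrt(var_fractions / (2 * f * (1 - f)))
    y <- drop(g$dosages[, ci, drop = FALSE] %*% beta) +
      stats::rnorm(n, sd = sqrt(1 - sum(var_fractions)))
    list(genotypes = g, trait = trait_vector(y, "quantitative"),
         causal = colnames(panel$haplotypes)[ci], beta = beta)
  })
}

#' Thin a genotype matrix to a random tag-SNP subset
#'
#' Parametric stand-in for restricting to a genotyping-array SNP list:
#' keeps a random subset of `ceil(fraction * p)` SNPs (causal SNPs are
#' removable like any other, emulating the tagging scenario).
#'
#' @param g a [genotype_matrix()].
#' @param fraction fraction of SNPs to keep, in `(0, 1]`.
#' @param seed integer seed.
#' @return A [genotype_matrix()] over the retained SNPs (position order).
#' @export
tag_subset <- function(g, fraction, seed = 1) {
  if (fraction <= 0 || fraction > 1)
    stop_validation("fraction must be in (0, 1]")
  p <- ncol(g$dosages)
  keep_n <- ceiling(fraction * p)
  if (keep_n == 0) stop_validation("tag subset is empty")
  if (keep_n == p) return(g)
  keep <- sort(with_seed(seed, sample(p, keep_n)))
  subset_snps(g, snp_ids(g)[keep])
}

#' Minimum single-SNP p-value screen
#'
#' Proportional testing is meant for regions with established association;
#' datasets where every single-SNP p-value exceeds the threshold are
#' discarded.
#'
#' @param g,y dataset to screen.
#' @param threshold keep iff min scan p <= threshold (default 1e-4).
#' @return `TRUE` to keep the dataset.
#' @export
screen_min_p <- function(g, y, threshold = 1e-4) {
  sc <- suppressWarnings(single_snp_scan(g, y))
  min(sc$p) <= threshold
}

#' Describe one simulation scenario
#'
#' @param name scenario identifier.
#' @param trait `"cc"` (case-control) or `"qt"` (quantitative).
#' @param causal sharing pattern: `"shared1"` (one variant shared by both
#'   traits), `"distinct"` (one private variant per trait), `"shared2"`
#'   (two shared), or a list `list(shared = a, private1 = b, private2 =
#'   c)` of variant counts.
#' @param rr per-allele relative risk (case-control traits).
#' @param var_explained variance fraction per causal variant
#'   (quantitative traits).
#' @param n_case,n_control,n_samples cohort sizes.
#' @param n_snp,n_hap,block_size,rho,maf_floor panel parameters.
#' @param tag_fraction tag-SNP fraction; 1 = complete genotyping.
#' @param admix_pi second-cohort admixture fraction (0 = equal LD).
#' @param r2_range optional `c(lo, hi)`: for distinct-variant scenarios,
#'   the causal pair is drawn among SNP pairs with haplotype r^2 in this
#'   range.
#' @param screen_threshold min single-SNP p screen (default 1e-4).
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(name, trait = c("cc", "qt"), causal = "shared1",
                         rr = 1.2, var_explained = 0.1,
                         n_case = 2000, n_control = 2000, n_samples = 1000,
                         n_snp = 60, n_hap = 1000, block_size = 20,
                         rho = 0.95, maf_floor = 0.05,
                         tag_fraction = 0.3, admix_pi = 0,
                         r2_range = NULL, screen_threshold = 1e-4) {
  trait <- match.arg(trait)
  if (is.character(causal)) {
    causal <- switch(causal,
                     shared1 = list(shared = 1, private1 = 0, private2 = 0),
                     shared2 = list(shared = 2, private1 = 0, private2 = 0),
                     distinct = list(shared = 0, private1 = 1, private2 = 1),
                     stop_validation("unknown causal pattern"))
  }
  structure(list(name = name, trait = trait, causal = causal, rr = rr,
                 var_explained = var_explained, n_case = n_case,
                 n_control = n_control, n_samples = n_samples,
                 n_snp = n_snp, n_hap = n_hap, block_size = block_size,
                 rho = rho, maf_floor = maf_floor,
                 tag_fraction = tag_fraction, admix_pi = admix_pi,
                 r2_range = r2_range, screen_threshold = screen_threshold),
            class = "sim_scenario")
}

# haplotype r^2 between two SNP columns of a panel
hap_r2 <- function(panel, i, j) {
  suppressWarnings(stats::cor(panel$haplotypes[, i], panel$haplotypes[, j]))^2
}

pick_causals <- function(panel, scen, seed) {
  with_seed(seed, {
    p <- ncol(panel$haplotypes)
    n_total <- scen$causal$shared + scen$causal$private1 + scen$causal$private2
    if (!is.null(scen$r2_range) && n_total == 2 && scen$causal$shared == 0) {
      # targeted r^2 between the two private variants
      r2m <- suppressWarnings(stats::cor(panel$haplotypes))^2
      diag(r2m) <- NA
      ok <- which(r2m >= scen$r2_range[1] & r2m <= scen$r2_range[2],
                  arr.ind = TRUE)
      if (nrow(ok) == 0) return(NULL)
      pick <- ok[sample(nrow(ok), 1), ]
      return(list(shared = integer(0), private1 = pick[1],
                  private2 = pick[2]))
    }
    idx <- sample(p, n_total)
    list(shared = idx[seq_len(scen$causal$shared)],
         private1 = idx[scen$causal$shared + seq_len(scen$causal$private1)],
         private2 = idx[scen$causal$shared + scen$causal$private1 +
                          seq_len(scen$causal$private2)])
  })
}

# Simulate one replicate (both cohorts, tagging, screening); returns NULL
# if no causal configuration with the requested r^2 exists in the panel.
simulate_pair <- function(scen, seed) {
  panel1 <- make_panel(scen$n_hap, scen$n_snp, scen$block_size, scen$rho,
                       scen$maf_floor, seed = derive_seed(seed, 1))
  panel2 <- panel1
  if (scen$admix_pi > 0) {
    alt <- make_panel(scen$n_hap, scen$n_snp, scen$block_size, scen$rho,
                      scen$maf_floor, seed = derive_seed(seed, 2),
                      population = "pop2")
    panel2 <- admix_panels(panel1, alt, scen$admix_pi,
                           seed = derive_seed(seed, 3))
  }
  cs <- pick_causals(panel1, scen, derive_seed(seed, 4))
  if (is.null(cs)) return(NULL)
  c1 <- c(cs$shared, cs$private1)
  c2 <- c(cs$shared, cs$private2)
  sim_one <- function(panel, causal, sub_seed) {
    if (scen$trait == "cc") {
      # one causal variant per trait under the multiplicative model
      simulate_case_control(panel, causal[1], scen$rr, scen$n_case,
                            scen$n_control, seed = sub_seed)
    } else {
      simulate_quantitative(panel, causal,
                            rep(scen$var_explained, length(causal)),
                            scen$n_samples, seed = sub_seed)
    }
  }
  # one tag set (the "array") applied to both cohorts; cohort 2 is only
  # simulated once cohort 1 has passed the screen
  tag_keep <- if (scen$tag_fraction < 1) {
    p <- ncol(panel1$haplotypes)
    sort(with_seed(derive_seed(seed, 7),
                   sample(p, ceiling(scen$tag_fraction * p))))
  } else seq_len(ncol(panel1$haplotypes))
  tag_ids <- colnames(panel1$haplotypes)[tag_keep]
  poly_ids <- function(g) {
    v <- apply(g$dosages, 2, stats::var)
    snp_ids(g)[v > 0]
  }
  d1 <- sim_one(panel1, c1, derive_seed(seed, 5))
  g1 <- subset_snps(d1$genotypes, intersect(tag_ids, poly_ids(d1$genotypes)))
  if (ncol(g1$dosages) < 3 ||
      !screen_min_p(g1, d1$trait, scen$screen_threshold)) return(NULL)
  d2 <- sim_one(panel2, c2, derive_seed(seed, 6))
  keep <- intersect(snp_ids(g1), poly_ids(d2$genotypes))
  if (length(keep) < 3) return(NULL)
  g1 <- subset_snps(g1, keep)
  g2 <- subset_snps(d2$genotypes, keep)
  if (!screen_min_p(g2, d2$trait, scen$screen_threshold)) return(NULL)
  r2 <- if (length(cs$private1) == 1 && length(cs$private2) == 1)
          hap_r2(panel1, cs$private1, cs$private2) else NA_real_
  list(g1 = g1, y1 = d1$trait, g2 = g2, y2 = d2$trait,
       causal1 = colnames(panel1$haplotypes)[c1],
       causal2 = colnames(panel1$haplotypes)[c2],
       panel = panel1, r2 = r2)
}

apply_method <- function(method, dat, pc_threshold, n_grid, seed) {
  switch(method,
    C1 = {
      sc1 <- suppressWarnings(single_snp_scan(dat$g1, dat$y1))
      sc2 <- suppressWarnings(single_snp_scan(dat$g2, dat$y2))
      kp <- attr(sc2, "top")
      ks <- order(sc1$p, seq_len(nrow(sc1)))
      k <- ks[ks != kp][1]
      conditional_test(dat$g1, dat$y1, k, kp)
    },
    C2 = {
      kp <- match(dat$causal2[1], snp_ids(dat$g1))
      if (is.na(kp)) {  # causal SNP tagged away: condition on best proxy
        r2s <- suppressWarnings(stats::cor(dat$panel$haplotypes[, dat$causal2[1]],
                 dat$panel$haplotypes[, snp_ids(dat$g1)]))^2
        kp <- which.max(drop(r2s))
      }
      sc1 <- suppressWarnings(single_snp_scan(dat$g1, dat$y1))
      ks <- order(sc1$p, seq_len(nrow(sc1)))
      k <- ks[ks != kp][1]
      conditional_test(dat$g1, dat$y1, k, kp)
    },
    P1 = suppressWarnings(baseline_test(dat$g1, dat$y1, dat$g2, dat$y2,
                                        "top_pair", seed = seed,
                                        n_grid = n_grid))$ppp,
    P2 = suppressWarnings(baseline_test(dat$g1, dat$y1, dat$g2, dat$y2,
                                        "lasso_union", seed = seed,
                                        n_grid = n_grid))$ppp,
    P3 = suppressWarnings(baseline_test(dat$g1, dat$y1, dat$g2, dat$y2,
                                        "lasso_two_stage", seed = seed,
                                        n_grid = n_grid))$ppp,
    PC = suppressWarnings(pc_test(dat$g1, dat$y1, dat$g2, dat$y2,
                                  threshold = pc_threshold,
                                  n_grid = n_grid))$ppp,
    BMA2 = suppressWarnings(bma_test(dat$g1, dat$y1, dat$g2, dat$y2,
                                     size = 2, n_grid = n_grid))$ppp,
    BMA3 = suppressWarnings(bma_test(dat$g1, dat$y1, dat$g2, dat$y2,
                                     size = 3, n_grid = n_grid))$ppp,
    causal_pair = {
      # oracle: test the true causal variants themselves (max power)
      ids <- unique(c(dat$causal1, dat$causal2))
      ids <- ids[ids %in% intersect(snp_ids(dat$g1), snp_ids(dat$g2))]
      if (length(ids) < 2) {
        sc1 <- suppressWarnings(single_snp_scan(dat$g1, dat$y1))
        ids <- unique(c(ids, sc1$snp[order(sc1$p)]))[1:2]
      }
      f1 <- fit_joint(dat$g1, dat$y1, ids)
      f2 <- fit_joint(dat$g2, dat$y2, ids)
      suppressWarnings(prop_test(f1, f2, n_grid = n_grid))$ppp
    },
    stop_validation("unknown method: ", method))
}

#' Run a simulation study over a scenario grid
#'
#' For each scenario and replicate: generate a fresh panel, simulate both
#' cohorts, apply tag thinning and the minimum-p screen (failing
#' replicates are redrawn, the redraws counted), and run every requested
#' method. All randomness flows from `seed`.
#'
#' @param scenarios a [sim_scenario()] or list of them.
#' @param methods character vector from `C1, C2, P1, P2, P3, PC, BMA2,
#'   BMA3, causal_pair`.
#' @param n_reps replicates per scenario.
#' @param alpha nominal level for the rejection-rate summary.
#' @param seed master seed.
#' @param pc_threshold PC variance threshold used by method `PC`.
#' @param n_grid posterior grid size used by the proportional methods.
#' @param max_redraw maximum redraws per replicate before giving up.
#' @return A `sim_study`: `summary` (scenario_id, method, n_reps,
#'   rejections, rate, se), `detail` (per-replicate p-values, causal-pair
#'   r^2, redraw counts), `alpha`.
#' @export
run_study <- function(scenarios, methods, n_reps, alpha = 0.05, seed = 1,
                      pc_threshold = 0.85, n_grid = 1001, max_redraw = 50) {
  if (inherits(scenarios, "sim_scenario")) scenarios <- list(scenarios)
  detail <- list()
  for (si in seq_along(scenarios)) {
    scen <- scenarios[[si]]
    for (rep in seq_len(n_reps)) {
      dat <- NULL; redraws <- -1L
      for (try in 0:max_redraw) {
        dat <- simulate_pair(scen, derive_seed(seed, si, rep, try))
        redraws <- redraws + 1L
        if (!is.null(dat)) break
      }
      if (is.null(dat)) next
      for (method in methods) {
        pv <- tryCatch(
          apply_method(method, dat, pc_threshold, n_grid,
                       seed = derive_seed(seed, si, rep, 999)),
          error = function(e) NA_real_)
        detail[[length(detail) + 1]] <- data.frame(
          scenario_id = scen$name, method = method, rep = rep,
          p = pv, r2 = dat$r2, redraws = redraws,
          stringsAsFactors = FALSE)
      }
    }
  }
  detail <- if (length(detail) > 0) do.call(rbind, detail)
            else data.frame(scenario_id = character(0), method = character(0),
                            rep = integer(0), p = numeric(0), r2 = numeric(0),
                            redraws = integer(0))
  summary <- summarise_study(detail, alpha)
  structure(list(summary = summary, detail = detail, alpha = alpha),
            class = "sim_study")
}

#' Summarise per-replicate study results into rejection rates
#'
#' @param detail the `detail` table of a [run_study()] result (optionally
#'   pre-filtered, e.g. into r^2 bins).
#' @param alpha nominal level.
#' @return Data frame with scenario_id, method, n_reps, rejections, rate
#'   and binomial standard error.
#' @export
summarise_study <- function(detail, alpha = 0.05) {
  if (nrow(detail) == 0)
    return(data.frame(scenario_id = character(0), method = character(0),
                      n_reps = integer(0), rejections = integer(0),
                      rate = numeric(0), se = numeric(0)))
  agg <- stats::aggregate(p ~ scenario_id + method, data = detail,
                          FUN = function(p) {
                            p <- p[!is.na(p)]
                            c(n = length(p), rej = sum(p < alpha))
                          })
  out <- data.frame(scenario_id = agg$scenario_id, method = agg$method,
                    n_reps = agg$p[, "n"],
                    rejections = agg$p[, "rej"],
                    stringsAsFactors = FALSE)
  out$rate <- ifelse(out$n_reps > 0, out$rejections / out$n_reps, NA)
  out$se <- sqrt(out$rate * (1 - out$rate) / pmax(out$n_reps, 1))
  out
}
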