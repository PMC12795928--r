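#' Trait, environment and latent-truth container
#'
#' Holds the simulated outcome `Y`, the binary environment `E`, covariates,
#' and the latent truth of the generative model: the true genetic value of
#' the outcome (`latent_gY`), the genetic score on which the environment was
#' assigned (`latent_Eg`; identically zero when E is not assigned on a SNP
#' score), and the causal effect vector.
#'
#' @param sample_ids character vector of individual ids.
#' @param Y numeric outcome vector.
#' @param E binary (0/1) environment vector.
#' @param covariates data.frame of named numeric covariates.
#' @param latent_gY numeric vector, true genetic value of Y.
#' @param latent_Eg numeric vector, genetic score driving E.
#' @param true_beta named numeric vector of causal SNP effects (analysis-
#'   sample effects when these differ between cohorts).
#' @return An object of class `trait_data`.
#' @export
trait_data <- function(sample_ids, Y, E, covariates, latent_gY, latent_Eg,
                       true_beta) {
  n <- length(sample_ids)
  if (length(Y) != n || length(E) != n || length(latent_gY) != n ||
      length(latent_Eg) != n || nrow(covariates) != n)
    input_error("trait_data vectors must all have length |sample_ids|")
  if (!is_binary01(E)) input_error("E must be a 0/1 vector")
  structure(list(sample_ids = as.character(sample_ids), Y = as.numeric(Y),
                 E = as.integer(E), covariates = covariates,
                 latent_gY = as.numeric(latent_gY),
                 latent_Eg = as.numeric(latent_Eg),
                 true_beta = true_beta),
            class = "trait_data")
}

#' @export
print.trait_data <- function(x, ...) {
  cat(sprintf("trait_data: n=%d, mean(E)=%.3f, var(Y)=%.3f\n",
              length(x$sample_ids), mean(x$E), stats::var(x$Y)))
  invisible(x)
}

#' Subset trait data by individual ids
#' @param data a [trait_data()].
#' @param ids ids to keep (order respected).
#' @return a `trait_data` restricted to `ids`.
#' @export
subset_traits <- function(data, ids) {
  idx <- match(ids, data$sample_ids)
  if (anyNA(idx)) input_error("unknown sample ids in subset")
  trait_data(ids, data$Y[idx], data$E[idx],
             data$covariates[idx, , drop = FALSE],
             data$latent_gY[idx], data$latent_Eg[idx], data$true_beta)
}

#' Simulate genotypes for a scenario
#'
#' Draws `n_training + n_analysis` individuals at `n_snps` mutually
#' independent SNPs. Ancestral coded-allele frequencies are uniform on
#' `maf_range`; with `fst > 0` two equally sized subpopulations receive
#' Balding-Nichols frequencies `p_s ~ Beta(p(1-fst)/fst, (1-p)(1-fst)/fst)`
#' and dosages are `Binomial(2, p_s)`. SNPs that come out monomorphic in the
#' realized sample are redrawn (fresh ancestral frequency) so downstream
#' standardization is always defined.
#'
#' @param scenario a [sim_scenario()].
#' @return a [genotype_matrix()]; `subpop_labels` is `NULL` when `fst = 0`.
#' @export
simulate_genotypes <- function(scenario) {
  validate_scenario(scenario)
  n <- scenario$n_training + scenario$n_analysis
  if (n < 2L) config_error("need at least 2 individuals in total")
  m <- scenario$n_snps
  set.seed(derive_seed(scenario$seed, 1L))

  subpop <- NULL
  if (scenario$fst > 0)
    subpop <- sample(rep(1:2, length.out = n))

  draw <- function(k) {
    # returns list(p = ancestral freqs (k), X = n x k dosages)
    p <- stats::runif(k, scenario$maf_range[1], scenario$maf_range[2])
    if (is.null(subpop)) {
      X <- matrix(stats::rbinom(n * k, 2L, rep(p, each = n)), n, k)
    } else {
      f <- scenario$fst
      ps <- matrix(stats::rbeta(2L * k, rep(p, 2L) * (1 - f) / f,
                                rep(1 - p, 2L) * (1 - f) / f), k, 2L)
      ps <- pmin(pmax(ps, 1e-6), 1 - 1e-6)
      P <- t(ps)[subpop, , drop = FALSE]          # n x k success probs
      X <- matrix(stats::rbinom(n * k, 2L, P), n, k)
    }
    list(p = p, X = X)
  }

  d <- draw(m)
  p <- d$p; X <- d$X
  for (tries in 1:50) {
    mono <- which(apply(X, 2L, function(col) all(col == col[1L])))
    if (length(mono) == 0L) break
    rd <- draw(length(mono))
    p[mono] <- rd$p
    X[, mono] <- rd$X
  }
  if (length(mono <- which(apply(X, 2L, function(col) all(col == col[1L])))) > 0L)
    degenerate_error("could not obtain polymorphic SNPs; widen maf_range or n")

  genotype_matrix(X, sample_ids = sprintf("id%05d", seq_len(n)),
                  snp_ids = sprintf("snp%04d", seq_len(m)),
                  allele_freq = p, subpop_labels = subpop)
}

# The training/analysis partition is a pure function of the scenario seed,
# shared by simulate_traits (which needs it for hidden_overlap effect
# heterogeneity) and split_sample.
scenario_split_idx <- function(scenario, n) {
  if (scenario$n_training < 1L || scenario$n_analysis < 1L)
    config_error("both n_training and n_analysis must be >= 1 to split")
  if (n != scenario$n_training + scenario$n_analysis)
    config_error("total rows do not equal n_training + n_analysis")
  set.seed(derive_seed(scenario$seed, 3L))
  sort(sample(n, scenario$n_training))
}

#' Simulate outcome and environment for a scenario
#'
#' Causal effects are drawn `N(0, h2_Y / n_causal)` on GCTA-standardized
#' dosages `Z`, so that the genetic value `g_Y = Z beta` satisfies
#' `cov(g_Y) = h2_Y * A` exactly under the GRM built from the same sample.
#' The outcome is `Y = g_Y + e`, `e ~ N(0, 1 - h2_Y)`. The binary
#' environment is assigned per mechanism:
#'
#' * `exogenous`: `E ~ Bernoulli(0.5)`, independent of everything.
#' * `genetic_selection`: `E = 1{ env_loading * standardize(g_Y) + delta > 0 }`
#'   with `delta ~ N(0, 1 - env_loading^2)` (liability threshold at zero, so
#'   strata are balanced in expectation).
#' * `hidden_overlap`: the causal SNPs are split into disjoint sets S1 and S2
#'   with variance shares `h2_Y - s2_share` and `s2_share`; in the training
#'   rows Y loads on S1 only, in the analysis rows on S1 and S2, and E is
#'   thresholded on the S2 score (`latent_Eg`). GWAS weights estimated in the
#'   training rows therefore carry no signal about E while Y and E share the
#'   S2 genetic component in the analysis rows.
#' * `strat_confound`: `E` is the subpopulation label; causal effects are
#'   identical across subpopulations and Y receives an additive mean shift of
#'   `strat_shift` SD for subpopulation 2. Any PGI-ancestry correlation then
#'   reflects allele-frequency differentiation, not shared SNP effects.
#'
#' Two covariates with no effect on Y are always generated (a 0/1 sex
#' analogue and a centered birth-year analogue) so downstream interfaces can
#' exercise covariate handling.
#'
#' @param G genotype matrix from [simulate_genotypes()] under the same
#'   scenario.
#' @param scenario the [sim_scenario()].
#' @return a [trait_data()] for all `n_training + n_analysis` individuals.
#' @export
simulate_traits <- function(G, scenario) {
  validate_scenario(scenario)
  n <- nrow(G$dosages)
  m <- ncol(G$dosages)
  if (m != scenario$n_snps)
    config_error("genotype matrix was not generated under this scenario")
  train_idx <- NULL
  if (identical(scenario$name, "hidden_overlap"))
    train_idx <- scenario_split_idx(scenario, n)

  set.seed(derive_seed(scenario$seed, 2L))
  sd0 <- standardized_dosages(G)
  Z <- sd0$Z
  h2 <- scenario$h2_Y
  causal <- sort(sample(m, scenario$n_causal))
  beta <- numeric(m)
  names(beta) <- G$snp_ids
  Eg <- numeric(n)

  if (identical(scenario$name, "hidden_overlap")) {
    k <- length(causal)
    if (k < 2L) config_error("hidden_overlap needs at least 2 causal SNPs")
    s1 <- causal[seq_len(floor(k / 2))]
    s2 <- setdiff(causal, s1)
    v1 <- (h2 - scenario$s2_share) / length(s1)
    v2 <- scenario$s2_share / length(s2)
    b1 <- numeric(m); b1[s1] <- stats::rnorm(length(s1), 0, sqrt(v1))
    b2 <- numeric(m); b2[s2] <- stats::rnorm(length(s2), 0, sqrt(v2))
    g1 <- drop(Z %*% b1)
    g2 <- drop(Z %*% b2)
    beta <- b1 + b2                       # analysis-sample truth
    names(beta) <- G$snp_ids
    Eg <- g2
    gY <- g1 + g2
    gY[train_idx] <- g1[train_idx]
    e <- stats::rnorm(n)
    Y <- gY + e * sqrt(1 - h2)
    Y[train_idx] <- gY[train_idx] + e[train_idx] *
      sqrt(1 - (h2 - scenario$s2_share))
  } else {
    if (h2 > 0) beta[causal] <- stats::rnorm(scenario$n_causal, 0,
                                             sqrt(h2 / scenario$n_causal))
    gY <- drop(Z %*% beta)
    Y <- gY + stats::rnorm(n, 0, sqrt(1 - h2))
    if (identical(scenario$name, "strat_confound")) {
      if (is.null(G$subpop_labels))
        config_error("strat_confound genotypes must carry subpop_labels")
      Y <- Y + scenario$strat_shift * (G$subpop_labels - 1L)
    }
  }

  covariates <- data.frame(
    sex = stats::rbinom(n, 1L, 0.5),
    birth_year = sample(seq(-2L, 2L), n, replace = TRUE)
  )

  E <- switch(scenario$name,
    exogenous = stats::rbinom(n, 1L, 0.5),
    genetic_selection = {
      lam <- scenario$env_loading
      liab <- lam * standardize(gY) + stats::rnorm(n, 0, sqrt(1 - lam^2))
      Eg <- gY
      as.integer(liab > 0)
    },
    hidden_overlap = {
      lam <- scenario$env_loading
      liab <- lam * standardize(Eg) + stats::rnorm(n, 0, sqrt(1 - lam^2))
      as.integer(liab > 0)
    },
    strat_confound = as.integer(G$subpop_labels - 1L)
  )
  if (identical(scenario$name, "exogenous")) Eg <- numeric(n)

  trait_data(G$sample_ids, Y, E, covariates, gY, Eg, beta)
}

#' Split a simulated cohort into training and analysis samples
#'
#' The partition is deterministic given the scenario (including its seed)
#' and is the same one [simulate_traits()] used for training/analysis effect
#' heterogeneity, so the two are always consistent.
#'
#' @param data a [trait_data()].
#' @param G the matching [genotype_matrix()].
#' @param scenario the [sim_scenario()].
#' @return list with elements `training` and `analysis`, each a list with
#'   elements `G` and `data`.
#' @export
split_sample <- function(data, G, scenario) {
  n <- nrow(G$dosages)
  if (length(data$sample_ids) != n ||
      !identical(data$sample_ids, G$sample_ids))
    input_error("trait data and genotypes carry different individuals")
  idx <- scenario_split_idx(scenario, n)
  tr_ids <- G$sample_ids[idx]
  an_ids <- G$sample_ids[-idx]
  list(
    training = list(G = subset_genotypes(G, tr_ids),
                    data = subset_traits(data, tr_ids)),
    analysis = list(G = subset_genotypes(G, an_ids),
                    data = subset_traits(data, an_ids))
  )
}

#' Simulate a pair of traits with a known genetic correlation
#'
#' Convenience generator for calibration studies of bivariate REML: a single
#' unstructured cohort, per-SNP effect pairs drawn bivariate normal with
#' correlation `rho_g`, and residuals with correlation `rho_e`.
#'
#' @param n individuals; @param m SNPs (all causal).
#' @param h2_1,h2_2 SNP heritabilities of the two traits.
#' @param rho_g true genetic correlation.
#' @param rho_e residual correlation (default 0).
#' @param maf_range ancestral allele-frequency range.
#' @param seed integer seed.
#' @return list with `G` (a [genotype_matrix()]), `y1`, `y2`.
#' @export
simulate_trait_pair <- function(n, m, h2_1 = 0.5, h2_2 = 0.5, rho_g = 0,
                                rho_e = 0, maf_range = c(0.05, 0.5),
                                seed = 1L) {
  sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = n - 1L,
                     n_snps = m, h2_Y = h2_1, maf_range = maf_range,
                     seed = seed)
  G <- simulate_genotypes(sc)
  set.seed(derive_seed(seed, 4L))
  Z <- standardized_dosages(G)$Z
  b1 <- stats::rnorm(m)
  b2 <- rho_g * b1 + sqrt(1 - rho_g^2) * stats::rnorm(m)
  b1 <- b1 * sqrt(h2_1 / m)
  b2 <- b2 * sqrt(h2_2 / m)
  e1 <- stats::rnorm(n)
  e2 <- rho_e * e1 + sqrt(1 - rho_e^2) * stats::rnorm(n)
  list(G = G,
       y1 = drop(Z %*% b1) + e1 * sqrt(1 - h2_1),
       y2 = drop(Z %*% b2) + e2 * sqrt(1 - h2_2))
}
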