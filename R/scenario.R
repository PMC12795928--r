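SCENARIO_NAMES <- c("exogenous", "genetic_selection", "hidden_overlap",
                    "strat_confound")

#' Simulation scenario configuration
#'
#' A scenario fixes one gene-environment correlation mechanism and the cohort
#' dimensions under which it is simulated. The four mechanisms correspond to
#' the four cells of the Corr(PGI, E) x r_g(Y, E) quadrant:
#'
#' * `exogenous` — E assigned by a fair coin, independent of everything
#'   (policy-reform analogue; both test families should stay silent).
#' * `genetic_selection` — E selected on the outcome's own genetic value
#'   through a liability threshold (both families should reject).
#' * `hidden_overlap` — E selected on a genetic score built from causal SNPs
#'   whose effects are absent in the GWAS training sample, so the PGI carries
#'   no signal about E while the genetic correlation between Y and E is real.
#' * `strat_confound` — E is a subpopulation label under Balding-Nichols
#'   differentiation; the PGI picks up ancestry via an uncorrected training
#'   GWAS while the genetic correlation vanishes once ancestry is adjusted.
#'
#' @param name one of `"exogenous"`, `"genetic_selection"`, `"hidden_overlap"`,
#'   `"strat_confound"`.
#' @param n_training GWAS training-sample size.
#' @param n_analysis analysis-sample size.
#' @param n_snps number of simulated (linkage-equilibrium) SNPs.
#' @param n_causal number of causal SNPs (`<= n_snps`).
#' @param h2_Y SNP heritability of the outcome in the analysis sample, in
#'   `[0, 1]`.
#' @param env_loading loading of the environment's liability on its genetic
#'   score, in `[-1, 1]`. Used by `genetic_selection` and `hidden_overlap`.
#' @param fst Balding-Nichols differentiation between the two subpopulations,
#'   in `[0, 1)`; 0 means panmictic.
#' @param maf_range length-2 numeric, ancestral minor/coded allele frequency
#'   range to draw from.
#' @param gwas_noise_sd extra normal noise added to estimated GWAS weights
#'   (an alternative weight-measurement-error mechanism; default 0).
#' @param s2_share share of Var(Y) explained by the hidden causal set S2 in
#'   the analysis sample (`hidden_overlap` only; must be `< h2_Y`).
#' @param strat_shift additive mean shift of Y (in SD units) for
#'   subpopulation 2 (`strat_confound` only).
#' @param seed integer seed; all simulation output is a pure function of the
#'   scenario including this seed.
#'
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(name,
                         n_training = 2000L, n_analysis = 2000L,
                         n_snps = 1000L, n_causal = n_snps,
                         h2_Y = 0.5,
                         env_loading = switch(name, genetic_selection = 0.8,
                                              hidden_overlap = 0.9, 0),
                         fst = if (identical(name, "strat_confound")) 0.05 else 0,
                         maf_range = c(0.05, 0.5),
                         gwas_noise_sd = 0,
                         s2_share = 0.25,
                         strat_shift = 0.5,
                         seed = 1L) {
  name <- match.arg(name, SCENARIO_NAMES)
  sc <- structure(list(
    name = name, n_training = as.integer(n_training),
    n_analysis = as.integer(n_analysis), n_snps = as.integer(n_snps),
    n_causal = as.integer(n_causal), h2_Y = h2_Y,
    env_loading = env_loading, fst = fst, maf_range = as.numeric(maf_range),
    gwas_noise_sd = gwas_noise_sd, s2_share = s2_share,
    strat_shift = strat_shift, seed = as.integer(seed)
  ), class = "sim_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  with(sc, {
    if (n_training < 0L || n_analysis < 0L || n_snps < 1L)
      config_error("sample and SNP counts must be non-negative (n_snps >= 1)")
    if (n_causal < 1L || n_causal > n_snps)
      config_error("n_causal must lie in [1, n_snps]")
    if (h2_Y < 0 || h2_Y > 1) config_error("h2_Y must lie in [0, 1]")
    if (abs(env_loading) > 1) config_error("env_loading must lie in [-1, 1]")
    if (fst < 0 || fst >= 1) config_error("fst must lie in [0, 1)")
    if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] >= 1 ||
        maf_range[1] > maf_range[2])
      config_error("maf_range must be (low, high) inside (0, 1)")
    if (gwas_noise_sd < 0) config_error("gwas_noise_sd must be >= 0")
    if (identical(name, "hidden_overlap") && (s2_share < 0 || s2_share >= h2_Y))
      config_error("s2_share must lie in [0, h2_Y) for hidden_overlap")
    if (identical(name, "strat_confound") && fst == 0)
      config_error("strat_confound requires fst > 0")
  })
  invisible(sc)
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "sim_scenario '%s': n_training=%d n_analysis=%d n_snps=%d n_causal=%d\n",
    x$name, x$n_training, x$n_analysis, x$n_snps, x$n_causal))
  cat(sprintf("  h2_Y=%.3g env_loading=%.3g fst=%.3g seed=%d\n",
              x$h2_Y, x$env_loading, x$fst, x$seed))
  invisible(x)
}

#' Read / write a scenario as JSON
#'
#' @param path JSON file path.
#' @param sc a [sim_scenario()].
#' @return `read_scenario` returns a `sim_scenario`; `write_scenario`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_scenario, cfg)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(sc, path) {
  jsonlite::write_json(unclass(sc), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
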