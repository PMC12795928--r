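#' Write / read a phenotype table (TSV: id, Y, E, covariates...)
#'
#' @param data a [trait_data()]; @param path file path.
#' @export
write_pheno <- function(data, path) {
  dt <- data.table::data.table(id = data$sample_ids, Y = data$Y, E = data$E)
  dt <- cbind(dt, data.table::as.data.table(data$covariates))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pheno
#' @return `read_pheno` returns a list with `sample_ids`, `Y`, `E`,
#'   `covariates` (a data.frame of all remaining columns).
#' @export
read_pheno <- function(path) {
  dt <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("id", "Y", "E")
  if (!all(need %in% names(dt)))
    input_error("phenotype file needs columns id, Y, E")
  list(sample_ids = as.character(dt$id), Y = dt$Y, E = dt$E,
       covariates = dt[setdiff(names(dt), need)])
}

write_truth <- function(data, path) {
  data.table::fwrite(
    data.table::data.table(id = data$sample_ids, latent_gY = data$latent_gY,
                           latent_Eg = data$latent_Eg),
    path, sep = "\t")
  invisible(path)
}

run_stage <- function(stage, expr) {
  withCallingHandlers(
    tryCatch(expr, error = function(e) {
      cls <- setdiff(class(e), c("error", "condition"))
      stop(structure(class = c(cls, "error", "condition"),
                     list(message = sprintf("[stage %s] %s", stage,
                                            conditionMessage(e)),
                          call = NULL)))
    }),
    warning = function(w) w)
}

#' Pipeline configuration
#'
#' @param scenario a [sim_scenario()] (or a list of its arguments), for
#'   simulated runs. Ignored when `files` is supplied.
#' @param files optional list with paths `geno`, `pheno` and `weights` to
#'   run the battery on existing data instead of a simulation.
#' @param prune_threshold relatedness cutoff for [prune_related()]. The
#'   default `NULL` resolves to `max(0.025, 5 / sqrt(m))` once the GRM SNP
#'   count `m` is known: off-diagonal GRM entries between unrelated
#'   individuals have sampling noise of order `1 / sqrt(m)`, so a cutoff
#'   meant to flag true relatedness must sit well above that noise floor.
#'   For real-scale panels (hundreds of thousands of SNPs) this reduces to
#'   the conventional 0.025.
#' @param pcs number of GRM principal components used as GREML fixed
#'   effects.
#' @param alpha significance level for the verdict.
#' @param gwas_covariates names of covariate columns residualized out of
#'   the phenotype in the training GWAS.
#' @param report_covariates names of covariate columns used for the
#'   conditional correlation and the G-by-E fits.
#' @return a named list (class `gxe_config`).
#' @export
gxe_config <- function(scenario = NULL, files = NULL,
                       prune_threshold = NULL, pcs = 10L, alpha = 0.05,
                       gwas_covariates = c("sex", "birth_year"),
                       report_covariates = c("sex", "birth_year")) {
  if (is.null(scenario) && is.null(files))
    config_error("config needs either a scenario or input files")
  if (!is.null(scenario) && !inherits(scenario, "sim_scenario"))
    scenario <- do.call(sim_scenario, scenario)
  structure(list(scenario = scenario, files = files,
                 prune_threshold = prune_threshold, pcs = as.integer(pcs),
                 alpha = alpha, gwas_covariates = gwas_covariates,
                 report_covariates = report_covariates),
            class = "gxe_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file path.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(gxe_config, cfg)
}

#' Run the full orthogonality pipeline
#'
#' Simulation mode: simulate the scenario, split into training and analysis
#' cohorts, run the training GWAS, build the GRM on the analysis sample and
#' prune related individuals, score the PGI, assemble the orthogonality
#' report, and — unless the verdict is `not_orthogonal`, in which case the
#' stage is skipped with a warning — fit the simple and robust G-by-E
#' specifications. File mode (`config$files`) runs the same battery on
#' supplied genotype/phenotype/weight files.
#'
#' All artifacts are written only after every stage has succeeded (no
#' partial outputs); report bodies contain no timestamps, so runs with the
#' same configuration are byte-identical.
#'
#' @param config a [gxe_config()] (or path to its JSON form).
#' @param out_dir optional output directory for artifacts.
#' @param write_geno also write the simulated genotype matrix (large).
#' @return list of class `gxe_pipeline`: `report`, `gxe_simple`,
#'   `gxe_robust`, `gxe_comparison`, `gxe_skipped`, `kept_ids`, `config`,
#'   `gwas`, `pgi`, `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL, write_geno = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "gxe_config")) config <- do.call(gxe_config, config)

  gwas <- NULL
  if (is.null(config$files)) {
    sc <- config$scenario
    G <- run_stage("simulate", simulate_genotypes(sc))
    td <- run_stage("simulate", simulate_traits(G, sc))
    sp <- run_stage("split", split_sample(td, G, sc))
    gwas <- run_stage("gwas", {
      covs <- sp$training$data$covariates[
        intersect(config$gwas_covariates,
                  names(sp$training$data$covariates))]
      g <- run_gwas(sp$training$G, sp$training$data$Y,
                    if (ncol(covs)) covs else NULL)
      if (sc$gwas_noise_sd > 0) {
        set.seed(derive_seed(sc$seed, 5L))
        g$beta <- g$beta + stats::rnorm(length(g$beta), 0, sc$gwas_noise_sd)
      }
      g
    })
    G_an <- sp$analysis$G
    d_an <- sp$analysis$data
    weights <- gwas
  } else {
    f <- config$files
    for (nm in c("geno", "pheno", "weights"))
      if (is.null(f[[nm]]) || !file.exists(f[[nm]]))
        run_stage("load", input_error(sprintf("missing %s file", nm)))
    G_an <- run_stage("load", read_geno(f$geno))
    ph <- run_stage("load", read_pheno(f$pheno))
    if (!identical(ph$sample_ids, G_an$sample_ids)) {
      G_an <- run_stage("load", subset_genotypes(G_an, ph$sample_ids))
    }
    d_an <- trait_data(ph$sample_ids, ph$Y, ph$E, ph$covariates,
                       numeric(length(ph$Y)), numeric(length(ph$Y)),
                       numeric(0))
    weights <- run_stage("load", read_sumstats(f$weights))
  }

  A <- run_stage("grm", compute_grm(G_an))
  thr <- config$prune_threshold %||%
    max(0.025, 5 / sqrt(A$n_snps_used))
  kept <- run_stage("prune", prune_related(A, thr))
  if (length(kept) < length(A$sample_ids)) {
    A <- subset_grm(A, kept)
    G_an <- subset_genotypes(G_an, kept)
    d_an <- subset_traits(d_an, kept)
  }
  pgi <- run_stage("pgi", build_pgi(G_an, weights))
  covs <- d_an$covariates[
    intersect(config$report_covariates, names(d_an$covariates))]
  if (!ncol(covs)) covs <- NULL
  report <- run_stage("orthotest",
    orthogonality_report(pgi, d_an$Y, d_an$E, covs, A,
                         pcs = config$pcs, alpha = config$alpha))

  gxe_simple <- gxe_robust <- comparison <- NULL
  skipped <- identical(report$verdict$label, "not_orthogonal")
  if (skipped) {
    warning("verdict is not_orthogonal: G x E stage skipped (a biased ",
            "moderator would produce uninterpretable interaction estimates)")
  } else {
    gxe_simple <- run_stage("gxe",
      fit_gxe(d_an$Y, pgi, d_an$E, covs, spec = "simple"))
    gxe_robust <- run_stage("gxe",
      fit_gxe(d_an$Y, pgi, d_an$E, covs, spec = "robust"))
    comparison <- compare_specs(gxe_simple, gxe_robust)
  }

  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(out_dir, x)
    if (!is.null(config$scenario))
      write_scenario(config$scenario, fp("scenario.json"))
    write_pheno(d_an, fp("pheno.tsv"))
    if (is.null(config$files)) write_truth(d_an, fp("truth.tsv"))
    if (!is.null(gwas)) write_sumstats(gwas, fp("sumstats.tsv"))
    write_pgi(pgi, fp("pgi.tsv"))
    write_ortho_report(report, fp("report.json"))
    if (!skipped) {
      jsonlite::write_json(
        list(simple = gxe_simple$terms, robust = gxe_robust$terms,
             n = gxe_simple$n,
             r2 = c(simple = gxe_simple$r2, robust = gxe_robust$r2)),
        fp("gxe.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    if (write_geno && is.null(config$files)) write_geno(G_an, fp("geno.txt"))
    paths <- list.files(out_dir, full.names = TRUE)
  }

  structure(list(report = report, gxe_simple = gxe_simple,
                 gxe_robust = gxe_robust, gxe_comparison = comparison,
                 gxe_skipped = skipped, kept_ids = kept, config = config,
                 gwas = gwas, pgi = pgi, paths = paths),
            class = "gxe_pipeline")
}

#' @export
print.gxe_pipeline <- function(x, ...) {
  print(x$report)
  if (x$gxe_skipped) {
    cat("G x E stage skipped (not_orthogonal verdict)\n")
  } else {
    print(x$gxe_simple); print(x$gxe_robust)
  }
  invisible(x)
}

#' Scenario study: rejection rates of the two test families
#'
#' Repeats [run_pipeline()] over `n_reps` seeds per scenario (seed of rep
#' `i` is `base_seed + i - 1`, so single reps can be re-run in isolation)
#' and tabulates how often each orthogonality test rejects at `alpha`. An
#' unavailable genetic correlation (boundary heritability) counts as a
#' non-rejection, mirroring how an N.A. entry is read in practice. Failed
#' reps are recorded and excluded from denominators with a warning.
#'
#' @param scenarios character vector of scenario names and/or a list of
#'   [sim_scenario()] objects.
#' @param n_reps repetitions per scenario (>= 1).
#' @param base_seed first seed.
#' @param alpha rejection level.
#' @param ... forwarded to [gxe_config()] (e.g. `pcs`, `gwas_covariates`).
#' @return data.frame of class `scenario_study`: one row per scenario with
#'   `rejection_rate_corr`, `rejection_rate_cond`, `rejection_rate_ks`,
#'   `rejection_rate_rg`, `mean_h2_env`, `mean_rho_g`, `n_reps`, `n_failed`;
#'   per-rep detail in `attr(, "details")`, seeds in `attr(, "seeds")`.
#' @export
run_scenario_study <- function(scenarios, n_reps = 50L, base_seed = 1L,
                               alpha = 0.05, ...) {
  if (n_reps < 1L) config_error("n_reps must be >= 1")
  if (!is.list(scenarios)) scenarios <- as.list(scenarios)
  seeds <- base_seed + seq_len(n_reps) - 1L
  rows <- list(); details <- list()
  for (sc0 in scenarios) {
    name <- if (inherits(sc0, "sim_scenario")) sc0$name else sc0
    det <- data.frame(seed = seeds, corr_p = NA_real_, cond_p = NA_real_,
                      ks_p = NA_real_, rg_p = NA_real_, h2_env = NA_real_,
                      rho_g = NA_real_, failed = FALSE)
    for (i in seq_len(n_reps)) {
      sc <- if (inherits(sc0, "sim_scenario")) {
        sc0$seed <- seeds[i]; validate_scenario(sc0); sc0
      } else sim_scenario(sc0, seed = seeds[i])
      rep_out <- tryCatch(
        suppressWarnings(run_pipeline(gxe_config(scenario = sc, ...))),
        error = function(e) e)
      if (inherits(rep_out, "error")) {
        det$failed[i] <- TRUE
        next
      }
      r <- rep_out$report
      det$corr_p[i] <- r$t_p
      det$cond_p[i] <- r$cond_p
      det$ks_p[i] <- r$ks_p
      det$rg_p[i] <- r$rho_g_p
      det$h2_env[i] <- r$h2_env[1L]
      det$rho_g[i] <- r$rho_g[1L]
    }
    ok <- !det$failed
    if (any(det$failed))
      warning(sprintf("%d/%d reps failed for scenario %s",
                      sum(det$failed), n_reps, name))
    denom <- sum(ok)
    rej <- function(p) sum(!is.na(p[ok]) & p[ok] < alpha) / denom
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = name, n_reps = denom, n_failed = sum(det$failed),
      rejection_rate_corr = rej(det$corr_p),
      rejection_rate_cond = rej(det$cond_p),
      rejection_rate_ks = rej(det$ks_p),
      rejection_rate_rg = rej(det$rg_p),
      mean_h2_env = mean(det$h2_env[ok], na.rm = TRUE),
      mean_rho_g = if (all(is.na(det$rho_g[ok]))) NA_real_
                   else mean(det$rho_g[ok], na.rm = TRUE),
      stringsAsFactors = FALSE)
    details[[name]] <- det
  }
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  attr(out, "seeds") <- seeds
  attr(out, "alpha") <- alpha
  class(out) <- c("scenario_study", "data.frame")
  out
}
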