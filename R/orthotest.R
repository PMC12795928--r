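new_ortho_test <- function(statistic, pvalue, kind, n0, n1, estimate = NA_real_) {
  structure(list(statistic = statistic, pvalue = pvalue, kind = kind,
                 n0 = as.integer(n0), n1 = as.integer(n1),
                 estimate = estimate),
            class = "ortho_test")
}

#' @export
print.ortho_test <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4f, p = %.4g (n0 = %d, n1 = %d)\n",
              x$kind, x$statistic, x$pvalue, x$n0, x$n1))
  invisible(x)
}

pgi_scores <- function(pgi) {
  if (inherits(pgi, "pgi")) pgi$score else as.numeric(pgi)
}

check_strata <- function(score, E, min_size = 1L) {
  if (length(E) != length(score))
    input_error("PGI and environment have different lengths")
  if (!is_binary01(E)) input_error("E must be a 0/1 vector")
  n1 <- sum(E == 1L); n0 <- sum(E == 0L)
  if (n0 < min_size || n1 < min_size)
    input_error(sprintf("each environmental stratum needs >= %d observations",
                        min_size))
  c(n0 = n0, n1 = n1)
}

#' Pooled-variance t test of the PGI mean across environmental strata
#'
#' Student's two-sample t (stratum E = 1 minus E = 0, pooled variance,
#' `n - 2` df, two-sided). For a binary environment this is algebraically
#' the Pearson correlation test between PGI and E: the reported p-value
#' equals the correlation-test p exactly.
#'
#' @param pgi a `pgi` object or numeric vector.
#' @param E binary 0/1 environment, both strata of size >= 2.
#' @return an `ortho_test` (kind `"t"`); `estimate` carries the Pearson
#'   correlation between PGI and E.
#' @export
test_mean_difference <- function(pgi, E) {
  s <- pgi_scores(pgi)
  ns <- check_strata(s, E, min_size = 2L)
  n <- length(s)
  x0 <- s[E == 0L]; x1 <- s[E == 1L]
  sp2 <- (sum((x0 - mean(x0))^2) + sum((x1 - mean(x1))^2)) / (n - 2L)
  tstat <- unname((mean(x1) - mean(x0)) /
                    sqrt(sp2 * (1 / ns["n0"] + 1 / ns["n1"])))
  p <- 2 * stats::pt(abs(tstat), df = n - 2L, lower.tail = FALSE)
  new_ortho_test(tstat, p, "t", ns["n0"], ns["n1"],
                 estimate = stats::cor(s, E))
}

#' Conditional correlation between the residualized PGI and the environment
#'
#' Residualizes the PGI on the covariates (plus intercept) and correlates
#' the residuals with E; the p-value uses the t transform of the correlation
#' on `n - 2 - p_cov` degrees of freedom. With an empty covariate set this
#' reduces to the marginal correlation test.
#'
#' @inheritParams test_mean_difference
#' @param covariates data.frame/matrix of covariates (may be `NULL`).
#' @return an `ortho_test` (kind `"cond_corr"`); `estimate` is the
#'   conditional correlation.
#' @export
test_conditional_correlation <- function(pgi, E, covariates = NULL) {
  s <- pgi_scores(pgi)
  ns <- check_strata(s, E, min_size = 2L)
  n <- length(s)
  p_cov <- if (is.null(covariates)) 0L
           else ncol(covariate_matrix(covariates, n))
  r <- residualize(s, covariates)
  if (stats::sd(r) < 1e-12) {
    # PGI fully explained by the covariates: zero conditional correlation
    return(new_ortho_test(0, 1, "cond_corr", ns["n0"], ns["n1"],
                          estimate = 0))
  }
  rho <- stats::cor(r, E)
  df <- n - 2L - p_cov
  if (df < 1L) input_error("too few observations for the covariate set")
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  }
  new_ortho_test(rho, p, "cond_corr", ns["n0"], ns["n1"], estimate = rho)
}

#' Two-sample Kolmogorov-Smirnov test of the PGI distribution across strata
#'
#' `D = sup_x |F0(x) - F1(x)|` between the empirical CDFs of the two
#' environmental strata; exact p-value when `n0 * n1 <= 10000` (and the
#' data are free of ties), asymptotic Kolmogorov distribution otherwise.
#'
#' @inheritParams test_mean_difference
#' @return an `ortho_test` (kind `"ks"`).
#' @export
test_ks <- function(pgi, E) {
  s <- pgi_scores(pgi)
  ns <- check_strata(s, E, min_size = 1L)
  x0 <- s[E == 0L]; x1 <- s[E == 1L]
  exact <- as.numeric(ns["n0"]) * as.numeric(ns["n1"]) <= 10000 &&
    !anyDuplicated(s)
  kt <- suppressWarnings(stats::ks.test(x0, x1, exact = exact))
  new_ortho_test(unname(kt$statistic), unname(kt$p.value), "ks",
                 ns["n0"], ns["n1"])
}

QUADRANT_LABELS <- c("orthogonal", "env_non_genetic",
                     "hidden_genetic_overlap", "not_orthogonal")

#' Four-quadrant interpretation of the two orthogonality test families
#'
#' Combines the PGI-by-environment correlation verdict with the bivariate
#' GREML genetic-correlation verdict:
#'
#' | Corr(PGI, E) sig. | r_g(Y, E) sig. | label |
#' |---|---|---|
#' | no  | no  | `orthogonal` — E can be used for G-by-E interplay analysis |
#' | yes | no  | `env_non_genetic` — genetic channels behind the PGI-E
#'   correlation are ruled out; look for environmental causes (non-genetic
#'   selection, differential exposure between training and analysis sample) |
#' | no  | yes | `hidden_genetic_overlap` — genetic mechanisms not captured
#'   by the PGI weights link Y and E |
#' | yes | yes | `not_orthogonal` — E cannot serve as an exogenous moderator;
#'   the direction of the interaction bias is undetermined |
#'
#' @param corr_significant logical: did the PGI-E correlation test reject?
#' @param rg_significant logical: did the LRT of `rho_g = 0` reject? (An
#'   unavailable `rho_g` counts as a non-rejection.)
#' @param alpha the significance level both flags were derived at.
#' @return An object of class `quadrant_verdict` with `label` and
#'   `rationale`.
#' @export
classify_quadrant <- function(corr_significant, rg_significant,
                              alpha = 0.05) {
  stopifnot(is.logical(corr_significant), is.logical(rg_significant))
  label <- if (!corr_significant && !rg_significant) "orthogonal"
    else if (corr_significant && !rg_significant) "env_non_genetic"
    else if (!corr_significant && rg_significant) "hidden_genetic_overlap"
    else "not_orthogonal"
  rationale <- switch(label,
    orthogonal = paste0(
      "No PGI-environment correlation and no genetic correlation at alpha = ",
      alpha, ": the environment can be used for GxE interplay analysis."),
    env_non_genetic = paste0(
      "The PGI correlates with the environment but Y and E share no ",
      "SNP-based genetic component: genetic channels are ruled out; the ",
      "correlation points to environmental causes such as non-genetic ",
      "selection or differential exposure across samples."),
    hidden_genetic_overlap = paste0(
      "The PGI appears uncorrelated with the environment, yet Y and E are ",
      "genetically correlated: genetic mechanisms not captured by the GWAS ",
      "weights link outcome and environment."),
    not_orthogonal = paste0(
      "Both the PGI-environment correlation and the genetic correlation are ",
      "significant: the environment cannot be used as an exogenous ",
      "moderator; the direction of the interaction bias is undetermined."))
  structure(list(label = label, rationale = rationale, alpha = alpha),
            class = "quadrant_verdict")
}

#' @export
print.quadrant_verdict <- function(x, ...) {
  cat(sprintf("verdict: %s\n  %s\n", x$label, x$rationale))
  invisible(x)
}

#' Full orthogonality report for one outcome/environment pair
#'
#' Runs the three PGI-distribution tests, univariate GREML on the outcome
#' and on the environment, and — unless a genetic variance is at the zero
#' boundary — bivariate GREML with the likelihood-ratio test of
#' `rho_g = 0`. The quadrant verdict uses the conditional-correlation
#' p-value when covariates are supplied (the t-test p otherwise) together
#' with the LRT p-value; an unavailable `rho_g` counts as non-significant.
#'
#' @param pgi a `pgi` object or numeric vector (analysis sample).
#' @param Y outcome vector.
#' @param E binary environment vector.
#' @param covariates data.frame of covariates for the conditional
#'   correlation (may be `NULL`).
#' @param A a `grm` for the same individuals.
#' @param pcs number of GRM principal components used as GREML fixed
#'   effects (default 10).
#' @param alpha significance level for the verdict (default 0.05).
#' @return An object of class `ortho_report`.
#' @export
orthogonality_report <- function(pgi, Y, E, covariates = NULL, A,
                                 pcs = 10L, alpha = 0.05) {
  s <- pgi_scores(pgi)
  n <- length(s)
  if (length(Y) != n || length(E) != n || length(A$sample_ids) != n)
    input_error("pgi, Y, E and GRM must cover the same individuals")
  A <- grm_with_spectral(A)

  t_res <- test_mean_difference(s, E)
  cond_res <- test_conditional_correlation(s, E, covariates)
  ks_res <- test_ks(s, E)

  X <- cbind(`(Intercept)` = 1,
             if (pcs > 0L) grm_principal_components(A, pcs))
  errors <- character(0)
  fit_y <- tryCatch(reml_univariate(A, Y, X),
                    error = function(e) { e })
  fit_e <- tryCatch(reml_univariate(A, E, X),
                    error = function(e) { e })
  h2 <- function(f) if (inherits(f, "greml_uni")) c(f$h2, f$se_h2)
                    else c(NA_real_, NA_real_)
  for (f in list(fit_y, fit_e))
    if (inherits(f, "error")) errors <- c(errors, conditionMessage(f))

  biv <- NULL
  rho_g <- c(NA_real_, NA_real_); rho_g_p <- NA_real_
  rg_available <- FALSE
  boundary_env <- inherits(fit_e, "greml_uni") && fit_e$boundary
  boundary_y <- inherits(fit_y, "greml_uni") && fit_y$boundary
  if (inherits(fit_y, "greml_uni") && inherits(fit_e, "greml_uni") &&
      !boundary_env && !boundary_y) {
    biv <- tryCatch(reml_bivariate(A, Y, E, X), error = function(e) e)
    if (inherits(biv, "error")) {
      errors <- c(errors, conditionMessage(biv))
      biv <- NULL
    } else if (biv$rg_available) {
      rg_available <- TRUE
      rho_g <- c(biv$rho_g, biv$se_rho_g)
      rho_g_p <- biv$lrt_p
    }
  }

  corr_p <- if (!is.null(covariates)) cond_res$pvalue else t_res$pvalue
  verdict <- classify_quadrant(corr_p < alpha,
                               rg_available && rho_g_p < alpha, alpha)

  structure(list(
    corr_pgi_env = t_res$estimate,
    t_stat = t_res$statistic, t_p = t_res$pvalue,
    cond_corr = cond_res$estimate, cond_p = cond_res$pvalue,
    ks_stat = ks_res$statistic, ks_p = ks_res$pvalue,
    h2_trait = h2(fit_y), h2_env = h2(fit_e),
    rho_g = rho_g, rho_g_p = rho_g_p, rg_available = rg_available,
    n = n, alpha = alpha, verdict = verdict,
    bivar = biv, errors = errors
  ), class = "ortho_report")
}

#' @export
print.ortho_report <- function(x, ...) {
  fmt <- function(v, se) {
    if (is.na(v)) "N.A." else sprintf("%.3f (%.3f)", v, se)
  }
  cat("Orthogonality report\n")
  cat(sprintf("  corr(PGI, E)        %8.4f   (t = %.3f, p = %.4g)\n",
              x$corr_pgi_env, x$t_stat, x$t_p))
  cat(sprintf("  corr | covariates   %8.4f   (p = %.4g)\n",
              x$cond_corr, x$cond_p))
  cat(sprintf("  KS statistic        %8.4f   (p = %.4g)\n",
              x$ks_stat, x$ks_p))
  cat(sprintf("  h2_SNP (trait)      %s\n", fmt(x$h2_trait[1], x$h2_trait[2])))
  cat(sprintf("  h2_SNP (env)        %s\n", fmt(x$h2_env[1], x$h2_env[2])))
  cat(sprintf("  rho_g               %s\n", fmt(x$rho_g[1], x$rho_g[2])))
  cat(sprintf("  LRT p (rho_g = 0)   %s\n",
              if (is.na(x$rho_g_p)) "N.A." else sprintf("%.4g", x$rho_g_p)))
  cat(sprintf("  N = %d\n", x$n))
  print(x$verdict)
  if (length(x$errors)) cat("  component errors:",
                            paste(x$errors, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize / restore an orthogonality report (JSON)
#'
#' The serialized body contains every report field except the raw bivariate
#' fit object; the round trip is field-identical. No timestamps are written,
#' so two runs of the same seeded configuration produce byte-identical
#' files.
#'
#' @param report an `ortho_report`; @param path JSON file path.
#' @export
write_ortho_report <- function(report, path) {
  body <- report[c("corr_pgi_env", "t_stat", "t_p", "cond_corr", "cond_p",
                   "ks_stat", "ks_p", "h2_trait", "h2_env", "rho_g",
                   "rho_g_p", "rg_available", "n", "alpha", "errors")]
  body$verdict <- report$verdict[c("label", "rationale", "alpha")]
  body$schema <- "gxeortho/ortho_report/1"
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_ortho_report
#' @export
read_ortho_report <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  verdict <- structure(list(label = b$verdict$label,
                            rationale = b$verdict$rationale,
                            alpha = b$verdict$alpha),
                       class = "quadrant_verdict")
  null2na <- function(v, k = 1L) {
    if (is.null(v) || length(v) == 0L) rep(NA_real_, k) else as.numeric(v)
  }
  structure(list(
    corr_pgi_env = b$corr_pgi_env, t_stat = b$t_stat, t_p = b$t_p,
    cond_corr = b$cond_corr, cond_p = b$cond_p,
    ks_stat = b$ks_stat, ks_p = b$ks_p,
    h2_trait = null2na(b$h2_trait, 2L), h2_env = null2na(b$h2_env, 2L),
    rho_g = null2na(b$rho_g, 2L), rho_g_p = null2na(b$rho_g_p),
    rg_available = b$rg_available, n = b$n, alpha = b$alpha,
    verdict = verdict, bivar = NULL,
    errors = as.character(b$errors %||% character(0))
  ), class = "ortho_report")
}
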