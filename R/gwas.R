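#' Per-SNP association scan (training-sample GWAS)
#'
#' The phenotype is residualized once on the covariates plus an intercept;
#' each SNP is then regressed on the residuals by simple least squares. This
#' residualize-then-regress order mirrors standard GWAS practice for
#' pre-adjusted phenotypes. P-values are two-sided on a Student t with
#' `n - 2` degrees of freedom. Monomorphic SNPs are reported with
#' `beta = 0`, `se = Inf`, `p = 1`; an exactly perfect fit (residual variance
#' numerically zero, `se < 1e-12`) is reported with `p = 0`.
#'
#' @param G a [genotype_matrix()].
#' @param y numeric phenotype vector.
#' @param covariates optional data.frame/matrix of covariates (residualized
#'   out before the scan).
#' @return An object of class `gwas_result`: fields `snp_ids`, `beta`, `se`,
#'   `pvalue`, `n_used`, `effect_allele`.
#' @export
run_gwas <- function(G, y, covariates = NULL) {
  n <- nrow(G$dosages)
  if (length(y) != n) input_error("phenotype length does not match genotypes")
  if (any(!is.finite(y))) input_error("phenotype contains non-finite values")
  p_cov <- if (is.null(covariates)) 0L else ncol(covariate_matrix(covariates, n))
  if (n <= p_cov + 2L) input_error("too few individuals for the covariate set")
  r <- residualize(y, covariates)
  if (stats::sd(r) < 1e-12)
    degenerate_error("phenotype variance is zero after residualization")

  X <- G$dosages
  xbar <- colMeans(X)
  Sxx <- colSums(X * X) - n * xbar^2
  Sxy <- drop(crossprod(X, r)) - n * xbar * mean(r)  # r is centered anyway
  Syy <- sum(r^2)
  mono <- Sxx < 1e-12

  beta <- se <- pval <- numeric(ncol(X))
  beta[!mono] <- Sxy[!mono] / Sxx[!mono]
  rss <- pmax(Syy - beta * Sxy, 0)
  s2 <- rss / (n - 2L)
  se[!mono] <- sqrt(s2[!mono] / Sxx[!mono])
  tiny <- !mono & se < 1e-12
  ok <- !mono & !tiny
  pval[ok] <- 2 * stats::pt(abs(beta[ok] / se[ok]), df = n - 2L,
                            lower.tail = FALSE)
  pval[tiny] <- 0
  beta[mono] <- 0; se[mono] <- Inf; pval[mono] <- 1

  structure(list(snp_ids = G$snp_ids, beta = beta, se = se, pvalue = pval,
                 n_used = n,
                 effect_allele = G$coded_allele %||%
                   rep("A", length(G$snp_ids))),
            class = "gwas_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gwas_result <- function(x, ...) {
  cat(sprintf("gwas_result: %d SNPs, n=%d, min p=%.3g\n",
              length(x$snp_ids), x$n_used, min(x$pvalue)))
  invisible(x)
}

#' @export
as.data.frame.gwas_result <- function(x, ...) {
  data.frame(snp_id = x$snp_ids, effect_allele = x$effect_allele,
             beta = x$beta, se = x$se, p = x$pvalue, n = x$n_used)
}

#' Write / read GWAS summary statistics (TSV)
#'
#' Columns: `snp_id`, `effect_allele`, `beta`, `se`, `p`, `n`.
#'
#' @param gwas a `gwas_result` (or a data.frame in the same layout).
#' @param path file path.
#' @return `read_sumstats` returns a data.frame usable as a weight table.
#' @export
write_sumstats <- function(gwas, path) {
  df <- if (is.data.frame(gwas)) gwas else as.data.frame(gwas)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}

#' Construct a standardized polygenic index
#'
#' Raw score: the weighted sum of dosages over the SNPs shared between the
#' genotypes and the weight table, then standardized to mean 0 / sd 1. When
#' both sides carry allele labels, dosages of SNPs whose coded allele
#' mismatches the weight's effect allele are flipped (`x -> 2 - x`).
#'
#' @param G a [genotype_matrix()] (n >= 2).
#' @param weights a `gwas_result` or a data.frame with columns `snp_id`,
#'   `beta` (or `weight`), optionally `effect_allele`.
#' @return An object of class `pgi`: fields `sample_ids`, `score`
#'   (mean 0, sd 1 within 1e-8).
#' @export
build_pgi <- function(G, weights) {
  if (nrow(G$dosages) < 2L) input_error("PGI needs at least 2 individuals")
  if (inherits(weights, "gwas_result")) weights <- as.data.frame(weights)
  wcol <- if ("beta" %in% names(weights)) "beta" else "weight"
  if (!all(c("snp_id", wcol) %in% names(weights)))
    input_error("weight table needs columns snp_id and beta/weight")
  shared <- intersect(G$snp_ids, weights$snp_id)
  if (length(shared) == 0L) input_error("no SNPs shared with the weight table")
  widx <- match(shared, weights$snp_id)
  gidx <- match(shared, G$snp_ids)
  w <- as.numeric(weights[[wcol]][widx])
  w[!is.finite(w)] <- 0
  X <- G$dosages[, gidx, drop = FALSE]
  if (!is.null(G$coded_allele) && "effect_allele" %in% names(weights)) {
    flip <- G$coded_allele[gidx] != weights$effect_allele[widx]
    if (any(flip)) X[, flip] <- 2L - X[, flip]
  }
  raw <- unname(drop(X %*% w))
  if (stats::sd(raw) < 1e-12)
    degenerate_error("raw polygenic score has zero variance")
  structure(list(sample_ids = G$sample_ids, score = standardize(raw)),
            class = "pgi")
}

#' @export
print.pgi <- function(x, ...) {
  cat(sprintf("pgi: %d individuals (standardized)\n", length(x$sample_ids)))
  invisible(x)
}

#' Write / read a polygenic index table (TSV: `id`, `pgi`)
#' @param pgi a `pgi` object; @param path file path.
#' @export
write_pgi <- function(pgi, path) {
  data.table::fwrite(data.table::data.table(id = pgi$sample_ids,
                                            pgi = pgi$score),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_pgi
#' @export
read_pgi <- function(path) {
  dt <- data.table::fread(path, header = TRUE)
  structure(list(sample_ids = as.character(dt$id), score = dt$pgi),
            class = "pgi")
}
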