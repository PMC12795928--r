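#' Gene-environment interaction regression (simple / robust specification)
#'
#' Ordinary least squares of the outcome on `PGI + Environment +
#' PGI x Environment` plus covariates. The robust specification follows the
#' standard recommendation for interaction models with polygenic scores: it
#' additionally controls for `PGI^2` and for every covariate-by-environment
#' interaction, so that the PGI x E coefficient is not contaminated by
#' nonlinear PGI effects or by covariate-E interactions. Covariates are
#' mean-centered before forming interactions (flag `center`, default on) to
#' limit the collinearity inflation that many correlated covariate-by-E
#' terms otherwise cause. Classical (homoskedastic) standard errors by
#' default; `robust_se = TRUE` switches to HC1.
#'
#' @param Y numeric outcome.
#' @param pgi a `pgi` object or numeric vector.
#' @param E binary 0/1 environment.
#' @param covariates data.frame/matrix of covariates (may be `NULL`).
#' @param spec `"simple"` or `"robust"`.
#' @param center center covariates before interacting them with E.
#' @param robust_se use heteroskedasticity-robust (HC1) standard errors.
#' @return An object of class `gxe_fit`: `spec`, `terms` (data.frame with
#'   `name`, `estimate`, `se`, `t`, `p`), `n`, `r2`.
#' @export
fit_gxe <- function(Y, pgi, E, covariates = NULL,
                    spec = c("simple", "robust"), center = TRUE,
                    robust_se = FALSE) {
  spec <- match.arg(spec)
  s <- pgi_scores(pgi)
  n <- length(Y)
  if (length(s) != n || length(E) != n)
    input_error("Y, PGI and E must have the same length")
  if (!is_binary01(E)) input_error("E must be a 0/1 vector")
  C <- covariate_matrix(covariates, n)
  if (!is.null(C) && is.null(colnames(C)))
    colnames(C) <- paste0("cov", seq_len(ncol(C)))
  Cc <- if (!is.null(C) && center) scale(C, center = TRUE, scale = FALSE)
        else C

  X <- cbind(`(Intercept)` = 1, PGI = s, Environment = E,
             `PGI:Environment` = s * E)
  if (!is.null(C)) X <- cbind(X, C)
  if (spec == "robust") {
    X <- cbind(X, PGI2 = s^2)
    if (!is.null(Cc)) {
      CE <- Cc * E
      colnames(CE) <- paste0(colnames(C), ":Environment")
      X <- cbind(X, CE)
    }
  }
  k <- ncol(X)
  if (n <= k) input_error("too few observations for the term count")
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    input_error(paste0("design is rank deficient after interaction ",
                       "construction; collinear terms: ",
                       paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  rss <- sum(res^2)
  XtXi <- chol2inv(chol(crossprod(X)))
  if (robust_se) {
    meat <- crossprod(X * res)
    vc <- XtXi %*% meat %*% XtXi * n / (n - k)
  } else {
    vc <- XtXi * rss / (n - k)
  }
  se <- sqrt(diag(vc))
  tstat <- beta / se
  p <- 2 * stats::pt(abs(tstat), df = n - k, lower.tail = FALSE)
  tss <- sum((Y - mean(Y))^2)
  structure(list(
    spec = spec,
    terms = data.frame(name = colnames(X), estimate = unname(beta),
                       se = unname(se), t = unname(tstat), p = unname(p),
                       stringsAsFactors = FALSE),
    n = n, r2 = 1 - rss / tss,
    robust_se = robust_se
  ), class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf("GxE fit (%s specification), n = %d, R2 = %.4f\n",
              x$spec, x$n, x$r2))
  tt <- x$terms
  stars <- ifelse(tt$p < 0.01, "***",
                  ifelse(tt$p < 0.05, "**", ifelse(tt$p < 0.1, "*", "")))
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-22s % .4f (%.4f)%s\n", tt$name[i], tt$estimate[i],
                tt$se[i], stars[i]))
  invisible(x)
}

#' Side-by-side comparison of the simple and robust G-by-E fits
#'
#' @param simple,robust [fit_gxe()] results for the same data.
#' @return list with `table` (aligned estimates/SEs of shared terms) and
#'   flags `interaction_sign_change`, `interaction_significance_change`
#'   (at alpha 0.05) for the PGI x Environment term.
#' @export
compare_specs <- function(simple, robust) {
  if (!inherits(simple, "gxe_fit") || !inherits(robust, "gxe_fit"))
    input_error("compare_specs expects two gxe_fit objects")
  if (simple$n != robust$n)
    input_error("the two fits were not run on the same data (n differs)")
  shared <- intersect(simple$terms$name, robust$terms$name)
  si <- match(shared, simple$terms$name)
  ri <- match(shared, robust$terms$name)
  tab <- data.frame(
    name = shared,
    estimate_simple = simple$terms$estimate[si],
    se_simple = simple$terms$se[si],
    estimate_robust = robust$terms$estimate[ri],
    se_robust = robust$terms$se[ri],
    stringsAsFactors = FALSE
  )
  ix <- which(shared == "PGI:Environment")
  sgn <- sign(tab$estimate_simple[ix]) != sign(tab$estimate_robust[ix])
  sig <- (simple$terms$p[si][ix] < 0.05) != (robust$terms$p[ri][ix] < 0.05)
  list(table = tab,
       interaction_sign_change = isTRUE(sgn),
       interaction_significance_change = isTRUE(sig))
}
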