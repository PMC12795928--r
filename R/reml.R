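#' Restricted log-likelihood of the univariate GRM model
#'
#' Evaluates the REML log-likelihood of `y ~ N(Xb, sigma2_g * A + sigma2_e *
#' I)` at fixed variance components:
#' `-0.5 * [ (n-p) log(2 pi) + log|V| + log|X'V^-1 X| + y'Py ]`.
#' Exposed so the maximized objective can be checked against direct dense
#' evaluation.
#'
#' @param A a `grm`.
#' @param y numeric phenotype.
#' @param X fixed-effect design matrix (default: intercept only).
#' @param sigma2_g,sigma2_e variance components (`>= 0`, not both 0).
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(A, y, X = NULL, sigma2_g, sigma2_e) {
  ctx <- reml_context(A, y, X)
  uni_eval(ctx, sigma2_g, sigma2_e)$ll
}

# Shared precomputation for the spectral REML engines.
reml_context <- function(A, y, X) {
  n <- length(A$sample_ids)
  y <- as.matrix(y)             # n x q (q = 1 or 2 traits)
  if (nrow(y) != n) input_error("phenotype length does not match the GRM")
  if (any(!is.finite(y))) input_error("phenotype contains non-finite values")
  if (is.null(X)) X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != n) input_error("design rows do not match the GRM")
  if (qr(X)$rank < ncol(X)) input_error("fixed-effect design is singular")
  p <- ncol(X)
  if (n <= p + 2L) input_error("too few individuals for the fixed effects")

  sp <- grm_spectral(A)
  dmin <- if (sp$n0 > 0L) 0 else min(sp$d)
  if (max(sp$d) - dmin < 1e-6)
    degenerate_error(paste0(
      "GRM eigenvalue spread below 1e-6: genetic and residual variance are ",
      "not separable (is the GRM an identity?)"))

  Ur <- sp$U
  Yr <- crossprod(Ur, y)
  Xr <- crossprod(Ur, X)
  XtX <- crossprod(X)
  list(n = n, p = p, q = ncol(y), y = y, X = X,
       Ur = Ur, d = sp$d, n0 = sp$n0,
       Yr = Yr, Xr = Xr,
       Xn2 = XtX - crossprod(Xr),
       xy_null = crossprod(X, y) - crossprod(Xr, Yr),
       yy_null = crossprod(y) - crossprod(Yr))
}

# --- univariate ------------------------------------------------------------

# Evaluate LL and everything the AI update needs at (sg, se).
uni_eval <- function(ctx, sg, se, derivs = FALSE) {
  if (sg < 0 || se <= 0) return(list(ll = -Inf))
  vv <- sg * ctx$d + se
  if (any(vv <= 0)) return(list(ll = -Inf))
  w <- 1 / vv
  w0 <- 1 / se
  K <- crossprod(ctx$Xr, ctx$Xr * w) + w0 * ctx$Xn2
  ky <- crossprod(ctx$Xr, ctx$Yr[, 1L] * w) + w0 * ctx$xy_null[, 1L]
  Kc <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(Kc)) return(list(ll = -Inf))
  b <- backsolve(Kc, forwardsolve(t(Kc), ky))
  ytViy <- sum(ctx$Yr[, 1L]^2 * w) + w0 * ctx$yy_null[1L, 1L]
  yPy <- ytViy - sum(b * ky)
  logdetV <- sum(log(sg * ctx$d + se)) + ctx$n0 * log(se)
  ll <- -0.5 * ((ctx$n - ctx$p) * log(2 * pi) + logdetV +
                  2 * sum(log(diag(Kc))) + yPy)
  if (!is.finite(ll)) return(list(ll = -Inf))
  out <- list(ll = ll, w = w, w0 = w0, Kc = Kc, b = b)
  if (!derivs) return(out)

  Kinv <- chol2inv(Kc)
  Er <- ctx$Yr[, 1L] - ctx$Xr %*% b
  ef <- ctx$y[, 1L] - ctx$X %*% b
  PyR <- w * Er
  Py <- ctx$Ur %*% ((w - w0) * Er) + w0 * ef
  trPA <- sum(ctx$d * w) -
    sum(Kinv * crossprod(ctx$Xr, ctx$Xr * (w^2 * ctx$d)))
  trP <- sum(w) + ctx$n0 * w0 -
    sum(Kinv * (crossprod(ctx$Xr, ctx$Xr * w^2) + w0^2 * ctx$Xn2))
  yPAPy <- sum(ctx$d * PyR^2)
  yPPy <- sum(Py^2)

  pmult <- function(v) {
    vr <- crossprod(ctx$Ur, v)
    Viv <- ctx$Ur %*% ((w - w0) * vr) + w0 * v
    cc <- Kinv %*% (crossprod(ctx$Xr, w * vr) +
                      w0 * (crossprod(ctx$X, v) - crossprod(ctx$Xr, vr)))
    Viv - (ctx$Ur %*% ((w - w0) * (ctx$Xr %*% cc)) + w0 * (ctx$X %*% cc))
  }
  ug <- ctx$Ur %*% (ctx$d * PyR)
  Pug <- pmult(ug)
  PPy <- pmult(Py)
  AI <- 0.5 * matrix(c(sum(ug * Pug), sum(ug * PPy),
                       sum(ug * PPy), sum(Py * PPy)), 2L, 2L)
  score <- -0.5 * c(trPA - yPAPy, trP - yPPy)
  c(out, list(score = score, AI = AI, trPA = trPA, trP = trP,
              yPAPy = yPAPy, yPPy = yPPy))
}

#' Univariate GREML (AI-REML) SNP-heritability estimation
#'
#' Maximizes the restricted likelihood of `y ~ N(Xb, sigma2_g * A +
#' sigma2_e * I)` by average-information updates with EM warm-start and EM /
#' step-halving fallback whenever an AI step leaves the feasible region or
#' decreases the objective. Variance components are constrained to at least
#' `1e-8 * var(y)`; a component pinned there is clamped to 0 and flagged as
#' a boundary estimate. The standard error of `h2 = sigma2_g / (sigma2_g +
#' sigma2_e)` comes from the inverse average-information matrix by the delta
#' method.
#'
#' @inheritParams reml_loglik
#' @param tol convergence tolerance on the log-likelihood change
#'   (default `1e-8`).
#' @param max_iter iteration cap (default 200).
#' @param em_iter number of EM warm-start iterations (default 3).
#' @return An object of class `greml_uni` with fields `sigma2_g`,
#'   `sigma2_e`, `h2`, `se_h2`, `loglik`, `converged`, `n_iter`,
#'   `boundary`, `vc_cov` (2x2 sampling covariance of the components).
#' @export
reml_univariate <- function(A, y, X = NULL, tol = 1e-8, max_iter = 200L,
                            em_iter = 3L) {
  ctx <- reml_context(A, y, X)
  vy <- stats::var(ctx$y[, 1L])
  if (vy < 1e-12) degenerate_error("phenotype has (near) zero variance")
  floorv <- 1e-8 * vy
  sg <- se <- vy / 2
  cur <- uni_eval(ctx, sg, se, derivs = TRUE)
  converged <- FALSE
  iter <- 0L
  em_step <- function(sg, se, ev) {
    c(max(sg + sg^2 * (ev$yPAPy - ev$trPA) / ctx$n, floorv),
      max(se + se^2 * (ev$yPPy - ev$trP) / ctx$n, floorv))
  }
  while (iter < max_iter) {
    iter <- iter + 1L
    if (iter <= em_iter) {
      theta <- em_step(sg, se, cur)
    } else {
      delta <- tryCatch(solve(cur$AI, cur$score), error = function(e) NULL)
      theta <- NULL
      if (!is.null(delta)) {
        step <- 1
        for (h in 1:8) {
          cand <- pmax(c(sg, se) + step * delta, floorv)
          if (uni_eval(ctx, cand[1L], cand[2L])$ll >= cur$ll - 1e-10) {
            theta <- cand
            break
          }
          step <- step / 2
        }
      }
      if (is.null(theta)) theta <- em_step(sg, se, cur)  # EM fallback
    }
    nxt <- uni_eval(ctx, theta[1L], theta[2L], derivs = TRUE)
    moved <- abs(nxt$ll - cur$ll)
    sg <- theta[1L]; se <- theta[2L]; cur <- nxt
    if (iter > em_iter && moved < tol) { converged <- TRUE; break }
  }
  # Boundary handling: the profile is numerically flat near sigma2_g = 0,
  # so also compare against the exact sigma2_g = 0 solution (where the REML
  # estimate of sigma2_e is the OLS residual variance in closed form) and
  # prefer it when it attains the maximum within 1e-6 log-units.
  se0 <- sum(qr.resid(qr(ctx$X), ctx$y[, 1L])^2) / (ctx$n - ctx$p)
  ll0 <- uni_eval(ctx, 0, se0)$ll
  boundary <- sg <= 2 * floorv || ll0 >= cur$ll - 1e-6
  if (boundary) {
    sg <- 0
    se <- se0
    cur <- uni_eval(ctx, sg, se, derivs = TRUE)
  }
  vc_cov <- tryCatch(solve(cur$AI), error = function(e)
    matrix(NA_real_, 2L, 2L))
  tot <- sg + se
  h2 <- sg / tot
  grad <- c(se, -sg) / tot^2
  se_h2 <- sqrt(max(drop(t(grad) %*% vc_cov %*% grad), 0))
  structure(list(sigma2_g = sg, sigma2_e = se, h2 = h2,
                 se_h2 = se_h2, loglik = cur$ll, converged = converged,
                 n_iter = iter, boundary = boundary, vc_cov = vc_cov,
                 n = ctx$n),
            class = "greml_uni")
}

#' @export
print.greml_uni <- function(x, ...) {
  cat(sprintf("GREML (univariate): h2 = %.4f (SE %.4f)%s\n", x$h2, x$se_h2,
              if (x$boundary) " [boundary]" else ""))
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g, logL = %.4f, %s in %d iter\n",
              x$sigma2_g, x$sigma2_e, x$loglik,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

# --- bivariate -------------------------------------------------------------

# theta = (g11, g12, g22, e11, e12, e22); Sigma_g = [[g11,g12],[g12,g22]].
biv_eval <- function(ctx, th, derivs = FALSE, free = 1:6) {
  g11 <- th[1L]; g12 <- th[2L]; g22 <- th[3L]
  e11 <- th[4L]; e12 <- th[5L]; e22 <- th[6L]
  detE <- e11 * e22 - e12^2
  if (g11 < 0 || g22 < 0 || e11 <= 0 || e22 <= 0 || detE <= 0)
    return(list(ll = -Inf))
  d <- ctx$d
  a <- g11 * d + e11; b <- g12 * d + e12; cc <- g22 * d + e22
  dt <- a * cc - b^2
  if (any(dt <= 1e-300) || any(a <= 0)) return(list(ll = -Inf))
  W11 <- cc / dt; W12 <- -b / dt; W22 <- a / dt
  Ei <- matrix(c(e22, -e12, -e12, e11), 2L) / detE
  W <- list(`11` = W11, `12` = W12, `22` = W22)

  Xr <- ctx$Xr; p <- ctx$p
  wcp <- function(wv) crossprod(Xr, Xr * wv)
  K <- rbind(cbind(wcp(W11) + Ei[1L, 1L] * ctx$Xn2,
                   wcp(W12) + Ei[1L, 2L] * ctx$Xn2),
             cbind(wcp(W12) + Ei[1L, 2L] * ctx$Xn2,
                   wcp(W22) + Ei[2L, 2L] * ctx$Xn2))
  Wm <- function(a_, b_) if (a_ == b_) W[[sprintf("%d%d", a_, b_)]] else W12
  kyb <- function(a_) {
    out <- numeric(p)
    for (b_ in 1:2)
      out <- out + crossprod(Xr, ctx$Yr[, b_] * Wm(a_, b_)) +
        Ei[a_, b_] * ctx$xy_null[, b_]
    out
  }
  ky <- c(kyb(1L), kyb(2L))
  Kc <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(Kc)) return(list(ll = -Inf))
  bc <- backsolve(Kc, forwardsolve(t(Kc), ky))
  ytViy <- 0
  for (a_ in 1:2) for (b_ in 1:2)
    ytViy <- ytViy + sum(Wm(a_, b_) * ctx$Yr[, a_] * ctx$Yr[, b_]) +
      Ei[a_, b_] * ctx$yy_null[a_, b_]
  yPy <- ytViy - sum(bc * ky)
  logdetV <- sum(log(dt)) + ctx$n0 * log(detE)
  ll <- -0.5 * ((2 * ctx$n - 2 * p) * log(2 * pi) + logdetV +
                  2 * sum(log(diag(Kc))) + yPy)
  out <- list(ll = ll)
  if (!derivs) return(out)

  Kinv <- chol2inv(Kc)
  B <- matrix(bc, p, 2L)
  Er <- ctx$Yr - Xr %*% B           # r x 2
  Ef <- ctx$y - ctx$X %*% B         # n x 2
  PyR <- cbind(W11 * Er[, 1L] + W12 * Er[, 2L],
               W12 * Er[, 1L] + W22 * Er[, 2L])
  Py <- matrix(0, ctx$n, 2L)
  for (a_ in 1:2) {
    corr <- PyR[, a_] - (Ei[a_, 1L] * Er[, 1L] + Ei[a_, 2L] * Er[, 2L])
    Py[, a_] <- ctx$Ur %*% corr + Ef %*% Ei[a_, ]
  }
  APy <- ctx$Ur %*% (d * PyR)       # n x 2, A %*% Py per trait

  # derivative structures: list(type, E) with E the 2x2 within-pair matrix
  E11 <- matrix(c(1, 0, 0, 0), 2L); E12 <- matrix(c(0, 1, 1, 0), 2L)
  E22 <- matrix(c(0, 0, 0, 1), 2L)
  structs <- list(list("g", E11), list("g", E12), list("g", E22),
                  list("e", E11), list("e", E12), list("e", E22))

  # tr(V^-1 dVk) and X'V^-1 dVk V^-1 X per structure
  trP <- numeric(6L)
  WEW <- function(Ek, a_, b_) {
    # per-eigenvalue weight of the (a_, b_) block of V^-1 (Ek ox c) V^-1
    out <- 0
    for (s in 1:2) for (t in 1:2)
      if (Ek[s, t] != 0) out <- out + Wm(a_, s) * Wm(t, b_)
    out
  }
  for (k in 1:6) {
    type <- structs[[k]][[1L]]; Ek <- structs[[k]][[2L]]
    cmult <- if (type == "g") d else rep(1, length(d))
    trVi <- sum(cmult * (Ek[1L, 1L] * W11 + 2 * Ek[1L, 2L] * W12 +
                           Ek[2L, 2L] * W22))
    Mk <- matrix(0, 2L * p, 2L * p)
    for (a_ in 1:2) for (b_ in 1:2) {
      if (b_ < a_) next
      blk <- crossprod(Xr, Xr * (cmult * WEW(Ek, a_, b_)))
      if (type == "e") {
        EiEkEi <- Ei %*% Ek %*% Ei
        blk <- blk + EiEkEi[a_, b_] * ctx$Xn2
      }
      ra <- (a_ - 1L) * p + 1:p; rb <- (b_ - 1L) * p + 1:p
      Mk[ra, rb] <- blk
      if (b_ > a_) Mk[rb, ra] <- t(blk)
    }
    if (type == "e") trVi <- trVi +
      ctx$n0 * sum(diag(Ei %*% Ek))
    trP[k] <- trVi - sum(Kinv * Mk)
  }

  uvec <- function(k) {
    Ek <- structs[[k]][[2L]]
    base <- if (structs[[k]][[1L]] == "g") APy else Py
    cbind(Ek[1L, 1L] * base[, 1L] + Ek[1L, 2L] * base[, 2L],
          Ek[2L, 1L] * base[, 1L] + Ek[2L, 2L] * base[, 2L])
  }
  pmult2 <- function(v) {
    vr <- crossprod(ctx$Ur, v)
    Viv <- matrix(0, ctx$n, 2L)
    for (a_ in 1:2) {
      R <- Wm(a_, 1L) * vr[, 1L] + Wm(a_, 2L) * vr[, 2L]
      corr <- R - (Ei[a_, 1L] * vr[, 1L] + Ei[a_, 2L] * vr[, 2L])
      Viv[, a_] <- ctx$Ur %*% corr + v %*% Ei[a_, ]
    }
    XtViv <- c(crossprod(ctx$X, Viv[, 1L]), crossprod(ctx$X, Viv[, 2L]))
    Cm <- matrix(Kinv %*% XtViv, p, 2L)
    XCr <- Xr %*% Cm; XC <- ctx$X %*% Cm
    ViXC <- matrix(0, ctx$n, 2L)
    for (a_ in 1:2) {
      R <- Wm(a_, 1L) * XCr[, 1L] + Wm(a_, 2L) * XCr[, 2L]
      corr <- R - (Ei[a_, 1L] * XCr[, 1L] + Ei[a_, 2L] * XCr[, 2L])
      ViXC[, a_] <- ctx$Ur %*% corr + XC %*% Ei[a_, ]
    }
    Viv - ViXC
  }

  q <- numeric(6L)
  us <- lapply(1:6, uvec)
  for (k in 1:6) q[k] <- sum(Py * us[[k]])
  score <- -0.5 * (trP - q)

  nf <- length(free)
  AI <- matrix(0, nf, nf)
  Pus <- lapply(free, function(k) pmult2(us[[k]]))
  for (i in seq_len(nf)) for (j in i:nf) {
    AI[i, j] <- AI[j, i] <- 0.5 * sum(us[[free[i]]] * Pus[[j]])
  }
  c(out, list(score = score, AI = AI, trP = trP, q = q,
              Sg = crossprod(PyR * sqrt(d)),   # Py' A Py (2x2)
              SgT = matrix(c(trP[1L], trP[2L] / 2, trP[2L] / 2, trP[3L]), 2L),
              Se = crossprod(Py),
              SeT = matrix(c(trP[4L], trP[5L] / 2, trP[5L] / 2, trP[6L]), 2L)))
}

# Project theta into the feasible region (PSD Sigma_g, PD Sigma_e,
# correlation magnitudes capped), honoring constraints.
biv_clip <- function(th, floors, constrain_rg, constrain_re) {
  th[c(1L, 3L)] <- pmax(th[c(1L, 3L)], floors$g)
  th[c(4L, 6L)] <- pmax(th[c(4L, 6L)], floors$e)
  cap_g <- 0.999 * sqrt(th[1L] * th[3L])
  cap_e <- 0.999 * sqrt(th[4L] * th[6L])
  th[2L] <- if (constrain_rg) 0 else max(min(th[2L], cap_g), -cap_g)
  th[5L] <- if (constrain_re) 0 else max(min(th[5L], cap_e), -cap_e)
  th
}

biv_fit <- function(ctx, init, floors, constrain_rg = FALSE,
                    constrain_re = FALSE, tol = 1e-8, max_iter = 200L,
                    em_iter = 3L) {
  free <- setdiff(1:6, c(if (constrain_rg) 2L, if (constrain_re) 5L))
  th <- biv_clip(init, floors, constrain_rg, constrain_re)
  cur <- biv_eval(ctx, th, derivs = TRUE, free = free)
  if (!is.finite(cur$ll)) {
    th <- biv_clip(c(th[1L], 0, th[3L], th[4L], 0, th[6L]), floors,
                   constrain_rg, constrain_re)
    cur <- biv_eval(ctx, th, derivs = TRUE, free = free)
  }
  em_step <- function(th, ev) {
    Sg <- matrix(th[c(1L, 2L, 2L, 3L)], 2L)
    Se <- matrix(th[c(4L, 5L, 5L, 6L)], 2L)
    Sg2 <- Sg + (Sg %*% (ev$Sg - ev$SgT) %*% Sg) / ctx$n
    Se2 <- Se + (Se %*% (ev$Se - ev$SeT) %*% Se) / ctx$n
    biv_clip(c(Sg2[1L, 1L], Sg2[1L, 2L], Sg2[2L, 2L],
               Se2[1L, 1L], Se2[1L, 2L], Se2[2L, 2L]),
             floors, constrain_rg, constrain_re)
  }
  converged <- FALSE
  iter <- 0L
  stall <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (iter <= em_iter) {
      cand <- em_step(th, cur)
    } else {
      delta <- tryCatch(solve(cur$AI, cur$score[free]),
                        error = function(e) NULL)
      cand <- NULL
      if (!is.null(delta)) {
        step <- 1
        for (h in 1:10) {
          pr <- th
          pr[free] <- th[free] + step * delta
          pr <- biv_clip(pr, floors, constrain_rg, constrain_re)
          if (biv_eval(ctx, pr)$ll >= cur$ll - 1e-10) { cand <- pr; break }
          step <- step / 2
        }
      }
      if (is.null(cand)) cand <- em_step(th, cur)
    }
    nxt <- biv_eval(ctx, cand, derivs = TRUE, free = free)
    if (!is.finite(nxt$ll)) { cand <- em_step(th, cur)
      nxt <- biv_eval(ctx, cand, derivs = TRUE, free = free) }
    moved <- abs(nxt$ll - cur$ll)
    th <- cand; cur <- nxt
    if (iter > em_iter && moved < tol) { converged <- TRUE; break }
    # boundary stall: when a correlation is pinned at its cap the EM
    # fallback crawls along the constraint with vanishing gains; treat a
    # long run of sub-1e-4 improvements as converged-at-boundary
    stall <- if (moved < 1e-4) stall + 1L else 0L
    if (iter > em_iter && stall >= 10L) { converged <- TRUE; break }
  }
  list(theta = th, ev = cur, converged = converged, n_iter = iter,
       free = free)
}

#' Bivariate GREML with a likelihood-ratio test of zero genetic correlation
#'
#' Fits the stacked two-trait model with covariance
#' `Sigma_g (x) A + Sigma_e (x) I` by AI-REML (genetic and residual
#' covariances parameterized directly; the residual covariance is estimated,
#' not fixed), then refits with the genetic covariance constrained to zero
#' and forms `LRT = 2 * (logL_full - logL_rg0)` against a central
#' chi-squared with 1 df. When either trait's genetic variance is pinned at
#' the zero boundary the genetic correlation is undefined and all `rho_g`
#' fields are `NA` with `rg_available = FALSE` (the "not available for this
#' outcome" rule).
#'
#' @inheritParams reml_univariate
#' @param y1,y2 the two phenotypes (same individuals, same order as the GRM).
#' @param constrain_re fix the residual covariance at 0 (default `FALSE`).
#' @return An object of class `greml_bivar` with per-trait `h2`/`se`,
#'   `rho_g`, `se_rho_g`, `rho_e`, `loglik_full`, `loglik_rg0`, `lrt_stat`,
#'   `lrt_p`, `rg_available`, boundary flags, convergence info and the raw
#'   component estimates in `sigma`.
#' @export
reml_bivariate <- function(A, y1, y2, X = NULL, tol = 1e-8, max_iter = 200L,
                           em_iter = 3L, constrain_re = FALSE) {
  A <- grm_with_spectral(A)
  ctx <- reml_context(A, cbind(y1, y2), X)
  v1 <- stats::var(ctx$y[, 1L]); v2 <- stats::var(ctx$y[, 2L])
  if (v1 < 1e-12 || v2 < 1e-12)
    degenerate_error("a phenotype has (near) zero variance")
  floors <- list(g = 1e-8 * c(v1, v2), e = 1e-8 * c(v1, v2))
  cv <- stats::cov(ctx$y[, 1L], ctx$y[, 2L])
  # univariate fits supply the per-trait boundary determination (which
  # compares against the exact sigma2_g = 0 solution) and a warm start
  u1 <- reml_univariate(A, y1, X, tol = tol, max_iter = max_iter,
                        em_iter = em_iter)
  u2 <- reml_univariate(A, y2, X, tol = tol, max_iter = max_iter,
                        em_iter = em_iter)
  init <- c(max(u1$sigma2_g, 0.05 * v1), cv / 2,
            max(u2$sigma2_g, 0.05 * v2),
            u1$sigma2_e, cv / 2, u2$sigma2_e)

  full <- biv_fit(ctx, init, floors, constrain_rg = FALSE,
                  constrain_re = constrain_re, tol = tol,
                  max_iter = max_iter, em_iter = em_iter)
  th <- full$theta
  null_init <- th; null_init[2L] <- 0
  rg0 <- biv_fit(ctx, null_init, floors, constrain_rg = TRUE,
                 constrain_re = constrain_re, tol = tol,
                 max_iter = max_iter, em_iter = em_iter)

  # a genetic variance at (or indistinguishable from) the zero boundary
  # makes rho_g undefined
  bnd1 <- u1$boundary || th[1L] <= 2 * floors$g[1L]
  bnd2 <- u2$boundary || th[3L] <= 2 * floors$g[2L]
  rg_available <- !(bnd1 || bnd2)

  vc_cov <- tryCatch(solve(full$ev$AI), error = function(e)
    matrix(NA_real_, length(full$free), length(full$free)))
  # map free-parameter indices into the 6-vector
  cov6 <- matrix(NA_real_, 6L, 6L)
  cov6[full$free, full$free] <- vc_cov

  h2_se <- function(ig, ie) {
    tot <- th[ig] + th[ie]
    grad <- c(th[ie], -th[ig]) / tot^2
    V <- cov6[c(ig, ie), c(ig, ie)]
    if (anyNA(V)) return(NA_real_)
    sqrt(max(drop(t(grad) %*% V %*% grad), 0))
  }
  h2_1 <- th[1L] / (th[1L] + th[4L])
  h2_2 <- th[3L] / (th[3L] + th[6L])

  rho_g <- if (rg_available) th[2L] / sqrt(th[1L] * th[3L]) else NA_real_
  rho_boundary <- rg_available && abs(rho_g) >= 0.998
  se_rho_g <- NA_real_
  if (rg_available && !rho_boundary && !anyNA(cov6[1:3, 1:3])) {
    grad <- c(-rho_g / (2 * th[1L]), 1 / sqrt(th[1L] * th[3L]),
              -rho_g / (2 * th[3L]))
    se_rho_g <- sqrt(max(drop(t(grad) %*% cov6[1:3, 1:3] %*% grad), 0))
  }
  rho_e <- th[5L] / sqrt(th[4L] * th[6L])

  lrt_stat <- if (rg_available)
    max(0, 2 * (full$ev$ll - rg0$ev$ll)) else NA_real_
  lrt_p <- if (rg_available)
    stats::pchisq(lrt_stat, df = 1L, lower.tail = FALSE) else NA_real_

  structure(list(
    h2_1 = h2_1, se_h2_1 = h2_se(1L, 4L),
    h2_2 = h2_2, se_h2_2 = h2_se(3L, 6L),
    rho_g = rho_g, se_rho_g = se_rho_g, rho_e = rho_e,
    sigma = list(Sigma_g = matrix(th[c(1L, 2L, 2L, 3L)], 2L),
                 Sigma_e = matrix(th[c(4L, 5L, 5L, 6L)], 2L)),
    loglik_full = full$ev$ll, loglik_rg0 = rg0$ev$ll,
    lrt_stat = lrt_stat, lrt_p = lrt_p,
    rg_available = rg_available,
    boundary_g1 = bnd1, boundary_g2 = bnd2, rho_boundary = rho_boundary,
    converged = full$converged && rg0$converged,
    n_iter = full$n_iter + rg0$n_iter, n = ctx$n
  ), class = "greml_bivar")
}

#' @export
print.greml_bivar <- function(x, ...) {
  cat(sprintf("GREML (bivariate): h2_1 = %.4f (%.4f), h2_2 = %.4f (%.4f)\n",
              x$h2_1, x$se_h2_1, x$h2_2, x$se_h2_2))
  if (x$rg_available) {
    cat(sprintf("  rho_g = %.4f (SE %s)%s, LRT(rho_g = 0) = %.3f, p = %.3g\n",
                x$rho_g,
                if (is.na(x$se_rho_g)) "NA" else sprintf("%.4f", x$se_rho_g),
                if (x$rho_boundary) " [boundary]" else "",
                x$lrt_stat, x$lrt_p))
  } else {
    cat("  rho_g = N.A. (a genetic variance is at the zero boundary)\n")
  }
  invisible(x)
}

#' Likelihood-ratio test of zero genetic correlation
#'
#' @param fit a [reml_bivariate()] result.
#' @return list with `stat`, `pvalue` and `available`. When the fit's
#'   `rg_available` flag is off (a genetic variance at the zero boundary),
#'   `available = FALSE` and the statistic and p-value are `NA`.
#' @export
lrt_rg_zero <- function(fit) {
  if (!inherits(fit, "greml_bivar")) input_error("expected a greml_bivar fit")
  if (!fit$rg_available)
    return(list(stat = NA_real_, pvalue = NA_real_, available = FALSE))
  list(stat = fit$lrt_stat, pvalue = fit$lrt_p, available = TRUE)
}
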