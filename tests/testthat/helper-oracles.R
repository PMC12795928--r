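# Independent oracles used across the suite. These deliberately take the
# brute-force route (dense solves, explicit normal equations, exhaustive
# CDF evaluation) so they share no code path with the package internals.

# Dense evaluation of the restricted log-likelihood of
# y ~ N(Xb, sg * A + se * I): -0.5[(n-p)log(2pi) + log|V| + log|X'V^-1X| + y'Py]
dense_reml_ll <- function(A, y, X, sg, se) {
  n <- length(y)
  p <- ncol(X)
  V <- sg * A + se * diag(n)
  Vi <- solve(V)
  K <- t(X) %*% Vi %*% X
  b <- solve(K, t(X) %*% Vi %*% y)
  e <- y - X %*% b
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(K, logarithm = TRUE)$modulus +
                       t(e) %*% Vi %*% e))
}

# Dense restricted LL of the stacked bivariate model at components
# th = (g11, g12, g22, e11, e12, e22).
dense_biv_ll <- function(A, y1, y2, X, th) {
  n <- length(y1)
  Sg <- matrix(th[c(1, 2, 2, 3)], 2)
  Se <- matrix(th[c(4, 5, 5, 6)], 2)
  V <- kronecker(Sg, A) + kronecker(Se, diag(n))
  Xs <- kronecker(diag(2), X)
  y <- c(y1, y2)
  Vi <- solve(V)
  K <- t(Xs) %*% Vi %*% Xs
  b <- solve(K, t(Xs) %*% Vi %*% y)
  e <- y - Xs %*% b
  as.numeric(-0.5 * ((2 * n - ncol(Xs)) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(K, logarithm = TRUE)$modulus +
                       t(e) %*% Vi %*% e))
}

# Grid + polish maximization of the dense univariate REML objective over
# (sg, se); independent of the AI engine.
dense_reml_max <- function(A, y, X, grid_n = 25) {
  vy <- stats::var(y)
  best <- optim(
    par = c(vy / 2, vy / 2),
    fn = function(th) {
      if (th[1] < 0 || th[2] <= 1e-10) return(1e10)
      -dense_reml_ll(A, y, X, th[1], th[2])
    },
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-12))
  grid <- expand.grid(sg = seq(1e-6, 2 * vy, length.out = grid_n),
                      se = seq(vy / 50, 2 * vy, length.out = grid_n))
  lls <- mapply(function(a, b) dense_reml_ll(A, y, X, a, b),
                grid$sg, grid$se)
  max(-best$value, max(lls))
}

# Closed-form OLS via explicit normal equations.
normal_eq_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Brute-force two-sample KS statistic over all step points.
brute_ks <- function(x0, x1) {
  pts <- sort(unique(c(x0, x1)))
  max(abs(ecdf(x0)(pts) - ecdf(x1)(pts)))
}

# Small simulated dataset with a GRM, used by several files.
small_sim <- function(n = 300, m = 200, h2 = 0.5, seed = 1) {
  sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = n - 1L,
                     n_snps = m, h2_Y = h2, seed = seed)
  G <- simulate_genotypes(sc)
  td <- simulate_traits(G, sc)
  list(G = G, td = td, A = compute_grm(G), sc = sc)
}
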