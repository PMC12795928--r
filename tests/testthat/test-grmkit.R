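test_that("the GRM formula reproduces the hand-evaluated toy", {
  # one SNP, dosages (0, 2): p = 0.5, z = (x - 1)/sqrt(0.5) = -+sqrt(2),
  # A = zz' = [[2, -2], [-2, 2]]
  G <- genotype_matrix(matrix(c(0L, 2L), 2L, 1L))
  A <- compute_grm(G)
  expect_equal(A$values, matrix(c(2, -2, -2, 2), 2L,
                                dimnames = list(G$sample_ids, G$sample_ids)),
               tolerance = 1e-12)
  expect_equal(A$n_snps_used, 1L)
})

test_that("an exact genotype copy yields identical relatedness entries", {
  set.seed(2)
  M <- matrix(sample(0:2, 60, replace = TRUE), 6L, 10L)
  M[2L, ] <- M[1L, ]
  A <- compute_grm(genotype_matrix(M))
  expect_equal(A$values[1L, 2L], A$values[1L, 1L], tolerance = 1e-12)
  expect_equal(A$values[2L, 2L], A$values[1L, 1L], tolerance = 1e-12)
})

test_that("the GRM is symmetric, excludes monomorphic SNPs, and is invariant
           to SNP order and allele-coding flips", {
  set.seed(5)
  M <- matrix(sample(0:2, 40 * 30, replace = TRUE), 40L, 30L)
  M[, 7L] <- 1L                               # monomorphic
  A <- compute_grm(genotype_matrix(M))
  expect_lt(max(abs(A$values - t(A$values))), 1e-12)
  expect_equal(A$n_snps_used, 29L)

  perm <- sample(30L)
  A2 <- compute_grm(genotype_matrix(M[, perm]))
  expect_equal(unname(A2$values), unname(A$values), tolerance = 1e-12)

  Mf <- M
  flip <- c(3L, 11L, 20L)
  Mf[, flip] <- 2L - Mf[, flip]               # standardization absorbs flips
  A3 <- compute_grm(genotype_matrix(Mf))
  expect_equal(unname(A3$values), unname(A$values), tolerance = 1e-12)

  expect_error(compute_grm(genotype_matrix(matrix(1L, 5L, 3L))),
               class = "gxeortho_degenerate_error")
})

test_that("Hardy-Weinberg genotypes give a near-unit mean GRM diagonal", {
  sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = 499L,
                     n_snps = 2000L, seed = 13L)
  A <- compute_grm(simulate_genotypes(sc))
  expect_gt(mean(diag(A$values)), 0.95)
  expect_lt(mean(diag(A$values)), 1.05)
})

test_that("greedy pruning removes hubs first and stops at a fixed point", {
  # identity: nothing to remove
  A <- as_grm(diag(4), paste0("s", 1:4))
  expect_identical(prune_related(A, 0.025), paste0("s", 1:4))

  # a single related pair: exactly one of the two goes
  V <- diag(4); V[1, 2] <- V[2, 1] <- 0.5
  kept <- prune_related(as_grm(V, paste0("s", 1:4)), 0.025)
  expect_length(kept, 3L)
  expect_length(intersect(kept, c("s1", "s2")), 1L)

  # individual 3 related to both 1 and 2: the hub is removed, and only it
  V <- diag(4); V[1, 3] <- V[3, 1] <- V[2, 3] <- V[3, 2] <- 0.1
  expect_identical(prune_related(as_grm(V, paste0("s", 1:4)), 0.025),
                   c("s1", "s2", "s4"))

  # fixed point: pruning the induced submatrix removes nobody
  set.seed(7)
  W <- matrix(rnorm(30 * 30, sd = 0.05), 30L)
  W <- (W + t(W)) / 2; diag(W) <- 1
  A <- as_grm(W, paste0("s", 1:30))
  kept <- prune_related(A, 0.06)
  A2 <- subset_grm(A, kept)
  expect_true(all(abs(A2$values[upper.tri(A2$values)]) <= 0.06))
  expect_identical(prune_related(A2, 0.06), kept)

  expect_error(prune_related(A, 0), class = "gxeortho_config_error")
})

test_that("principal components are orthonormal and recover known structure", {
  A <- as_grm(diag(6))
  V <- grm_principal_components(A, 3L)
  expect_equal(unname(crossprod(V)), diag(3), tolerance = 1e-10)
  expect_error(grm_principal_components(A, 6L),
               class = "gxeortho_config_error")

  # construct-then-recover: a fixed spectrum under a known rotation
  set.seed(31)
  Q <- qr.Q(qr(matrix(rnorm(64), 8L)))
  lam <- c(5, 3, 2, 1.5, 1, 0.7, 0.4, 0.1)
  A2 <- as_grm(Q %*% diag(lam) %*% t(Q))
  V2 <- grm_principal_components(A2, 3L)
  for (j in 1:3) {
    v <- Q[, j]
    i <- which.max(abs(v)); if (v[i] < 0) v <- -v   # same sign convention
    expect_equal(V2[, j], setNames(v, rownames(V2)), tolerance = 1e-8)
  }
})

test_that("PC1 separates the two subpopulations under differentiation", {
  sc <- sim_scenario("strat_confound", n_training = 1L, n_analysis = 999L,
                     n_snps = 500L, fst = 0.05, seed = 17L)
  G <- simulate_genotypes(sc)
  A <- compute_grm(G)
  pc1 <- grm_principal_components(A, 1L)[, 1L]
  expect_gt(abs(cor(pc1, G$subpop_labels)), 0.9)
})

test_that("GRM text serialization round-trips bit-exactly", {
  s <- small_sim(n = 25, m = 40, seed = 23)
  path <- withr::local_tempfile(fileext = ".grm.tsv")
  write_grm(s$A, path)
  A2 <- read_grm(path)
  expect_identical(A2$values, s$A$values)
  expect_identical(A2$sample_ids, s$A$sample_ids)
  expect_identical(A2$n_snps_used, s$A$n_snps_used)
})

test_that("low-rank and dense spectral routes agree", {
  s <- small_sim(n = 60, m = 30, seed = 29)
  sp_lr <- gxeortho:::grm_spectral(s$A)                       # via Z (m < n)
  A_dense <- as_grm(s$A$values, s$A$sample_ids, s$A$n_snps_used)
  sp_d <- gxeortho:::grm_spectral(A_dense)
  expect_equal(sp_lr$d, sp_d$d[seq_along(sp_lr$d)], tolerance = 1e-8)
  expect_equal(sp_lr$n0 + length(sp_lr$d), 60L)
  # reconstruct A from the low-rank factors
  expect_equal(sp_lr$U %*% (sp_lr$d * t(sp_lr$U)), unname(s$A$values),
               tolerance = 1e-8, ignore_attr = TRUE)
})
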