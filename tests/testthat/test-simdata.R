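test_that("simulated dosages respect the support and dimension contracts", {
  for (nm in c("exogenous", "genetic_selection", "hidden_overlap",
               "strat_confound")) {
    sc <- sim_scenario(nm, n_training = 4L, n_analysis = 6L, n_snps = 3L,
                       n_causal = 2L, seed = 3L)
    G <- simulate_genotypes(sc)
    expect_equal(dim(G$dosages), c(10L, 3L))
    expect_true(all(G$dosages %in% 0:2))
    expect_false(anyDuplicated(G$sample_ids) > 0)
    if (nm == "strat_confound") {
      expect_equal(sort(unique(G$subpop_labels)), c(1L, 2L))
    } else {
      expect_null(G$subpop_labels)
    }
  }
})

test_that("fst = 0 collapses Balding-Nichols to the ancestral frequency", {
  # with one SNP at fixed ancestral p = 0.3, the mean dosage at n = 10,000
  # must sit within 3 binomial standard errors of 2p = 0.6
  sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = 9999L,
                     n_snps = 1L, maf_range = c(0.3, 0.3), seed = 11L)
  G <- simulate_genotypes(sc)
  expect_null(G$subpop_labels)
  expect_equal(G$allele_freq, 0.3)
  expect_lt(abs(mean(G$dosages) - 0.6), 3 * sqrt(2 * 0.3 * 0.7 / 10000))
})

test_that("the generator is a pure function of the scenario seed", {
  sc <- sim_scenario("genetic_selection", n_training = 30L,
                     n_analysis = 30L, n_snps = 40L, seed = 99L)
  G1 <- simulate_genotypes(sc); G2 <- simulate_genotypes(sc)
  expect_identical(G1, G2)
  t1 <- simulate_traits(G1, sc); t2 <- simulate_traits(G2, sc)
  expect_identical(t1, t2)
  s1 <- split_sample(t1, G1, sc); s2 <- split_sample(t2, G2, sc)
  expect_identical(s1$training$data$sample_ids, s2$training$data$sample_ids)
})

test_that("a zero-heritability outcome is pure unit-variance noise", {
  sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = 4999L,
                     n_snps = 50L, h2_Y = 0, seed = 21L)
  G <- simulate_genotypes(sc)
  td <- simulate_traits(G, sc)
  expect_true(all(td$latent_gY == 0))
  expect_true(all(td$latent_Eg == 0))
  expect_gt(var(td$Y), 0.9)
  expect_lt(var(td$Y), 1.1)
})

test_that("exogenous E is uncorrelated with the genetic value", {
  hits <- 0L
  n <- 5000L
  for (seed in 1:30) {
    sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = n - 1L,
                       n_snps = 100L, seed = seed)
    td <- simulate_traits(simulate_genotypes(sc), sc)
    if (abs(cor(td$E, td$latent_gY)) < 3 / sqrt(n)) hits <- hits + 1L
  }
  expect_gte(hits, 28L)   # 3-sigma band holds ~99.7% of the time
})

test_that("genetic selection induces a strong point-biserial E-g correlation", {
  # liability threshold with loading 0.8 implies corr(E, g) near
  # 0.8 * dnorm(0) / 0.5 ~ 0.64, far above the 0.3 floor
  hits <- 0L
  for (seed in 1:20) {
    sc <- sim_scenario("genetic_selection", n_training = 1L,
                       n_analysis = 4999L, n_snps = 100L,
                       env_loading = 0.8, seed = seed)
    td <- simulate_traits(simulate_genotypes(sc), sc)
    r <- cor(td$E, td$latent_gY)
    if (r > 0.3) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("heritability is calibrated: var(g)/var(Y) tracks h2_Y", {
  ratios <- vapply(1:10, function(seed) {
    sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = 2999L,
                       n_snps = 800L, h2_Y = 0.5, seed = seed)
    td <- simulate_traits(simulate_genotypes(sc), sc)
    var(td$latent_gY) / var(td$Y)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.05)
})

test_that("hidden_overlap keeps the PGI-visible and E-driving scores disjoint", {
  cors <- vapply(1:20, function(seed) {
    sc <- sim_scenario("hidden_overlap", n_training = 400L,
                       n_analysis = 400L, n_snps = 300L, seed = seed)
    G <- simulate_genotypes(sc)
    td <- simulate_traits(G, sc)
    an <- split_sample(td, G, sc)$analysis$data
    g1 <- an$latent_gY - an$latent_Eg    # analysis rows: gY = g1 + g2
    cor(an$latent_Eg, g1)
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("hidden_overlap training outcome carries no S2 signal", {
  sc <- sim_scenario("hidden_overlap", n_training = 1500L,
                     n_analysis = 500L, n_snps = 400L, seed = 5L)
  G <- simulate_genotypes(sc)
  td <- simulate_traits(G, sc)
  sp <- split_sample(td, G, sc)
  tr <- sp$training
  # in the training rows Y was built on S1 only: regressing Y on the
  # E-driving score must find (at most noise-level) association
  expect_lt(abs(cor(tr$data$Y, tr$data$latent_Eg)), 4 / sqrt(1500))
  # while the analysis rows carry the S2 share by construction
  an <- sp$analysis
  expect_gt(cor(an$data$Y, an$data$latent_Eg), 0.3)
})

test_that("strat_confound assigns E by subpopulation and shifts the mean", {
  sc <- sim_scenario("strat_confound", n_training = 200L,
                     n_analysis = 1800L, n_snps = 300L, h2_Y = 0,
                     seed = 9L)
  G <- simulate_genotypes(sc)
  td <- simulate_traits(G, sc)
  expect_identical(td$E, as.integer(G$subpop_labels - 1L))
  expect_true(all(td$latent_Eg == 0))
  # with h2_Y = 0 the only systematic Y difference is the additive
  # subpopulation shift of 0.5 SD
  diff <- mean(td$Y[td$E == 1]) - mean(td$Y[td$E == 0])
  expect_lt(abs(diff - 0.5), 3 * sqrt(2 / 1000))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_scenario("strat_confound", fst = 0),
               class = "gxeortho_config_error")
  expect_error(sim_scenario("exogenous", h2_Y = 1.2),
               class = "gxeortho_config_error")
  expect_error(sim_scenario("exogenous", n_causal = 50L, n_snps = 10L),
               class = "gxeortho_config_error")
  expect_error(sim_scenario("hidden_overlap", s2_share = 0.7, h2_Y = 0.5),
               class = "gxeortho_config_error")
  sc <- sim_scenario("exogenous", n_training = 0L, n_analysis = 10L,
                     n_snps = 5L)
  G <- simulate_genotypes(sc)
  td <- simulate_traits(G, sc)
  expect_error(split_sample(td, G, sc), class = "gxeortho_config_error")
})

test_that("split_sample partitions the cohort deterministically", {
  sc <- sim_scenario("exogenous", n_training = 100L, n_analysis = 50L,
                     n_snps = 20L, seed = 4L)
  G <- simulate_genotypes(sc)
  td <- simulate_traits(G, sc)
  sp <- split_sample(td, G, sc)
  expect_length(sp$training$data$sample_ids, 100L)
  expect_length(sp$analysis$data$sample_ids, 50L)
  expect_length(intersect(sp$training$data$sample_ids,
                          sp$analysis$data$sample_ids), 0L)
  expect_setequal(c(sp$training$data$sample_ids,
                    sp$analysis$data$sample_ids), G$sample_ids)
})

test_that("low-MAF panels are resampled to polymorphism", {
  sc <- sim_scenario("exogenous", n_training = 1L, n_analysis = 39L,
                     n_snps = 100L, maf_range = c(0.01, 0.05), seed = 8L)
  G <- simulate_genotypes(sc)
  expect_true(all(apply(G$dosages, 2, var) > 0))
})
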