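test_that("base probability vectors are valid and evenness responds to sdlog", {
  expect_equal(simulate_probabilities(1), 1)
  p <- simulate_probabilities(100, sdlog = 1, seed = 3)
  expect_length(p, 100)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(simulate_probabilities(0), "richness")

  # larger sdlog -> more uneven vector (larger Gini), Monte Carlo over draws
  gini <- function(x) {
    x <- sort(x); n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  g_small <- mean(sapply(1:100, function(s) gini(simulate_probabilities(50, sdlog = 0.5, seed = s))))
  g_large <- mean(sapply(1:100, function(s) gini(simulate_probabilities(50, sdlog = 2, seed = s))))
  expect_gt(g_large, g_small)
})

test_that("Dirichlet-multinomial rows sum to depth and approach multinomial as concentration grows", {
  p <- simulate_probabilities(30, seed = 1)
  counts <- simulate_dirichlet_multinomial(p, n_samples = 25, depth = 2000, seed = 2)
  expect_equal(dim(counts), c(25, 30))
  expect_true(all(rowSums(counts) == 2000))

  one <- simulate_dirichlet_multinomial(1, n_samples = 4, depth = 77, seed = 3)
  expect_true(all(one == 77))

  expect_error(simulate_dirichlet_multinomial(c(0.5, 0.6), 5, 100), "sum to 1")

  # concentration -> infinity: column means / depth converge to p
  p4 <- c(0.4, 0.3, 0.2, 0.1)
  big <- simulate_dirichlet_multinomial(p4, 200, 1000, concentration = 1e6, seed = 4)
  expect_equal(unname(colMeans(big) / 1000), p4, tolerance = 0.02)
})

test_that("finite concentration adds overdispersion beyond multinomial sampling", {
  p4 <- c(0.4, 0.3, 0.2, 0.1)
  dm <- simulate_dirichlet_multinomial(p4, 400, 500, concentration = 5, seed = 5)
  set.seed(6)
  mn <- t(rmultinom(400, 500, p4))
  # multinomial variance n p (1 - p) is the lower bound
  expect_true(all(apply(dm, 2, var) > apply(mn, 2, var)))
})

test_that("spatial layout and covariate gradient behave as configured", {
  md <- simulate_environment_spatial(75, grid_spacing = 50, seed = 7)
  expect_equal(nrow(md$coords), 75)
  expect_gt(min(dist(md$coords)), 0)

  # no shared gradient: axis-1 variance fraction matches the iid
  # random-matrix oracle at the same dimensions (tends to 1/k as n grows)
  fr0 <- sapply(1:50, function(s) {
    md0 <- simulate_environment_spatial(40, n_covariates = 5,
                                        gradient_weight = 0, seed = s)
    sv <- svd(scale(as.matrix(md0$covariates)))$d
    sv[1]^2 / sum(sv^2)
  })
  set.seed(77)
  oracle <- replicate(200, {
    sv <- svd(scale(matrix(rnorm(40 * 5), 40, 5)))$d
    sv[1]^2 / sum(sv^2)
  })
  expect_equal(mean(fr0), mean(oracle), tolerance = 0.03)

  # default shared gradient: axis 1 explains a majority of the variance
  fr1 <- pca_stage_scores(md)$var_fraction[1]
  expect_gt(fr1, 0.5)
})

test_that("clr-space generator matches its planted correlation structure", {
  md <- simulate_environment_spatial(200, seed = 1)

  # no loadings, no covariate effects: inter-taxon correlations near zero
  tr0 <- sim_truth(10, n_covariates = 1, n_latent = 2, beta_sd = 0,
                   prop_loaded = 0, phi = NA, seed = 2)
  sim0 <- simulate_jsdm_community(tr0, md, seed = 3, recentre = FALSE)
  off <- abs(cor(sim0$Y)[upper.tri(diag(10))])
  expect_lt(max(off), 0.25)
  expect_lt(mean(off), 0.15)

  # identical loadings and vanishing noise: correlation tends to 1
  tr1 <- sim_truth(4, n_covariates = 1, n_latent = 1, beta_sd = 0,
                   prop_loaded = 0, sigma = 1e-4, phi = NA, seed = 4)
  tr1$lambda_true[, 1] <- 1.5
  sim1 <- simulate_jsdm_community(tr1, md, seed = 5, recentre = FALSE)
  expect_gt(min(cor(sim1$Y)), 0.999)

  # planted rho recovered empirically at large n
  md5 <- simulate_environment_spatial(500, seed = 6)
  tr <- sim_truth(15, n_covariates = 1, n_latent = 2, beta_sd = 0,
                  lambda_scale = 1.5, phi = NA, seed = 7)
  sim <- simulate_jsdm_community(tr, md5, seed = 8, recentre = FALSE)
  emp <- cor(sim$Y)
  ut <- upper.tri(emp)
  rmse <- sqrt(mean((emp[ut] - tr$rho_true[ut])^2))
  expect_lt(rmse, 0.1)
})

test_that("generators are deterministic given the seed", {
  expect_identical(simulate_probabilities(20, seed = 9),
                   simulate_probabilities(20, seed = 9))
  expect_identical(simulate_dirichlet_multinomial(c(.5, .5), 5, 100, seed = 9),
                   simulate_dirichlet_multinomial(c(.5, .5), 5, 100, seed = 9))
  md_a <- simulate_environment_spatial(20, seed = 9)
  md_b <- simulate_environment_spatial(20, seed = 9)
  expect_identical(md_a$coords, md_b$coords)
  s1 <- simulate_survey(12, groups = list(bacteria = list(richness = 15, depth = 300)),
                        seed = 9)
  s2 <- simulate_survey(12, groups = list(bacteria = list(richness = 15, depth = 300)),
                        seed = 9)
  expect_identical(s1$table$counts, s2$table$counts)
})
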