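test_that("spherical correlation matches the cubic and its endpoints", {
  expect_equal(spherical_correlation(0, 10), 1)
  expect_equal(spherical_correlation(10, 10), 0)
  expect_equal(spherical_correlation(25, 10), 0)
  expect_equal(spherical_correlation(5, 10), 0.3125)  # 1 - 1.5/2 + 0.5/8
  expect_error(spherical_correlation(1, 0), "phi")
  expect_error(spherical_correlation(-1, 5), ">= 0")
  D <- as.matrix(dist(cbind(c(0, 3, 50), c(0, 4, 0))))
  R <- spherical_corr_matrix(D, 10)
  expect_equal(R[1, 3], 0)
  expect_true(isSymmetric(R))
})

test_that("retained-draw accounting matches the settings", {
  expect_equal(mcmc_retained(40000, 10000, 30), 1000)
  expect_equal(mcmc_retained(200, 50, 5), 30)
  expect_error(mcmc_retained(100, 100, 1), "burn_in")
  Y <- null_clr(10, 4, seed = 1)
  post <- fit_jsdm(Y, n_latent = 1, iterations = 200, burn_in = 50, thin = 5,
                   seed = 1)
  expect_equal(post$m, 30)
  expect_equal(dim(post$sigma2), c(30, 4))
})

test_that("forward selection finds the true covariate and skips collinear copies", {
  set.seed(8)
  n <- 60
  cand <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  Y <- outer(cand$A, rnorm(6, sd = 2)) + matrix(rnorm(n * 6, sd = 0.5), n, 6)
  sel <- forward_select_env(Y, cand, k = 2)
  expect_equal(sel[1], "A")
  expect_equal(forward_select_env(Y, cand, k = 0), character(0))
  cand$A2 <- cand$A
  expect_warning(sel2 <- forward_select_env(Y, cand, k = 4), "collinear")
  expect_false(all(c("A", "A2") %in% sel2))
  expect_error(forward_select_env(Y, cand, k = 10), "exceeds")
})

test_that("environment-only sampler matches the least-squares oracle", {
  set.seed(9)
  n <- 60; p <- 3; q <- 1
  X <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "x"))
  Bt <- matrix(c(1.5, -0.8, 0.3), p, q)
  Y <- X %*% t(Bt) + matrix(rnorm(n * p), n, p)
  colnames(Y) <- paste0("t", 1:p)
  post <- fit_jsdm(Y, X, n_latent = 0, iterations = 2000, burn_in = 500,
                   thin = 1, seed = 2, scale_x = FALSE)
  ols <- coef(lm(Y ~ X))
  bhat <- apply(post$B, c(2, 3), mean)
  mcse <- apply(post$B, c(2, 3), function(ch) {
    sd(ch) / sqrt(coda::effectiveSize(ch))
  })
  expect_true(all(abs(bhat - ols) < 3 * mcse + 1e-3))
})

test_that("degenerate all-zero data concentrates coefficients near zero", {
  Y <- matrix(0, 20, 4, dimnames = list(NULL, paste0("t", 1:4)))
  post <- fit_jsdm(Y, n_latent = 1, iterations = 400, burn_in = 100, thin = 1,
                   seed = 3)
  expect_lt(max(abs(apply(post$B, c(2, 3), mean))), 0.05)
  expect_lt(max(abs(apply(post$Lambda, c(2, 3), mean))), 0.2)
})

test_that("residual correlations follow the loading geometry", {
  expect_equal(residual_correlation_matrix(matrix(0, 3, 2), rep(1, 3)),
               diag(3))
  lam <- rbind(c(1, 0, 0), c(1, 0, 0))
  rho <- residual_correlation_matrix(lam, rep(1e-12, 2))
  expect_equal(rho[1, 2], 1)
  lam2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(residual_correlation_matrix(lam2, rep(0.5, 2))[1, 2], 0)
})

test_that("per-draw residual correlation matrices are symmetric PSD with unit diagonal", {
  Y <- null_clr(15, 6, seed = 4)
  post <- fit_jsdm(Y, n_latent = 2, iterations = 400, burn_in = 100, thin = 3,
                   seed = 4)
  for (s in seq(1, post$m, by = 20)) {
    rho <- residual_correlation_matrix(post$Lambda[s, , ], post$sigma2[s, ])
    expect_equal(diag(rho), rep(1, 6), tolerance = 1e-12)
    expect_true(isSymmetric(rho))
    expect_gte(min(eigen(rho, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("edge calling uses credible-interval exclusion of zero", {
  summ <- data.frame(taxon_a = c("a", "a", "b"), taxon_b = c("b", "c", "c"),
                     median = c(0.1, 0.2, -0.3),
                     lower = c(-0.1, 0.05, -0.5),
                     upper = c(0.2, 0.4, -0.1))
  ed <- significant_edges(summ)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$sign, c("positive", "negative"))
  expect_false(any(ed$taxon_a == "a" & ed$taxon_b == "b"))
})

test_that("environmental variance explained matches the regression structure", {
  set.seed(10)
  n <- 50; q <- 2
  X <- matrix(rnorm(n * q), n, q, dimnames = list(NULL, c("u", "v")))
  # exactly linear response: mean R^2 near 1
  Y_lin <- X %*% matrix(c(1, 2, -1, 0.5), q, 2) +
    matrix(rnorm(n * 2, sd = 1e-3), n, 2)
  colnames(Y_lin) <- c("t1", "t2")
  post_lin <- fit_jsdm(Y_lin, X, n_latent = 0, iterations = 800, burn_in = 200,
                       thin = 1, seed = 5, scale_x = FALSE)
  expect_gt(env_variance_explained(post_lin)$mean, 0.99)

  # X independent of Y: small in-sample R^2 at the chance level. The
  # posterior-expected residual SS exceeds the least-squares RSS by the
  # factor 1 + (q+1)/(n-q-3) (posterior spread of the coefficients), so the
  # independent oracle is the per-taxon lm fit with that adjustment.
  Y_null <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("t", 1:8)))
  post_null <- fit_jsdm(Y_null, X, n_latent = 0, iterations = 800,
                        burn_in = 200, thin = 1, seed = 6, scale_x = FALSE)
  r2_ols <- sapply(1:8, function(j) summary(lm(Y_null[, j] ~ X))$r.squared)
  oracle <- mean(1 - (1 - r2_ols) * (1 + (q + 1) / (n - q - 3)))
  got <- env_variance_explained(post_null)$mean
  expect_lt(abs(got - oracle), 0.03)
  expect_lt(abs(got), 0.12)

  expect_error(env_variance_explained(
    fit_jsdm(Y_null, X, n_latent = 1, iterations = 200, burn_in = 50,
             thin = 1, seed = 7)), "d = 0")
})

test_that("Geweke z flags drifting chains and passes stationary ones", {
  set.seed(11)
  z_iid <- replicate(100, geweke_diagnostic(rnorm(1000)))
  expect_gte(mean(abs(z_iid) < 3), 0.97)
  drift <- c(rnorm(500), rnorm(500, mean = 3))
  expect_gt(abs(geweke_diagnostic(drift)), 5)
  expect_warning(z_const <- geweke_diagnostic(rep(1, 100)), "constant")
  expect_true(is.na(z_const))
  expect_error(geweke_diagnostic(rnorm(10)), "50")
})

test_that("standardised residuals are near standard normal under the model", {
  md <- simulate_environment_spatial(40, seed = 12)
  tr <- sim_truth(8, n_covariates = 2, n_latent = 1, lambda_scale = 1,
                  phi = NA, seed = 12)
  sim <- simulate_jsdm_community(tr, md, seed = 13, recentre = FALSE)
  post <- fit_jsdm(sim$Y, sim$X, n_latent = 1, iterations = 1500,
                   burn_in = 500, thin = 2, seed = 14, scale_x = FALSE)
  qr_ <- quantile_residuals(post)
  expect_lt(abs(mean(qr_$residuals)), 0.1)
  expect_equal(sd(qr_$residuals), 1, tolerance = 0.15)
  expect_equal(qr_$qq_slope, 1, tolerance = 0.15)

  # heavy-tailed errors are detected: the fitted residual SD absorbs the
  # outlier variance, so the bulk of the standardised residuals is squeezed
  # (QQ slope well below 1) while the tails are heavy (excess kurtosis)
  set.seed(15)
  mu_true <- sim$X %*% t(tr$beta_true) + sim$Z %*% t(tr$lambda_true)
  Yc <- mu_true + matrix(rt(length(mu_true), df = 3), nrow(mu_true))
  colnames(Yc) <- colnames(sim$Y)
  post_c <- fit_jsdm(Yc, sim$X, n_latent = 1, iterations = 1000,
                     burn_in = 300, thin = 2, seed = 16, scale_x = FALSE)
  qr_c <- quantile_residuals(post_c)
  expect_lt(qr_c$qq_slope, 0.95)
  kurt <- function(x) mean((x - mean(x))^4) / mean((x - mean(x))^2)^2
  expect_gt(kurt(qr_c$residuals), kurt(qr_$residuals) + 0.5)
})

test_that("residual correlation summaries are stable across sampler seeds", {
  md <- simulate_environment_spatial(40, seed = 17)
  tr <- sim_truth(12, n_covariates = 1, n_latent = 2, lambda_scale = 1.5,
                  phi = NA, seed = 17)
  sim <- simulate_jsdm_community(tr, md, seed = 18, recentre = FALSE)
  r1 <- residual_correlation_draws(
    fit_jsdm(sim$Y, sim$X, n_latent = 2, iterations = 2000, burn_in = 600,
             thin = 2, seed = 19, scale_x = FALSE))
  r2 <- residual_correlation_draws(
    fit_jsdm(sim$Y, sim$X, n_latent = 2, iterations = 2000, burn_in = 600,
             thin = 2, seed = 20, scale_x = FALSE))
  rmse <- sqrt(mean((r1$summary$median - r2$summary$median)^2))
  expect_lt(rmse, 0.1)
})
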