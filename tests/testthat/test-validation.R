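small_fit <- list(n_latent = 2, iterations = 600, burn_in = 200, thin = 2)

test_that("within-taxon randomisation preserves per-taxon abundance multisets", {
  set.seed(20)
  m <- matrix(rpois(20 * 6, 3), 20, 6,
              dimnames = list(paste0("s", 1:20), paste0("t", 1:6)))
  tab <- community_table(m)
  rnd <- randomize_within_taxa(tab, seed = 1)
  expect_equal(dim(rnd$counts), dim(m))
  for (j in seq_len(ncol(m))) {
    expect_equal(sort(unname(rnd$counts[, j])),
                 sort(unname(m[, j])))  # multiset preserved
  }
  expect_equal(colSums(rnd$counts > 0), colSums(m > 0))  # occurrence frequency
  expect_equal(colSums(rnd$counts), colSums(m))
  one <- community_table(m[1, , drop = FALSE])
  expect_equal(randomize_within_taxa(one, seed = 2)$counts, one$counts)
})

test_that("false-positive percentages follow mean(randomised)/observed", {
  expect_equal(round_half_up(false_positive_rate(1.0, 3481)$percent, 3), 0.029)
  expect_equal(round_half_up(false_positive_rate(3.1, 963)$percent, 2), 0.32)
  expect_equal(false_positive_rate(c(0, 0, 0), 100)$percent, 0)
  r <- false_positive_rate(c(2, 4), 100)
  expect_equal(r$mean, 3)
  expect_equal(r$sd, sd(c(2, 4)))
  expect_error(false_positive_rate(c(1, 2), 0), "> 0")
})

test_that("richness simulation produces one row per usable replicate and four regressions", {
  probs <- list(poor = simulate_probabilities(30, seed = 1),
                rich = simulate_probabilities(60, seed = 2))
  rep_ <- richness_effect_simulation(probs, n_reps = 2, n_samples = 20,
                                     depth = 800, cutoff = 10,
                                     seed = 1, fit_settings = small_fit)
  expect_s3_class(rep_, "validation_report")
  expect_equal(nrow(rep_$replicates), 4)
  expect_equal(nrow(rep_$regressions), 4)
  expect_true(all(c("r_squared", "p_value") %in% names(rep_$regressions)))
  expect_true(all(rep_$replicates$modeled_richness <=
                    rep_$replicates$total_richness))
  expect_error(richness_effect_simulation(probs[1]), "two scenarios")
})

test_that("taxon subsampling reruns summarise replicate networks", {
  md <- simulate_environment_spatial(25, seed = 21)
  tr <- sim_truth(14, n_covariates = 1, n_latent = 2, lambda_scale = 1.5,
                  phi = NA, seed = 21)
  sim <- simulate_jsdm_community(tr, md, seed = 22, recentre = FALSE)

  full <- subsample_taxa_rerun(sim$Y, n_taxa = 14, X = sim$X, seed = 5,
                               fit_settings = small_fit)
  expect_equal(nrow(full$replicates), 1)  # all taxa: plain full fit

  sub <- subsample_taxa_rerun(sim$Y, n_taxa = 9, n_reps = 3, X = sim$X,
                              seed = 5, fit_settings = small_fit)
  expect_equal(nrow(sub$replicates), 3)
  expect_true(all(sub$replicates$nodes <= 9))
  expect_gt(sum(sub$summary$sd, na.rm = TRUE), 0)  # replicates differ
  expect_error(subsample_taxa_rerun(sim$Y, n_taxa = 99), "exceeds")
})

test_that("axis-range standardisation picks windows of bounded score spread", {
  md <- simulate_environment_spatial(36, seed = 23)
  tr <- sim_truth(10, n_covariates = 1, n_latent = 2, lambda_scale = 1.5,
                  phi = NA, seed = 23)
  sim <- simulate_jsdm_community(tr, md, seed = 24, recentre = FALSE)
  scores <- setNames(pca_stage_scores(md)$scores[, 1], md$sample_ids)
  st <- assign_stages(scores, 3)

  rep_ <- standardize_axis_range_rerun(scores, st, sim$Y, window_width = 10,
                                       n_plots = 6, seed = 3,
                                       fit_settings = small_fit)
  expect_equal(nrow(rep_$replicates), 3)
  expect_true(all(rep_$replicates$score_range <= 10))

  expect_error(
    standardize_axis_range_rerun(scores, st, sim$Y, window_width = 1e-6,
                                 n_plots = 6, seed = 3,
                                 fit_settings = small_fit),
    "width")
})
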