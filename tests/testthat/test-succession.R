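make_md <- function(n, vars, seed = 1) {
  set.seed(seed)
  covs <- as.data.frame(vars)
  rownames(covs) <- paste0("s", seq_len(n))
  sample_metadata(covs, cbind(runif(n), runif(n)))
}

test_that("stage PCA variance fractions and orientation follow the conventions", {
  n <- 20
  set.seed(4)
  g <- rnorm(n)
  md <- make_md(n, list(a = g, b = 2 * g, plant_cover = -g))
  pc <- pca_stage_scores(md, orient_by = "plant_cover")
  expect_equal(unname(pc$var_fraction[1]), 1, tolerance = 1e-10)
  expect_gte(pc$loadings["plant_cover", 1], 0)
  expect_equal(sum(pc$var_fraction), 1)

  md0 <- make_md(n, list(a = rnorm(n), b = rnorm(n), zv = rep(1, n)))
  expect_error(pca_stage_scores(md0), "zv")

  # isotropic noise: axis-1 fraction matches the iid random-matrix oracle
  # (above 1/k in finite samples, approaching it as n grows)
  fr <- sapply(1:40, function(s) {
    mdn <- make_md(60, replicate(5, rnorm(60), simplify = FALSE) |>
                     setNames(paste0("v", 1:5)), seed = s)
    pca_stage_scores(mdn, orient_by = "none")$var_fraction[1]
  })
  set.seed(99)
  oracle <- replicate(200, {
    sv <- svd(scale(matrix(rnorm(60 * 5), 60, 5)))$d
    sv[1]^2 / sum(sv^2)
  })
  expect_equal(mean(fr), mean(oracle), tolerance = 0.03)
  expect_gt(mean(fr), 1 / 5)
  expect_lt(mean(fr), 2 / 5)
})

test_that("stage assignment splits ranked scores into near-equal contiguous groups", {
  set.seed(5)
  sc <- setNames(rnorm(75), paste0("s", sprintf("%02d", 1:75)))
  st <- assign_stages(sc, 3)
  expect_equal(as.integer(table(st$stage)), c(25L, 25L, 25L))
  # stage ordering monotone in score
  expect_true(max(st$axis1_score[st$stage == "early"]) <=
                min(st$axis1_score[st$stage == "mid"]))
  expect_true(max(st$axis1_score[st$stage == "mid"]) <=
                min(st$axis1_score[st$stage == "late"]))

  sc7 <- setNames(c(3, 1, 4, 1.5, 9, 2.6, 5), paste0("s", 1:7))
  st7 <- assign_stages(sc7, 3)
  expect_equal(as.integer(table(st7$stage)), c(3L, 2L, 2L))  # earliest group largest

  # rank invariance under monotone relabeling
  st_mono <- assign_stages(exp(sc), 3)
  expect_identical(st_mono$stage, st$stage)

  # input-order invariance
  perm <- sample(length(sc))
  st_perm <- assign_stages(sc[perm], 3)
  expect_identical(st_perm$stage[match(st$sample_id, st_perm$sample_id)], st$stage)
})

test_that("RDA fraction, pseudo-F and permutation p behave correctly", {
  set.seed(6)
  stage <- factor(rep(c("early", "mid", "late"), each = 8))
  means <- matrix(rnorm(3 * 5, sd = 2), 3, 5)
  exact <- means[as.integer(stage), ]  # response identical to stage means
  res <- rda_permutation(exact, stage, n_perm = 99, seed = 1)
  expect_equal(res$variance_fraction, 1)

  y <- exact + matrix(rnorm(24 * 5), 24, 5)
  r1 <- rda_permutation(y, stage, n_perm = 199, seed = 3)
  r2 <- rda_permutation(y, stage, n_perm = 199, seed = 3)
  expect_identical(r1$p_value, r2$p_value)  # deterministic given seed
  expect_lt(r1$p_value, 0.05)
  expect_equal(sum(r1$ss[c("constrained", "residual")]), r1$ss[["total"]],
               tolerance = 1e-8)
  expect_error(rda_permutation(y, rep("one", 24)), "two stages")

  # under the null the mean constrained fraction approaches df_c/(n-1)
  fr <- replicate(200, {
    yn <- matrix(rnorm(24 * 4), 24, 4)
    rda_permutation(yn, stage, n_perm = 0, seed = 1)$variance_fraction
  })
  expect_lt(abs(mean(fr) - 2 / 23), 0.01)
})

test_that("RDA agrees with the constrained-ordination reference implementation", {
  set.seed(7)
  stage <- factor(rep(c("a", "b", "c"), each = 7))
  y <- matrix(rnorm(21 * 6), 21, 6)
  ours <- rda_permutation(y, stage, n_perm = 0, seed = 1)
  ref <- vegan::rda(y ~ stage)
  expect_equal(ours$variance_fraction,
               unname(ref$CCA$tot.chi / ref$tot.chi), tolerance = 1e-10)
  ref_aov <- vegan::anova.cca(ref, permutations = 99)
  expect_equal(ours$pseudo_F, ref_aov$F[1], tolerance = 1e-8)
})
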