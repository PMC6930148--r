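#' Simulate a species-abundance probability vector
#'
#' Draws base relative abundances from a lognormal species-abundance
#' distribution and normalises them to sum to one. The lognormal SAD is the
#' standard parametric stand-in when observed relative abundances are not
#' available.
#'
#' @param richness number of taxa (`>= 1`).
#' @param distribution currently `"lognormal"`.
#' @param meanlog,sdlog lognormal parameters; larger `sdlog` gives a more
#'   uneven community.
#' @param seed integer seed.
#' @return probability vector of length `richness`, positive, summing to 1.
#' @export
simulate_probabilities <- function(richness, distribution = "lognormal",
                                   meanlog = 0, sdlog = 1, seed = 1) {
  if (richness < 1) stop("richness must be >= 1")
  distribution <- match.arg(distribution, "lognormal")
  local_seed(seed)
  x <- stats::rlnorm(richness, meanlog = meanlog, sdlog = sdlog)
  x / sum(x)
}

# Dirichlet draws by gamma normalisation; one row per sample.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  g <- pmax(g, 1e-300)
  g / rowSums(g)
}

#' Simulate counts from a Dirichlet-multinomial distribution
#'
#' Per sample, a proportion vector is drawn from
#' `Dirichlet(concentration * p)` and counts from a multinomial at the given
#' read depth. Finite concentration adds overdispersion relative to a plain
#' multinomial; as `concentration` grows the distribution approaches
#' multinomial sampling from `p`.
#'
#' @param p base probability vector (must sum to 1).
#' @param n_samples number of samples (rows).
#' @param depth reads per sample.
#' @param concentration Dirichlet concentration scale (`> 0`).
#' @param seed integer seed.
#' @return `n_samples x length(p)` count matrix; every row sums to `depth`.
#' @export
simulate_dirichlet_multinomial <- function(p, n_samples, depth,
                                           concentration = 50, seed = 1) {
  if (abs(sum(p) - 1) > 1e-8) stop("p must sum to 1")
  if (depth < 1) stop("depth must be >= 1")
  if (concentration <= 0) stop("concentration must be > 0")
  local_seed(seed)
  pi <- rdirichlet_mat(n_samples, concentration * p)
  counts <- matrix(0, n_samples, length(p),
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   paste0("t", seq_along(p))))
  for (i in seq_len(n_samples)) {
    counts[i, ] <- stats::rmultinom(1, depth, pi[i, ])[, 1]
  }
  counts
}

#' Simulate plot coordinates and correlated environmental covariates
#'
#' Emulates the sampling design of a gridded field survey: a square grid at
#' `grid_spacing` metres with 10% positional jitter, plus three tight
#' clusters of plots about `cluster_spacing` metres apart (when there are
#' enough samples). Covariates share one dominant spatial gradient --
#' `covariate = gradient_weight * g + noise` with `g` a standardised
#' function of position -- so that the first principal component explains a
#' majority of their variance, plus independent unit noise.
#'
#' @param n_samples number of plots (`>= 2`).
#' @param grid_spacing grid step in metres (default 50).
#' @param n_covariates number of covariates (default 6; the first six are
#'   named snow_depth, cv_snow, pH, moisture, whc, plant_cover).
#' @param gradient_weight strength of the shared gradient (0 = independent
#'   covariates; default 1).
#' @param cluster_spacing within-cluster plot spacing in metres (default 5).
#' @param seed integer seed.
#' @return a [sample_metadata()].
#' @export
simulate_environment_spatial <- function(n_samples, grid_spacing = 50,
                                         n_covariates = 6,
                                         gradient_weight = 1,
                                         cluster_spacing = 5, seed = 1) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  local_seed(seed)
  n_cluster <- if (n_samples >= 18) 9L else 0L
  m <- n_samples - n_cluster
  side <- ceiling(sqrt(m))
  gx <- (seq_len(side) - 1) * grid_spacing
  grid <- expand.grid(x = gx, y = gx)[seq_len(m), ]
  jitter <- matrix(stats::runif(2 * m, -0.05, 0.05) * grid_spacing, m, 2)
  coords <- as.matrix(grid) + jitter
  if (n_cluster > 0) {
    centers <- coords[sample.int(m, 3), , drop = FALSE] +
      grid_spacing / 2
    offs <- rbind(c(0, 0), c(cluster_spacing, 0), c(0, cluster_spacing))
    cl <- do.call(rbind, lapply(seq_len(3), function(i) {
      sweep(offs + matrix(stats::runif(6, -0.05, 0.05) * cluster_spacing, 3, 2),
            2, centers[i, ], `+`)
    }))
    coords <- rbind(coords, cl)
  }
  rownames(coords) <- paste0("p", sprintf("%02d", seq_len(n_samples)))
  g <- as.vector(scale(coords[, 1] + coords[, 2] +
                         stats::rnorm(n_samples, sd = 0.2 * grid_spacing)))
  base_names <- c("snow_depth", "cv_snow", "pH", "moisture", "whc", "plant_cover")
  nm <- if (n_covariates <= length(base_names)) base_names[seq_len(n_covariates)]
        else c(base_names, paste0("cov", seq_len(n_covariates - length(base_names))))
  covs <- sapply(seq_len(n_covariates), function(k) {
    gradient_weight * g + stats::rnorm(n_samples)
  })
  colnames(covs) <- nm
  rownames(covs) <- rownames(coords)
  sample_metadata(as.data.frame(covs), coords)
}

#' Construct a ground-truth parameter set for the latent-variable model
#'
#' Builds the "planted" parameters a simulated community is generated from:
#' per-taxon base probabilities, covariate coefficients, sparse latent
#' loadings (a fraction of taxa load on one latent factor each, with sign
#' chosen at random), residual standard deviations, the implied residual
#' correlation matrix, and a spatial range. Pairs of taxa sharing a factor
#' have residual correlation `+/- lambda^2 / (lambda^2 + sigma^2)`.
#'
#' @param n_taxa number of taxa.
#' @param n_covariates number of environmental covariates (`q`).
#' @param n_latent number of latent factors (`d`).
#' @param beta_sd SD of covariate coefficients.
#' @param lambda_scale magnitude of non-zero loadings.
#' @param sigma residual SD (scalar or per-taxon vector).
#' @param phi spatial range in metres for the latent factors.
#' @param prop_loaded fraction of taxa carrying a non-zero loading.
#' @param sdlog lognormal SAD parameter for base probabilities.
#' @param seed integer seed.
#' @return list of class `sim_truth` with elements `base_probabilities`,
#'   `beta_true`, `lambda_true`, `sigma_true`, `rho_true`, `phi_true`.
#' @export
sim_truth <- function(n_taxa, n_covariates = 2, n_latent = 2,
                      beta_sd = 1, lambda_scale = 1.5, sigma = 1,
                      phi = 100, prop_loaded = 0.6, sdlog = 1, seed = 1) {
  local_seed(seed)
  p <- n_taxa
  probs <- stats::rlnorm(p, sdlog = sdlog)
  probs <- probs / sum(probs)
  beta <- matrix(stats::rnorm(p * n_covariates, sd = beta_sd), p, n_covariates)
  lambda <- matrix(0, p, max(n_latent, 1))
  if (n_latent > 0 && prop_loaded > 0) {
    loaded <- sample.int(p, max(2, round(prop_loaded * p)))
    fac <- sample.int(n_latent, length(loaded), replace = TRUE)
    sgn <- sample(c(-1, 1), length(loaded), replace = TRUE)
    lambda[cbind(loaded, fac)] <- sgn * lambda_scale
    lambda <- lambda[, seq_len(n_latent), drop = FALSE]
  } else {
    lambda <- matrix(0, p, n_latent)
  }
  sig <- rep_len(sigma, p)
  cov <- tcrossprod(lambda) + diag(sig^2, p)
  rho <- stats::cov2cor(cov)
  taxa <- paste0("t", sprintf("%03d", seq_len(p)))
  dimnames(rho) <- list(taxa, taxa)
  rownames(beta) <- rownames(lambda) <- taxa
  structure(list(base_probabilities = stats::setNames(probs, taxa),
                 beta_true = beta, lambda_true = lambda,
                 sigma_true = stats::setNames(sig, taxa),
                 rho_true = rho, phi_true = phi),
            class = "sim_truth")
}

#' Taxon pairs with a planted residual correlation
#'
#' @param truth a [sim_truth()].
#' @param threshold minimum `|rho_true|` for a pair to count as planted.
#' @return data.frame with columns `taxon_a`, `taxon_b`, `rho_true`.
#' @export
planted_edges <- function(truth, threshold = 0.2) {
  rho <- truth$rho_true
  idx <- which(upper.tri(rho) & abs(rho) >= threshold, arr.ind = TRUE)
  data.frame(taxon_a = rownames(rho)[idx[, 1]],
             taxon_b = colnames(rho)[idx[, 2]],
             rho_true = rho[idx])
}

#' Simulate a clr-space community from latent-variable model ground truth
#'
#' Generates `y_ij = beta0_j + x_i . beta_j + z_i . lambda_j + eps_ij` with
#' latent-score columns drawn from a Gaussian process with spherical spatial
#' correlation at range `phi_true` over the metadata coordinates (iid when
#' `phi_true` is `NA` or no coordinates are given). Rows are recentred to
#' sum to zero so the output respects clr geometry. Generation is in clr
#' space because that is the space the Gaussian model is fitted in; the
#' count-space path is [simulate_dirichlet_multinomial()].
#'
#' @param truth a [sim_truth()].
#' @param metadata a [sample_metadata()]; the first `q` covariates are
#'   z-scored and used as `X`.
#' @param seed integer seed.
#' @param intercept_sd SD of per-taxon intercepts (default 0).
#' @param recentre recentre rows to sum 0 (default `TRUE`).
#' @return list with `Y` (clr matrix), `X`, `Z`, and `truth`.
#' @export
simulate_jsdm_community <- function(truth, metadata, seed = 1,
                                    intercept_sd = 0, recentre = TRUE) {
  stopifnot(inherits(truth, "sim_truth"), inherits(metadata, "sample_metadata"))
  p <- length(truth$sigma_true)
  q <- ncol(truth$beta_true)
  d <- ncol(truth$lambda_true)
  n <- length(metadata$sample_ids)
  if (q > ncol(metadata$covariates)) {
    stop("metadata has fewer covariates than beta_true expects")
  }
  local_seed(seed)
  X <- scale(as.matrix(metadata$covariates[, seq_len(q), drop = FALSE]))
  Z <- matrix(stats::rnorm(n * d), n, d)
  if (d > 0 && is.finite(truth$phi_true)) {
    D <- as.matrix(stats::dist(metadata$coords))
    R <- spherical_corr_matrix(D, truth$phi_true)
    L <- t(chol(R))
    Z <- L %*% Z
  }
  b0 <- stats::rnorm(p, sd = intercept_sd)
  E <- matrix(stats::rnorm(n * p), n, p) %*% diag(truth$sigma_true, p)
  Y <- matrix(b0, n, p, byrow = TRUE) +
    (if (q > 0) X %*% t(truth$beta_true) else 0) +
    (if (d > 0) Z %*% t(truth$lambda_true) else 0) + E
  dimnames(Y) <- list(metadata$sample_ids, names(truth$sigma_true))
  if (recentre) Y <- sweep(Y, 1, rowMeans(Y))
  list(Y = Y, X = X, Z = Z, truth = truth)
}

#' Simulate a multi-group amplicon survey (counts, metadata, annotations)
#'
#' End-to-end fixture generator for the pipeline: plot layout and correlated
#' environment from [simulate_environment_spatial()], then for each organism
#' group a lognormal base community whose per-sample expected proportions
#' are tilted along the environmental gradient (taxon responses
#' `exp(a_j * g_i)` with `a_j ~ N(0, effect_sd)`), sampled through a
#' Dirichlet-multinomial at the group's read depth.
#'
#' @param n_samples number of plots.
#' @param groups named list: for each organism group, a list with `richness`,
#'   `depth`, and optionally `sdlog`, `concentration`.
#' @param effect_sd SD of per-taxon gradient responses (default 0.5).
#' @param gradient_weight passed to [simulate_environment_spatial()].
#' @param n_latent number of planted latent interaction factors shared
#'   across all groups (default 2).
#' @param lambda_scale log-abundance loading magnitude of taxa on their
#'   factor (default 0.8); 0 disables the planted interactions.
#' @param prop_loaded fraction of taxa carrying a latent loading.
#' @param prop_photosynthetic fraction of taxa labelled photosynthetic.
#' @param seed integer seed.
#' @return list with `table` (a combined [community_table()]), `metadata`,
#'   `gradient` (the latent gradient used for the tilt), and `loadings`
#'   (the planted per-taxon factor loadings).
#' @export
simulate_survey <- function(n_samples = 75,
                            groups = list(
                              bacteria = list(richness = 120, depth = 8000),
                              fungi = list(richness = 60, depth = 1100),
                              small_eukaryote = list(richness = 40, depth = 900),
                              microfauna = list(richness = 20, depth = 750)),
                            effect_sd = 0.5, gradient_weight = 1,
                            n_latent = 2, lambda_scale = 0.8,
                            prop_loaded = 0.25,
                            prop_photosynthetic = 0.15, seed = 1) {
  metadata <- simulate_environment_spatial(n_samples,
                                           gradient_weight = gradient_weight,
                                           seed = seed)
  g <- as.vector(scale(rowMeans(as.matrix(metadata$covariates))))
  local_seed(seed + 1L)
  # per-sample scores of the planted interaction factors (shared across
  # groups, independent of the environmental gradient)
  zf <- matrix(stats::rnorm(n_samples * max(n_latent, 1)),
               n_samples, max(n_latent, 1))
  tabs <- list()
  loadings <- list()
  for (gi in seq_along(groups)) {
    gname <- names(groups)[gi]
    spec <- groups[[gi]]
    sdlog <- spec$sdlog %||% 1
    conc <- spec$concentration %||% 50
    p <- stats::rlnorm(spec$richness, sdlog = sdlog)
    p <- p / sum(p)
    a <- stats::rnorm(spec$richness, sd = effect_sd)
    lam <- matrix(0, spec$richness, max(n_latent, 1))
    if (n_latent > 0 && lambda_scale > 0 && prop_loaded > 0) {
      loaded <- which(stats::runif(spec$richness) < prop_loaded)
      if (length(loaded)) {
        lam[cbind(loaded, sample.int(n_latent, length(loaded), replace = TRUE))] <-
          sample(c(-1, 1), length(loaded), replace = TRUE) * lambda_scale
      }
    }
    counts <- matrix(0L, n_samples, spec$richness)
    for (i in seq_len(n_samples)) {
      pi_i <- p * exp(a * g[i] + as.vector(lam %*% zf[i, ]))
      pi_i <- pi_i / sum(pi_i)
      pp <- rdirichlet_mat(1, conc * pi_i)[1, ]
      counts[i, ] <- stats::rmultinom(1, spec$depth, pp)[, 1]
    }
    loadings[[gname]] <- lam
    taxa <- paste0(substr(gname, 1, 3), sprintf("%03d", seq_len(spec$richness)))
    dimnames(counts) <- list(metadata$sample_ids, taxa)
    trophic <- sample(c("photosynthetic", "heterotrophic", "unknown"),
                      spec$richness, replace = TRUE,
                      prob = c(prop_photosynthetic,
                               0.9 - prop_photosynthetic, 0.1))
    if (gname == "plant") trophic <- rep("photosynthetic", spec$richness)
    tabs[[gname]] <- community_table(counts,
                                     group = rep(gname, spec$richness),
                                     trophic = trophic)
  }
  lam_all <- do.call(rbind, unname(loadings))
  rownames(lam_all) <- unlist(lapply(tabs, function(t) colnames(t$counts)))
  list(table = bind_communities(tabs), metadata = metadata, gradient = g,
       loadings = lam_all)
}
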