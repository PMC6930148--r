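#' Spherical spatial correlation function
#'
#' `1 - 1.5 (h/phi) + 0.5 (h/phi)^3` for distances `h <= phi`, and exactly 0
#' beyond the range `phi`.
#'
#' @param h distance(s) in metres, `>= 0`.
#' @param phi range parameter in metres, `> 0`.
#' @return correlation value(s) in `[0, 1]`.
#' @export
spherical_correlation <- function(h, phi) {
  if (phi <= 0) stop("phi must be > 0")
  if (any(h < 0)) stop("distances must be >= 0")
  r <- h / phi
  ifelse(h >= phi, 0, 1 - 1.5 * r + 0.5 * r^3)
}

#' Spherical correlation matrix over a distance matrix
#'
#' @param D symmetric distance matrix (metres).
#' @param phi range parameter (metres).
#' @param nugget small diagonal jitter for numerical stability.
#' @return correlation matrix.
#' @export
spherical_corr_matrix <- function(D, phi, nugget = 1e-8) {
  R <- spherical_correlation(D, phi)
  diag(R) <- 1 + nugget
  R
}

#' Number of MCMC draws retained after burn-in and thinning
#'
#' Draws are stored at iterations `t` in `(burn_in, iterations]` with
#' `(t - burn_in)` a multiple of `thin`; the default settings of 40,000
#' iterations, burn-in 10,000 and thin 30 retain exactly 1000 draws.
#'
#' @param iterations,burn_in,thin MCMC settings.
#' @return retained draw count.
#' @export
mcmc_retained <- function(iterations, burn_in, thin) {
  if (burn_in >= iterations) stop("burn_in must be < iterations")
  if (thin < 1) stop("thin must be >= 1")
  floor((iterations - burn_in) / thin)
}

#' Greedy forward selection of environmental covariates
#'
#' Adds, one at a time, the candidate covariate that maximises the mean
#' per-taxon variance explained (ordinary least squares R-squared of the
#' environment-only model) until `k` covariates are selected. Candidates
#' effectively collinear with an already selected covariate are skipped with
#' a warning. The procedure is deterministic.
#'
#' @param Y response matrix (samples x taxa), e.g. clr abundances.
#' @param candidates data.frame or matrix of candidate covariates.
#' @param k number of covariates to select.
#' @return character vector of selected covariate names (length `<= k`).
#' @export
forward_select_env <- function(Y, candidates, k = 4) {
  Y <- as.matrix(Y)
  X <- scale(as.matrix(candidates))
  if (k > ncol(X)) stop("k exceeds the number of candidates")
  if (k == 0) return(character(0))
  tss <- colSums(scale(Y, scale = FALSE)^2)
  ok <- tss > 0
  selected <- character(0)
  mean_r2 <- function(cols) {
    W <- cbind(1, X[, cols, drop = FALSE])
    qr_w <- qr(W)
    fitted <- qr.fitted(qr_w, Y)
    rss <- colSums((Y - fitted)^2)
    mean(1 - rss[ok] / tss[ok])
  }
  warned <- character(0)
  for (step in seq_len(k)) {
    remaining <- setdiff(colnames(X), selected)
    scores <- rep(NA_real_, length(remaining))
    names(scores) <- remaining
    for (cand in remaining) {
      if (length(selected) &&
          any(abs(stats::cor(X[, cand], X[, selected])) > 1 - 1e-10)) {
        if (!cand %in% warned) {
          warning("candidate '", cand, "' collinear with selection; skipped")
          warned <- c(warned, cand)
        }
        next
      }
      scores[cand] <- mean_r2(c(selected, cand))
    }
    if (all(is.na(scores))) break
    selected <- c(selected, names(which.max(scores)))
  }
  selected
}

#' Fit the hierarchical Bayesian latent-variable joint species distribution model
#'
#' Gaussian response on clr abundances:
#' `y_ij = beta0_j + x_i . beta_j + z_i . lambda_j + eps_ij`,
#' `eps_ij ~ N(0, sigma_j^2)`. Latent-score columns carry a spherical
#' spatial correlation structure, `z_k ~ N(0, R(phi))` over the plot
#' distance matrix, accounting for the non-independence of nearby plots
#' (iid scores when no coordinates are supplied). Loadings obey the usual
#' factor-model identifiability constraint: upper-triangular entries of the
#' first `d` rows are fixed at zero and the diagonal is positive, which
#' makes the residual correlations invariant to rotation of the factors.
#'
#' Sampling is by Gibbs updates, conjugate throughout -- normal updates for
#' intercepts/coefficients, loadings and latent scores; inverse-gamma for
#' residual variances -- except the spatial range `phi`, which takes a
#' random-walk Metropolis step under a uniform prior spanning the observed
#' pairwise distances. Priors: `beta0, beta, free lambda ~ N(0, 10^2)`
#' (diagonal loadings truncated positive), `sigma_j^2 ~ InvGamma(0.01,
#' 0.01)`.
#'
#' @param Y response matrix (samples x taxa), typically clr values.
#' @param X covariate matrix/data.frame (z-scored internally), or `NULL`
#'   for a latent-only model.
#' @param coords optional n x 2 coordinate matrix (metres); enables the
#'   spatial correlation structure on the latent scores.
#' @param n_latent number of latent variables `d` (default 3).
#' @param iterations,burn_in,thin MCMC settings (defaults 40000/10000/30,
#'   retaining 1000 draws).
#' @param seed integer seed; the fit is deterministic given the seed.
#' @param prior optional list overriding `beta_var`, `lambda_var`,
#'   `sigma_shape`, `sigma_rate`.
#' @param scale_x z-score covariates before fitting (default `TRUE`).
#' @return object of class `jsdm_posterior`: arrays of retained draws
#'   (`B` `[m, q+1, p]`, `Lambda` `[m, p, d]`, `Z` `[m, n, d]`, `sigma2`
#'   `[m, p]`, `phi` `[m]`), model matrices, dimensions and settings.
#' @export
fit_jsdm <- function(Y, X = NULL, coords = NULL, n_latent = 3,
                     iterations = 40000, burn_in = 10000, thin = 30,
                     seed = 1, prior = list(), scale_x = TRUE) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("Y contains non-finite values")
  n <- nrow(Y); p <- ncol(Y)
  d <- as.integer(n_latent)
  if (d > p) stop("n_latent must not exceed the number of taxa")
  m_keep <- mcmc_retained(iterations, burn_in, thin)
  pr <- utils::modifyList(list(beta_var = 100, lambda_var = 100,
                               sigma_shape = 0.01, sigma_rate = 0.01), prior)
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("X and Y disagree on sample count")
    if (scale_x) X <- scale(X)
  }
  q <- if (is.null(X)) 0L else ncol(X)
  W <- if (q > 0) cbind(`(Intercept)` = 1, X) else
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  qw <- ncol(W)
  WtW <- crossprod(W)
  spatial <- !is.null(coords) && d > 0
  if (spatial) {
    coords <- as.matrix(coords)
    D <- as.matrix(stats::dist(coords))
    dpos <- D[upper.tri(D)]
    phi_lo <- max(min(dpos), 1e-6)
    phi_hi <- max(dpos)
    if (phi_hi <= phi_lo) stop("degenerate coordinate layout for spatial model")
    phi_step <- (phi_hi - phi_lo) / 10
  }

  local_seed(seed)
  # initial state
  B <- rbind(colMeans(Y),
             matrix(0, qw - 1, p))
  sig2 <- pmax(apply(Y, 2, stats::var), 1e-3)
  Lambda <- matrix(0, p, max(d, 1))[, seq_len(d), drop = FALSE]
  if (d > 0) {
    Lambda[] <- stats::rnorm(p * d, sd = 0.1)
    for (j in seq_len(d)) {
      if (j < d) Lambda[j, (j + 1):d] <- 0
      Lambda[j, j] <- abs(Lambda[j, j]) + 0.1
    }
  }
  Z <- matrix(stats::rnorm(n * max(d, 1)), n, max(d, 1))[, seq_len(d), drop = FALSE]
  phi <- if (spatial) (phi_lo + phi_hi) / 2 else NA_real_
  if (spatial) {
    R <- spherical_corr_matrix(D, phi)
    Uchol <- chol(R)
    Rinv <- chol2inv(Uchol)
    logdetR <- 2 * sum(log(diag(Uchol)))
  }
  M <- if (d > 0) Z %*% t(Lambda) else matrix(0, n, p)

  # storage
  B_s <- array(NA_real_, c(m_keep, qw, p),
               dimnames = list(NULL, colnames(W), colnames(Y)))
  L_s <- array(NA_real_, c(m_keep, p, d))
  Z_s <- array(NA_real_, c(m_keep, n, d))
  s_s <- matrix(NA_real_, m_keep, p, dimnames = list(NULL, colnames(Y)))
  phi_s <- rep(NA_real_, m_keep)
  n_acc <- 0L; n_prop <- 0L
  kept <- 0L

  for (t in seq_len(iterations)) {
    ## coefficients (intercept + environment), conjugate normal
    Rb <- Y - M
    WtR <- crossprod(W, Rb)
    if (qw == 1L) {
      prec <- n / sig2 + 1 / pr$beta_var
      mu <- (WtR[1, ] / sig2) / prec
      B[1, ] <- stats::rnorm(p, mu, sqrt(1 / prec))
    } else {
      for (j in seq_len(p)) {
        A <- WtW / sig2[j] + diag(1 / pr$beta_var, qw)
        U <- chol(A)
        mu <- backsolve(U, backsolve(U, WtR[, j] / sig2[j], transpose = TRUE))
        B[, j] <- mu + backsolve(U, stats::rnorm(qw))
      }
    }
    E <- Y - W %*% B

    if (d > 0) {
      ## loadings, column-wise conjugate normal with identifiability constraint
      C <- E - M
      for (k in seq_len(d)) {
        Ck <- C + tcrossprod(Z[, k], Lambda[, k])
        zk <- Z[, k]
        zz <- sum(zk^2)
        prec <- zz / sig2 + 1 / pr$lambda_var
        mu <- (as.vector(crossprod(zk, Ck)) / sig2) / prec
        lam_new <- stats::rnorm(p, mu, sqrt(1 / prec))
        # identifiability: rows j < k among the first d rows are zero,
        # the diagonal entry is truncated positive
        lam_new[k] <- rtnorm_pos(1, mu[k], sqrt(1 / prec[k]))
        if (k >= 2) lam_new[seq_len(k - 1)] <- 0
        C <- Ck - tcrossprod(zk, lam_new)
        Lambda[, k] <- lam_new
      }
      M <- Z %*% t(Lambda)

      ## latent scores, column-wise; prior N(0, R(phi)) or N(0, I)
      C <- E - M
      for (k in seq_len(d)) {
        Ck <- C + tcrossprod(Z[, k], Lambda[, k])
        lam <- Lambda[, k]
        ck <- sum(lam^2 / sig2)
        h <- Ck %*% (lam / sig2)
        if (spatial) {
          P <- Rinv
          diag(P) <- diag(P) + ck
        } else {
          P <- diag(1 + ck, n)
        }
        U <- chol(P)
        mu <- backsolve(U, backsolve(U, h, transpose = TRUE))
        z_new <- as.vector(mu + backsolve(U, stats::rnorm(n)))
        C <- Ck - tcrossprod(z_new, lam)
        Z[, k] <- z_new
      }
      M <- Z %*% t(Lambda)
    }

    ## residual variances, conjugate inverse-gamma
    Ef <- E - M
    SS <- colSums(Ef^2)
    sig2 <- 1 / stats::rgamma(p, shape = pr$sigma_shape + n / 2,
                              rate = pr$sigma_rate + SS / 2)

    ## spatial range, random-walk Metropolis under Uniform(phi_lo, phi_hi)
    if (spatial) {
      n_prop <- n_prop + 1L
      phi_new <- phi + stats::rnorm(1, sd = phi_step)
      if (phi_new > phi_lo && phi_new < phi_hi) {
        R_new <- spherical_corr_matrix(D, phi_new)
        U_new <- tryCatch(chol(R_new), error = function(e) NULL)
        if (!is.null(U_new)) {
          logdet_new <- 2 * sum(log(diag(U_new)))
          Rinv_new <- chol2inv(U_new)
          quad_old <- sum(vapply(seq_len(d), function(k)
            crossprod(Z[, k], Rinv %*% Z[, k])[1, 1], numeric(1)))
          quad_new <- sum(vapply(seq_len(d), function(k)
            crossprod(Z[, k], Rinv_new %*% Z[, k])[1, 1], numeric(1)))
          log_acc <- -0.5 * d * (logdet_new - logdetR) -
            0.5 * (quad_new - quad_old)
          if (log(stats::runif(1)) < log_acc) {
            phi <- phi_new; Rinv <- Rinv_new; logdetR <- logdet_new
            n_acc <- n_acc + 1L
          }
        }
      }
    }

    if (!all(is.finite(sig2)) || !all(is.finite(B)) ||
        (d > 0 && !(all(is.finite(Lambda)) && all(is.finite(Z))))) {
      stop("sampler divergence at iteration ", t)
    }

    if (t > burn_in && (t - burn_in) %% thin == 0) {
      kept <- kept + 1L
      B_s[kept, , ] <- B
      if (d > 0) {
        L_s[kept, , ] <- Lambda
        Z_s[kept, , ] <- Z
      }
      s_s[kept, ] <- sig2
      phi_s[kept] <- phi
    }
  }

  structure(list(B = B_s, Lambda = L_s, Z = Z_s, sigma2 = s_s, phi = phi_s,
                 n = n, p = p, q = q, d = d, m = kept,
                 Y = Y, W = W, coords = if (spatial) coords else NULL,
                 taxon_ids = colnames(Y),
                 accept_phi = if (spatial) n_acc / n_prop else NA_real_,
                 settings = list(iterations = iterations, burn_in = burn_in,
                                 thin = thin, seed = seed, prior = pr)),
            class = "jsdm_posterior")
}

#' @export
print.jsdm_posterior <- function(x, ...) {
  cat(sprintf(paste0("jsdm_posterior: n=%d samples, p=%d taxa, q=%d covariates, ",
                     "d=%d latent variables; %d retained draws\n"),
              x$n, x$p, x$q, x$d, x$m))
  if (!is.na(x$accept_phi)) {
    cat(sprintf("  spatial range phi: posterior median %.1f m (MH acceptance %.2f)\n",
                stats::median(x$phi), x$accept_phi))
  }
  invisible(x)
}

#' Residual correlation matrix implied by one draw of loadings and variances
#'
#' `rho_jk = lambda_j . lambda_k / sqrt((|lambda_j|^2 + sigma_j^2)
#' (|lambda_k|^2 + sigma_k^2))`; symmetric, unit diagonal, positive
#' semidefinite.
#'
#' @param lambda p x d loading matrix.
#' @param sigma2 length-p residual variances.
#' @return p x p correlation matrix.
#' @export
residual_correlation_matrix <- function(lambda, sigma2) {
  lambda <- as.matrix(lambda)
  S <- tcrossprod(lambda) + diag(sigma2, nrow(lambda))
  stats::cov2cor(S)
}

#' Posterior residual species-to-species correlations
#'
#' For every retained draw, computes the residual correlation matrix implied
#' by the loadings and residual variances, then summarises each taxon pair
#' by the pointwise posterior median and an equal-tailed credible interval.
#' These are the correlations remaining after the environmental covariates'
#' effects are removed -- the quantity interpreted as putative interaction.
#'
#' @param post a `jsdm_posterior` with `d >= 1`.
#' @param level credible level (default 0.95).
#' @return list with `summary` (data.frame: `taxon_a`, `taxon_b`, `median`,
#'   `lower`, `upper`), `rho_draws` (draws x pairs matrix), `pairs` (index
#'   matrix) and `level`.
#' @export
residual_correlation_draws <- function(post, level = 0.95) {
  stopifnot(inherits(post, "jsdm_posterior"))
  if (post$d == 0) stop("no latent structure to correlate (d = 0)")
  p <- post$p; m <- post$m
  ut <- which(upper.tri(diag(p)), arr.ind = TRUE)
  rho_draws <- matrix(NA_real_, m, nrow(ut))
  for (s in seq_len(m)) {
    rho <- residual_correlation_matrix(post$Lambda[s, , , drop = TRUE],
                                       post$sigma2[s, ])
    rho_draws[s, ] <- rho[ut]
  }
  alpha <- (1 - level) / 2
  qs <- apply(rho_draws, 2, stats::quantile, probs = c(alpha, 0.5, 1 - alpha))
  taxa <- post$taxon_ids %||% paste0("t", seq_len(p))
  summary <- data.frame(taxon_a = taxa[ut[, 1]],
                        taxon_b = taxa[ut[, 2]],
                        median = qs[2, ], lower = qs[1, ], upper = qs[3, ])
  list(summary = summary, rho_draws = rho_draws, pairs = ut, level = level)
}

#' Call network edges from residual-correlation credible intervals
#'
#' A taxon pair becomes an edge when its credible interval excludes zero:
#' positive when the lower bound is above zero, negative when the upper
#' bound is below zero. The edge weight is the posterior median and the
#' sign is the median's sign.
#'
#' @param summary the `summary` data.frame from
#'   [residual_correlation_draws()] (or the full list).
#' @return data.frame of edges: `taxon_a`, `taxon_b`, `median`, `lower`,
#'   `upper`, `sign` (`"positive"`/`"negative"`).
#' @export
significant_edges <- function(summary) {
  if (is.list(summary) && !is.data.frame(summary) && !is.null(summary$summary)) {
    summary <- summary$summary
  }
  keep <- summary$lower > 0 | summary$upper < 0
  ed <- summary[keep, , drop = FALSE]
  ed$sign <- ifelse(ed$median > 0, "positive", "negative")
  rownames(ed) <- NULL
  ed
}

#' Variance in clr abundance explained by the environment
#'
#' For an environment-only fit (`d = 0`), the per-taxon variance explained
#' is `R2_j = 1 - E[residual SS_j] / total SS_j`, with the expectation taken
#' over the posterior draws. Taxa with zero variance are excluded with a
#' warning.
#'
#' @param post a `jsdm_posterior` fitted with `n_latent = 0`.
#' @return list with `per_taxon` (named vector) and `mean`.
#' @export
env_variance_explained <- function(post) {
  stopifnot(inherits(post, "jsdm_posterior"))
  if (post$d != 0) stop("environment-only fit (d = 0) required")
  Y <- post$Y; W <- post$W
  tss <- colSums(scale(Y, scale = FALSE)^2)
  ok <- tss > 0
  if (!all(ok)) warning("zero-variance taxa excluded: ",
                        paste(colnames(Y)[!ok], collapse = ", "))
  rss <- matrix(NA_real_, post$m, post$p)
  for (s in seq_len(post$m)) {
    fitted <- W %*% post$B[s, , ]
    rss[s, ] <- colSums((Y - fitted)^2)
  }
  r2 <- 1 - colMeans(rss) / tss
  r2[!ok] <- NA_real_
  names(r2) <- colnames(Y)
  list(per_taxon = r2, mean = mean(r2[ok]))
}

#' Geweke convergence diagnostic for one MCMC chain
#'
#' Z-score comparing the mean of the first 10% of the chain with the mean of
#' the last 50%, each standardised by its spectral-density-at-zero variance
#' estimate (via `coda::spectrum0.ar`). `|z|` well above 2 indicates the
#' chain had not reached its stationary distribution.
#'
#' @param chain numeric vector of at least 50 draws.
#' @param frac1,frac2 window fractions (defaults 0.1 and 0.5).
#' @return z score (NA with a warning for a constant chain).
#' @export
geweke_diagnostic <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 50) stop("need at least 50 draws")
  if (stats::var(chain) == 0) {
    warning("constant chain; Geweke z undefined")
    return(NA_real_)
  }
  n1 <- max(2, floor(frac1 * n))
  n2 <- max(2, floor(frac2 * n))
  w1 <- chain[seq_len(n1)]
  w2 <- chain[(n - n2 + 1):n]
  s1 <- coda::spectrum0.ar(w1)$spec
  s2 <- coda::spectrum0.ar(w2)$spec
  if (!is.finite(s1) || !is.finite(s2) || s1 + s2 == 0) {
    warning("degenerate window variance; Geweke z undefined")
    return(NA_real_)
  }
  (mean(w1) - mean(w2)) / sqrt(s1 / n1 + s2 / n2)
}

#' Standardised (Dunn-Smyth) residuals and normal-quantile summary
#'
#' For the Gaussian response, randomized quantile residuals reduce to
#' `(y_ij - mu_hat_ij) / sigma_hat_j` with `mu_hat` the posterior-mean
#' fitted values (environmental plus latent part) and `sigma_hat_j` the
#' posterior-mean residual SD. Under a well-specified model they are
#' standard normal; the QQ summary reports the slope and intercept of the
#' least-squares line through the normal quantile plot.
#'
#' @param post a `jsdm_posterior`.
#' @return list with `residuals` (n x p matrix), `qq_slope`, `qq_intercept`.
#' @export
quantile_residuals <- function(post) {
  stopifnot(inherits(post, "jsdm_posterior"))
  B_bar <- apply(post$B, c(2, 3), mean)
  mu <- post$W %*% B_bar
  if (post$d > 0) {
    L_bar <- apply(post$Lambda, c(2, 3), mean)
    Z_bar <- apply(post$Z, c(2, 3), mean)
    mu <- mu + Z_bar %*% t(L_bar)
  }
  sig <- sqrt(colMeans(post$sigma2))
  res <- sweep(post$Y - mu, 2, sig, `/`)
  r <- sort(as.vector(res))
  th <- stats::qnorm(stats::ppoints(length(r)))
  fit <- stats::lm.fit(cbind(1, th), r)
  list(residuals = res,
       qq_slope = unname(fit$coefficients[2]),
       qq_intercept = unname(fit$coefficients[1]))
}
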