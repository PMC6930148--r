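#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; reported network statistics use
#' conventional half-up rounding so printed values match field usage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Sample from a normal distribution truncated to the positive half-line
#'
#' Inverse-CDF sampling when the positive tail has non-negligible mass, and
#' Robert's shifted-exponential rejection sampler when the mean is far below
#' zero (where the inverse CDF loses precision).
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (vectorised).
#' @return positive draws.
#' @keywords internal
rtnorm_pos <- function(n, mean = 0, sd = 1) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  alpha <- -mean / sd  # lower bound in standard units
  out <- numeric(n)
  easy <- alpha < 6
  if (any(easy)) {
    lo <- stats::pnorm(alpha[easy])
    u <- lo + stats::runif(sum(easy)) * (1 - lo)
    out[easy] <- mean[easy] + sd[easy] * stats::qnorm(pmin(u, 1 - 1e-16))
  }
  for (i in which(!easy)) {
    a <- alpha[i]
    lam <- (a + sqrt(a^2 + 4)) / 2
    repeat {
      x <- a + stats::rexp(1, rate = lam)
      if (stats::runif(1) <= exp(-(x - lam)^2 / 2)) break
    }
    out[i] <- mean[i] + sd[i] * x
  }
  out
}

# Stage-granularity logging; suppressed with options(jsdmnet.quiet = TRUE).
log_stage <- function(...) {
  if (!isTRUE(getOption("jsdmnet.quiet", FALSE))) {
    message("[jsdmnet] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed-taking functions use their own RNG stream and must not disturb the
# caller's: capture the global state, set the local seed, restore on exit.
local_seed <- function(seed, envir = parent.frame()) {
  prev <- get0(".Random.seed", globalenv(), inherits = FALSE)
  do.call(on.exit, list(quote({
    if (is.null(.jsdmnet_prev_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", .jsdmnet_prev_seed, globalenv())
    }
  }), add = TRUE), envir = envir)
  assign(".jsdmnet_prev_seed", prev, envir = envir)
  set.seed(seed)
  invisible(seed)
}
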