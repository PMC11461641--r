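## Truncated-normal draws with moment matching.
##
## Cohort quantities are reported in the literature as mean +- SD of data that
## are physically bounded (percents in [0,100], concentrations >= 0).  Naively
## truncating N(mean, sd) shifts the realised mean whenever a bound is within a
## few SD of it, so the generator solves for latent normal parameters whose
## *truncated* law has exactly the requested moments.

tnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  if (Z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  pa <- dnorm(a); pb <- dnorm(b)
  m <- mu + sigma * (pa - pb) / Z
  t1 <- ifelse(is.finite(a), a * pa, 0)
  t2 <- ifelse(is.finite(b), b * pb, 0)
  v <- sigma^2 * (1 + (t1 - t2) / Z - ((pa - pb) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Latent parameters of a moment-matched truncated normal
#'
#' Finds `(mu, sigma)` such that N(mu, sigma) truncated to `[lower, upper]`
#' has the requested mean and standard deviation. When both bounds are more
#' than 6 SD away the identity is returned.
#'
#' @param mean,sd target moments of the truncated distribution.
#' @param lower,upper truncation bounds.
#' @return list with elements `mu`, `sigma`, `lower`, `upper`.
#' @keywords internal
tnorm_match <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(list(mu = mean, sigma = 0, lower = lower, upper = upper))
  if (mean < lower || mean > upper) {
    stop_input(sprintf("target mean %s outside truncation bounds [%s, %s]",
                       format(mean), format(lower), format(upper)))
  }
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  if ((!is.finite(a) || a < -6) && (!is.finite(b) || b > 6)) {
    return(list(mu = mean, sigma = sd, lower = lower, upper = upper))
  }
  obj <- function(p) {
    mo <- tnorm_moments(p[1], exp(p[2]), lower, upper)
    if (anyNA(mo)) return(1e10)
    (mo[["mean"]] - mean)^2 + (mo[["sd"]] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
  if (fit$value > 1e-6) {
    stop_input(sprintf(
      "cannot realise mean %s, sd %s on [%s, %s]: truncation bounds too tight",
      format(mean), format(sd), format(lower), format(upper)))
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]), lower = lower, upper = upper)
}

#' Truncated-normal random deviates
#'
#' Inverse-CDF sampler for the normal distribution truncated to
#' `[lower, upper]`. With `moment_match = TRUE` (the generator default),
#' `mean` and `sd` are the moments of the truncated law itself rather than of
#' the latent normal; `sd = 0` yields a point mass at `mean` (clamped to the
#' bounds).
#'
#' @param n number of draws.
#' @param mean,sd moments (see `moment_match`).
#' @param lower,upper truncation bounds.
#' @param moment_match logical; solve for latent parameters so the truncated
#'   distribution has exactly `mean` and `sd`.
#' @return numeric vector of length `n` within `[lower, upper]`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rtnorm(1e4, mean = 56, sd = 23.1, lower = 0, upper = 100)
#' c(mean(x), sd(x))
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf, moment_match = TRUE) {
  check_number(mean, "mean"); check_number(sd, "sd", lower = 0)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  par <- if (moment_match) tnorm_match(mean, sd, lower, upper)
         else list(mu = mean, sigma = sd, lower = lower, upper = upper)
  pa <- pnorm((lower - par$mu) / par$sigma)
  pb <- pnorm((upper - par$mu) / par$sigma)
  u <- runif(n, pa, pb)
  x <- par$mu + par$sigma * qnorm(u)
  pmin(pmax(x, lower), upper)
}
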