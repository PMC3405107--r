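#' Draw from a truncated normal distribution
#'
#' Samples from the normal(mean, sd^2) distribution restricted to the
#' interval (lower, upper); either bound may be infinite.  This is the data
#' augmentation primitive for censored years-of-life records: a
#' right-censored record contributes a draw truncated below at the age at
#' censoring, a left-censored record a draw truncated above, and an
#' interval record a doubly truncated draw.
#'
#' Sampling uses CDF inversion after reflecting the interval into the lower
#' tail, where `pnorm`/`qnorm` retain full relative accuracy, so draws are
#' stable for bounds many (>30) standard deviations into the tail.  In the
#' extreme regime where the interval's normal mass underflows entirely, a
#' shifted-exponential rejection sampler (Robert's method) takes over.
#'
#' @param n number of draws.
#' @param mean,sd mean and standard deviation of the untruncated normal
#'   (recycled to length `n`); `sd` must be positive.
#' @param lower,upper truncation bounds (recycled); `lower < upper`.
#' @return numeric vector of `n` draws, each within its bounds.
#' @examples
#' set.seed(1)
#' mean(rtruncnorm(1e4, 0, 1, lower = 0))  # ~ sqrt(2/pi) = 0.798
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(sd <= 0)) stop_config("rtruncnorm: sd must be positive")
  if (any(lower >= upper)) stop_config("rtruncnorm: lower must be < upper")
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  # reflect intervals sitting in the upper tail into the lower tail
  mid <- ifelse(is.finite(a), a, 0) + ifelse(is.finite(b), b, 0)
  flip <- mid > 0
  a2 <- ifelse(flip, -b, a)
  b2 <- ifelse(flip, -a, b)
  pa <- pnorm(a2)
  pb <- pnorm(b2)
  z <- numeric(n)
  ok <- (pb - pa) > 0
  if (any(ok)) {
    u <- pa[ok] + (pb[ok] - pa[ok]) * runif(sum(ok))
    u <- pmax(u, .Machine$double.xmin)
    z[ok] <- qnorm(u)
  }
  if (any(!ok)) {
    # whole interval beyond ~38 sd: interval (a2, b2) lies in the deep
    # lower tail, i.e. -b2 is a large positive truncation point.
    idx <- which(!ok)
    for (i in idx) {
      lo <- -b2[i]           # sample Z >= lo, return -Z
      hi <- -a2[i]
      repeat {
        zz <- lo + rexp(1, rate = lo)
        if (zz <= hi && runif(1) <= exp(-0.5 * (zz - lo)^2)) break
      }
      z[i] <- -zz
    }
  }
  z <- ifelse(flip, -z, z)
  out <- mean + sd * z
  pmin(pmax(out, lower), upper)
}

#' Draw from the inverse-Gaussian distribution
#'
#' Transformation-rejection sampler of Michael, Schucany and Haas for the
#' inverse-Gaussian (Wald) distribution with mean `mean` and shape
#' `shape` (density proportional to x^-3/2 exp(-shape (x - mean)^2 /
#' (2 mean^2 x))).  Used for the Bayesian LASSO full conditional of the
#' reciprocal marker-variance 1/tau^2_j.
#'
#' @param n number of draws.
#' @param mean,shape positive parameters (recycled to length `n`).
#' @return numeric vector of positive draws.
#' @export
rinvgauss <- function(n, mean, shape) {
  mean <- rep_len(mean, n); shape <- rep_len(shape, n)
  if (any(mean <= 0) || any(shape <= 0))
    stop_config("rinvgauss: mean and shape must be positive")
  y <- rnorm(n)^2
  w <- mean * y / (2 * shape)
  # smaller root of the quadratic, written to avoid cancellation
  x1 <- mean / ((1 + w) + sqrt((1 + w)^2 - 1))
  u <- runif(n)
  ifelse(u <= mean / (mean + x1), x1, mean^2 / x1)
}
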