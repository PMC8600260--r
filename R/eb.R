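## Empirical-Bayes moment matching on the log scale for scaled-F-distributed
## variance-like quantities (QL dispersions s^2 and the NB dispersion ratio
## against its abundance trend). If x_g ~ s0 * F(df1, df0), then
## log x_g has mean log s0 + digamma(df1/2) - log(df1/2) - digamma(df0/2)
## + log(df0/2) and variance trigamma(df1/2) + trigamma(df0/2); matching the
## observed mean and variance of log x_g yields the prior (s0, df0).

# Solve trigamma(x) = y for x > 0 (vectorized, Newton with monotone map).
trigamma_inverse <- function(y) {
  out <- y
  large <- is.finite(y) & y > 1e7
  small <- is.finite(y) & y < 1e-6 & y > 0
  out[large] <- 1 / sqrt(y[large])
  out[small] <- 1 / y[small]
  mid <- is.finite(y) & !large & !small & y > 0
  if (any(mid)) {
    x <- 0.5 + 1 / y[mid]
    for (i in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(abs(dif) / x) < 1e-10) break
    }
    out[mid] <- x
  }
  out[!is.finite(y) | y <= 0] <- NA_real_
  out
}

# Moment-match a scaled F prior to observed x_g with known df1.
# Returns list(scale = s0, df2 = prior df, possibly Inf).
fit_f_dist <- function(x, df1) {
  x <- x[is.finite(x)]
  x <- pmax(x, 1e-12)
  if (length(x) < 2) return(list(scale = mean(x), df2 = Inf))
  z <- log(x)
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df1 / 2)
  if (is.finite(evar) && evar > 0) {
    df2 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(df2 / 2) - log(df2 / 2))
  } else {
    df2 <- Inf
    s0 <- exp(emean)
  }
  list(scale = s0, df2 = df2)
}

# Squeeze observed variance-like values toward the moment-matched prior.
# Returns list(value = posterior values, prior_df, prior_scale).
squeeze_var <- function(x, df1) {
  fit <- fit_f_dist(x, df1)
  if (is.finite(fit$df2)) {
    post <- (df1 * x + fit$df2 * fit$scale) / (df1 + fit$df2)
  } else {
    post <- rep(fit$scale, length(x))
  }
  list(value = post, prior_df = fit$df2, prior_scale = fit$scale)
}
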