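# Independent oracles used across the suite. These re-derive expected
# values from first principles (sort-based quantiles, explicit Welch
# formulas, closed-form moments) so they never share code with the
# implementation they check.

# Linear-interpolation quantile from the sorted sample (the classic
# h = (n-1)p + 1 rule), written without stats::quantile.
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Welch statistic, Welch-Satterthwaite df and two-sided p from the
# textbook formulas.
welch_oracle <- function(a, b) {
  ma <- sum(a) / length(a)
  mb <- sum(b) / length(b)
  va <- sum((a - ma)^2) / (length(a) - 1)
  vb <- sum((b - mb)^2) / (length(b) - 1)
  sa2 <- va / length(a)
  sb2 <- vb / length(b)
  t <- (ma - mb) / sqrt(sa2 + sb2)
  df <- (sa2 + sb2)^2 / (sa2^2 / (length(a) - 1) + sb2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Closed-form ensemble moments of the Poisson bond model.
bond_model_moments <- function(f_i, f_0, lambda, noise_sd = 0) {
  list(mean = f_0 + lambda * f_i,
       var = lambda * f_i^2 + noise_sd^2)
}

# Standard errors of a sample mean and sample variance (the latter via the
# fourth central moment), for z-style closeness checks on simulations.
mean_se <- function(x) stats::sd(x) / sqrt(length(x))
var_se <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m4 <- mean((x - m)^4)
  sqrt((m4 - m2^2) / n)
}
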