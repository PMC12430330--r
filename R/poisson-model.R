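#' Group adhesion forces into ensembles for Poisson step analysis
#'
#' The variance-mean regression needs per-group (mean, variance) pairs.
#' Curves are partitioned into disjoint groups of `group_size`; leftover
#' curves that do not fill a final group are dropped (and reported in the
#' `dropped` attribute). Grouping schemes: `"sequential"` keeps acquisition
#' order; `"random"` permutes the curves first (seeded); `"spatial"` orders
#' the curves by a caller-supplied index (`order_by`, e.g. a scan-position
#' rank) before sequential grouping.
#'
#' @param adhesions Numeric adhesion forces (pN); `NA`s (no-event curves)
#'   are removed first.
#' @param group_size Curves per group (>= 5); default 30.
#' @param scheme One of `"sequential"`, `"random"`, `"spatial"`.
#' @param seed Seed for the `"random"` scheme.
#' @param order_by Numeric ordering index for the `"spatial"` scheme; same
#'   length as `adhesions`.
#'
#' @return Data frame of class `adhesion_groups` with columns `group_id`,
#'   `mu_m` (group mean, pN), `sigma2_m` (unbiased group variance, pN^2)
#'   and `n`; attribute `dropped` gives the number of leftover curves.
#' @export
group_curves <- function(adhesions, group_size = 30L,
                         scheme = c("sequential", "random", "spatial"),
                         seed = 1L, order_by = NULL) {
  scheme <- match.arg(scheme)
  keep <- is.finite(adhesions)
  if (scheme == "spatial") {
    if (is.null(order_by) || length(order_by) != length(adhesions)) {
      stop("'spatial' scheme needs 'order_by' of the same length as 'adhesions'",
           call. = FALSE)
    }
    order_by <- order_by[keep]
  }
  adhesions <- adhesions[keep]
  if (group_size < 5L) stop("'group_size' must be >= 5", call. = FALSE)
  if (length(adhesions) < 2L * group_size) {
    stop("need at least 2 * group_size usable curves (have ",
         length(adhesions), ")", call. = FALSE)
  }
  idx <- switch(scheme,
    sequential = seq_along(adhesions),
    random = with_seed(seed, sample.int(length(adhesions))),
    spatial = order(order_by)
  )
  adhesions <- adhesions[idx]
  n_groups <- length(adhesions) %/% group_size
  dropped <- length(adhesions) - n_groups * group_size
  g <- rep(seq_len(n_groups), each = group_size)
  used <- adhesions[seq_len(n_groups * group_size)]
  out <- data.frame(
    group_id = seq_len(n_groups),
    mu_m = as.numeric(tapply(used, g, mean)),
    sigma2_m = as.numeric(tapply(used, g, stats::var)),
    n = as.integer(group_size)
  )
  class(out) <- c("adhesion_groups", "data.frame")
  attr(out, "dropped") <- dropped
  if (dropped > 0L) {
    message(dropped, " leftover curve(s) dropped from incomplete final group")
  }
  out
}

#' Poisson step analysis: decompose adhesion into specific and non-specific
#' force
#'
#' If each contact ruptures a Poisson-distributed number of discrete bonds
#' of fixed force `F_i` on top of a non-specific offset `F_0`, the variance
#' of an ensemble's adhesion force is linear in its mean:
#' `sigma2_m = mu_m * F_i - F_i * F_0`. Ordinary least squares of the group
#' variances on the group means therefore yields `F_i` as the slope and
#' `F_0 = -intercept / slope`. The standard error of `F_0` is propagated
#' from the (slope, intercept) covariance by the delta method. A weighted
#' variant (weights = group sizes) is available behind `weighted = TRUE`.
#'
#' Measurement-noise variance is not subtracted from the group variances;
#' with additive noise of SD `s` the intercept is shifted by `+s^2`, biasing
#' the recovered `F_0` low by `s^2 / F_i`. This follows the conventional
#' practice of fitting the raw variances and is documented as a known bias
#' source.
#'
#' @param groups An `adhesion_groups` data frame (or any data frame with
#'   columns `mu_m`, `sigma2_m`, and optionally `n`).
#' @param weighted Use per-group weights `n`; default `FALSE` (plain OLS).
#'
#' @return An object of class `poisson_decomposition`: `f_i` (slope, pN),
#'   `f_0` (-intercept/slope, pN), `f_i_se`, `f_0_se`, `intercept` (pN^2),
#'   `intercept_se`, `r_squared`, `n_groups`, `valid` (TRUE when `f_i > 0`
#'   and the intercept is negative so `f_0 > 0`). A negative slope is
#'   returned as-is with `valid = FALSE`, never silently sign-flipped.
#' @examples
#' g <- data.frame(mu_m = c(120, 150, 180), sigma2_m = c(900, 1800, 2700))
#' fit_poisson_decomposition(g)  # F_i = 30, F_0 = 90, R^2 = 1
#' @export
fit_poisson_decomposition <- function(groups, weighted = FALSE) {
  if (!is.data.frame(groups) ||
      !all(c("mu_m", "sigma2_m") %in% names(groups))) {
    stop("'groups' must be a data frame with columns mu_m and sigma2_m",
         call. = FALSE)
  }
  ok <- is.finite(groups$mu_m) & is.finite(groups$sigma2_m)
  groups <- groups[ok, , drop = FALSE]
  if (length(unique(groups$mu_m)) < 3L) {
    stop("need at least 3 groups with distinct mean adhesion", call. = FALSE)
  }
  w <- if (weighted) {
    if (is.null(groups$n)) stop("weighted fit needs a group-size column 'n'",
                                call. = FALSE)
    groups$n
  } else {
    NULL
  }
  fit <- stats::lm(sigma2_m ~ mu_m, data = groups, weights = w)
  # exactly collinear input is legitimate here; summary()'s perfect-fit
  # warning is not informative for it
  smry <- suppressWarnings(summary(fit))
  co <- smry$coefficients
  b0 <- co["(Intercept)", "Estimate"]
  b1 <- co["mu_m", "Estimate"]
  V <- suppressWarnings(stats::vcov(fit))
  f_0 <- -b0 / b1
  # delta method: grad of -b0/b1 wrt (b0, b1) is (-1/b1, b0/b1^2)
  grad <- c(-1 / b1, b0 / b1^2)
  f_0_var <- drop(t(grad) %*% V %*% grad)
  structure(
    list(f_i = b1,
         f_0 = f_0,
         f_i_se = co["mu_m", "Std. Error"],
         f_0_se = sqrt(max(f_0_var, 0)),
         intercept = b0,
         intercept_se = co["(Intercept)", "Std. Error"],
         r_squared = smry$r.squared,
         n_groups = nrow(groups),
         valid = b1 > 0 && b0 < 0),
    class = "poisson_decomposition"
  )
}

#' @export
print.poisson_decomposition <- function(x, ...) {
  cat("Poisson step analysis (variance-mean regression)\n")
  cat(sprintf("  F_i = %.2f +/- %.2f pN (slope)\n", x$f_i, x$f_i_se))
  cat(sprintf("  F_0 = %.2f +/- %.2f pN (-intercept/slope)\n",
              x$f_0, x$f_0_se))
  cat(sprintf("  R^2 = %.4f over %d groups%s\n", x$r_squared, x$n_groups,
              if (x$valid) "" else "  [INVALID: sign constraint violated]"))
  invisible(x)
}
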