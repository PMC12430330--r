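#' Fit a Gaussian peak to a force histogram
#'
#' Bins the forces, then fits `A * exp(-(x - mu)^2 / (2 sigma^2))` to the
#' bin counts by nonlinear least squares (Levenberg-Marquardt). The fitted
#' centre `mu` is the most likely force of the ensemble, the standard way to
#' summarize unbinding-force distributions robustly against outlier events.
#' Initialisation: `mu0` at the modal bin centre, `sigma0` at the sample SD,
#' `A0` at the maximum count; `sigma` is bounded away from zero.
#'
#' @param values Numeric forces (pN); at least 30.
#' @param bin_width Histogram bin width (pN). Default: Freedman-Diaconis.
#'
#' @return An object of class `gaussian_peak_fit`: list with `peak`, `sd`,
#'   `amplitude`, `peak_se`, `converged`, `bin_width`, `n`. On degenerate
#'   input (e.g. all values equal) `converged` is `FALSE` and the estimates
#'   are `NA`; the fit never errors out on such input.
#' @examples
#' x <- rnorm(5000, 347, 25)
#' fit_gaussian_peak(x)$peak
#' @export
fit_gaussian_peak <- function(values, bin_width = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 30L) {
    stop("Gaussian peak fit needs at least 30 finite values", call. = FALSE)
  }
  failed <- function(bw) {
    structure(
      list(peak = NA_real_, sd = NA_real_, amplitude = NA_real_,
           peak_se = NA_real_, converged = FALSE, bin_width = bw,
           n = length(values)),
      class = "gaussian_peak_fit"
    )
  }
  if (is.null(bin_width)) {
    iqr <- stats::IQR(values)
    bin_width <- 2 * iqr / length(values)^(1 / 3)
    if (!is.finite(bin_width) || bin_width <= 0) return(failed(NA_real_))
  }
  check_scalar(bin_width, "bin_width", positive = TRUE)
  # breaks anchored at the data minimum so the fit is translation-equivariant
  rng <- range(values)
  breaks <- seq(rng[1L] - bin_width / 2,
                rng[2L] + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids
  y <- h$counts
  if (sum(y > 0) < 3L) return(failed(bin_width))
  start <- list(A = max(y), mu = x[which.max(y)], sigma = stats::sd(values))
  if (!is.finite(start$sigma) || start$sigma <= 0) {
    start$sigma <- bin_width
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * sigma^2)),
      data = data.frame(x = x, y = y),
      start = start,
      lower = c(A = 0, mu = -Inf, sigma = bin_width * 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit)) return(failed(bin_width))
  co <- summary(fit)$coefficients
  peak <- co["mu", "Estimate"]
  if (!is.finite(peak) || peak < rng[1L] - bin_width ||
      peak > rng[2L] + bin_width) {
    return(failed(bin_width))
  }
  structure(
    list(peak = peak,
         sd = abs(co["sigma", "Estimate"]),
         amplitude = co["A", "Estimate"],
         peak_se = co["mu", "Std. Error"],
         converged = TRUE,
         bin_width = bin_width,
         n = length(values)),
    class = "gaussian_peak_fit"
  )
}

#' @export
print.gaussian_peak_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Gaussian peak: %.2f +/- %.2f (fit SE), width %.2f, n = %d\n",
                x$peak, x$peak_se, x$sd, x$n))
  } else {
    cat("Gaussian peak fit did not converge\n")
  }
  invisible(x)
}

#' Box-plot statistics of a force ensemble
#'
#' Quartiles by linear interpolation (R's default type-7 convention),
#' whiskers at the Tukey 1.5 x IQR rule (most extreme data points inside
#' the fences), and an outlier count beyond the fences.
#'
#' @param values Numeric vector; at least 5 finite values.
#'
#' @return An object of class `box_stats`: `median`, `q1`, `q3`, `iqr`,
#'   `whisker_low`, `whisker_high`, `n`, `outlier_count`.
#' @export
box_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 5L) {
    stop("box_stats needs at least 5 finite values", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3L] - q[1L]
  lo_fence <- q[1L] - 1.5 * iqr
  hi_fence <- q[3L] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(
    list(median = q[2L], q1 = q[1L], q3 = q[3L], iqr = iqr,
         whisker_low = min(values[inside]),
         whisker_high = max(values[inside]),
         n = length(values),
         outlier_count = sum(!inside)),
    class = "box_stats"
  )
}

#' Percent reduction between two levels
#'
#' `100 * (initial - final) / initial`, rounded half-away-from-zero to the
#' nearest integer by default -- the convention under which printed force
#' pairs like 202 -> 126 pN read as a 38\% reduction.
#'
#' @param initial Baseline value; must be > 0.
#' @param final Value after treatment.
#' @param rounding `"integer"` (default) or `"none"`.
#'
#' @return Percent reduction (positive when `final < initial`).
#' @examples
#' percent_reduction(372, 228)  # 39
#' percent_reduction(202, 126)  # 38
#' @export
percent_reduction <- function(initial, final, rounding = c("integer", "none")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(initial) || !is.numeric(final)) {
    stop("'initial' and 'final' must be numeric", call. = FALSE)
  }
  if (any(!is.finite(initial)) || any(initial <= 0)) {
    stop("'initial' must be finite and > 0", call. = FALSE)
  }
  pct <- 100 * (initial - final) / initial
  if (rounding == "integer") round_half_away(pct) else pct
}

#' Significance star annotation for a p-value
#'
#' Maps a p-value to the star annotation used in force-spectroscopy figure
#' panels. The `"methods"` table uses thresholds 0.05 / 0.01 / 0.001 /
#' 0.0001; the `"captions"` table replaces the `**` threshold with 0.005,
#' as some figure captions do.
#'
#' @param p P-value in `[0, 1]`.
#' @param star_table `"methods"` (default) or `"captions"`.
#'
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significance_stars <- function(p, star_table = c("methods", "captions")) {
  star_table <- match.arg(star_table)
  if (!is.numeric(p) || any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("'p' must be in [0, 1]", call. = FALSE)
  }
  thr <- if (star_table == "methods") {
    c(0.0001, 0.001, 0.01, 0.05)
  } else {
    c(0.0001, 0.001, 0.005, 0.05)
  }
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < thr[1L]) "****"
    else if (pi < thr[2L]) "***"
    else if (pi < thr[3L]) "**"
    else if (pi < thr[4L]) "*"
    else "ns"
  }, character(1L))
}

#' Welch's unpaired two-sample t-test with star annotation
#'
#' Unequal-variance (Welch) t-test, two-sided, with the
#' Welch-Satterthwaite degrees of freedom, plus the star annotation of
#' [significance_stars()]. When both groups have zero variance and equal
#' means the statistic is undefined; by convention `t = 0`, `p = 1`,
#' flagged `degenerate`.
#'
#' @param group_a,group_b Numeric vectors, each with at least 2 values.
#' @param star_table Passed to [significance_stars()].
#'
#' @return An object of class `significance_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `stars`, `degenerate`.
#' @export
welch_t_test <- function(group_a, group_b,
                         star_table = c("methods", "captions")) {
  star_table <- match.arg(star_table)
  group_a <- group_a[is.finite(group_a)]
  group_b <- group_b[is.finite(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 finite values", call. = FALSE)
  }
  degenerate <- stats::var(group_a) == 0 && stats::var(group_b) == 0
  if (degenerate) {
    if (mean(group_a) != mean(group_b)) {
      stop("zero-variance groups with different means: p-value undefined",
           call. = FALSE)
    }
    res <- list(t = 0, df = length(group_a) + length(group_b) - 2L, p = 1)
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  structure(
    list(t_statistic = res$t,
         degrees_of_freedom = res$df,
         p_value = res$p,
         stars = significance_stars(res$p, star_table),
         degenerate = degenerate),
    class = "significance_result"
  )
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.1f, p = %.3g [%s]\n",
              x$t_statistic, x$degrees_of_freedom, x$p_value, x$stars))
  invisible(x)
}
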