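# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without touching the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Validate one scalar numeric field; `what` names the field in the error.
check_scalar <- function(x, what, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop("'", what, "' must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("'", what, "' must be > 0", call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop("'", what, "' must be >= 0", call. = FALSE)
  }
  invisible(x)
}

# nN -> pN conversion factor for k[N/m] * d[nm] products.
NN_PER_NM_TO_PN <- 1000
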