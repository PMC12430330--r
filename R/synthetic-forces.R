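#' Ground-truth parameters for the rupture-force generator
#'
#' The generative model behind Poisson step analysis: each tip-sample contact
#' ruptures `n` discrete bonds with `n ~ Poisson(lambda_mean)`, each bond
#' contributing a fixed specific force `f_i`, on top of a non-specific offset
#' `f_0`, plus Gaussian measurement noise. Under this model a force ensemble
#' has mean `f_0 + lambda * f_i` and variance `lambda * f_i^2 + noise_sd^2`,
#' which is what the variance-mean regression exploits.
#'
#' @param f_i Specific (per-bond) rupture force, pN; must be > 0.
#' @param f_0 Non-specific force offset, pN; must be >= 0.
#' @param lambda_mean Mean number of bonds per contact; must be > 0
#'   (0 is accepted for the degenerate no-bond case).
#' @param noise_sd Gaussian measurement noise SD on the rupture force, pN.
#' @param n_curves Number of force curves (draws).
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return An object of class `adhesion_model_params`.
#' @export
adhesion_model_params <- function(f_i, f_0, lambda_mean, noise_sd = 0,
                                  n_curves = 300L, seed = 1L) {
  check_scalar(f_i, "f_i", positive = TRUE)
  check_scalar(f_0, "f_0", nonneg = TRUE)
  check_scalar(lambda_mean, "lambda_mean", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(n_curves, "n_curves", positive = TRUE)
  check_scalar(seed, "seed")
  structure(
    list(f_i = f_i, f_0 = f_0, lambda_mean = lambda_mean,
         noise_sd = noise_sd, n_curves = as.integer(n_curves),
         seed = as.integer(seed)),
    class = "adhesion_model_params"
  )
}

#' Draw rupture forces from the Poisson bond model
#'
#' Draws `n_curves` rupture forces as `f_0 + n * f_i + eps` with
#' `n ~ Poisson(lambda_mean)` and `eps ~ Normal(0, noise_sd)`. Negative
#' draws (possible at high noise) are clipped to zero and flagged, since a
#' physical rupture force is non-negative; the flag preserves auditability.
#'
#' @param params An [adhesion_model_params()] object.
#'
#' @return Numeric vector of rupture forces (pN) with attributes
#'   `clipped` (logical, which draws were clipped to 0) and
#'   `n_bonds` (integer, the latent bond count per draw).
#' @examples
#' f <- draw_rupture_forces(adhesion_model_params(
#'   f_i = 33.4, f_0 = 90, lambda_mean = 3, noise_sd = 10,
#'   n_curves = 300, seed = 7))
#' mean(f)  # near 90 + 3 * 33.4
#' @export
draw_rupture_forces <- function(params) {
  if (!inherits(params, "adhesion_model_params")) {
    params <- do.call(adhesion_model_params, params)
  }
  with_seed(params$seed, {
    n_bonds <- stats::rpois(params$n_curves, params$lambda_mean)
    eps <- if (params$noise_sd > 0) {
      stats::rnorm(params$n_curves, 0, params$noise_sd)
    } else {
      numeric(params$n_curves)
    }
    force <- params$f_0 + n_bonds * params$f_i + eps
    clipped <- force < 0
    force[clipped] <- 0
    structure(force, clipped = clipped, n_bonds = n_bonds)
  })
}

#' Simulate a friction loop with known half-width
#'
#' Generates paired trace/retrace lateral-signal scans with a common offset
#' and a symmetric separation of `2 * true_vf`, so the loop half-width
#' (half the trace-retrace difference) converges to `true_vf` as the noise
#' vanishes.
#'
#' @param true_vf Ground-truth half-width (signal units).
#' @param offset Common lateral-signal offset for both scan directions.
#' @param noise_sd Gaussian noise SD added independently per point and
#'   direction (signal units).
#' @param n_points Points per scan line (>= 2).
#' @param seed Integer seed.
#' @param load Optional applied normal load tag (nN) carried into metadata.
#' @param metadata Optional named list (e.g. drug, field strength).
#'
#' @return A [friction_loop()] object.
#' @export
synthesize_friction_loop <- function(true_vf, offset = 0, noise_sd = 0,
                                     n_points = 512L, seed = 1L,
                                     load = NULL, metadata = list()) {
  check_scalar(true_vf, "true_vf", nonneg = TRUE)
  check_scalar(offset, "offset")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (n_points < 2L) stop("'n_points' must be >= 2", call. = FALSE)
  with_seed(seed, {
    x <- seq(0, by = 1, length.out = n_points)
    noise <- function() {
      if (noise_sd > 0) stats::rnorm(n_points, 0, noise_sd) else numeric(n_points)
    }
    friction_loop(
      x_nm = x,
      v_trace = offset + true_vf + noise(),
      v_retrace = offset - true_vf + noise(),
      load = load, metadata = metadata
    )
  })
}
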