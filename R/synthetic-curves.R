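#' Parameters for synthetic force-distance curve generation
#'
#' Geometry and noise model for the piecewise-linear synthetic curve: a
#' contact ramp on approach, a retraction adhesion well descending to the
#' rupture force followed by a jump-off to the free baseline, optional
#' linear baseline drift and Gaussian signal noise.
#'
#' @param spring_constant Cantilever normal stiffness (N/m); default 0.2.
#' @param sensitivity Deflection sensitivity (nm per signal unit).
#' @param sample_spacing Piezo step between samples (nm).
#' @param contact_stiffness_fraction Slope of the contact-region deflection
#'   relative to the piezo travel, in (0, 1]; 1 means an infinitely stiff
#'   sample.
#' @param baseline_drift_slope Linear drift of the free baseline (signal
#'   units per nm); 0 for a flat baseline.
#' @param noise_sd_signal Gaussian noise SD added to every sample (signal
#'   units).
#' @param z_range Total piezo travel (nm).
#' @param contact_z Piezo position of the contact point (nm; snapped to the
#'   sample grid).
#' @param pull_length Distance past contact at which the unbinding event
#'   ruptures (nm; snapped to the sample grid).
#'
#' @return An object of class `curve_synthesis_params`.
#' @export
curve_synthesis_params <- function(spring_constant = 0.2, sensitivity = 25,
                                   sample_spacing = 0.5,
                                   contact_stiffness_fraction = 0.8,
                                   baseline_drift_slope = 0,
                                   noise_sd_signal = 0,
                                   z_range = 200, contact_z = 30,
                                   pull_length = 40) {
  check_scalar(spring_constant, "spring_constant", positive = TRUE)
  check_scalar(sensitivity, "sensitivity", positive = TRUE)
  check_scalar(sample_spacing, "sample_spacing", positive = TRUE)
  check_scalar(contact_stiffness_fraction, "contact_stiffness_fraction",
               positive = TRUE)
  if (contact_stiffness_fraction > 1) {
    stop("'contact_stiffness_fraction' must be in (0, 1]", call. = FALSE)
  }
  check_scalar(baseline_drift_slope, "baseline_drift_slope")
  check_scalar(noise_sd_signal, "noise_sd_signal", nonneg = TRUE)
  check_scalar(z_range, "z_range", positive = TRUE)
  check_scalar(contact_z, "contact_z", positive = TRUE)
  check_scalar(pull_length, "pull_length", positive = TRUE)
  structure(
    list(spring_constant = spring_constant, sensitivity = sensitivity,
         sample_spacing = sample_spacing,
         contact_stiffness_fraction = contact_stiffness_fraction,
         baseline_drift_slope = baseline_drift_slope,
         noise_sd_signal = noise_sd_signal,
         z_range = z_range, contact_z = contact_z,
         pull_length = pull_length),
    class = "curve_synthesis_params"
  )
}

#' Synthesize a force-distance curve with a known rupture force
#'
#' Builds a piecewise-linear force curve whose retraction segment descends
#' into an adhesion well reaching exactly `rupture_force` (attractive) at a
#' grid point before jumping off to the free baseline, so that adhesion
#' extraction recovers the input force to within one sample-spacing step.
#' The approach segment has the matching contact ramp and a flat non-contact
#' baseline. Drift and noise are applied to the raw signal, as an instrument
#' would record them.
#'
#' @param rupture_force Ground-truth adhesion force (pN, >= 0); 0 produces
#'   a curve with no unbinding feature.
#' @param params A [curve_synthesis_params()] object.
#' @param seed Integer seed for the signal noise.
#' @param metadata Metadata list stored on the curve.
#'
#' @return A [force_curve()] whose calibration matches
#'   `params$spring_constant` and `params$sensitivity`.
#' @export
synthesize_force_curve <- function(rupture_force,
                                   params = curve_synthesis_params(),
                                   seed = 1L, metadata = list()) {
  check_scalar(rupture_force, "rupture_force", nonneg = TRUE)
  if (!inherits(params, "curve_synthesis_params")) {
    params <- do.call(curve_synthesis_params, params)
  }
  dz <- params$sample_spacing
  z <- seq(0, params$z_range, by = dz)
  z_c <- round(params$contact_z / dz) * dz
  z_r <- z_c + max(round(params$pull_length / dz), 1L) * dz
  if (z_r >= params$z_range) {
    stop("'z_range' too small for contact_z + pull_length", call. = FALSE)
  }
  cal <- afm_calibration(k = params$spring_constant,
                         sensitivity = params$sensitivity)
  # contact ramp: deflection (nm) = fraction * indentation depth
  contact_signal <- ifelse(
    z < z_c,
    params$contact_stiffness_fraction * (z_c - z) / params$sensitivity,
    0
  )
  # adhesion well: linear descent from contact point to the rupture signal
  signal_rupture <- -rupture_force /
    (params$spring_constant * params$sensitivity * NN_PER_NM_TO_PN)
  well <- ifelse(
    z >= z_c & z <= z_r,
    signal_rupture * (z - z_c) / (z_r - z_c),
    0
  )
  approach_signal <- contact_signal
  retract_signal <- contact_signal + if (rupture_force > 0) well else 0
  drift <- params$baseline_drift_slope * z
  with_seed(seed, {
    noise <- function() {
      if (params$noise_sd_signal > 0) {
        stats::rnorm(length(z), 0, params$noise_sd_signal)
      } else {
        numeric(length(z))
      }
    }
    force_curve(
      approach = data.frame(z_nm = rev(z),
                            signal = rev(approach_signal + drift + noise())),
      retract = data.frame(z_nm = z,
                           signal = retract_signal + drift + noise()),
      calibration = cal,
      metadata = metadata
    )
  })
}

#' Synthesize an ensemble of force curves from the Poisson bond model
#'
#' Convenience composition: draws rupture forces with
#' [draw_rupture_forces()] and renders each as a full force-distance curve.
#' Per-curve seeds are derived deterministically from `params$seed`.
#'
#' @param params An [adhesion_model_params()] object.
#' @param curve_params A [curve_synthesis_params()] object.
#' @param metadata Metadata list applied to every curve (an `id` per curve
#'   is added).
#'
#' @return List of [force_curve()] objects, with the drawn rupture forces
#'   in attribute `rupture_forces`.
#' @export
synthesize_curve_ensemble <- function(params,
                                      curve_params = curve_synthesis_params(),
                                      metadata = list()) {
  forces <- draw_rupture_forces(params)
  curves <- lapply(seq_along(forces), function(i) {
    md <- metadata
    md$id <- sprintf("curve%04d", i)
    synthesize_force_curve(forces[[i]], curve_params,
                           seed = params$seed + i, metadata = md)
  })
  attr(curves, "rupture_forces") <- as.numeric(forces)
  curves
}
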