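#' Cantilever calibration constants
#'
#' Bundles the calibration constants needed to convert raw AFM signals into
#' forces: the normal spring constant and deflection sensitivity for the
#' vertical channel (Hooke's-law conversion of force-distance curves), and
#' the lateral spring coefficient, tip height, cantilever length and lateral
#' deflection sensitivity for the friction channel.
#'
#' @param k Normal spring constant of the cantilever (N/m).
#' @param sensitivity Deflection sensitivity of the vertical channel
#'   (nm per signal unit): multiplied into the raw signal to obtain the
#'   cantilever deflection in nm.
#' @param k_f Lateral (torsional) spring coefficient (N/m).
#' @param tip_height_h Tip height (micrometres).
#' @param cantilever_length_l Cantilever length (micrometres).
#' @param lateral_sensitivity_S Deflection sensitivity of the detector for
#'   the lateral channel (signal units per nm), so that dividing a lateral
#'   signal by it yields a length.
#'
#' @return An object of class `afm_calibration`.
#' @examples
#' cal <- afm_calibration(k = 0.2, sensitivity = 25)
#' signal_to_force(-0.07, cal)  # -350 pN
#' @export
afm_calibration <- function(k = 0.2, sensitivity = 25,
                            k_f = 80, tip_height_h = 17,
                            cantilever_length_l = 450,
                            lateral_sensitivity_S = 0.02) {
  check_scalar(k, "k", positive = TRUE)
  check_scalar(sensitivity, "sensitivity", positive = TRUE)
  check_scalar(k_f, "k_f", positive = TRUE)
  check_scalar(tip_height_h, "tip_height_h", positive = TRUE)
  check_scalar(cantilever_length_l, "cantilever_length_l", positive = TRUE)
  check_scalar(lateral_sensitivity_S, "lateral_sensitivity_S", positive = TRUE)
  structure(
    list(k = k, sensitivity = sensitivity, k_f = k_f,
         tip_height_h = tip_height_h,
         cantilever_length_l = cantilever_length_l,
         lateral_sensitivity_S = lateral_sensitivity_S),
    class = "afm_calibration"
  )
}

#' @export
print.afm_calibration <- function(x, ...) {
  cat("AFM calibration\n")
  cat(sprintf("  normal:  k = %g N/m, sensitivity = %g nm/signal\n",
              x$k, x$sensitivity))
  cat(sprintf("  lateral: k_f = %g N/m, h = %g um, l = %g um, S = %g signal/nm\n",
              x$k_f, x$tip_height_h, x$cantilever_length_l,
              x$lateral_sensitivity_S))
  invisible(x)
}

is_calibration <- function(x) inherits(x, "afm_calibration")

as_calibration <- function(x) {
  if (is_calibration(x)) return(x)
  if (is.list(x)) return(do.call(afm_calibration, x))
  stop("'calibration' must be an afm_calibration object or a named list",
       call. = FALSE)
}
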