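#' Friction loop container
#'
#' A friction loop pairs the lateral-signal trace (forward scan) and retrace
#' (reverse scan) recorded over the same fast-scan positions. Half the
#' trace-retrace difference measures the friction signal; the common offset
#' cancels.
#'
#' @param x_nm Fast-scan positions (nm), strictly increasing.
#' @param v_trace,v_retrace Lateral signals for the forward and reverse
#'   scan directions; same length as `x_nm` (>= 2).
#' @param load Optional applied normal load (nN).
#' @param metadata Named list (drug, field strength, ...).
#'
#' @return An object of class `friction_loop`.
#' @export
friction_loop <- function(x_nm, v_trace, v_retrace, load = NULL,
                          metadata = list()) {
  if (length(v_trace) != length(x_nm) || length(v_retrace) != length(x_nm)) {
    stop("trace and retrace must match the position vector in length",
         call. = FALSE)
  }
  if (length(x_nm) < 2L) stop("a friction loop needs >= 2 points",
                              call. = FALSE)
  if (any(diff(x_nm) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (!all(is.finite(v_trace)) || !all(is.finite(v_retrace))) {
    stop("non-finite lateral signal values", call. = FALSE)
  }
  if (!is.null(load)) check_scalar(load, "load", nonneg = TRUE)
  structure(
    list(x_nm = as.numeric(x_nm), v_trace = as.numeric(v_trace),
         v_retrace = as.numeric(v_retrace), load = load,
         metadata = metadata),
    class = "friction_loop"
  )
}

#' Friction-loop half-width
#'
#' The friction signal is half the difference between the lateral signals
#' of the forward and reverse scan directions. Per-position half-widths
#' `(trace - retrace) / 2` are averaged over the central portion of the
#' scan line (the outer ends are dropped to avoid turnaround artifacts) and
#' the absolute value is taken, so the result does not depend on scan
#' orientation.
#'
#' @param loop A [friction_loop()].
#' @param central_fraction Fraction of the scan line, centred, used for the
#'   average; default 0.8.
#'
#' @return Half-width `v_f` (signal units, >= 0), with the per-position
#'   half-widths in attribute `per_position` for diagnostics.
#' @export
loop_half_width <- function(loop, central_fraction = 0.8) {
  stopifnot(inherits(loop, "friction_loop"))
  check_scalar(central_fraction, "central_fraction", positive = TRUE)
  if (central_fraction > 1) {
    stop("'central_fraction' must be in (0, 1]", call. = FALSE)
  }
  half <- (loop$v_trace - loop$v_retrace) / 2
  n <- length(half)
  drop_each <- floor(n * (1 - central_fraction) / 2)
  use <- seq.int(drop_each + 1L, n - drop_each)
  v_f <- abs(mean(half[use]))
  structure(v_f, per_position = half)
}

#' Convert a friction half-width to a friction force
#'
#' Lateral force calibration: `F_f = (3/2) * K_f * (h / l) * (V_f / S)`,
#' where `K_f` is the lateral spring coefficient, `h` the tip height, `l`
#' the cantilever length and `S` the lateral deflection sensitivity of the
#' detector. With `K_f` in N/m, `h` and `l` in the same length unit and
#' `V_f / S` in nm, the result is reported in pN. Linear in `v_f`.
#'
#' @param v_f Half-width (signal units, >= 0); vectorised.
#' @param calibration An [afm_calibration()] providing `k_f`,
#'   `tip_height_h`, `cantilever_length_l`, `lateral_sensitivity_S`.
#'
#' @return Friction force (pN).
#' @examples
#' cal <- afm_calibration(k_f = 80, tip_height_h = 17,
#'                        cantilever_length_l = 450,
#'                        lateral_sensitivity_S = 0.02)
#' friction_force(0.001, cal)  # ~226.7 pN
#' @export
friction_force <- function(v_f, calibration) {
  calibration <- as_calibration(calibration)
  if (!is.numeric(v_f) || any(!is.finite(v_f)) || any(v_f < 0)) {
    stop("'v_f' must be finite and >= 0", call. = FALSE)
  }
  1.5 * calibration$k_f *
    (calibration$tip_height_h / calibration$cantilever_length_l) *
    (v_f / calibration$lateral_sensitivity_S) * NN_PER_NM_TO_PN
}

#' Per-loop friction forces for an ensemble of loops
#'
#' Computes the half-width and calibrated friction force for every loop.
#' In `"constant-load"` mode every loop must carry a load tag and all tags
#' must agree (the constant-load protocol applies one fixed normal load,
#' e.g. 1 nN); a mixed or untagged set is an error in that mode.
#'
#' @param loops List of [friction_loop()] objects.
#' @param calibration An [afm_calibration()].
#' @param mode `"loop"` (default) or `"constant-load"`.
#' @param central_fraction Passed to [loop_half_width()].
#'
#' @return Data frame with one row per loop: `id`, `drug`, `field_mV_mm`,
#'   `load_nN`, `v_f`, `f_f_pN`, `n_points`.
#' @export
friction_ensemble <- function(loops, calibration,
                              mode = c("loop", "constant-load"),
                              central_fraction = 0.8) {
  mode <- match.arg(mode)
  stopifnot(is.list(loops), length(loops) >= 1L)
  calibration <- as_calibration(calibration)
  loads <- lapply(loops, `[[`, "load")
  if (mode == "constant-load") {
    if (any(vapply(loads, is.null, logical(1L)))) {
      stop("constant-load mode requires a load tag on every loop",
           call. = FALSE)
    }
    if (length(unique(unlist(loads))) > 1L) {
      stop("constant-load mode requires a single common load; got mixed loads",
           call. = FALSE)
    }
  }
  rows <- lapply(seq_along(loops), function(i) {
    lp <- loops[[i]]
    v_f <- as.numeric(loop_half_width(lp, central_fraction))
    md <- lp$metadata
    data.frame(
      id = if (!is.null(md$id)) as.character(md$id) else as.character(i),
      drug = if (!is.null(md$drug)) as.character(md$drug) else NA_character_,
      field_mV_mm = if (!is.null(md$field_mV_mm))
        as.numeric(md$field_mV_mm) else NA_real_,
      load_nN = if (!is.null(lp$load)) lp$load else NA_real_,
      v_f = v_f,
      f_f_pN = friction_force(v_f, calibration),
      n_points = length(lp$x_nm),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
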