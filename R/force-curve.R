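#' Force-distance curve container
#'
#' A force curve holds the approach and retraction traces of an AFM
#' force-distance measurement as (piezo position, deflection signal) pairs,
#' together with the cantilever calibration and free-form metadata (sample
#' id, drug label, field strength). Positions must be strictly monotone
#' within a segment and each segment must have at least 16 points.
#'
#' @param approach,retract Data frames with columns `z_nm` (piezo position,
#'   nm) and `signal` (deflection signal, instrument units).
#' @param calibration An [afm_calibration()] object (or named list coercible
#'   to one).
#' @param metadata Named list; conventionally `id`, `drug`,
#'   `field_mV_mm`.
#'
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(approach, retract, calibration = afm_calibration(),
                        metadata = list()) {
  check_segment <- function(seg, name) {
    if (!is.data.frame(seg) || !all(c("z_nm", "signal") %in% names(seg))) {
      stop("'", name, "' must be a data frame with columns z_nm and signal",
           call. = FALSE)
    }
    if (nrow(seg) < 16L) {
      stop("'", name, "' must have at least 16 points", call. = FALSE)
    }
    dz <- diff(seg$z_nm)
    if (!(all(dz > 0) || all(dz < 0))) {
      stop("positions in '", name, "' must be strictly monotone",
           call. = FALSE)
    }
    if (!all(is.finite(seg$signal))) {
      stop("non-finite signal values in '", name, "'", call. = FALSE)
    }
    seg[, c("z_nm", "signal")]
  }
  structure(
    list(approach = check_segment(approach, "approach"),
         retract = check_segment(retract, "retract"),
         calibration = as_calibration(calibration),
         metadata = metadata),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("Force-distance curve: %d approach / %d retract points\n",
              nrow(x$approach), nrow(x$retract)))
  if (length(x$metadata)) {
    cat("  metadata:",
        paste(names(x$metadata), unlist(x$metadata), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Convert a deflection signal to force via Hooke's law
#'
#' The photodetector signal times the deflection sensitivity gives the
#' cantilever deflection `d` in nm; Hooke's law `F = k d` then gives the
#' force, reported in pN. Attractive (downward) deflections give negative
#' forces.
#'
#' @param signal Deflection signal (instrument units); vectorised.
#' @param calibration An [afm_calibration()] object.
#'
#' @return Force in pN, same length as `signal`.
#' @examples
#' cal <- afm_calibration(k = 0.2, sensitivity = 25)
#' signal_to_force(-0.07, cal)  # d = -1.75 nm -> -350 pN
#' @export
signal_to_force <- function(signal, calibration) {
  calibration <- as_calibration(calibration)
  if (!is.numeric(signal) || any(!is.finite(signal))) {
    stop("'signal' must be finite numeric", call. = FALSE)
  }
  calibration$k * (calibration$sensitivity * signal) * NN_PER_NM_TO_PN
}

#' Subtract the non-contact baseline from a force curve
#'
#' Fits a least-squares straight line to the configured tail fraction of the
#' retraction segment -- the points farthest from the surface, where the tip
#' is out of contact -- and subtracts that line from the signal of both
#' segments. This removes constant offsets and linear drift so that the
#' non-contact force baseline is zero.
#'
#' @param curve A [force_curve()].
#' @param tail_fraction Fraction of the retract segment (by position,
#'   farthest points) used for the baseline fit; default 0.3.
#'
#' @return The corrected `force_curve`, with attributes `baseline_slope`
#'   and `baseline_intercept` (signal units, per nm and absolute).
#' @export
correct_baseline <- function(curve, tail_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  check_scalar(tail_fraction, "tail_fraction", positive = TRUE)
  if (tail_fraction > 1) stop("'tail_fraction' must be <= 1", call. = FALSE)
  ret <- curve$retract
  n_tail <- floor(nrow(ret) * tail_fraction)
  if (n_tail < 8L) {
    stop("baseline tail has fewer than 8 points; increase 'tail_fraction'",
         call. = FALSE)
  }
  tail_idx <- order(ret$z_nm, decreasing = TRUE)[seq_len(n_tail)]
  z <- ret$z_nm[tail_idx]
  s <- ret$signal[tail_idx]
  if (stats::var(z) == 0) stop("degenerate baseline tail", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, z), s)
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  out <- curve
  out$approach$signal <- out$approach$signal -
    (intercept + slope * out$approach$z_nm)
  out$retract$signal <- out$retract$signal -
    (intercept + slope * out$retract$z_nm)
  attr(out, "baseline_slope") <- slope
  attr(out, "baseline_intercept") <- intercept
  attr(out, "baseline_corrected") <- TRUE
  out
}

#' Extract the adhesion (unbinding) force from a retraction segment
#'
#' The adhesion force is the maximum attractive force required to separate
#' tip and sample: the magnitude of the minimum (most negative) force on the
#' baseline-corrected retraction segment. An event is reported only when
#' that magnitude reaches the detection threshold, `threshold_mads` times a
#' robust noise estimate (the median absolute deviation of the corrected
#' non-contact tail) with a small absolute floor; the boundary is closed
#' (magnitude equal to the threshold counts as an event). When no event is
#' detected the adhesion force is reported as `NA`, never as a zero datum.
#'
#' @param curve A [force_curve()]; baseline-corrected (corrected on the fly
#'   with defaults otherwise).
#' @param threshold_mads Event threshold in units of the robust tail noise
#'   SD (MAD); default 5.
#' @param min_force_pN Absolute floor on the event threshold (pN), so a
#'   perfectly noiseless flat retract never reports an event; default 1.
#' @param tail_fraction Tail fraction for baseline correction (when the
#'   curve is not corrected yet).
#' @param noise_fraction Fraction of the retract (farthest positions) used
#'   for the robust noise estimate; wider than the baseline tail because
#'   the MAD tolerates partial overlap with curve structure and a larger
#'   window stabilizes the threshold; default 0.5.
#'
#' @return An object of class `adhesion_event`: list with
#'   `adhesion_force` (pN, positive magnitude; `NA` when no event),
#'   `rupture_position` (nm), `baseline_slope`, `baseline_intercept`,
#'   `has_event`, `threshold` (pN) and `noise_sd` (pN, robust).
#' @export
extract_adhesion <- function(curve, threshold_mads = 5, min_force_pN = 1,
                             tail_fraction = 0.3, noise_fraction = 0.5) {
  stopifnot(inherits(curve, "force_curve"))
  if (!isTRUE(attr(curve, "baseline_corrected"))) {
    curve <- correct_baseline(curve, tail_fraction)
  }
  ret <- curve$retract
  force <- signal_to_force(ret$signal, curve$calibration)
  n_tail <- floor(length(force) * noise_fraction)
  tail_idx <- order(ret$z_nm, decreasing = TRUE)[seq_len(max(n_tail, 1L))]
  noise_sd <- stats::mad(force[tail_idx], center = 0)
  threshold <- max(threshold_mads * noise_sd, min_force_pN)
  i_min <- which.min(force)
  magnitude <- max(-force[i_min], 0)
  has_event <- magnitude >= threshold
  structure(
    list(adhesion_force = if (has_event) magnitude else NA_real_,
         rupture_position = if (has_event) ret$z_nm[i_min] else NA_real_,
         baseline_slope = attr(curve, "baseline_slope"),
         baseline_intercept = attr(curve, "baseline_intercept"),
         has_event = has_event,
         threshold = threshold,
         noise_sd = noise_sd),
    class = "adhesion_event"
  )
}

#' @export
print.adhesion_event <- function(x, ...) {
  if (x$has_event) {
    cat(sprintf("Adhesion event: %.1f pN at z = %.1f nm\n",
                x$adhesion_force, x$rupture_position))
  } else {
    cat(sprintf("No adhesion event (threshold %.2f pN)\n", x$threshold))
  }
  invisible(x)
}

#' Batch adhesion extraction over a set of curves
#'
#' @param curves List of [force_curve()] objects.
#' @param ... Passed to [extract_adhesion()].
#'
#' @return Data frame with one row per curve: `id`, `drug`, `field_mV_mm`
#'   (from metadata, `NA` when absent), `adhesion_pN`, `has_event`.
#' @export
adhesion_table <- function(curves, ...) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    ev <- extract_adhesion(cv, ...)
    md <- cv$metadata
    data.frame(
      id = if (!is.null(md$id)) as.character(md$id) else as.character(i),
      drug = if (!is.null(md$drug)) as.character(md$drug) else NA_character_,
      field_mV_mm = if (!is.null(md$field_mV_mm))
        as.numeric(md$field_mV_mm) else NA_real_,
      adhesion_pN = ev$adhesion_force,
      has_event = ev$has_event,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
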