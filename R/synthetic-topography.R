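#' Parameters for the synthetic protein-layer topograph generator
#'
#' The generator emulates a protein monolayer on a flat substrate: a
#' baseline plane plus `bump_count` Gaussian bumps (protein particles) with
#' random centres, heights and a common lateral width. A multiplicative
#' `compaction_factor` in (0, 1] scales the bump field, phenomenologically
#' emulating field-induced compaction of the layer: the mean height above
#' baseline and the roughness metrics scale exactly linearly with it.
#'
#' Defaults are tuned so that a full-compaction map resembles a serum
#' albumin monolayer on gold: mean height about 8.5 nm above the substrate
#' and RMS roughness (Sq) about 2.6 nm.
#'
#' @param grid_size Pixels per side (>= 16); default 128.
#' @param pixel_nm Lateral nm per pixel; default 1000/128 (a 1 um scan).
#' @param baseline_height Substrate reference height (nm).
#' @param bump_count Number of protein bumps.
#' @param bump_height_mean,bump_height_sd Bump height distribution (nm,
#'   Gaussian truncated at 0); mean must be > 0.
#' @param bump_sigma_nm Lateral Gaussian width of a bump (nm).
#' @param compaction_factor Multiplicative height scale in (0, 1].
#' @param seed Integer seed.
#'
#' @return An object of class `topography_model_params`.
#' @export
topography_model_params <- function(grid_size = 128L, pixel_nm = 1000 / 128,
                                    baseline_height = 6.9,
                                    bump_count = 2400L,
                                    bump_height_mean = 1.45,
                                    bump_height_sd = 0.5,
                                    bump_sigma_nm = 20,
                                    compaction_factor = 1,
                                    seed = 1L) {
  if (grid_size < 16L) stop("'grid_size' must be >= 16", call. = FALSE)
  check_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  check_scalar(baseline_height, "baseline_height")
  check_scalar(bump_count, "bump_count", nonneg = TRUE)
  check_scalar(bump_height_mean, "bump_height_mean", positive = TRUE)
  check_scalar(bump_height_sd, "bump_height_sd", nonneg = TRUE)
  check_scalar(bump_sigma_nm, "bump_sigma_nm", positive = TRUE)
  check_scalar(compaction_factor, "compaction_factor", positive = TRUE)
  if (compaction_factor > 1) {
    stop("'compaction_factor' must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(grid_size = as.integer(grid_size), pixel_nm = pixel_nm,
         baseline_height = baseline_height,
         bump_count = as.integer(bump_count),
         bump_height_mean = bump_height_mean,
         bump_height_sd = bump_height_sd,
         bump_sigma_nm = bump_sigma_nm,
         compaction_factor = compaction_factor,
         seed = as.integer(seed)),
    class = "topography_model_params"
  )
}

#' Synthesize a protein-layer height map with known ground truth
#'
#' Deterministic under a fixed seed. Bump centres are uniform over the scan
#' area; each bump adds `h * exp(-r^2 / (2 * sigma^2))` evaluated on a
#' local patch out to 4 sigma. The whole bump field is multiplied by
#' `compaction_factor`, so halving the factor exactly halves the mean
#' height above baseline as well as Sa and Sq (for a fixed seed).
#'
#' @param params A [topography_model_params()] object.
#' @param metadata Metadata list stored on the map.
#'
#' @return A [height_map()].
#' @export
synthesize_height_map <- function(params = topography_model_params(),
                                  metadata = list()) {
  if (!inherits(params, "topography_model_params")) {
    params <- do.call(topography_model_params, params)
  }
  n <- params$grid_size
  extent <- n * params$pixel_nm
  bumps <- matrix(0, n, n)
  if (params$bump_count > 0L) {
    with_seed(params$seed, {
      cx <- stats::runif(params$bump_count, 0, extent)
      cy <- stats::runif(params$bump_count, 0, extent)
      h <- pmax(stats::rnorm(params$bump_count, params$bump_height_mean,
                             params$bump_height_sd), 0)
      sig_px <- params$bump_sigma_nm / params$pixel_nm
      reach <- ceiling(4 * sig_px)
      ax <- (seq_len(n) - 0.5)  # pixel centres, in pixel units
      for (b in seq_len(params$bump_count)) {
        px <- cx[b] / params$pixel_nm
        py <- cy[b] / params$pixel_nm
        ix <- max(1L, floor(px - reach)):min(n, ceiling(px + reach))
        iy <- max(1L, floor(py - reach)):min(n, ceiling(py + reach))
        gx <- exp(-(ax[ix] - px)^2 / (2 * sig_px^2))
        gy <- exp(-(ax[iy] - py)^2 / (2 * sig_px^2))
        bumps[iy, ix] <- bumps[iy, ix] + h[b] * outer(gy, gx)
      }
    })
  }
  grid <- params$baseline_height + params$compaction_factor * bumps
  height_map(grid, pixel_nm = params$pixel_nm, metadata = metadata)
}
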