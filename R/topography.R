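#' Height-map container
#'
#' A rectangular grid of surface heights (nm) with its lateral pixel scale,
#' as produced by tapping-mode AFM imaging. At least 16 x 16 pixels and all
#' values finite.
#'
#' @param grid Numeric matrix of heights (nm).
#' @param pixel_nm Lateral size of one pixel (nm).
#' @param metadata Named list (surface label, field strength, ...).
#'
#' @return An object of class `height_map`.
#' @export
height_map <- function(grid, pixel_nm = 1, metadata = list()) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("'grid' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(grid) < 16L || ncol(grid) < 16L) {
    stop("'grid' must be at least 16 x 16", call. = FALSE)
  }
  n_bad <- sum(!is.finite(grid))
  if (n_bad > 0L) {
    stop(n_bad, " non-finite cell(s) in height grid", call. = FALSE)
  }
  check_scalar(pixel_nm, "pixel_nm", positive = TRUE)
  structure(list(grid = grid, pixel_nm = pixel_nm, metadata = metadata),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("Height map: %d x %d pixels, %.3g nm/pixel\n",
              nrow(x$grid), ncol(x$grid), x$pixel_nm))
  invisible(x)
}

#' Level a height map by plane subtraction
#'
#' Order 1 subtracts the least-squares plane `a + b x + c y` fitted to the
#' whole grid, removing sample tilt before roughness analysis; order 0 is
#' the identity (the raw reference plane at zero).
#'
#' @param map A [height_map()].
#' @param order 0 (no leveling) or 1 (plane subtraction).
#'
#' @return The leveled `height_map`, with the fitted plane coefficients in
#'   attribute `plane` for order 1.
#' @export
level_plane <- function(map, order = 1L) {
  stopifnot(inherits(map, "height_map"))
  if (!order %in% c(0L, 1L)) stop("'order' must be 0 or 1", call. = FALSE)
  if (order == 0L) return(map)
  nr <- nrow(map$grid); nc <- ncol(map$grid)
  x <- rep(seq_len(nc), each = nr) * map$pixel_nm
  y <- rep(seq_len(nr), times = nc) * map$pixel_nm
  z <- as.vector(map$grid)
  fit <- stats::lm.fit(cbind(1, x, y), z)
  plane <- matrix(fit$fitted.values, nr, nc)
  out <- map
  out$grid <- map$grid - plane
  attr(out, "plane") <- fit$coefficients
  attr(out, "leveled") <- TRUE
  out
}

#' Average surface height and roughness of a height map
#'
#' Three standard areal metrics over the full scanned area:
#' average height relative to a reference level, the average roughness
#' `Sa = mean(|z - mean(z)|)` and the root-mean-square roughness
#' `Sq = sqrt(mean((z - mean(z))^2))`. `Sq >= Sa` always (Cauchy-Schwarz),
#' with equality when the deviations have constant magnitude.
#'
#' @param map A [height_map()], leveled beforehand if desired (see
#'   [level_plane()]).
#' @param reference Reference height subtracted from the mean (nm);
#'   default 0 (e.g. the substrate plane after leveling, or the generator's
#'   baseline for synthetic maps).
#'
#' @return An object of class `surface_stats`: `avg_height`, `sa`, `sq`
#'   (all nm), `leveling_order` (1 if the map was plane-leveled, else 0),
#'   `n_pixels`.
#' @examples
#' m <- height_map(matrix(6.9, 32, 32))
#' surface_stats(m)  # avg 6.9, Sa = Sq = 0
#' @export
surface_stats <- function(map, reference = 0) {
  stopifnot(inherits(map, "height_map"))
  check_scalar(reference, "reference")
  z <- as.vector(map$grid)
  mu <- mean(z)
  dev <- z - mu
  structure(
    list(avg_height = mu - reference,
         sa = mean(abs(dev)),
         sq = sqrt(mean(dev^2)),
         leveling_order = if (isTRUE(attr(map, "leveled"))) 1L else 0L,
         n_pixels = length(z)),
    class = "surface_stats"
  )
}

#' @export
print.surface_stats <- function(x, ...) {
  cat(sprintf("Surface: avg height %.2f nm, Sa %.2f nm, Sq %.2f nm (%d px)\n",
              x$avg_height, x$sa, x$sq, x$n_pixels))
  invisible(x)
}
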