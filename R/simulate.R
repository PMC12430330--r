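#' Write a synthetic dataset to disk in the package's TSV dialects
#'
#' Generates force curves, friction loops and a height map with known
#' ground truth and writes them under `out_dir` (`curves/`, `loops/`,
#' `map.tsv`), mirroring what an instrument-export session would produce.
#' The config is a named list (or YAML file path) whose keys follow the
#' generator parameter objects:
#'
#' \describe{
#'   \item{adhesion}{arguments of [adhesion_model_params()]}
#'   \item{curve}{arguments of [curve_synthesis_params()] (optional)}
#'   \item{friction}{`true_vf`, `offset`, `noise_sd`, `n_points`,
#'     `n_loops`, `load` (optional)}
#'   \item{topography}{arguments of [topography_model_params()] (optional)}
#'   \item{metadata}{named list stamped on every file (optional)}
#' }
#'
#' @param config Named list or YAML file path.
#' @param out_dir Output directory (created if absent).
#'
#' @return Invisibly, a list with the ground truth actually used
#'   (`rupture_forces`, `true_vf`, `topography` params) and the file paths
#'   written.
#' @export
simulate_dataset <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  metadata <- if (!is.null(config$metadata)) config$metadata else list()
  truth <- list()
  paths <- list()

  if (!is.null(config$adhesion)) {
    ap <- do.call(adhesion_model_params, config$adhesion)
    cp <- if (!is.null(config$curve)) {
      do.call(curve_synthesis_params, config$curve)
    } else {
      curve_synthesis_params()
    }
    curves <- synthesize_curve_ensemble(ap, cp, metadata = metadata)
    curve_dir <- file.path(out_dir, "curves")
    dir.create(curve_dir, showWarnings = FALSE)
    paths$curves <- vapply(seq_along(curves), function(i) {
      write_force_curve(curves[[i]],
                        file.path(curve_dir, sprintf("curve%04d.tsv", i)))
    }, character(1L))
    truth$rupture_forces <- attr(curves, "rupture_forces")
  }

  if (!is.null(config$friction)) {
    fr <- config$friction
    n_loops <- if (!is.null(fr$n_loops)) fr$n_loops else 1L
    loop_dir <- file.path(out_dir, "loops")
    dir.create(loop_dir, showWarnings = FALSE)
    seed0 <- if (!is.null(fr$seed)) fr$seed else 1L
    paths$loops <- vapply(seq_len(n_loops), function(i) {
      loop <- synthesize_friction_loop(
        true_vf = fr$true_vf,
        offset = if (!is.null(fr$offset)) fr$offset else 0,
        noise_sd = if (!is.null(fr$noise_sd)) fr$noise_sd else 0,
        n_points = if (!is.null(fr$n_points)) fr$n_points else 512L,
        seed = seed0 + i,
        load = fr$load,
        metadata = metadata)
      write_friction_loop(loop,
                          file.path(loop_dir, sprintf("loop%04d.tsv", i)))
    }, character(1L))
    truth$true_vf <- fr$true_vf
  }

  if (!is.null(config$topography)) {
    tp <- do.call(topography_model_params, config$topography)
    map <- synthesize_height_map(tp, metadata = metadata)
    paths$map <- write_height_map(map, file.path(out_dir, "map.tsv"))
    truth$topography <- tp
  }

  invisible(list(truth = truth, paths = paths))
}
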