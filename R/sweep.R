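#' Published specific and non-specific force table
#'
#' Reads the bundled table of published specific (`F_i`) and non-specific
#' (`F_0`) forces between serum-albumin molecules for six tyrosine kinase
#' inhibitors at electric field strengths 0-100 mV/mm (Poisson step
#' analysis of >300 curves per condition, mean and SD in pN). Used as the
#' ground-truth operating points for simulation scenarios and for the
#' percent-reduction worked examples.
#'
#' @return Data frame with columns `drug`, `field_mV_mm`, `f_i_pN`,
#'   `f_i_sd`, `f_0_pN`, `f_0_sd`.
#' @export
tki_reference_forces <- function() {
  path <- system.file("extdata", "tki_reference_forces.tsv",
                      package = "afmforce", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Inverse of friction_force(): the half-width producing a target force.
vf_for_force <- function(f_f_pN, calibration) {
  f_f_pN / friction_force(1, calibration)
}

#' Build the demonstration drug-by-field simulation scenario
#'
#' Assembles a full sweep configuration covering the six tyrosine kinase
#' inhibitors at field strengths 0-100 mV/mm. Per-condition (`F_i`, `F_0`)
#' ground truth comes from [tki_reference_forces()]; loop and constant-load
#' friction levels and the topographic compaction follow the published
#' drug ordering and reduction trends, attenuated monotonically with field
#' strength. Every metric's ground truth is therefore monotone
#' non-increasing in field strength.
#'
#' @param drugs Drug labels to include (subset of the six).
#' @param fields Field strengths (mV/mm, subset of 0,20,...,100).
#' @param seed Master seed; per-condition seeds are derived from it.
#' @param lambda_levels Poisson bond-count means simulated per condition
#'   (one group per level).
#' @param curves_per_level Curves per bond-count level.
#' @param noise_sd Measurement noise SD on rupture forces (pN).
#' @param n_loops Friction loops per condition.
#' @param loop_noise_frac Friction-loop noise SD as a fraction of the true
#'   half-width.
#' @param grid_size Height-map pixels per side.
#' @param render_curves Render every rupture force as a full force-distance
#'   curve and re-extract the adhesion through the curve-processing stage
#'   (slower); otherwise the drawn rupture forces feed the ensemble stage
#'   directly.
#'
#' @return A config list accepted by [run_sweep()].
#' @export
demo_sweep_config <- function(drugs = c("imatinib", "bosutinib", "dasatinib",
                                        "nilotinib", "ponatinib", "radotinib"),
                              fields = c(0, 20, 40, 60, 80, 100),
                              seed = 1L,
                              lambda_levels = 1:6,
                              curves_per_level = 50L,
                              noise_sd = 10,
                              n_loops = 100L,
                              loop_noise_frac = 0.1,
                              grid_size = 64L,
                              render_curves = FALSE) {
  ref <- tki_reference_forces()
  canonical_fields <- c(0, 20, 40, 60, 80, 100)
  if (!all(fields %in% canonical_fields)) {
    stop("demo scenario defines fields 0, 20, ..., 100 mV/mm only",
         call. = FALSE)
  }
  # loop friction at 20 mV/mm and constant-load friction at 0 mV/mm follow
  # the published per-drug ordering; remaining fields follow monotone
  # attenuation ramps consistent with the published end-to-end reductions.
  loop_f20 <- c(imatinib = 202, bosutinib = 157, dasatinib = 185,
                nilotinib = 274, ponatinib = 206, radotinib = 292)
  const_f0 <- c(imatinib = 398, bosutinib = 365, dasatinib = 386,
                nilotinib = 423, ponatinib = 410, radotinib = 448)
  loop_ramp <- c(`0` = 1, `20` = 0.95, `40` = 0.86, `60` = 0.77,
                 `80` = 0.68, `100` = 0.593)
  const_ramp <- c(`0` = 1, `20` = 0.93, `40` = 0.85, `60` = 0.77,
                  `80` = 0.70, `100` = 0.64)
  topo_ramp <- c(`0` = 1, `20` = 0.93, `40` = 0.84, `60` = 0.74,
                 `80` = 0.64, `100` = 0.55)
  if (!all(drugs %in% names(loop_f20))) {
    stop("unknown drug label(s): ",
         paste(setdiff(drugs, names(loop_f20)), collapse = ", "),
         call. = FALSE)
  }
  conditions <- list()
  for (drug in drugs) {
    for (field in fields) {
      key <- as.character(field)
      row <- ref[ref$drug == drug & ref$field_mV_mm == field, ]
      conditions[[length(conditions) + 1L]] <- list(
        drug = drug,
        field_mV_mm = field,
        sim = list(
          f_i = row$f_i_pN,
          f_0 = row$f_0_pN,
          lambda_levels = lambda_levels,
          curves_per_level = as.integer(curves_per_level),
          noise_sd = noise_sd,
          loop_f_f = unname(loop_f20[drug] / loop_ramp[["20"]] *
                              loop_ramp[[key]]),
          constload_f_f = unname(const_f0[drug] * const_ramp[[key]]),
          load_nN = 1,
          n_loops = as.integer(n_loops),
          loop_noise_frac = loop_noise_frac,
          compaction = unname(topo_ramp[[key]]),
          grid_size = as.integer(grid_size),
          render_curves = isTRUE(render_curves)
        )
      )
    }
  }
  list(
    seed = as.integer(seed),
    baseline_field = 0,
    calibration = afm_calibration(),
    conditions = conditions
  )
}

analyze_condition <- function(cond, calibration, seed) {
  drug <- cond$drug
  field <- cond$field_mV_mm
  adhesions <- NULL
  groups <- NULL
  loop_tab <- NULL
  const_tab <- NULL
  topo <- NULL

  if (!is.null(cond$sim)) {
    sim <- cond$sim
    group_size <- sim$curves_per_level
    forces <- unlist(lapply(seq_along(sim$lambda_levels), function(j) {
      draw_rupture_forces(adhesion_model_params(
        f_i = sim$f_i, f_0 = sim$f_0,
        lambda_mean = sim$lambda_levels[[j]],
        noise_sd = sim$noise_sd,
        n_curves = sim$curves_per_level,
        seed = seed + j))
    }))
    if (isTRUE(sim$render_curves)) {
      cp <- curve_synthesis_params(spring_constant = calibration$k,
                                   sensitivity = calibration$sensitivity)
      curves <- lapply(seq_along(forces), function(i) {
        synthesize_force_curve(forces[[i]], cp, seed = seed + 100L + i,
                               metadata = list(drug = drug,
                                               field_mV_mm = field))
      })
      tab <- adhesion_table(curves)
      adhesions <- tab$adhesion_pN
    } else {
      adhesions <- forces
    }
    groups <- group_curves(adhesions, group_size = group_size,
                           scheme = "sequential")
    make_loops <- function(f_f, load, seed_off) {
      true_vf <- vf_for_force(f_f, calibration)
      lapply(seq_len(sim$n_loops), function(i) {
        synthesize_friction_loop(
          true_vf = true_vf, offset = 0.1,
          noise_sd = sim$loop_noise_frac * true_vf,
          n_points = 256L, seed = seed + seed_off + i,
          load = load,
          metadata = list(drug = drug, field_mV_mm = field))
      })
    }
    loop_tab <- friction_ensemble(make_loops(sim$loop_f_f, NULL, 20000L),
                                  calibration, mode = "loop")
    const_tab <- friction_ensemble(
      make_loops(sim$constload_f_f, sim$load_nN, 40000L),
      calibration, mode = "constant-load")
    topo_params <- topography_model_params(
      grid_size = sim$grid_size,
      compaction_factor = sim$compaction,
      seed = seed + 60000L)
    topo <- list(map = synthesize_height_map(topo_params),
                 reference = topo_params$baseline_height)
  } else if (!is.null(cond$paths)) {
    p <- cond$paths
    if (!is.null(p$curve_dir)) {
      files <- list.files(p$curve_dir, pattern = "\\.tsv$", full.names = TRUE)
      if (!length(files)) stop("no curve files in ", p$curve_dir,
                               call. = FALSE)
      curves <- lapply(files, read_force_curve, calibration = calibration)
      tab <- adhesion_table(curves)
      adhesions <- tab$adhesion_pN
      gs <- if (!is.null(cond$group_size)) cond$group_size else 30L
      groups <- group_curves(adhesions, group_size = gs,
                             scheme = "sequential")
    }
    if (!is.null(p$loop_dir)) {
      files <- list.files(p$loop_dir, pattern = "\\.tsv$", full.names = TRUE)
      loops <- lapply(files, read_friction_loop)
      loop_tab <- friction_ensemble(loops, calibration, mode = "loop")
    }
    if (!is.null(p$constload_dir)) {
      files <- list.files(p$constload_dir, pattern = "\\.tsv$",
                          full.names = TRUE)
      loops <- lapply(files, read_friction_loop)
      const_tab <- friction_ensemble(loops, calibration,
                                     mode = "constant-load")
    }
    if (!is.null(p$map)) {
      topo <- list(map = level_plane(read_height_map(p$map), order = 1L),
                   reference = 0)
    }
  } else {
    stop("condition for ", drug, " at ", field,
         " mV/mm has neither 'sim' nor 'paths'", call. = FALSE)
  }

  peak <- if (!is.null(adhesions) && sum(is.finite(adhesions)) >= 30L) {
    fit_gaussian_peak(adhesions)
  } else {
    NULL
  }
  bx <- if (!is.null(adhesions)) box_stats(adhesions) else NULL
  pd <- if (!is.null(groups)) fit_poisson_decomposition(groups) else NULL
  loop_peak <- if (!is.null(loop_tab) && nrow(loop_tab) >= 30L) {
    fit_gaussian_peak(loop_tab$f_f_pN)$peak
  } else if (!is.null(loop_tab)) {
    mean(loop_tab$f_f_pN)
  } else {
    NA_real_
  }
  const_peak <- if (!is.null(const_tab) && nrow(const_tab) >= 30L) {
    fit_gaussian_peak(const_tab$f_f_pN)$peak
  } else if (!is.null(const_tab)) {
    mean(const_tab$f_f_pN)
  } else {
    NA_real_
  }
  ss <- if (!is.null(topo)) surface_stats(topo$map, reference = topo$reference)

  list(
    adhesions = adhesions,
    row = data.frame(
      drug = drug,
      field_mV_mm = field,
      n_curves = if (!is.null(adhesions)) sum(is.finite(adhesions)) else 0L,
      adhesion_peak_pN = if (!is.null(peak) && peak$converged)
        peak$peak else NA_real_,
      adhesion_peak_se = if (!is.null(peak) && peak$converged)
        peak$peak_se else NA_real_,
      adhesion_median_pN = if (!is.null(bx)) bx$median else NA_real_,
      adhesion_iqr_pN = if (!is.null(bx)) bx$iqr else NA_real_,
      f_i_pN = if (!is.null(pd)) pd$f_i else NA_real_,
      f_i_se = if (!is.null(pd)) pd$f_i_se else NA_real_,
      f_0_pN = if (!is.null(pd)) pd$f_0 else NA_real_,
      f_0_se = if (!is.null(pd)) pd$f_0_se else NA_real_,
      poisson_r2 = if (!is.null(pd)) pd$r_squared else NA_real_,
      loop_friction_pN = loop_peak,
      constload_friction_pN = const_peak,
      avg_height_nm = if (!is.null(ss)) ss$avg_height else NA_real_,
      sa_nm = if (!is.null(ss)) ss$sa else NA_real_,
      sq_nm = if (!is.null(ss)) ss$sq else NA_real_,
      stringsAsFactors = FALSE
    )
  )
}

#' Run the full drug-by-field analysis sweep
#'
#' Orchestrates all analysis stages over every (drug, field strength)
#' condition of a configuration and joins the module outputs into one
#' report row per condition: Gaussian adhesion peak, box statistics,
#' Poisson decomposition (`F_i`, `F_0`), loop and constant-load friction
#' peaks, and surface metrics, plus a Welch-test star annotation of each
#' condition's adhesion ensemble against the baseline field of the same
#' drug. Deterministic given the config seed. A condition whose inputs are
#' missing is skipped with a warning, never imputed.
#'
#' @param config Config list (see [demo_sweep_config()]) or the path of a
#'   YAML file with the same structure. Fields: `seed`, `baseline_field`,
#'   `calibration`, `conditions` (each with `drug`, `field_mV_mm` and
#'   either a `sim` block or a `paths` block).
#'
#' @return An object of class `sweep_report`: the report data frame with
#'   attribute `baseline_field`.
#' @export
run_sweep <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), length(config$conditions) >= 1L)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  baseline_field <- if (!is.null(config$baseline_field))
    config$baseline_field else 0
  calibration <- if (!is.null(config$calibration)) {
    as_calibration(config$calibration)
  } else {
    afm_calibration()
  }
  star_table <- if (!is.null(config$star_table)) config$star_table
                else "methods"

  results <- list()
  for (i in seq_along(config$conditions)) {
    cond <- config$conditions[[i]]
    res <- tryCatch(
      analyze_condition(cond, calibration, seed = seed + 100000L * (i - 1L)),
      error = function(e) {
        warning("condition '", cond$drug, "' at ", cond$field_mV_mm,
                " mV/mm skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      }
    )
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  if (!length(results)) stop("no condition could be analyzed", call. = FALSE)
  report <- do.call(rbind, lapply(results, `[[`, "row"))

  # significance of each condition against the baseline field, per drug
  report$stars_vs_baseline <- NA_character_
  for (i in seq_len(nrow(report))) {
    base_idx <- which(vapply(results, function(r) {
      r$row$drug == report$drug[i] &&
        r$row$field_mV_mm == baseline_field
    }, logical(1L)))
    if (!length(base_idx)) next
    a <- results[[base_idx[1L]]]$adhesions
    b <- results[[i]]$adhesions
    if (is.null(a) || is.null(b)) next
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L) next
    report$stars_vs_baseline[i] <- if (report$field_mV_mm[i] ==
                                       baseline_field) {
      "ns"
    } else {
      welch_t_test(a, b, star_table = star_table)$stars
    }
  }
  structure(report, class = c("sweep_report", "data.frame"),
            baseline_field = baseline_field)
}

#' Percent-reduction summary between two field strengths
#'
#' For one report metric, computes the per-drug integer-rounded percent
#' reduction from a baseline field strength to a target field strength and
#' the minimum / maximum reduction across drugs with the drugs achieving
#' them.
#'
#' @param report A `sweep_report` (or any data frame with `drug`,
#'   `field_mV_mm` and the metric column).
#' @param metric Report column to summarize, e.g. `"f_0_pN"`,
#'   `"f_i_pN"`, `"adhesion_peak_pN"`.
#' @param baseline_field,target_field Field strengths (mV/mm); both must
#'   be present for every drug included.
#'
#' @return List with `per_drug` (data frame: `drug`, `baseline`, `target`,
#'   `reduction_pct`), `min_reduction`, `min_drug`, `max_reduction`,
#'   `max_drug`.
#' @examples
#' reduction_summary(tki_reference_forces(), "f_0_pN", 0, 100)
#' @export
reduction_summary <- function(report, metric, baseline_field = 0,
                              target_field = 100) {
  if (!metric %in% names(report)) {
    stop("metric '", metric, "' not found in report", call. = FALSE)
  }
  drugs <- unique(report$drug)
  rows <- lapply(drugs, function(d) {
    b <- report[report$drug == d & report$field_mV_mm == baseline_field,
                metric]
    t <- report[report$drug == d & report$field_mV_mm == target_field,
                metric]
    if (length(b) != 1L || length(t) != 1L || !is.finite(b) ||
        !is.finite(t)) {
      stop("drug '", d, "' lacks a finite '", metric, "' at field ",
           baseline_field, " or ", target_field, call. = FALSE)
    }
    data.frame(drug = d, baseline = b, target = t,
               reduction_pct = percent_reduction(b, t),
               stringsAsFactors = FALSE)
  })
  per_drug <- do.call(rbind, rows)
  i_min <- which.min(per_drug$reduction_pct)
  i_max <- which.max(per_drug$reduction_pct)
  list(per_drug = per_drug,
       min_reduction = per_drug$reduction_pct[i_min],
       min_drug = per_drug$drug[i_min],
       max_reduction = per_drug$reduction_pct[i_max],
       max_drug = per_drug$drug[i_max])
}
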