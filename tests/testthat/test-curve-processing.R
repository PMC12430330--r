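test_that("Hooke's-law signal conversion is exact and linear", {
  cal <- afm_calibration(k = 0.2, sensitivity = 25)
  # signal of -0.07 => deflection -1.75 nm => F = k d = -350 pN
  expect_equal(signal_to_force(-0.07, cal), -350)
  expect_equal(signal_to_force(0, cal), 0)
  cal2 <- afm_calibration(k = 0.2, sensitivity = 50)
  expect_equal(signal_to_force(-0.07, cal2), 2 * signal_to_force(-0.07, cal))
  expect_error(signal_to_force(NaN, cal), "finite")
})

test_that("baseline correction removes injected linear drift", {
  cv <- synthesize_force_curve(
    350, curve_synthesis_params(baseline_drift_slope = 2e-4,
                                noise_sd_signal = 1e-3), seed = 5)
  cc <- correct_baseline(cv)
  tail_idx <- which(cc$retract$z_nm >= 0.7 * max(cc$retract$z_nm))
  tail_force <- signal_to_force(cc$retract$signal[tail_idx], cc$calibration)
  expect_lt(abs(mean(tail_force)),
            3 * sd(tail_force) / sqrt(length(tail_force)))
})

test_that("baseline correction is a near-identity on drift-free curves", {
  cv <- synthesize_force_curve(350)
  cc <- correct_baseline(cv)
  expect_equal(cc$retract$signal, cv$retract$signal, tolerance = 1e-12)
})

test_that("an all-constant retract gives slope 0 and intercept the constant", {
  z <- seq(0, 50, by = 1)
  cv <- force_curve(
    approach = data.frame(z_nm = rev(z), signal = rep(0.25, length(z))),
    retract = data.frame(z_nm = z, signal = rep(0.25, length(z)))
  )
  cc <- correct_baseline(cv)
  expect_equal(attr(cc, "baseline_slope"), 0, tolerance = 1e-12)
  expect_equal(attr(cc, "baseline_intercept"), 0.25, tolerance = 1e-12)
  expect_equal(max(abs(cc$retract$signal)), 0, tolerance = 1e-12)
})

test_that("a too-small baseline tail is rejected", {
  cv <- synthesize_force_curve(100)
  expect_error(correct_baseline(cv, tail_fraction = 0.01), "8 points")
})

test_that("adhesion extraction round-trips the injected rupture force", {
  cv <- synthesize_force_curve(350)
  ev <- extract_adhesion(cv)
  expect_true(ev$has_event)
  # exact at zero noise: the well bottom sits on a grid point
  expect_equal(ev$adhesion_force, 350, tolerance = 1e-9)

  # under drift, the corrected extraction still recovers the input
  cvd <- synthesize_force_curve(
    350, curve_synthesis_params(baseline_drift_slope = 5e-4))
  evd <- extract_adhesion(cvd)
  step_pN <- 350 / (70 / 0.5)  # force change per sample step in the well
  expect_lt(abs(evd$adhesion_force - 350), step_pN + 1)
})

test_that("flat retracts report no event, never a zero-force datum", {
  cv <- synthesize_force_curve(0)
  ev <- extract_adhesion(cv)
  expect_false(ev$has_event)
  expect_true(is.na(ev$adhesion_force))
})

test_that("the event threshold boundary is closed", {
  cv <- synthesize_force_curve(350)
  ev0 <- extract_adhesion(cv)
  # re-extract with the threshold raised exactly to the observed magnitude
  ev <- extract_adhesion(cv, min_force_pN = ev0$adhesion_force)
  expect_true(ev$has_event)
  ev_above <- extract_adhesion(cv,
                               min_force_pN = ev0$adhesion_force * (1 + 1e-9))
  expect_false(ev_above$has_event)
})

test_that("extraction error is zero on 200 noiseless synthetic curves", {
  set.seed(314)
  ruptures <- runif(200, 50, 600)
  errs <- vapply(seq_along(ruptures), function(i) {
    cv <- synthesize_force_curve(ruptures[i], seed = i)
    extract_adhesion(cv)$adhesion_force - ruptures[i]
  }, numeric(1))
  expect_equal(max(abs(errs)), 0, tolerance = 1e-9)
})

test_that("extracted adhesion scales linearly with the spring constant", {
  base_params <- curve_synthesis_params(spring_constant = 0.2)
  cv <- synthesize_force_curve(300, base_params)
  ev1 <- extract_adhesion(cv)
  cv3 <- cv
  cv3$calibration <- afm_calibration(k = 0.6,
                                     sensitivity = cv$calibration$sensitivity)
  ev3 <- extract_adhesion(cv3)
  expect_equal(ev3$adhesion_force, 3 * ev1$adhesion_force, tolerance = 1e-12)
})

test_that("false-positive event rate on pure-noise curves stays below 1%", {
  params <- curve_synthesis_params(noise_sd_signal = 1e-3)
  fp <- vapply(1:1000, function(i) {
    cv <- synthesize_force_curve(0, params, seed = i)
    extract_adhesion(cv)$has_event
  }, logical(1))
  expect_lte(mean(fp), 0.01)
})

test_that("curves survive a write/read round trip through the TSV dialect", {
  cv <- synthesize_force_curve(
    275, curve_synthesis_params(noise_sd_signal = 5e-4), seed = 9,
    metadata = list(id = "c1", drug = "imatinib", field_mV_mm = 20))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_curve(cv, path)
  cv2 <- read_force_curve(path, calibration = cv$calibration)
  expect_equal(cv2$retract$signal, cv$retract$signal, tolerance = 1e-8)
  expect_equal(cv2$metadata$drug, "imatinib")
  expect_equal(cv2$metadata$field_mV_mm, 20)
  expect_equal(extract_adhesion(cv2)$adhesion_force,
               extract_adhesion(cv)$adhesion_force, tolerance = 1e-6)
})

test_that("malformed curves are rejected with a format error", {
  z <- seq(0, 50, by = 1)
  expect_error(
    force_curve(approach = data.frame(z_nm = c(z[1:10], z[10:20]),
                                      signal = numeric(21)),
                retract = data.frame(z_nm = z, signal = numeric(length(z)))),
    "monotone")
  expect_error(
    force_curve(approach = data.frame(z_nm = z[1:5], signal = numeric(5)),
                retract = data.frame(z_nm = z, signal = numeric(length(z)))),
    "16 points")
})

test_that("adhesion_table reports one row per curve with metadata", {
  curves <- lapply(1:3, function(i) {
    synthesize_force_curve(100 * i, seed = i,
                           metadata = list(id = paste0("c", i),
                                           drug = "dasatinib",
                                           field_mV_mm = 40))
  })
  tab <- adhesion_table(curves)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$drug, rep("dasatinib", 3))
  expect_equal(tab$adhesion_pN, c(100, 200, 300), tolerance = 1e-9)
})
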