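test_that("zero bond count leaves only the non-specific offset", {
  p <- adhesion_model_params(f_i = 30, f_0 = 90, lambda_mean = 0,
                             noise_sd = 0, n_curves = 5, seed = 1)
  f <- draw_rupture_forces(p)
  expect_equal(as.numeric(f), rep(90, 5))
  expect_false(any(attr(f, "clipped")))
})

test_that("rupture-force ensembles match the closed-form Poisson moments", {
  p <- adhesion_model_params(f_i = 30, f_0 = 90, lambda_mean = 1,
                             noise_sd = 0, n_curves = 1e5, seed = 42)
  f <- as.numeric(draw_rupture_forces(p))
  mom <- bond_model_moments(30, 90, 1)
  expect_lt(abs(mean(f) - mom$mean), 3 * mean_se(f))
  expect_lt(abs(var(f) - mom$var), 3 * var_se(f))
})

test_that("moment match holds across seeds at n = 1e4 (property)", {
  f_i <- 33.4; f_0 <- 90; lambda <- 3; noise <- 10
  mom <- bond_model_moments(f_i, f_0, lambda, noise)
  for (seed in 1:20) {
    f <- as.numeric(draw_rupture_forces(adhesion_model_params(
      f_i, f_0, lambda, noise, n_curves = 1e4, seed = seed)))
    expect_lt(abs(mean(f) - mom$mean), 4 * mean_se(f))
    expect_lt(abs(var(f) - mom$var), 4 * var_se(f))
  }
})

test_that("a Gaussian fit of a high-lambda ensemble peaks near the target mean", {
  # lambda chosen so the ensemble mean sits at 347 pN given the
  # imatinib-like operating point f_i = 33.4, f_0 = 90
  f_i <- 33.4; f_0 <- 90
  lambda <- (347 - f_0) / f_i
  f <- as.numeric(draw_rupture_forces(adhesion_model_params(
    f_i, f_0, lambda, noise_sd = 25, n_curves = 300, seed = 11)))
  fit <- fit_gaussian_peak(f)
  expect_true(fit$converged)
  expect_lt(abs(fit$peak - 347), 2 * mean_se(f) + 2 * fit$peak_se)
})

test_that("negative draws are clipped to zero and flagged", {
  p <- adhesion_model_params(f_i = 1, f_0 = 1, lambda_mean = 0.1,
                             noise_sd = 50, n_curves = 2000, seed = 3)
  f <- draw_rupture_forces(p)
  expect_true(any(attr(f, "clipped")))
  expect_true(all(f >= 0))
  expect_true(all(f[attr(f, "clipped")] == 0))
})

test_that("invalid generator parameters name the offending field", {
  expect_error(adhesion_model_params(f_i = -1, f_0 = 90, lambda_mean = 1),
               "f_i")
  expect_error(adhesion_model_params(f_i = 30, f_0 = -5, lambda_mean = 1),
               "f_0")
  expect_error(adhesion_model_params(f_i = 30, f_0 = 90, lambda_mean = 1,
                                     noise_sd = -2), "noise_sd")
})

test_that("identical seeds give bit-identical generator output", {
  p <- adhesion_model_params(f_i = 30, f_0 = 90, lambda_mean = 2,
                             noise_sd = 5, n_curves = 500, seed = 99)
  expect_identical(draw_rupture_forces(p), draw_rupture_forces(p))
  lp1 <- synthesize_friction_loop(0.4, 1, 0.05, 128, seed = 7)
  lp2 <- synthesize_friction_loop(0.4, 1, 0.05, 128, seed = 7)
  expect_identical(lp1, lp2)
  tp <- topography_model_params(grid_size = 32, bump_count = 50, seed = 5)
  expect_identical(synthesize_height_map(tp), synthesize_height_map(tp))
})

test_that("generator calls leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  draw_rupture_forces(adhesion_model_params(30, 90, 2, 5, 100, seed = 1))
  synthesize_height_map(topography_model_params(grid_size = 16,
                                                bump_count = 5, seed = 2))
  expect_identical(.Random.seed, before)
})

test_that("synthetic friction loops have the prescribed half-width structure", {
  # degenerate: no friction, pure offset
  lp <- synthesize_friction_loop(0, offset = 0.3, noise_sd = 0, n_points = 64)
  expect_equal(lp$v_trace, lp$v_retrace)
  expect_equal(as.numeric(loop_half_width(lp)), 0)
  # exact arithmetic at zero noise
  lp <- synthesize_friction_loop(0.4, offset = 0, noise_sd = 0, n_points = 64)
  expect_equal(as.numeric(loop_half_width(lp)), 0.4)
  # noisy loop recovers the truth within sampling error
  lp <- synthesize_friction_loop(0.4, offset = 1.0, noise_sd = 0.05,
                                 n_points = 512, seed = 21)
  half <- attr(loop_half_width(lp), "per_position")
  se <- sd(half) / sqrt(length(half))
  expect_lt(abs(as.numeric(loop_half_width(lp)) - 0.4), 3 * se)
})

test_that("bump-free height maps are flat at the baseline", {
  tp <- topography_model_params(grid_size = 32, bump_count = 0,
                                baseline_height = 6.9)
  st <- surface_stats(synthesize_height_map(tp))
  expect_equal(st$avg_height, 6.9)
  expect_equal(st$sa, 0)
  expect_equal(st$sq, 0)
})

test_that("compaction scales height above baseline exactly linearly", {
  base <- 6.9
  tp1 <- topography_model_params(grid_size = 48, bump_count = 200,
                                 compaction_factor = 1, seed = 8)
  tp2 <- topography_model_params(grid_size = 48, bump_count = 200,
                                 compaction_factor = 0.5, seed = 8)
  m1 <- synthesize_height_map(tp1)
  m2 <- synthesize_height_map(tp2)
  s1 <- surface_stats(m1, reference = base)
  s2 <- surface_stats(m2, reference = base)
  expect_equal(s2$avg_height, s1$avg_height / 2)
  expect_equal(s2$sa, s1$sa / 2)
  expect_equal(s2$sq, s1$sq / 2)
})

test_that("default topography emulates a protein monolayer (Sq near 2.6 nm)", {
  st <- surface_stats(synthesize_height_map(topography_model_params(seed = 1)),
                      reference = 6.9)
  expect_lt(abs(st$sq - 2.6) / 2.6, 0.15)
})
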