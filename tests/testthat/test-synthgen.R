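test_that("an isletless experiment contains only background and noise", {
  exp <- generate_experiment(tiny_config(n_islets = 0L))
  expect_equal(nrow(exp$truth$catalog), 0)
  expect_true(all(exp$truth$label_map == 0))
  f <- exp$frames$get(0, 0, 0)
  # background mean 20, amplitude ~10+10, read/shot noise: stays far below
  # any islet intensity
  expect_lt(max(f), 200)
  expect_gte(min(f), 0)
})

test_that("identical config and seed give bit-identical frames", {
  e1 <- generate_experiment(tiny_config(seed = 7L))
  e2 <- generate_experiment(tiny_config(seed = 7L))
  expect_identical(e1$truth$catalog, e2$truth$catalog)
  for (tp in e1$truth$time_points) {
    expect_identical(e1$frames$get(tp, 0, 0), e2$frames$get(tp, 0, 0))
  }
  # access order does not change rendered content
  e3 <- generate_experiment(tiny_config(seed = 7L))
  last_tp <- max(e3$truth$time_points)
  f_last_first <- e3$frames$get(last_tp, 0, 0)
  expect_identical(f_last_first, e1$frames$get(last_tp, 0, 0))
})

test_that("homogeneous ground truth releases exactly the configured fractions", {
  exp <- generate_experiment(sim_preset("invitro_gsis", rng_seed = 1))
  ct <- exp$truth$content
  expect_equal(mean(1 - ct[, "30"] / ct[, "15"]), 0.10, tolerance = 1e-12)
  expect_equal(mean(1 - ct[, "60"] / ct[, "15"]), 0.125, tolerance = 1e-12)
})

test_that("content only falls by secretion and losses compose multiplicatively", {
  cfg <- tiny_config(n_islets = 4L, response_regime = "heterogeneous",
                     phase_schedule = data.frame(
                       phase = c("low", "high", "kcl"),
                       duration_min = c(5, 10, 10),
                       release_fraction = c(0, 0.08, 0.05)))
  exp <- generate_experiment(cfg)
  ct <- exp$truth$content
  expect_true(all(diff(t(ct)) <= 1e-12))
  fr <- exp$truth$release_fractions
  expect_equal(ct[, ncol(ct)], ct[, 1] * apply(1 - fr, 1, prod),
               tolerance = 1e-9)
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("emitted pixels are integers in the 12-bit range, clipped at 4095", {
  exp <- generate_experiment(tiny_config())
  f <- exp$frames$get(0, 0, 0)
  expect_true(is.integer(f))
  expect_true(all(f >= 0 & f <= 4095))
  # amplitude far above the 12-bit ceiling must clip exactly at 4095
  hot <- generate_experiment(tiny_config(intensity_density_range = c(9000, 9000)))
  expect_identical(max(hot$frames$get(0, 0, 0)), 4095L)
})

test_that("heterogeneous release fractions are independent of islet size", {
  exp <- generate_experiment(sim_preset("invivo_fullpancreas", rng_seed = 1))
  f <- exp$truth$release_fractions[, 1]
  d <- exp$truth$catalog$diameter_um
  expect_length(f, 200)
  expect_lt(abs(cor(f, d)), 0.2)
})

test_that("a noiseless uniform disk renders with the analytic integrated intensity", {
  cfg <- tiny_config(
    n_islets = 1L, diameters_um = 20,
    background_mean = 0, background_amplitude = 0,
    background_texture_amplitude = 0, background_fine_amplitude = 0,
    noise_gaussian_sd = 0, shot_noise = FALSE, soft_edge = FALSE,
    intensity_density_range = c(1500, 1500),
    depth_attenuation_range = c(1, 1)
  )
  exp <- generate_experiment(cfg)
  f <- exp$frames$get(0, 0, 0)
  area <- sum(exp$truth$label_map > 0)
  expect_equal(sum(as.numeric(f)), area * 1500, tolerance = 1e-9)
  expect_identical(sort(unique(as.vector(f))), c(0L, 1500L))
})

test_that("a blur-flagged frame scores strictly lower than its sharp twin", {
  mk <- function(p) tiny_config(n_islets = 2L, seed = 3L, burst_size = 2L,
                                blur_frame_prob = p)
  sharp <- generate_experiment(mk(0))
  blurred <- generate_experiment(mk(1))
  f_s <- sharp$frames$get(0, 0, 0)
  f_b <- blurred$frames$get(0, 0, 0)
  expect_true(blurred$truth$blur$blurred[1])
  expect_false(sharp$truth$blur$blurred[1])
  expect_lt(focus_score(f_b), focus_score(f_s))
})

test_that("presets encode the reference protocols", {
  st <- sim_preset("stability")
  expect_true(all(st$phase_schedule$release_fraction == 0))
  iv <- sim_preset("invitro_gsis")
  expect_identical(iv$phase_schedule$phase, c("low", "high", "low", "kcl"))
  expect_identical(iv$n_islets, 50L)
  expect_identical(sim_preset("invivo_fullpancreas")$n_islets, 200L)
  expect_error(sim_preset("no_such_preset"), "unknown preset")
  trunc <- sim_preset("invitro_gsis", phases = 1:2)
  expect_identical(nrow(trunc$phase_schedule), 2L)
  expect_identical(max(isletscope:::sim_time_points(trunc)), 30)
})

test_that("impossible islet placement raises an explicit error", {
  cfg <- tiny_config(n_islets = 40L, diameters_um = rep(30, 40L),
                     max_placement_attempts = 50L)
  expect_error(generate_experiment(cfg), "placement")
})
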