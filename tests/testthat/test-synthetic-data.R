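test_that("noiseless trace without events has R identically 1", {
  train <- default_train()
  tr <- gen_trace(trace_gen_config(noise_cv = 0, seed = 1), train,
                  responsive = FALSE, rupture_index = NA)
  r <- normalize_ratio(tr)
  expect_equal(r$r, rep(1, nrow(r)))
})

test_that("generator seeds make traces bit-identical", {
  train <- default_train()
  cfg <- trace_gen_config(seed = 42)
  t1 <- gen_trace(cfg, train, responsive = TRUE, activation_index = 3)
  t2 <- gen_trace(cfg, train, responsive = TRUE, activation_index = 3)
  expect_identical(t1$f340, t2$f340)
  expect_identical(t1$f380, t2$f380)
  c1 <- gen_cohort(cohort_spec("WT", 5, 0.4, seed = 9), trace_gen_config(), train)
  c2 <- gen_cohort(cohort_spec("WT", 5, 0.4, seed = 9), trace_gen_config(), train)
  expect_identical(lapply(c1, as.data.frame), lapply(c2, as.data.frame))
})

test_that("invalid activation/rupture ordering is rejected", {
  train <- default_train()
  cfg <- trace_gen_config(seed = 1)
  expect_error(gen_trace(cfg, train, responsive = TRUE, activation_index = 6,
                         rupture_index = 6), "precede")
  expect_error(gen_trace(cfg, train, responsive = TRUE), "activation_index")
})

test_that("responsive construction yields one detectable wide transient", {
  train <- default_train()
  cfg <- trace_gen_config(peak_ratio_amplitude = 3.0, peak_fwhm = 40, seed = 5)
  tr <- gen_trace(cfg, train, responsive = TRUE, activation_index = 4)
  r <- normalize_ratio(tr)
  ev <- detect_activation_peaks(r, tr, 2.5, rupture_time = detect_rupture(tr, r))
  expect_equal(nrow(ev), 1)
  expect_gte(ev$width_s, 30)
  gt <- attr(tr, "ground_truth")
  move_end <- train$t_start_s[4] + 2 * train$dt_s[4]
  expect_gte(gt$activation_time_s, move_end)
  expect_lte(gt$activation_time_s - move_end, 10 + cfg$peak_fwhm / 2)
})

test_that("unresponsive construction shows no excursion before the plateau", {
  train <- default_train()
  tr <- gen_trace(trace_gen_config(seed = 6), train, responsive = FALSE)
  r <- normalize_ratio(tr)
  pre <- r$r[r$time_s < attr(tr, "ground_truth")$rupture_time_s - 5]
  expect_lt(max(pre), 1.2) # nothing above baseline noise
  ev <- detect_activation_peaks(r, tr, 2.5, rupture_time = detect_rupture(tr, r))
  expect_equal(nrow(ev), 0)
})

test_that("rupture decays both channels and flattens the ratio", {
  train <- default_train()
  tr <- gen_trace(trace_gen_config(noise_cv = 0, seed = 1), train,
                  responsive = FALSE, rupture_index = 6)
  gt <- attr(tr, "ground_truth")
  tail_i <- tr$time_s > gt$rupture_time_s + 20
  expect_lt(max(tr$f340[tail_i]) / 800, 0.11)  # both channels near 10% floor
  expect_lt(max(tr$f380[tail_i]) / 1000, 0.11)
  r <- normalize_ratio(tr)
  expect_equal(sd(r$r[tail_i]), 0, tolerance = 1e-9) # ratio plateau
})

test_that("cohorts honour exact responsive counts and group rules", {
  train <- default_train()
  cfg <- trace_gen_config()
  coh <- gen_cohort(cohort_spec("WT", 10, 0.5, seed = 2), cfg, train)
  gt <- ground_truth(coh)
  expect_equal(sum(gt$responsive), 5)
  expect_warning(spec <- cohort_spec("CaFree", 8, 0.6), "unresponsive")
  expect_equal(spec$responsive_fraction, 0)
  gt_ca <- ground_truth(gen_cohort(spec, cfg, train))
  expect_equal(sum(gt_ca$responsive), 0)
  expect_error(cohort_spec("HEK", 5, 0.5), "unknown group")
  # activation indices drawn from the deeper half, before the terminal step
  coh2 <- gen_cohort(cohort_spec("Piezo1", 40, 1, seed = 3), cfg, train)
  idx <- ground_truth(coh2)$activation_index
  expect_true(all(idx %in% 3:5))
})

test_that("stage simulator is ideal at zero backlash/noise and reproducible", {
  cmds <- sawtooth_commands(5, 1, 2)
  ideal <- gen_stage_trajectory(stage_sim_config(0, 0), cmds)
  expect_equal(ideal$measured_um, ideal$target_um)
  cfg <- stage_sim_config(1, 1, position_noise_sd_um = 0.1,
                          step_noise_sd_nm = 5, seed = 77)
  t1 <- gen_stage_trajectory(cfg, cmds)
  t2 <- gen_stage_trajectory(cfg, cmds)
  expect_identical(t1$measured_um, t2$measured_um)
  expect_error(gen_stage_trajectory(cfg, numeric(0)), "empty")
})

test_that("phase maps realise the forward optical model and round-trip", {
  spec <- phase_map_spec(image_shape = c(96, 96), n_cells = 1, seed = 4)
  pm <- gen_phase_map(spec, tmax_um = 9.6)
  expect_equal(max(pm$phase), 2 * pi * 0.04 * 9.6 / 0.635, tolerance = 1e-12)
  expect_equal(max(pm$phase), 3.80, tolerance = 1e-3)
  # inverse recovers ground truth to machine precision without noise
  tm <- cell_tmax(pm$phase, pm$mask)
  expect_equal(tm$tmax_um, 9.6, tolerance = 1e-12)
  # flat map for zero thickness
  pm0 <- gen_phase_map(spec, tmax_um = 1e-12)
  expect_lt(max(abs(pm0$phase)), 1e-10)
  # determinism and placement failure
  pm2 <- gen_phase_map(spec, tmax_um = 9.6)
  expect_identical(pm$phase, pm2$phase)
  expect_error(gen_phase_map(phase_map_spec(image_shape = c(64, 64),
                                            n_cells = 50, seed = 1)),
               "place")
})

test_that("noisy phase maps recover thickness within propagated tolerance", {
  spec <- phase_map_spec(image_shape = c(128, 128), n_cells = 3,
                         phase_noise_sd = 0.02, seed = 8)
  pm <- gen_phase_map(spec, tmax_um = c(8, 9.6, 11))
  tm <- cell_tmax(pm$phase, pm$mask)
  tol <- phase_to_thickness(3 * spec$phase_noise_sd)
  expect_true(all(abs(tm$tmax_um - c(8, 9.6, 11)) <= tol))
})
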