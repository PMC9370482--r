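test_that("ratio normalization gives unit baseline and scale invariance", {
  train <- default_train()
  tr <- gen_trace(trace_gen_config(seed = 3), train, responsive = FALSE,
                  rupture_index = NA)
  r <- normalize_ratio(tr)
  expect_equal(mean(r$r[r$time_s < 10]), 1, tolerance = 1e-12)
  # identical channels: R identically 1
  same <- data.frame(time_s = seq(0, 30, 0.44), f340 = 500, f380 = 500)
  expect_equal(unique(normalize_ratio(same)$r), 1)
  # joint positive rescaling of both channels leaves R unchanged
  scaled <- tr
  scaled$f340 <- scaled$f340 * 3.7
  scaled$f380 <- scaled$f380 * 3.7
  expect_equal(normalize_ratio(scaled)$r, r$r, tolerance = 1e-12)
  # data errors
  bad <- same; bad$f380[4] <- -1
  expect_error(normalize_ratio(bad), "non-positive")
  expect_error(normalize_ratio(same, baseline_end = 0.5), "at least 5")
})

test_that("a doubled F340 bump with constant F380 gives peak R of 2", {
  tt <- seq(0, 200, 0.44)
  bump <- 1 + exp(-(tt - 120)^2 / (2 * (40 / 2.355)^2))
  tr <- data.frame(time_s = tt, f340 = 500 * bump, f380 = 800)
  r <- normalize_ratio(tr)
  expect_equal(max(r$r), 2, tolerance = 1e-3) # grid may straddle the apex
})

test_that("peak detection honours threshold, width and channel coincidence", {
  train <- default_train()
  # flat noisy trace: nothing detected
  flat <- gen_trace(trace_gen_config(seed = 10), train, responsive = FALSE,
                    rupture_index = NA)
  rf <- normalize_ratio(flat)
  expect_equal(nrow(detect_activation_peaks(rf, flat, 2.5)), 0)
  # configured transient: exactly one event
  tr <- gen_trace(trace_gen_config(peak_ratio_amplitude = 3.0, seed = 11),
                  train, responsive = TRUE, activation_index = 3)
  r <- normalize_ratio(tr)
  ev <- detect_activation_peaks(r, tr, 2.5,
                                rupture_time = detect_rupture(tr, r))
  expect_equal(nrow(ev), 1)
  expect_gt(ev$peak_r, 2.5)
  expect_gte(ev$width_s, 30)
  expect_lte(abs(ev$t_f340_s - ev$peak_time_s), 2)
  expect_lte(abs(ev$t_f380_s - ev$peak_time_s), 2)
  # the same amplitude compressed to 10 s FWHM fails the width rule
  nar <- gen_trace(trace_gen_config(peak_fwhm = 10, seed = 11), train,
                   responsive = TRUE, activation_index = 3)
  rn <- normalize_ratio(nar)
  expect_equal(nrow(detect_activation_peaks(rn, nar, 2.5,
                                            rupture_time = detect_rupture(nar, rn))), 0)
})

test_that("rupture detection requires a dual-channel drop plus flat ratio", {
  train <- default_train()
  # both channels constant: no rupture
  const <- data.frame(time_s = seq(0, 300, 0.44), f340 = 500, f380 = 800)
  expect_true(is.na(detect_rupture(const)))
  # synthetic rupture is localised within +/- 5 s
  tr <- gen_trace(trace_gen_config(seed = 12), train, responsive = FALSE,
                  rupture_index = 5)
  truth <- attr(tr, "ground_truth")$rupture_time_s
  expect_lt(abs(detect_rupture(tr) - truth), 5)
  # a single-channel drop (F380 dip of a transient) is not rupture
  tt <- seq(0, 300, 0.44)
  dip <- 1 - 0.6 * exp(-(tt - 150)^2 / (2 * 17^2))
  one <- data.frame(time_s = tt, f340 = 500, f380 = 800 * dip)
  expect_true(is.na(detect_rupture(one)))
})

test_that("cells are classified with the activation depth of their step", {
  train <- default_train()
  cfg <- trace_gen_config()
  depths <- depth_map(train, 9.4)
  coh <- gen_cohort(cohort_spec("Piezo1", 30, 0.5, seed = 14), cfg, train)
  gt <- ground_truth(coh)
  cls <- classify_cohort(coh, train, depths = depths, r_threshold = 2.5)
  hit <- gt$responsive & cls$responsive
  expect_equal(cls$activation_index[hit], gt$activation_index[hit])
  expect_equal(cls$activation_delta_um[hit],
               depths$delta_um[gt$activation_index[hit]])
  expect_true(all(is.na(cls$activation_delta_um[!cls$responsive])))
  # no activation events after rupture
  expect_true(all(cls$activation_time_s[hit] < cls$rupture_time_s[hit]))
})

test_that("classifier reaches 95% sensitivity and specificity on a seeded cohort", {
  train <- default_train()
  cfg <- trace_gen_config(peak_ratio_amplitude = 3.0, peak_fwhm = 40,
                          noise_cv = 0.02)
  coh <- gen_cohort(cohort_spec("Piezo1", 100, 0.5, seed = 15), cfg, train)
  gt <- ground_truth(coh)
  cls <- classify_cohort(coh, train, r_threshold = 2.5, tmax_mean = 9.4)
  sens <- mean(cls$responsive[gt$responsive])
  spec <- mean(!cls$responsive[!gt$responsive])
  expect_gte(sens, 0.95)
  expect_gte(spec, 0.95)
})

test_that("raising the threshold never converts unresponsive to responsive", {
  train <- default_train()
  coh <- gen_cohort(cohort_spec("WT", 20, 0.5, seed = 16),
                    trace_gen_config(), train)
  low <- classify_cohort(coh, train, r_threshold = 1.8, tmax_mean = 9.4)
  high <- classify_cohort(coh, train, r_threshold = 2.8, tmax_mean = 9.4)
  expect_true(all(low$responsive >= high$responsive))
})

test_that("calcium-free cells stay unresponsive at any threshold above noise", {
  train <- default_train()
  coh <- gen_cohort(suppressWarnings(cohort_spec("CaFree", 20, 0, seed = 17)),
                    trace_gen_config(), train)
  for (rt in c(1.5, 2.5, 3.5)) {
    cls <- classify_cohort(coh, train, r_threshold = rt, tmax_mean = 9.4)
    expect_equal(sum(cls$responsive), 0)
  }
})
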