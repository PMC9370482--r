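make_cls <- function(responsive, index = NA_integer_, group = "WT",
                     delta = NA_real_, peak = ifelse(responsive, 3, NA)) {
  n <- length(responsive)
  if (n == 0) return(make_cls(FALSE, index, group, delta, peak)[0, ])
  data.frame(cell_id = sprintf("c%02d", seq_len(n)), group = group,
             responsive = responsive,
             activation_index = rep_len(index, n),
             activation_delta_um = rep_len(delta, n),
             activation_time_s = NA_real_, peak_r = rep_len(peak, n),
             max_peak_r = rep_len(peak, n), rupture_time_s = NA_real_)
}

test_that("activation rate is the responsive percentage", {
  expect_equal(activation_rate(make_cls(rep(FALSE, 7))), 0)
  expect_equal(activation_rate(make_cls(rep(c(TRUE, FALSE), 5))), 50)
  expect_error(activation_rate(make_cls(logical(0))), "empty")
})

test_that("depth histogram bins responsive cells and conserves AR", {
  depths <- depth_map(default_train(), 9.4)
  cls <- make_cls(c(TRUE, TRUE, TRUE, FALSE), index = c(4L, 4L, 6L, NA))
  h <- activation_rate_at_depth(cls, depths)
  expect_equal(sum(h$ar_delta_percent), activation_rate(cls))
  expect_equal(h$ar_delta_percent[h$delta_um == depths$delta_um[4] &
                                    !is.na(h$delta_um)], 50)
  # all responsive at one depth: that bin carries the whole AR
  one <- make_cls(rep(TRUE, 4), index = 5L)
  h1 <- activation_rate_at_depth(one, depths)
  expect_equal(h1$ar_delta_percent[!is.na(h1$delta_um)][
    which(depths$index[depths$contact] == 5)], 100)
  # no responsive cells: all bins zero
  h0 <- activation_rate_at_depth(make_cls(rep(FALSE, 3)), depths)
  expect_true(all(h0$ar_delta_percent == 0))
  # unassigned responsive cells go to the NA bin with a warning
  expect_warning(hu <- activation_rate_at_depth(
    make_cls(TRUE, index = NA_integer_), depths), "unassigned")
  expect_equal(hu$ar_delta_percent[is.na(hu$delta_um)], 100)
})

test_that("ground-truth activation steps reappear as occupied depth bins", {
  train <- default_train()
  depths <- depth_map(train, 9.4)
  coh <- gen_cohort(cohort_spec("Piezo1", 30, 0.6,
                                responsive_depth_index = 3:5, seed = 31),
                    trace_gen_config(), train)
  gt <- ground_truth(coh)
  cls <- classify_cohort(coh, train, depths = depths, r_threshold = 2.5)
  h <- activation_rate_at_depth(cls, depths)
  occupied <- h$delta_um[h$ar_delta_percent > 0 & !is.na(h$delta_um)]
  expect_setequal(round(occupied, 9),
                  round(depths$delta_um[sort(unique(gt$activation_index[gt$responsive]))], 9))
  expect_equal(sum(h$ar_delta_percent), activation_rate(cls))
})

test_that("threshold sweep is monotone and vanishes above the peak amplitude", {
  train <- default_train()
  cfg <- trace_gen_config(peak_ratio_amplitude = 3.0)
  cohorts <- list(
    Piezo1 = gen_cohort(cohort_spec("Piezo1", 15, 0.6, seed = 32), cfg, train),
    CaFree = gen_cohort(suppressWarnings(cohort_spec("CaFree", 10, 0, seed = 33)),
                        cfg, train))
  sw <- threshold_sweep(cohorts, train, tmax_mean = 9.4)
  for (g in unique(sw$group)) {
    curve <- sw$ar_percent[sw$group == g][order(sw$rt[sw$group == g])]
    expect_true(all(diff(curve) <= 0))
  }
  pz <- sw[sw$group == "Piezo1", ]
  expect_true(all(pz$ar_percent[pz$rt > 3.05] == 0))
  ca <- sw[sw$group == "CaFree", ]
  expect_true(all(ca$ar_percent[ca$rt >= 1.5] == 0))
  expect_error(threshold_sweep(unname(cohorts), train, tmax_mean = 9.4), "named")
  expect_error(threshold_sweep(cohorts, train, tmax_mean = 9.4,
                               grid = c(0, 5)), "4.5")
})

test_that("threshold selection takes the median of the stable interval", {
  grid <- seq(0, 4.5, 0.1)
  mk <- function(group, ar) data.frame(group = group, rt = grid, ar_percent = ar)
  ctrl <- ifelse(grid < 1.5, 60, 0)
  piezo <- ifelse(grid < 3.5 + 1e-9, 40, 0) # responds up to and at 3.5
  sweep <- rbind(mk("CaFree", ctrl), mk("Piezo1", piezo))
  sel <- select_threshold(sweep, "CaFree")
  expect_equal(as.numeric(sel), 2.5)
  expect_equal(attr(sel, "lower"), 1.5)
  expect_equal(attr(sel, "upper"), 3.5)
  # degenerate interval: bounds coincide
  only <- rbind(mk("CaFree", ifelse(grid < 2.0, 10, 0)),
                mk("Piezo1", ifelse(grid < 2.0, 40, 0)))
  degen <- select_threshold(only, "CaFree")
  expect_equal(as.numeric(degen), 2.0)
  # control never silent: selection error
  noisy <- rbind(mk("CaFree", rep(5, length(grid))), mk("Piezo1", piezo))
  expect_error(select_threshold(noisy, "CaFree"), "never reaches 0")
  expect_error(select_threshold(sweep, "Locke"), "not present")
})

test_that("an end-to-end sweep on a constructed study recovers R_T = 2.5", {
  train <- default_train()
  # responsive transients peak at 3.55 (inside the (3.5, 3.6] grid cell);
  # control cells carry wide spurious excursions up to 1.45 (inside
  # (1.4, 1.5]); low frame noise keeps grid-cell membership unambiguous
  cfg <- trace_gen_config(noise_cv = 0.005, peak_ratio_amplitude = 3.55)
  cohorts <- list(
    Piezo1 = gen_cohort(cohort_spec("Piezo1", 12, 0.5, seed = 34), cfg, train),
    CaFree = gen_cohort(suppressWarnings(
      cohort_spec("CaFree", 12, 0, artifact_amplitude = 1.45, seed = 35)),
      cfg, train))
  sw <- threshold_sweep(cohorts, train, tmax_mean = 9.4)
  sel <- select_threshold(sw, "CaFree")
  expect_equal(as.numeric(sel), 2.5)
  expect_equal(attr(sel, "lower"), 1.5)
  expect_equal(attr(sel, "upper"), 3.5)
})

test_that("cohort AR recovers the generating responsive fraction", {
  train <- default_train()
  cfg <- trace_gen_config()
  for (case in list(list(p = 0.18, n = 33), list(p = 0.32, n = 28))) {
    ars <- vapply(1:20, function(i) {
      coh <- gen_cohort(cohort_spec("WT", case$n, case$p, seed = 100 + i),
                        cfg, train)
      activation_rate(classify_cohort(coh, train, r_threshold = 2.5,
                                      tmax_mean = 9.4))
    }, numeric(1))
    se <- 100 * sqrt(case$p * (1 - case$p) / case$n)
    expect_lt(abs(mean(ars) - 100 * case$p), 2 * se)
  }
})

test_that("the report aggregates, prints and round-trips through JSON", {
  train <- default_train()
  depths <- depth_map(train, 9.4)
  cfg <- trace_gen_config()
  cohorts <- list(
    Piezo1 = gen_cohort(cohort_spec("Piezo1", 8, 0.5, seed = 36), cfg, train),
    CaFree = gen_cohort(suppressWarnings(cohort_spec("CaFree", 6, 0, seed = 37)),
                        cfg, train))
  sw <- threshold_sweep(cohorts, train, depths = depths)
  cls <- do.call(rbind, lapply(names(cohorts), function(g)
    classify_cohort(cohorts[[g]], train, depths = depths, r_threshold = 2.5)))
  rep <- build_report(cls, sw, 2.5, depths, provenance = list(seed = 36))
  expect_equal(rep$groups$Piezo1$ar_percent,
               sum(rep$groups$Piezo1$ar_delta$ar_delta_percent))
  expect_output(print(rep), "R_T = 2.50")
  # single responsive cell: AR 100, one occupied bin
  one <- build_report(make_cls(TRUE, index = 5L, group = "WT"), sw, 2.5, depths)
  expect_equal(one$groups$WT$ar_percent, 100)
  expect_equal(sum(one$groups$WT$ar_delta$ar_delta_percent > 0), 1)
  # file round-trip
  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  back <- read_report_json(f)
  expect_equal(back$selected_rt, rep$selected_rt)
  expect_equal(back$groups$Piezo1$ar_percent, rep$groups$Piezo1$ar_percent)
  expect_equal(as.data.frame(back$sweep), as.data.frame(rep$sweep))
})
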