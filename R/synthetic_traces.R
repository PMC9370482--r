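#' Trace generator configuration
#'
#' Parameters of the synthetic dual-channel (F340/F380) fluorescence trace
#' generator. An activation transient is a Gaussian-in-time kernel applied
#' anti-correlated to the two channels (F340 up, F380 down) so that the
#' normalized ratio R reaches `peak_ratio_amplitude` at the peak; membrane
#' rupture is a simultaneous exponential decay of both channels to 10% of
#' baseline, leaving R flat.
#'
#' @param sampling_interval Ratio sampling interval (s); 0.44 s corresponds
#'   to 220 ms exposures on each of the two excitation channels.
#' @param baseline_f340,baseline_f380 Baseline channel intensities
#'   (arbitrary units). The ratio analysis is independent of their values.
#' @param noise_cv Multiplicative Gaussian noise coefficient of variation
#'   per frame per channel.
#' @param peak_fwhm Full width at half maximum of the activation transient (s).
#' @param peak_ratio_amplitude Target maximum of the normalized ratio R at
#'   the transient peak.
#' @param rupture_decay_tau Time constant (s) of the post-rupture decay.
#' @param seed Optional integer seed.
#' @return An object of class `trace_gen_config`.
#' @export
trace_gen_config <- function(sampling_interval = 0.44,
                             baseline_f340 = 800, baseline_f380 = 1000,
                             noise_cv = 0.02, peak_fwhm = 40,
                             peak_ratio_amplitude = 3.0,
                             rupture_decay_tau = 3, seed = NULL) {
  if (sampling_interval <= 0) stop("sampling_interval must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (peak_fwhm <= 0) stop("peak_fwhm must be > 0", call. = FALSE)
  if (baseline_f340 <= 0 || baseline_f380 <= 0)
    stop("baseline intensities must be > 0", call. = FALSE)
  if (peak_ratio_amplitude <= 1)
    stop("peak_ratio_amplitude must be > 1", call. = FALSE)
  if (rupture_decay_tau <= 0) stop("rupture_decay_tau must be > 0", call. = FALSE)
  structure(list(sampling_interval = sampling_interval,
                 baseline_f340 = baseline_f340, baseline_f380 = baseline_f380,
                 noise_cv = noise_cv, peak_fwhm = peak_fwhm,
                 peak_ratio_amplitude = peak_ratio_amplitude,
                 rupture_decay_tau = rupture_decay_tau, seed = seed),
            class = "trace_gen_config")
}

# Gaussian kernel in time, unit peak
gauss_kernel <- function(t, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-(t - center)^2 / (2 * sigma^2))
}

# anti-correlated channel multipliers achieving ratio amplitude A at k = 1:
# F340 scaled by sqrt(A), F380 by 1/sqrt(A)
transient_multipliers <- function(k, amplitude) {
  a340 <- sqrt(amplitude) - 1
  a380 <- 1 - 1 / sqrt(amplitude)
  list(m340 = 1 + a340 * k, m380 = 1 - a380 * k)
}

#' Generate one synthetic dual-channel fluorescence trace
#'
#' Builds a time-stamped F340/F380 trace spanning an indentation train. A
#' responsive cell shows a single activation transient: its onset is drawn
#' uniformly within `latency_max_s` after the activating indentation's
#' down-and-up travel ends, and the Gaussian peak sits half an FWHM later.
#' All cells rupture at `rupture_index` (both channels decay together; the
#' ratio stays flat). An optional low-amplitude `artifact_amplitude`
#' excursion, labelled non-responsive in the ground truth, emulates the
#' noise/store-release regime seen below the useful threshold range.
#'
#' @param config A [trace_gen_config()].
#' @param train An [build_train()] indentation train.
#' @param responsive Logical: does the cell show an activation transient?
#' @param activation_index Index of the activating indentation (required when
#'   `responsive`); must precede `rupture_index`.
#' @param rupture_index Index of the rupturing indentation, or `NA` for no
#'   rupture.
#' @param artifact_amplitude Peak R amplitude of a spurious wide excursion
#'   (0 disables; must stay below the working threshold range to be an
#'   artifact rather than a fake activation).
#' @param cell_id,group Labels attached to the trace.
#' @param duration Total trace duration (s); default covers the train plus a
#'   30 s tail.
#' @param latency_max_s Upper bound of the uniform activation latency (s).
#' @return A data frame of class `dual_channel_trace` with columns `time_s`,
#'   `f340`, `f380` and attributes `cell_id`, `group`, `ground_truth`.
#' @export
gen_trace <- function(config, train, responsive = FALSE,
                      activation_index = NA, rupture_index = nrow(train),
                      artifact_amplitude = 0, cell_id = "cell_1",
                      group = "WT", duration = NULL, latency_max_s = 10) {
  stopifnot(inherits(config, "trace_gen_config"),
            inherits(train, "indentation_train"))
  if (isTRUE(responsive)) {
    if (is.na(activation_index))
      stop("responsive traces need an activation_index", call. = FALSE)
    if (!is.na(rupture_index) && activation_index >= rupture_index)
      stop("activation_index must precede rupture_index", call. = FALSE)
  }
  if (is.null(duration)) duration <- train_end_time(train) + 30
  tt <- seq(0, duration, by = config$sampling_interval)

  build <- function() {
    m340 <- rep(1, length(tt))
    m380 <- rep(1, length(tt))
    activation_time <- NA_real_
    artifact_time <- NA_real_
    rupture_time <- NA_real_
    if (!is.na(rupture_index))
      rupture_time <- train$t_start_s[rupture_index] + train$dt_s[rupture_index]
    if (isTRUE(responsive)) {
      move_end <- train$t_start_s[activation_index] + 2 * train$dt_s[activation_index]
      onset <- move_end + stats::runif(1, 0, latency_max_s)
      activation_time <- onset + config$peak_fwhm / 2
      k <- gauss_kernel(tt, activation_time, config$peak_fwhm)
      tm <- transient_multipliers(k, config$peak_ratio_amplitude)
      m340 <- m340 * tm$m340
      m380 <- m380 * tm$m380
    }
    if (artifact_amplitude > 1) {
      t_lo <- train$t_start_s[1]
      t_hi <- max(t_lo + 1, (if (is.na(rupture_time)) duration else rupture_time) -
                    1.5 * config$peak_fwhm)
      artifact_time <- stats::runif(1, t_lo, t_hi)
      k <- gauss_kernel(tt, artifact_time, config$peak_fwhm)
      tm <- transient_multipliers(k, artifact_amplitude)
      m340 <- m340 * tm$m340
      m380 <- m380 * tm$m380
    }
    if (!is.na(rupture_time)) {
      post <- tt >= rupture_time
      decay <- 0.1 + 0.9 * exp(-(tt[post] - rupture_time) / config$rupture_decay_tau)
      m340[post] <- m340[post] * decay
      m380[post] <- m380[post] * decay
    }
    noise <- function(n) if (config$noise_cv > 0)
      pmax(1 + stats::rnorm(n, 0, config$noise_cv), 1e-6) else rep(1, n)
    f340 <- config$baseline_f340 * m340 * noise(length(tt))
    f380 <- config$baseline_f380 * m380 * noise(length(tt))
    list(f340 = f340, f380 = f380,
         activation_time = activation_time, artifact_time = artifact_time,
         rupture_time = rupture_time)
  }
  sim <- with_seed(config$seed, build())

  trace <- data.frame(time_s = tt, f340 = sim$f340, f380 = sim$f380)
  attr(trace, "cell_id") <- cell_id
  attr(trace, "group") <- group
  attr(trace, "ground_truth") <- list(
    responsive = isTRUE(responsive),
    activation_index = if (isTRUE(responsive)) activation_index else NA_integer_,
    rupture_index = rupture_index,
    activation_time_s = sim$activation_time,
    rupture_time_s = sim$rupture_time,
    artifact_time_s = sim$artifact_time)
  class(trace) <- c("dual_channel_trace", "data.frame")
  trace
}

#' Cohort specification
#'
#' @param group_name One of `"WT"`, `"Piezo1"`, `"CaFree"`, `"GsMTx4"`.
#'   The calcium-free group is forced to a zero responsive fraction: with no
#'   extracellular calcium there is no influx on channel opening.
#' @param n_cells Number of cells.
#' @param responsive_fraction Probability in `[0, 1]`; exactly
#'   `round(n_cells * responsive_fraction)` cells are made responsive.
#' @param responsive_depth_index Optional fixed activation step index (or a
#'   vector of eligible indices to draw from) for responsive cells; default
#'   draws uniformly over the deeper half of the train excluding the
#'   terminal (rupturing) step.
#' @param artifact_amplitude Per-cell spurious excursion amplitude passed to
#'   [gen_trace()] (0 disables).
#' @param seed Optional integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_name, n_cells, responsive_fraction,
                        responsive_depth_index = NULL,
                        artifact_amplitude = 0, seed = NULL) {
  known <- c("WT", "Piezo1", "CaFree", "GsMTx4")
  if (!group_name %in% known)
    stop("unknown group label '", group_name, "'; expected one of ",
         paste(known, collapse = ", "), call. = FALSE)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (responsive_fraction < 0 || responsive_fraction > 1)
    stop("responsive_fraction must be in [0, 1]", call. = FALSE)
  if (group_name == "CaFree" && responsive_fraction > 0) {
    warning("CaFree group is always unresponsive; forcing responsive_fraction = 0",
            call. = FALSE)
    responsive_fraction <- 0
  }
  structure(list(group_name = group_name, n_cells = as.integer(n_cells),
                 responsive_fraction = responsive_fraction,
                 responsive_depth_index = responsive_depth_index,
                 artifact_amplitude = artifact_amplitude, seed = seed),
            class = "cohort_spec")
}

#' Generate a cohort of synthetic traces
#'
#' Exactly `round(n_cells * responsive_fraction)` traces are responsive;
#' which cells, and their activation steps and latencies, are drawn under
#' the cohort seed, so identical seeds give identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param config A [trace_gen_config()] (its own `seed` is ignored; the
#'   cohort seed governs).
#' @param train An [build_train()] indentation train.
#' @return A list of `dual_channel_trace` objects of class `trace_cohort`.
#' @export
gen_cohort <- function(spec, config, train) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "trace_gen_config"))
  config$seed <- NULL
  n <- spec$n_cells
  n_steps <- nrow(train)
  eligible <- spec$responsive_depth_index
  if (is.null(eligible)) {
    eligible <- seq(max(2L, n_steps %/% 2L), max(1L, n_steps - 1L))
  }
  build <- function() {
    n_resp <- round(n * spec$responsive_fraction)
    resp <- rep(FALSE, n)
    if (n_resp > 0) resp[sample.int(n, n_resp)] <- TRUE
    lapply(seq_len(n), function(i) {
      ai <- if (resp[i]) {
        if (length(eligible) == 1) eligible else sample(eligible, 1)
      } else NA_integer_
      gen_trace(config, train, responsive = resp[i], activation_index = ai,
                rupture_index = n_steps,
                artifact_amplitude = spec$artifact_amplitude,
                cell_id = sprintf("%s_%03d", spec$group_name, i),
                group = spec$group_name)
    })
  }
  traces <- with_seed(spec$seed, build())
  structure(traces, class = "trace_cohort", group = spec$group_name)
}

#' Ground-truth table of a cohort or trace list
#'
#' @param traces A `trace_cohort` or list of `dual_channel_trace` objects.
#' @return Data frame with one row per cell: `cell_id`, `group`,
#'   `responsive`, `activation_index`, `rupture_index`, `activation_time_s`,
#'   `rupture_time_s`.
#' @export
ground_truth <- function(traces) {
  rows <- lapply(traces, function(tr) {
    gt <- attr(tr, "ground_truth")
    data.frame(cell_id = attr(tr, "cell_id"), group = attr(tr, "group"),
               responsive = gt$responsive,
               activation_index = gt$activation_index,
               rupture_index = gt$rupture_index,
               activation_time_s = gt$activation_time_s,
               rupture_time_s = gt$rupture_time_s)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
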