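#' Stage simulator configuration
#'
#' Parameters of the simulated screw-driven stepper stage used to emulate
#' interferometric calibration runs: direction-dependent backlash (lost
#' motion traversed in full at every direction reversal), nominal
#' single-step displacements for the two motion directions, an accumulating
#' per-step noise and a white positioning/measurement noise.
#'
#' @param true_backlash_pos_neg,true_backlash_neg_pos Injected backlash
#'   magnitudes (um) for +/- and -/+ reversals.
#' @param nominal_step_pos_nm,nominal_step_neg_nm Nominal single motor-step
#'   displacement (nm) in the + and - directions.
#' @param step_noise_sd_nm Standard deviation (nm) of the per-motor-step
#'   displacement noise; accumulates as a random walk along the trajectory.
#' @param position_noise_sd_um Standard deviation (um) of white
#'   positioning/measurement noise, independent per record.
#' @param seed Optional integer seed.
#' @return An object of class `stage_sim_config`.
#' @export
stage_sim_config <- function(true_backlash_pos_neg = 3.7,
                             true_backlash_neg_pos = 3.1,
                             nominal_step_pos_nm = 21.1,
                             nominal_step_neg_nm = 18.9,
                             step_noise_sd_nm = 0,
                             position_noise_sd_um = 0,
                             seed = NULL) {
  if (true_backlash_pos_neg < 0 || true_backlash_neg_pos < 0)
    stop("backlash values must be >= 0", call. = FALSE)
  if (step_noise_sd_nm < 0 || position_noise_sd_um < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (nominal_step_pos_nm <= 0 || nominal_step_neg_nm <= 0)
    stop("nominal steps must be > 0", call. = FALSE)
  structure(list(true_backlash_pos_neg = true_backlash_pos_neg,
                 true_backlash_neg_pos = true_backlash_neg_pos,
                 nominal_step_pos_nm = nominal_step_pos_nm,
                 nominal_step_neg_nm = nominal_step_neg_nm,
                 step_noise_sd_nm = step_noise_sd_nm,
                 position_noise_sd_um = position_noise_sd_um,
                 seed = seed),
            class = "stage_sim_config")
}

#' Saw-tooth calibration command sequence
#'
#' The standard calibration pattern: `n_steps` displacements of `step_um`
#' forward then the same back down, the whole cycle repeated `repeats`
#' times. Position indices are shared between the two legs so approaches
#' from both directions to the same position can be paired.
#'
#' @param n_steps Number of forward steps per leg.
#' @param step_um Commanded displacement per step (um).
#' @param repeats Number of saw-tooth repeats.
#' @return Data frame with columns `repeat_idx`, `position_index`,
#'   `direction`, `target_um`.
#' @export
sawtooth_commands <- function(n_steps = 20, step_um = 1, repeats = 3) {
  stopifnot(n_steps >= 1, repeats >= 1, step_um > 0)
  one <- rbind(
    data.frame(position_index = seq_len(n_steps), direction = "+",
               target_um = step_um * seq_len(n_steps)),
    data.frame(position_index = (n_steps - 1):0, direction = "-",
               target_um = step_um * ((n_steps - 1):0))
  )
  out <- do.call(rbind, lapply(seq_len(repeats), function(r)
    cbind(repeat_idx = r, one)))
  rownames(out) <- NULL
  out
}

#' Simulate a stage trajectory with backlash and noise
#'
#' The measured position is the commanded position plus a hysteresis offset
#' (the full direction-dependent backlash is traversed at every reversal;
#' the stage lags behind the commanded motion), plus accumulated per-step
#' noise and white positioning noise. With zero backlash and zero noise the
#' measured positions equal the commands exactly.
#'
#' If the commands carry a `command_um` column (from [apply_overshoot()]),
#' the stage is driven with the corrected commands while deviations remain
#' referenced to `target_um`.
#'
#' @param config A [stage_sim_config()].
#' @param commands Data frame from [sawtooth_commands()] (optionally passed
#'   through [apply_overshoot()]), or a numeric vector of target positions
#'   (um) treated as a single repeat.
#' @param start_um Starting stage position (um).
#' @param initial_direction Direction of the motion that reached the start
#'   position.
#' @return A [stage_trajectory()].
#' @export
gen_stage_trajectory <- function(config, commands, start_um = 0,
                                 initial_direction = "+") {
  stopifnot(inherits(config, "stage_sim_config"))
  if (!is.data.frame(commands)) {
    if (length(commands) == 0) stop("command sequence is empty", call. = FALSE)
    d <- c(commands[1] - start_um, diff(commands))
    dirs <- ifelse(d >= 0, "+", "-")
    commands <- data.frame(repeat_idx = 1L,
                           position_index = seq_along(commands),
                           direction = dirs, target_um = commands)
  }
  if (nrow(commands) == 0) stop("command sequence is empty", call. = FALSE)
  cmd <- if ("command_um" %in% names(commands)) commands$command_um else commands$target_um

  run <- function() {
    n <- length(cmd)
    measured <- numeric(n)
    offset <- 0
    walk <- 0
    dir <- initial_direction
    prev <- start_um
    for (i in seq_len(n)) {
      step <- cmd[i] - prev
      new_dir <- if (step > 0) "+" else if (step < 0) "-" else dir
      if (dir == "+" && new_dir == "-") offset <- offset + config$true_backlash_pos_neg
      if (dir == "-" && new_dir == "+") offset <- offset - config$true_backlash_neg_pos
      dir <- new_dir
      if (config$step_noise_sd_nm > 0 && step != 0) {
        nominal <- if (dir == "+") config$nominal_step_pos_nm else config$nominal_step_neg_nm
        n_motor <- max(1, round(abs(step) * 1000 / nominal))
        walk <- walk + stats::rnorm(1, 0, config$step_noise_sd_nm * sqrt(n_motor) / 1000)
      }
      white <- if (config$position_noise_sd_um > 0)
        stats::rnorm(1, 0, config$position_noise_sd_um) else 0
      measured[i] <- cmd[i] + offset + walk + white
      prev <- cmd[i]
    }
    measured
  }
  measured <- if (is.null(config$seed)) run() else with_seed(config$seed, run())
  stage_trajectory(commands$repeat_idx, commands$position_index,
                   commands$direction, commands$target_um, measured)
}
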