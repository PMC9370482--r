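#' Assemble a stage trajectory table
#'
#' A stage trajectory records, for every commanded position of a calibration
#' run, the repeat index, the position index along the axis, the approach
#' direction (`"+"` or `"-"`), the target position and the measured
#' (interferometric) position, all in micrometres.
#'
#' @param repeat_idx Integer repeat index (1..m).
#' @param position_index Integer position index along the axis.
#' @param direction Approach direction, `"+"` or `"-"`.
#' @param target_um Commanded position (um).
#' @param measured_um Measured position (um).
#' @return A data frame of class `stage_trajectory`.
#' @export
stage_trajectory <- function(repeat_idx, position_index, direction,
                             target_um, measured_um) {
  direction <- as.character(direction)
  if (!all(direction %in% c("+", "-")))
    stop("direction must be '+' or '-'", call. = FALSE)
  df <- data.frame(repeat_idx = as.integer(repeat_idx),
                   position_index = as.integer(position_index),
                   direction = direction,
                   target_um = target_um, measured_um = measured_um)
  key <- paste(df$repeat_idx, df$position_index, df$direction)
  if (anyDuplicated(key))
    stop("duplicate (repeat, position, direction) records", call. = FALSE)
  class(df) <- c("stage_trajectory", "data.frame")
  df
}

#' Per-position, per-direction mean deviations and standard uncertainties
#'
#' For each target position and approach direction, computes the arithmetic
#' mean over repeats of the deviation (measured - target), `zbar`, and the
#' sample standard deviation over repeats, `sigma` (0 when only one repeat is
#' available).
#'
#' @param traj A [stage_trajectory()].
#' @return Data frame with columns `position_index`, `direction`, `zbar_um`,
#'   `sigma_um`, `n`.
#' @export
deviations <- function(traj) {
  dev <- traj$measured_um - traj$target_um
  key <- interaction(traj$position_index, traj$direction, drop = TRUE)
  zbar <- tapply(dev, key, mean)
  sig <- tapply(dev, key, function(x) if (length(x) > 1) stats::sd(x) else 0)
  n <- tapply(dev, key, length)
  parts <- do.call(rbind, strsplit(names(zbar), ".", fixed = TRUE))
  out <- data.frame(position_index = as.integer(parts[, 1]),
                    direction = parts[, 2],
                    zbar_um = as.numeric(zbar), sigma_um = as.numeric(sig),
                    n = as.integer(n))
  out[order(out$position_index, out$direction), , drop = FALSE]
}

#' Bidirectional systematic positioning deviation E
#'
#' `E = max(zbar_i+, zbar_i-) - min(zbar_i+, zbar_i-)`: the span of the
#' per-position mean deviations over both approach directions.
#'
#' @param traj A [stage_trajectory()].
#' @return E in um (non-negative).
#' @export
bidirectional_systematic_error <- function(traj) {
  dv <- deviations(traj)
  if (length(unique(dv$direction)) < 2)
    stop("both approach directions are required to compute E", call. = FALSE)
  max(dv$zbar_um) - min(dv$zbar_um)
}

#' Estimate direction-dependent backlash from a bidirectional trajectory
#'
#' Backlash (lost motion at a direction reversal) is estimated from
#' positions approached from both directions. Within one saw-tooth repeat the
#' forward (+) approach to position i precedes the backward (-) approach,
#' with the +/- reversal between them, so `dz_i(+-) = z_i(+) - z_i(-)`
#' estimates the +/- backlash. The -/+ reversal lies between the backward leg
#' of repeat r and the forward leg of repeat r+1, so `dz_i(-+) = z_i(-, r) -
#' z_i(+, r+1)` estimates the -/+ backlash. Both are averaged over positions
#' and repeats and reported as magnitudes.
#'
#' @param traj A [stage_trajectory()].
#' @return Named numeric vector `c(B_pos_neg = , B_neg_pos = )` in um.
#'   `B_neg_pos` is `NA` when the trajectory has a single repeat (no -/+
#'   reversal is observed between comparable approaches).
#' @export
estimate_backlash <- function(traj) {
  dev <- traj$measured_um - traj$target_um
  reps <- sort(unique(traj$repeat_idx))
  pick <- function(r, dir) {
    sel <- traj$repeat_idx == r & traj$direction == dir
    stats::setNames(dev[sel], traj$position_index[sel])
  }
  dz_pn <- dz_np <- numeric(0)
  for (r in reps) {
    zp <- pick(r, "+"); zm <- pick(r, "-")
    common <- intersect(names(zp), names(zm))
    dz_pn <- c(dz_pn, zp[common] - zm[common])
    if ((r + 1) %in% reps) {
      zp_next <- pick(r + 1, "+")
      common <- intersect(names(zm), names(zp_next))
      dz_np <- c(dz_np, zm[common] - zp_next[common])
    }
  }
  if (length(dz_pn) == 0)
    stop("no positions approached from both directions", call. = FALSE)
  c(B_pos_neg = abs(mean(dz_pn)),
    B_neg_pos = if (length(dz_np)) abs(mean(dz_np)) else NA_real_)
}

#' Plan an integer-step overshoot correction
#'
#' Converts backlash magnitudes into integer motor-step counts by which the
#' first move after each direction reversal is extended. The nominal single
#' step differs between the two motion directions of the screw.
#'
#' @param b_pos_neg,b_neg_pos Backlash magnitudes (um) for the +/- and -/+
#'   reversals.
#' @param step_pos_nm,step_neg_nm Nominal single-step displacement (nm) used
#'   to quantise the respective correction.
#' @return An object of class `overshoot_plan` with fields `steps_pos_neg`,
#'   `steps_neg_pos`, `step_pos_nm`, `step_neg_nm`.
#' @examples
#' plan_overshoot(3.7, 3.1) # 175 and 164 steps
#' @export
plan_overshoot <- function(b_pos_neg, b_neg_pos,
                           step_pos_nm = 21.1, step_neg_nm = 18.9) {
  if (step_pos_nm <= 0 || step_neg_nm <= 0)
    stop("nominal step sizes must be > 0", call. = FALSE)
  if (b_pos_neg < 0 || b_neg_pos < 0)
    stop("backlash magnitudes must be >= 0", call. = FALSE)
  structure(list(steps_pos_neg = round(b_pos_neg * 1000 / step_pos_nm),
                 steps_neg_pos = round(b_neg_pos * 1000 / step_neg_nm),
                 step_pos_nm = step_pos_nm, step_neg_nm = step_neg_nm),
            class = "overshoot_plan")
}

#' Apply an overshoot plan to a command sequence
#'
#' Shifts the commanded positions so that, after every direction reversal,
#' the motion is extended by the planned integer number of motor steps; the
#' screw's lost motion absorbs the extension and the stage lands on target.
#' Monotone segments are unchanged relative to one another. Targets are kept
#' alongside the corrected commands so deviations are still evaluated
#' against the intended positions.
#'
#' @param commands Either a numeric vector of target positions (um) or a
#'   command data frame with a `target_um` column (e.g. from
#'   [sawtooth_commands()]).
#' @param plan An [plan_overshoot()] result.
#' @param initial_direction Direction of the motion that brought the stage
#'   to its starting position (`"+"` or `"-"`).
#' @param start_um Starting position of the stage (um).
#' @return The commands with a `command_um` column holding the corrected
#'   commanded positions (vector input is promoted to a data frame).
#' @export
apply_overshoot <- function(commands, plan, initial_direction = "+",
                            start_um = 0) {
  stopifnot(inherits(plan, "overshoot_plan"))
  df <- if (is.data.frame(commands)) commands else data.frame(target_um = commands)
  corr_pn <- plan$steps_pos_neg * plan$step_pos_nm / 1000
  corr_np <- plan$steps_neg_pos * plan$step_neg_nm / 1000
  dir <- initial_direction
  offset <- 0
  prev <- start_um
  cmd <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    step <- df$target_um[i] - prev
    new_dir <- if (step > 0) "+" else if (step < 0) "-" else dir
    if (dir == "+" && new_dir == "-") offset <- offset - corr_pn
    if (dir == "-" && new_dir == "+") offset <- offset + corr_np
    dir <- new_dir
    cmd[i] <- df$target_um[i] + offset
    prev <- df$target_um[i]
  }
  df$command_um <- cmd
  df
}

#' Bidirectional positioning accuracy A
#'
#' `A = max(zbar +/- k sigma) - min(zbar -/+ k sigma)` over all positions and
#' both directions, with coverage factor `k` (2 by default). Degenerates to
#' the bidirectional systematic error E when all sigma are zero.
#'
#' @param traj A [stage_trajectory()].
#' @param k Coverage factor.
#' @return A in um.
#' @export
positioning_accuracy <- function(traj, k = 2) {
  dv <- deviations(traj)
  if (length(unique(dv$direction)) < 2)
    stop("both approach directions are required to compute A", call. = FALSE)
  max(dv$zbar_um + k * dv$sigma_um) - min(dv$zbar_um - k * dv$sigma_um)
}

#' Random positioning error
#'
#' Operationalised as the mean absolute deviation of the measured from the
#' target positions across all positions and repeats, intended for
#' backlash-corrected trajectories where the systematic offset has been
#' removed.
#'
#' @param traj A [stage_trajectory()].
#' @return E_R in um.
#' @export
random_error <- function(traj) {
  mean(abs(traj$measured_um - traj$target_um))
}

#' Total positioning uncertainty
#'
#' Sum of the residual bidirectional systematic error after backlash
#' correction and the random error: `dz = E_residual + E_R`.
#'
#' @param e_residual Residual systematic error E (um), >= 0.
#' @param e_random Random error E_R (um), >= 0.
#' @return Total uncertainty in um.
#' @examples
#' total_uncertainty(0.5, 0.4) # 0.9 um
#' @export
total_uncertainty <- function(e_residual, e_random) {
  if (e_residual < 0 || e_random < 0)
    stop("error terms must be >= 0", call. = FALSE)
  e_residual + e_random
}

#' Full calibration report for a trajectory
#'
#' Computes E, the backlash estimators, A (coverage factor `k`), E_R and the
#' total uncertainty for one trajectory. For the standard workflow run it
#' once on the uncorrected trajectory (E, backlash) and once on the
#' overshoot-corrected trajectory (residual E, E_R, total uncertainty).
#'
#' @param traj A [stage_trajectory()].
#' @param k Coverage factor for A.
#' @return A list of class `calibration_report` with fields `E_um`,
#'   `B_pos_neg_um`, `B_neg_pos_um`, `A_um`, `E_R_um`, `delta_z_um`, `k`.
#' @export
calibration_report <- function(traj, k = 2) {
  b <- estimate_backlash(traj)
  e <- bidirectional_systematic_error(traj)
  er <- random_error(traj)
  structure(list(E_um = e,
                 B_pos_neg_um = unname(b["B_pos_neg"]),
                 B_neg_pos_um = unname(b["B_neg_pos"]),
                 A_um = positioning_accuracy(traj, k),
                 E_R_um = er,
                 delta_z_um = total_uncertainty(e, er),
                 k = k),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Stage calibration report\n")
  cat(sprintf("  bidirectional systematic error E : %.3f um\n", x$E_um))
  cat(sprintf("  backlash B(+-) / B(-+)           : %.3f / %.3f um\n",
              x$B_pos_neg_um, x$B_neg_pos_um))
  cat(sprintf("  positioning accuracy A (k = %g)  : %.3f um\n", x$k, x$A_um))
  cat(sprintf("  random error E_R                 : %.3f um\n", x$E_R_um))
  cat(sprintf("  total uncertainty dz = E + E_R   : %.3f um\n", x$delta_z_um))
  invisible(x)
}
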