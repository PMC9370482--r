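#' Indentation protocol configuration
#'
#' Parameters of the progressive single-cell microindentation train. The
#' probe rests `h0` micrometres above the coverslip; each indentation moves
#' the tip down by a travelled distance `D` at speed `v` and back up, and a
#' dwell separates successive indentations so that late calcium-activation
#' events can still be observed.
#'
#' @param h0 Rest height of the probe tip above the coverslip (um).
#' @param d_start First travelled distance D (um).
#' @param d_step Increment of D between successive indentations (um).
#' @param d_max Maximum travelled distance D (um). Must not exceed `h0`:
#'   the tip is never commanded below the coverslip.
#' @param speed Stage speed v during the moves (um/s).
#' @param dwell Waiting time between indentations (s).
#' @return An object of class `protocol_config`.
#' @examples
#' cfg <- protocol_config()
#' build_train(cfg)
#' @export
protocol_config <- function(h0 = 20, d_start = 8, d_step = 2, d_max = 18,
                            speed = 3, dwell = 40) {
  if (!(d_start > 0 && d_start <= d_max && d_max <= h0))
    stop("need 0 < d_start <= d_max <= h0", call. = FALSE)
  if (d_step <= 0) stop("d_step must be > 0", call. = FALSE)
  if (speed <= 0) stop("speed must be > 0", call. = FALSE)
  if (dwell < 0) stop("dwell must be >= 0", call. = FALSE)
  structure(list(h0 = h0, d_start = d_start, d_step = d_step, d_max = d_max,
                 speed = speed, dwell = dwell),
            class = "protocol_config")
}

#' Travel time of a single probe move
#'
#' @param d Travelled distance D (um), possibly a vector.
#' @param v Stage speed (um/s).
#' @return Travel time D / v in seconds.
#' @examples
#' travel_time(12, 3) # 4 s
#' @export
travel_time <- function(d, v) {
  if (v <= 0) stop("speed must be > 0", call. = FALSE)
  d / v
}

#' Build a progressive indentation train
#'
#' Enumerates the travelled distances `D = d_start, d_start + d_step, ...,
#' d_max`, the corresponding tip heights `Z = h0 - D`, per-step travel times
#' `dt = D / v`, and start timestamps. Each step starts after the previous
#' step's full down-and-up travel plus the dwell.
#'
#' @param config A [protocol_config()].
#' @param t_start Timestamp of the first indentation start (s); the interval
#'   before it is baseline recording.
#' @return A data frame of class `indentation_train` with columns `index`,
#'   `d_um`, `z_um`, `dt_s`, `t_start_s`; the configuration is attached as
#'   attribute `config`.
#' @export
build_train <- function(config = protocol_config(), t_start = 20) {
  stopifnot(inherits(config, "protocol_config"))
  d <- seq(config$d_start, config$d_max, by = config$d_step)
  z <- config$h0 - d
  dt <- travel_time(d, config$speed)
  # start of step i follows down+up travel of step i-1 plus the dwell
  starts <- t_start + c(0, cumsum(2 * dt[-length(dt)] + config$dwell))
  train <- data.frame(index = seq_along(d), d_um = d, z_um = z,
                      dt_s = dt, t_start_s = starts)
  attr(train, "config") <- config
  class(train) <- c("indentation_train", "data.frame")
  train
}

#' End time of an indentation train
#'
#' Time at which the final step's travel and dwell have completed.
#' @param train An [build_train()] result.
#' @return Time in seconds.
#' @export
train_end_time <- function(train) {
  cfg <- attr(train, "config")
  n <- nrow(train)
  train$t_start_s[n] + 2 * train$dt_s[n] + cfg$dwell
}

#' Indentation depth from tip height and cell thickness
#'
#' The indentation depth is `delta = <T_max> - Z`: the penetration of the tip
#' below the average maximal cell thickness. Negative values mean the tip did
#' not reach the cell surface (no contact).
#'
#' @param z Tip height above the coverslip (um), possibly a vector.
#' @param tmax_mean Average maximal cell thickness `<T_max>` (um).
#' @return Depth(s) in um; negative values indicate no contact.
#' @examples
#' indentation_depth(2, 9.2)  # 7.2 um
#' indentation_depth(12, 9.2) # -2.8 um: no contact
#' @export
indentation_depth <- function(z, tmax_mean) {
  stopifnot(is.finite(z), is.finite(tmax_mean))
  tmax_mean - z
}

#' Per-step indentation depths for a train
#'
#' @param train An [build_train()] result.
#' @param tmax_mean Average maximal cell thickness (um). Group mean by
#'   default; pass a per-cell thickness for per-cell depths.
#' @return A data frame of class `depth_map` with columns `index`, `d_um`,
#'   `z_um`, `delta_um`, `contact` (logical, `delta_um > 0`).
#' @export
depth_map <- function(train, tmax_mean) {
  delta <- indentation_depth(train$z_um, tmax_mean)
  out <- data.frame(index = train$index, d_um = train$d_um, z_um = train$z_um,
                    delta_um = delta, contact = delta > 0)
  attr(out, "tmax_mean") <- tmax_mean
  class(out) <- c("depth_map", "data.frame")
  out
}

#' Emit the indentation train as a G-code motion program
#'
#' Produces a plain-text program in millimetre units with relative moves:
#' one linear feed move down and one up per indentation (`G1`), and a dwell
#' (`G4 P<seconds>`) between steps. The feed rate is the protocol speed
#' converted to mm/min (3 um/s -> `F0.18`).
#'
#' When an [plan_overshoot()] is supplied, every move (each move here is a
#' direction reversal) is extended by the planned integer number of motor
#' steps so that the screw's lost motion is taken up and the tip lands on
#' target; the commanded extra lengths cancel mechanically, not numerically.
#'
#' @param train An [build_train()] result.
#' @param config The [protocol_config()] used (defaults to the train's).
#' @param overshoot Optional `overshoot_plan` for backlash compensation.
#' @return Character vector of program lines.
#' @export
emit_gcode <- function(train, config = attr(train, "config"),
                       overshoot = NULL) {
  stopifnot(inherits(config, "protocol_config"))
  feed <- config$speed * 60 / 1000 # um/s -> mm/min
  lines <- c("G21 ; millimetre units", "G91 ; relative moves")
  ov_dn <- ov_up <- 0
  if (!is.null(overshoot)) {
    stopifnot(inherits(overshoot, "overshoot_plan"))
    # moving down is a +/- reversal, moving up a -/+ reversal
    ov_dn <- overshoot$steps_pos_neg * overshoot$step_pos_nm / 1e6 # mm
    ov_up <- overshoot$steps_neg_pos * overshoot$step_neg_nm / 1e6
  }
  for (i in seq_len(nrow(train))) {
    d_mm <- train$d_um[i] / 1000
    lines <- c(lines,
               sprintf("G1 Z%.6f F%.4f", -(d_mm + ov_dn), feed),
               sprintf("G1 Z%.6f F%.4f", d_mm + ov_up, feed),
               sprintf("G4 P%g", config$dwell))
  }
  c(lines, "M2 ; end of program")
}

#' Parse a G-code indentation program back into travelled distances
#'
#' Inverse of [emit_gcode()] for programs emitted without overshoot
#' compensation: recovers the travelled-distance sequence `D` (um) from the
#' downward relative `G1` moves.
#'
#' @param lines Character vector of program lines.
#' @return Numeric vector of travelled distances D in um.
#' @export
parse_gcode <- function(lines) {
  mv <- regmatches(lines, regexec("^G1 Z(-?[0-9.]+)", lines))
  z_mm <- vapply(mv, function(m) if (length(m) == 2) as.numeric(m[2]) else NA_real_,
                 numeric(1))
  z_mm <- z_mm[!is.na(z_mm)]
  -1000 * z_mm[z_mm < 0]
}

#' Ratiometric sampling interval from per-channel exposure
#'
#' Dual-excitation ratiometric imaging alternates the two excitation
#' wavelengths; one ratio sample takes the sum of the channel exposures
#' (220 ms per channel -> 440 ms per ratio frame).
#'
#' @param exposure_s Exposure time per channel (s).
#' @param n_channels Number of excitation channels.
#' @return Sampling interval of the ratio signal (s).
#' @export
ratiometric_interval <- function(exposure_s = 0.22, n_channels = 2) {
  stopifnot(exposure_s > 0, n_channels >= 1)
  exposure_s * n_channels
}

#' @export
print.indentation_train <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Indentation train: %d steps, D = %g..%g um (step %g), v = %g um/s, dwell = %g s\n",
              nrow(x), cfg$d_start, cfg$d_max, cfg$d_step, cfg$speed, cfg$dwell))
  print.data.frame(x, ...)
  invisible(x)
}
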