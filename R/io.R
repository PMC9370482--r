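#' Write a cohort of traces as CSV with a ground-truth sidecar
#'
#' Long format: columns `time_s`, `f340`, `f380`, `cell_id`, `group`. The
#' sidecar (`<path minus .csv>_truth.csv`) holds one row per cell with the
#' generator's ground-truth labels.
#'
#' @param traces A `trace_cohort` or list of `dual_channel_trace` objects.
#' @param path Output CSV path.
#' @param truth_path Sidecar path; default derives from `path`.
#' @return Invisibly, `path`.
#' @export
write_traces_csv <- function(traces, path,
                             truth_path = sub("\\.csv$", "_truth.csv", path)) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = tr$time_s, f340 = tr$f340, f380 = tr$f380,
               cell_id = attr(tr, "cell_id"), group = attr(tr, "group"))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  utils::write.csv(ground_truth(traces), truth_path, row.names = FALSE)
  invisible(path)
}

#' Read traces from CSV
#'
#' @param path CSV written by [write_traces_csv()] (ground truth sidecar is
#'   not required).
#' @return A list of `dual_channel_trace` objects (class `trace_cohort`).
#' @export
read_traces_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "f340", "f380", "cell_id", "group")
  if (!all(need %in% names(long)))
    stop("trace CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  traces <- lapply(split(long, long$cell_id), function(d) {
    d <- d[order(d$time_s), ]
    tr <- data.frame(time_s = d$time_s, f340 = d$f340, f380 = d$f380)
    attr(tr, "cell_id") <- d$cell_id[1]
    attr(tr, "group") <- d$group[1]
    class(tr) <- c("dual_channel_trace", "data.frame")
    tr
  })
  structure(unname(traces), class = "trace_cohort")
}

#' Write a stage trajectory as CSV
#'
#' Columns: `repeat`, `position_index`, `direction` (+/-), `target_um`,
#' `measured_um`.
#'
#' @param traj A [stage_trajectory()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(traj$repeat_idx, traj$position_index, traj$direction,
                    traj$target_um, traj$measured_um)
  names(out) <- c("repeat", "position_index", "direction", "target_um",
                  "measured_um")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a stage trajectory from CSV
#'
#' @param path CSV with columns `repeat`, `position_index`, `direction`,
#'   `target_um`, `measured_um`.
#' @return A [stage_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("repeat", "position_index", "direction", "target_um", "measured_um")
  if (!all(need %in% names(d)))
    stop("trajectory CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  stage_trajectory(d[["repeat"]], d$position_index, d$direction,
                   d$target_um, d$measured_um)
}

#' Write an indentation train as CSV
#'
#' @param train An [build_train()] result.
#' @param path Output path.
#' @param tmax_mean Optional `<T_max>` to add a `delta_um` column.
#' @return Invisibly, `path`.
#' @export
write_train_csv <- function(train, path, tmax_mean = NULL) {
  out <- as.data.frame(train)
  if (!is.null(tmax_mean)) out$delta_um <- indentation_depth(train$z_um, tmax_mean)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a phase map as a 32-bit float TIFF (radians)
#'
#' Writes a minimal single-strip uncompressed grayscale TIFF with
#' SampleFormat = IEEE float, so phase values keep their full range and sign
#' (standard TIFF writers in R clamp data to `[0, 1]`). Readable by
#' [read_phase_tiff()] and by any libtiff-based tool.
#'
#' @param phase Numeric matrix of phase shifts (radians).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phase_tiff <- function(phase, path) {
  stopifnot(is.matrix(phase), all(is.finite(phase)))
  nr <- nrow(phase); nc <- ncol(phase)
  con <- file(path, "wb")
  on.exit(close(con))
  data_offset <- 8L
  n_bytes <- 4L * nr * nc
  ifd_offset <- data_offset + n_bytes
  # header: little-endian, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  writeBin(c(42L, 0L), con, size = 1)
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  # pixel data, row-major as TIFF expects
  writeBin(as.numeric(t(phase)), con, size = 4, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  entries <- list(
    c(256, 4, 1, nc),          # ImageWidth
    c(257, 4, 1, nr),          # ImageLength
    c(258, 3, 1, 32),          # BitsPerSample
    c(259, 3, 1, 1),           # Compression: none
    c(262, 3, 1, 1),           # Photometric: BlackIsZero
    c(273, 4, 1, data_offset), # StripOffsets
    c(277, 3, 1, 1),           # SamplesPerPixel
    c(278, 4, 1, nr),          # RowsPerStrip
    c(279, 4, 1, n_bytes),     # StripByteCounts
    c(339, 3, 1, 3)            # SampleFormat: IEEE float
  )
  writeBin(as.integer(length(entries)), con, size = 2, endian = "little")
  for (e in entries) tag(e[1], e[2], e[3], e[4])
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

#' Read a float phase TIFF
#'
#' @param path TIFF path (32-bit float, radians).
#' @return Numeric matrix of phase shifts.
#' @export
read_phase_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Write an ROI label mask as a 16-bit TIFF
#'
#' @param mask Integer label matrix (0 = background, labels < 65536).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(all(mask >= 0), all(mask < 65536))
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read an ROI label mask TIFF
#'
#' @param path TIFF path (16-bit integer labels).
#' @return Integer label matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (is.array(m) && length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "integer"
  m
}

#' Write a cohort report as JSON
#'
#' @param report A [build_report()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a cohort report from JSON
#'
#' @param path JSON written by [write_report_json()].
#' @return A `cohort_report` list.
#' @export
read_report_json <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$sweep <- as.data.frame(rep$sweep)
  rep$depths <- as.data.frame(rep$depths)
  rep$groups <- lapply(rep$groups, function(g) {
    g$ar_delta <- as.data.frame(g$ar_delta)
    if (!"delta_um" %in% names(g$ar_delta)) g$ar_delta$delta_um <- numeric(0)
    g
  })
  class(rep) <- "cohort_report"
  rep
}

#' Load generator configurations from a YAML file
#'
#' Recognised top-level keys: `trace` ([trace_gen_config()]), `protocol`
#' ([protocol_config()]), `stage` ([stage_sim_config()]), `phase_map`
#' ([phase_map_spec()]), `cohorts` (list of [cohort_spec()] argument sets).
#'
#' @param path YAML path.
#' @return Named list of constructed configuration objects.
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(cfg$trace)) out$trace <- do.call(trace_gen_config, cfg$trace)
  if (!is.null(cfg$protocol)) out$protocol <- do.call(protocol_config, cfg$protocol)
  if (!is.null(cfg$stage)) out$stage <- do.call(stage_sim_config, cfg$stage)
  if (!is.null(cfg$phase_map)) {
    pm <- cfg$phase_map
    if (!is.null(pm$image_shape)) pm$image_shape <- unlist(pm$image_shape)
    out$phase_map <- do.call(phase_map_spec, pm)
  }
  if (!is.null(cfg$cohorts))
    out$cohorts <- lapply(cfg$cohorts, function(x) do.call(cohort_spec, x))
  out
}
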