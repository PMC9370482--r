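#' Optical constants for phase-to-thickness conversion
#'
#' Mean integral refractive indices of the cells and the surrounding medium.
#'
#' @param n_cell Cell refractive index.
#' @param n_medium Medium refractive index.
#' @return An object of class `optical_constants`.
#' @export
optical_constants <- function(n_cell = 1.38, n_medium = 1.34) {
  if (!(n_cell > n_medium && n_medium > 1))
    stop("need n_cell > n_medium > 1", call. = FALSE)
  structure(list(n_cell = n_cell, n_medium = n_medium),
            class = "optical_constants")
}

#' Convert phase shift to cell thickness
#'
#' `T = (lambda / 2 pi) * phi / (n_cell - n_medium)`, with the wavelength in
#' nm and the result in um. Inverse of [thickness_to_phase()].
#'
#' @param phi Phase shift (radians), vector or matrix.
#' @param wavelength_nm Laser wavelength (nm).
#' @param constants An [optical_constants()].
#' @return Thickness in um, same shape as `phi`.
#' @examples
#' phase_to_thickness(3.80, 635) # ~9.6 um
#' @export
phase_to_thickness <- function(phi, wavelength_nm = 635,
                               constants = optical_constants()) {
  stopifnot(inherits(constants, "optical_constants"))
  dn <- constants$n_cell - constants$n_medium
  (wavelength_nm / 1000) / (2 * pi) * phi / dn
}

#' Convert cell thickness to phase shift
#'
#' Forward optical model `phi = (2 pi / lambda) * (n_cell - n_medium) * T`.
#'
#' @param thickness_um Thickness (um), vector or matrix.
#' @inheritParams phase_to_thickness
#' @return Phase shift in radians.
#' @export
thickness_to_phase <- function(thickness_um, wavelength_nm = 635,
                               constants = optical_constants()) {
  stopifnot(inherits(constants, "optical_constants"))
  dn <- constants$n_cell - constants$n_medium
  2 * pi / (wavelength_nm / 1000) * dn * thickness_um
}

#' Subtract the background phase
#'
#' Calibrates a phase map against the optical thickness of the medium: the
#' mean phase over the background region is subtracted everywhere, so the
#' returned map has (near-)zero mean background. Idempotent on an already
#' calibrated map.
#'
#' @param phase Phase matrix (radians).
#' @param background_mask Logical matrix (TRUE = background pixel), or an
#'   integer label matrix in which 0 marks background.
#' @return Calibrated phase matrix.
#' @export
calibrate_background <- function(phase, background_mask) {
  if (is.numeric(background_mask)) background_mask <- background_mask == 0
  if (!any(background_mask))
    stop("background region is empty", call. = FALSE)
  phase - mean(phase[background_mask])
}

#' Per-cell maximal thickness from a phase map and ROI labels
#'
#' For each ROI label, converts the maximum phase shift within the label's
#' pixels to thickness. A percentile below 100 replaces the maximum by the
#' corresponding within-ROI phase quantile for noise robustness; the default
#' is the plain maximum.
#'
#' @param phase Phase matrix (radians), background-calibrated.
#' @param mask Integer label matrix (0 = background).
#' @param constants An [optical_constants()].
#' @param wavelength_nm Laser wavelength (nm).
#' @param percentile Percentile of the within-ROI phase used as the "max"
#'   (100 = maximum).
#' @param background_mask Optional background region; when supplied the map
#'   is passed through [calibrate_background()] first.
#' @return Data frame with columns `label`, `tmax_um`.
#' @export
cell_tmax <- function(phase, mask, constants = optical_constants(),
                      wavelength_nm = 635, percentile = 100,
                      background_mask = NULL) {
  if (!is.null(background_mask))
    phase <- calibrate_background(phase, background_mask)
  labels <- sort(unique(as.integer(mask[mask > 0])))
  if (length(labels) == 0)
    stop("mask contains no labelled pixels", call. = FALSE)
  phi_max <- vapply(labels, function(lab) {
    px <- phase[mask == lab]
    if (length(px) == 0) {
      warning("label ", lab, " has no pixels; skipped", call. = FALSE)
      return(NA_real_)
    }
    if (percentile >= 100) max(px) else
      as.numeric(stats::quantile(px, percentile / 100))
  }, numeric(1))
  if (any(phi_max > 2 * pi, na.rm = TRUE))
    warning("phase values exceed 2*pi; the map may be wrapped and ",
            "thicknesses underestimated", call. = FALSE)
  data.frame(label = labels,
             tmax_um = phase_to_thickness(phi_max, wavelength_nm, constants))
}

#' Cohort summary of per-cell maximal thickness
#'
#' Mean and standard error of the per-cell `T_max`; the mean feeds the
#' indentation-depth map as `<T_max>`.
#'
#' @param tmax Numeric vector of per-cell maximal thicknesses (um), or a
#'   [cell_tmax()] result data frame.
#' @return A list of class `morphometry_summary` with `mean_um`, `se_um`,
#'   `n_cells`.
#' @export
cohort_thickness_summary <- function(tmax) {
  if (is.data.frame(tmax)) tmax <- tmax$tmax_um
  tmax <- tmax[!is.na(tmax)]
  if (length(tmax) == 0) stop("no cells to summarise", call. = FALSE)
  se <- if (length(tmax) > 1) stats::sd(tmax) / sqrt(length(tmax)) else 0
  structure(list(mean_um = mean(tmax), se_um = se, n_cells = length(tmax)),
            class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat(sprintf("<T_max> = (%.2f +/- %.2f) um over %d cells (mean +/- SE)\n",
              x$mean_um, x$se_um, x$n_cells))
  invisible(x)
}
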