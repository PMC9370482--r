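#' Phase-map simulation specification
#'
#' Parameters for generating synthetic holographic phase maps: cells are
#' smooth non-overlapping domes whose peak phase follows the forward optical
#' model `phi = (2 pi / lambda) * (n_cell - n_medium) * T_max`, on a
#' zero-phase (pre-calibrated) background with optional Gaussian phase noise.
#'
#' @param image_shape Image dimensions in pixels, `c(rows, cols)`.
#' @param n_cells Number of cells to place.
#' @param tmax_mean,tmax_sd Mean and SD (um) of the per-cell maximal
#'   thickness, drawn Normal and truncated at 0.5 um.
#' @param wavelength_nm Laser wavelength (nm).
#' @param n_cell,n_medium Refractive indices of cell and medium
#'   (`n_cell > n_medium`).
#' @param phase_noise_sd Per-pixel Gaussian phase noise SD (radians).
#' @param cell_radius_px Footprint radius of each dome (pixels).
#' @param seed Optional integer seed.
#' @return An object of class `phase_map_spec`.
#' @export
phase_map_spec <- function(image_shape = c(256, 256), n_cells = 8,
                           tmax_mean = 9.4, tmax_sd = 1.5,
                           wavelength_nm = 635, n_cell = 1.38,
                           n_medium = 1.34, phase_noise_sd = 0,
                           cell_radius_px = 14, seed = NULL) {
  if (n_cell <= n_medium) stop("n_cell must exceed n_medium", call. = FALSE)
  if (wavelength_nm <= 0) stop("wavelength must be > 0", call. = FALSE)
  if (tmax_mean <= 0) stop("tmax_mean must be > 0", call. = FALSE)
  if (tmax_sd < 0 || phase_noise_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(list(image_shape = as.integer(image_shape), n_cells = as.integer(n_cells),
                 tmax_mean = tmax_mean, tmax_sd = tmax_sd,
                 wavelength_nm = wavelength_nm, n_cell = n_cell,
                 n_medium = n_medium, phase_noise_sd = phase_noise_sd,
                 cell_radius_px = as.integer(cell_radius_px), seed = seed),
            class = "phase_map_spec")
}

#' Generate a synthetic phase map with ROI labels and ground truth
#'
#' Each cell is a raised-cosine-squared dome of thickness `T(r) =
#' T_max * cos(pi r / (2 R))^2` centred on a pixel, so the peak phase at the
#' centre pixel equals the forward model exactly. Cells are placed by
#' rejection sampling without overlap; an error is raised if they cannot be
#' fitted.
#'
#' @param spec A [phase_map_spec()].
#' @param tmax_um Optional vector of per-cell maximal thicknesses (um),
#'   overriding the Normal draw (recycled to `n_cells`).
#' @return A list of class `phase_map_sim` with elements `phase` (matrix,
#'   radians), `mask` (integer label matrix, 0 = background), `truth` (data
#'   frame `label`, `tmax_um`) and `spec`.
#' @export
gen_phase_map <- function(spec, tmax_um = NULL) {
  stopifnot(inherits(spec, "phase_map_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  R <- spec$cell_radius_px
  if (2 * R + 2 > min(nr, nc))
    stop("cell radius too large for the image", call. = FALSE)

  build <- function() {
    tmax <- if (is.null(tmax_um)) {
      pmax(0.5, stats::rnorm(spec$n_cells, spec$tmax_mean, spec$tmax_sd))
    } else rep(tmax_um, length.out = spec$n_cells)
    centres <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(centres) < spec$n_cells) {
      tries <- tries + 1
      if (tries > 2000 * spec$n_cells)
        stop("could not place ", spec$n_cells,
             " non-overlapping cells in the image", call. = FALSE)
      cand <- c(sample(seq(R + 2, nr - R - 1), 1),
                sample(seq(R + 2, nc - R - 1), 1))
      if (nrow(centres) == 0 ||
          all(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) >
              2 * R + 2)) {
        centres <- rbind(centres, cand)
      }
    }
    phase <- matrix(0, nr, nc)
    mask <- matrix(0L, nr, nc)
    consts <- optical_constants(spec$n_cell, spec$n_medium)
    for (i in seq_len(spec$n_cells)) {
      rows <- (centres[i, 1] - R):(centres[i, 1] + R)
      cols <- (centres[i, 2] - R):(centres[i, 2] + R)
      rr <- sqrt(outer((rows - centres[i, 1])^2, (cols - centres[i, 2])^2, "+"))
      dome <- ifelse(rr < R, tmax[i] * cos(pi * rr / (2 * R))^2, 0)
      phase[rows, cols] <- phase[rows, cols] +
        thickness_to_phase(dome, spec$wavelength_nm, consts)
      mask[rows, cols][dome > 0] <- i
    }
    if (spec$phase_noise_sd > 0)
      phase <- phase + matrix(stats::rnorm(nr * nc, 0, spec$phase_noise_sd), nr, nc)
    list(phase = phase, mask = mask,
         truth = data.frame(label = seq_len(spec$n_cells), tmax_um = tmax))
  }
  out <- with_seed(spec$seed, build())
  structure(c(out, list(spec = spec)), class = "phase_map_sim")
}
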