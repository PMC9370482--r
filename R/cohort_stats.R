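#' Activation rate of a group
#'
#' `AR = 100 * (# responsive cells) / (total cells)`, in percent.
#'
#' @param classifications Classification rows of one group (see
#'   [classify_cohort()]).
#' @return AR in percent.
#' @export
activation_rate <- function(classifications) {
  if (nrow(classifications) == 0) stop("empty group", call. = FALSE)
  100 * mean(classifications$responsive)
}

#' Activation rate binned by indentation depth
#'
#' `AR_delta = 100 * (# cells activated at depth delta) / (total cells)` for
#' every contact-making (positive-depth) step of the train. Responsive cells
#' whose event could not be attributed to a step, or that were assigned a
#' non-contact step, are counted in an `unassigned` bin (delta `NA`) so that
#' the histogram still sums to AR.
#'
#' @param classifications Classification rows of one group.
#' @param depths A [depth_map()].
#' @return Data frame with columns `delta_um` (`NA` for the unassigned bin,
#'   present only when non-empty) and `ar_delta_percent`.
#' @export
activation_rate_at_depth <- function(classifications, depths) {
  if (nrow(classifications) == 0) stop("empty group", call. = FALSE)
  n <- nrow(classifications)
  pos <- depths[depths$contact, , drop = FALSE]
  counts <- vapply(pos$index, function(i)
    sum(classifications$responsive &
          !is.na(classifications$activation_index) &
          classifications$activation_index == i), numeric(1))
  out <- data.frame(delta_um = pos$delta_um,
                    ar_delta_percent = 100 * counts / n)
  unassigned <- sum(classifications$responsive) - sum(counts)
  if (unassigned > 0) {
    warning(unassigned, " responsive cell(s) without an assigned ",
            "contact-making depth; reported in the unassigned bin",
            call. = FALSE)
    out <- rbind(out, data.frame(delta_um = NA_real_,
                                 ar_delta_percent = 100 * unassigned / n))
  }
  out
}

#' Activation-rate threshold sweep
#'
#' Classifies every cohort once (candidate transients do not depend on the
#' threshold) and evaluates the activation rate at each grid threshold: a
#' cell is responsive at `R_T` iff its best pre-rupture candidate peak
#' exceeds `R_T`. The resulting per-group curve AR(R_T) is non-increasing by
#' construction.
#'
#' @param cohorts Named list of trace collections (one element per group;
#'   names are the group labels).
#' @param train An [build_train()] indentation train.
#' @param depths A [depth_map()] (or pass `tmax_mean`).
#' @param grid Increasing vector of thresholds, within `[0, 4.5]`.
#' @param tmax_mean Average maximal thickness used when `depths` is missing.
#' @param ... Passed to [classify_cell()] / [detect_activation_peaks()].
#' @return Data frame of class `sweep_curve` with columns `group`, `rt`,
#'   `ar_percent`; per-cell best peaks are attached as attribute
#'   `cell_peaks`.
#' @export
threshold_sweep <- function(cohorts, train, depths = NULL,
                            grid = seq(0, 4.5, by = 0.1), tmax_mean = NULL,
                            ...) {
  if (is.null(names(cohorts)) || any(names(cohorts) == ""))
    stop("cohorts must be a named list (group labels)", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE) || min(grid) < 0 || max(grid) > 4.5)
    stop("grid must be strictly increasing within [0, 4.5]", call. = FALSE)
  peaks <- lapply(cohorts, function(traces) {
    cls <- classify_cohort(traces, train, depths = depths, r_threshold = 0,
                           tmax_mean = tmax_mean, ...)
    ifelse(cls$responsive, cls$max_peak_r, -Inf)
  })
  curve <- do.call(rbind, lapply(names(peaks), function(g) {
    data.frame(group = g, rt = grid,
               ar_percent = vapply(grid, function(rt)
                 100 * mean(peaks[[g]] > rt), numeric(1)))
  }))
  attr(curve, "cell_peaks") <- peaks
  class(curve) <- c("sweep_curve", "data.frame")
  curve
}

#' Select the activation threshold from a sweep
#'
#' The usable threshold interval is bounded below by the noise regime --
#' the smallest grid threshold at which the calcium-free control group's AR
#' reaches 0 and stays 0 -- and above by the largest grid threshold at which
#' any group still responds. The selected threshold is the median (midpoint)
#' of that interval.
#'
#' @param sweep A [threshold_sweep()] result (or a data frame with columns
#'   `group`, `rt`, `ar_percent`).
#' @param control_group Label of the calcium-free control group.
#' @return Selected R_T with attributes `lower` and `upper`.
#' @export
select_threshold <- function(sweep, control_group = "CaFree") {
  if (!control_group %in% sweep$group)
    stop("control group '", control_group, "' not present in the sweep",
         call. = FALSE)
  ctrl <- sweep[sweep$group == control_group, ]
  ctrl <- ctrl[order(ctrl$rt), ]
  zero_tail <- rev(cumprod(rev(ctrl$ar_percent == 0))) == 1
  if (!any(zero_tail))
    stop("control group AR never reaches 0: no usable threshold interval ",
         "(max control AR = ", max(ctrl$ar_percent), "%)", call. = FALSE)
  lower <- min(ctrl$rt[zero_tail])
  any_pos <- tapply(sweep$ar_percent > 0, sweep$rt, any)
  rts <- as.numeric(names(any_pos))
  if (!any(any_pos)) stop("no group ever responds", call. = FALSE)
  upper <- max(rts[any_pos])
  if (upper < lower) upper <- lower
  structure((lower + upper) / 2, lower = lower, upper = upper)
}

#' Build the cohort report
#'
#' Aggregates per-group activation rates at the selected threshold, the
#' per-depth histograms, the sweep curves and provenance into one object
#' that serialises to JSON.
#'
#' @param classifications Combined [classify_cohort()] rows for all groups
#'   (classified at `selected_rt`).
#' @param sweep A [threshold_sweep()] result.
#' @param selected_rt The chosen threshold (e.g. from [select_threshold()]).
#' @param depths The [depth_map()] used.
#' @param provenance Optional list (seeds, configs) stored verbatim.
#' @return A list of class `cohort_report`.
#' @export
build_report <- function(classifications, sweep, selected_rt, depths,
                         provenance = list()) {
  groups <- split(classifications, classifications$group)
  per_group <- lapply(groups, function(cls) {
    hist <- suppressWarnings(activation_rate_at_depth(cls, depths))
    list(n = nrow(cls), ar_percent = activation_rate(cls),
         ar_delta = hist)
  })
  sweep <- as.data.frame(sweep)
  attr(sweep, "cell_peaks") <- NULL
  structure(list(selected_rt = as.numeric(selected_rt),
                 rt_interval = c(attr(selected_rt, "lower") %||% NA_real_,
                                 attr(selected_rt, "upper") %||% NA_real_),
                 groups = per_group,
                 sweep = sweep,
                 depths = as.data.frame(depths),
                 provenance = provenance),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report (R_T = %.2f, stable interval [%.2f, %.2f])\n",
              x$selected_rt, x$rt_interval[1], x$rt_interval[2]))
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    cat(sprintf("  %-8s n = %3d  AR = %5.1f%%\n", g, gr$n, gr$ar_percent))
  }
  invisible(x)
}
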