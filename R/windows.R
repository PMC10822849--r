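# Sliding-window analysis planning: square blocks tiled over the combined ROI
# (tumor core + margin) at a configurable overlap.

#' Plan sliding analysis windows over an ROI
#'
#' Enumerates square analysis-block centers on a regular lattice with step
#' `(1 - overlap) * block_side`, keeping centers that fall inside the combined
#' ROI (core plus margin). By default the block side is the explicitly
#' configured 2.2 mm; passing `block_side = NULL` applies the
#' ten-ultrasonic-wavelength rule `10 * sound_speed / center_frequency`
#' instead (about 2.57 mm at 6 MHz in tissue — the two prescriptions are not
#' equivalent, which is why the explicit side takes precedence).
#'
#' @param roi An `roi_mask` (see [ellipse_roi_mask()] / [roi_mask()]).
#' @param pulse A [pulse_spec()].
#' @param overlap Fractional overlap of adjacent blocks in both directions,
#'   in `[0, 1)` (0.94 in the reference protocol).
#' @param block_side Block side in mm, or `NULL` for the 10-wavelength rule.
#' @param sound_speed Sound speed (m/s) for the wavelength rule.
#' @return A `window_plan`: center lattices (`ax_centers`, `lat_centers`, mm),
#'   an `in_roi` logical matrix (axial rows x lateral columns), `block_side`
#'   and `step`.
#' @export
plan_windows <- function(roi, pulse, overlap = 0.94, block_side = 2.2,
                         sound_speed = pulse$sound_speed) {
  if (overlap < 0 || overlap >= 1) {
    stop_qus("overlap must lie in [0, 1)", "qus_validation_error")
  }
  if (is.null(block_side)) {
    block_side <- 10 * sound_speed / (pulse$center_frequency * 1e6) * 1e3
  }
  step <- (1 - overlap) * block_side
  if (!any(roi$combined)) {
    stop_qus("ROI is empty", "qus_insufficient_roi_error")
  }

  lat_pos <- geometry_lateral_positions(roi$geometry)
  ax_pos <- geometry_sample_depths(roi$geometry, roi$pulse)
  idx <- which(roi$combined, arr.ind = TRUE)   # rows = lines, cols = samples
  lat_rng <- range(lat_pos[idx[, 1]]) + c(-0.5, 0.5) * roi$lateral_spacing
  ax_rng <- range(ax_pos[idx[, 2]]) + c(-0.5, 0.5) * roi$axial_spacing
  half <- block_side / 2
  if (diff(ax_rng) < block_side || diff(lat_rng) < block_side) {
    stop_qus("ROI is smaller than one analysis block", "qus_insufficient_roi_error")
  }
  ax_centers <- seq(ax_rng[1] + half, ax_rng[2] - half + 1e-9, by = step)
  lat_centers <- seq(lat_rng[1] + half, lat_rng[2] - half + 1e-9, by = step)

  # a center is usable when its nearest RF pixel lies in the combined ROI
  line_of <- pmin(pmax(round(lat_centers / roi$lateral_spacing) + 1L, 1L),
                  roi$geometry$n_lines)
  samp_of <- pmin(pmax(round((ax_centers - roi$geometry$depth_offset) /
                               roi$axial_spacing) + 1L, 1L), length(ax_pos))
  in_roi <- t(roi$combined[line_of, samp_of, drop = FALSE])  # ax x lat
  if (!any(in_roi)) {
    stop_qus("no block center falls inside the ROI", "qus_insufficient_roi_error")
  }
  structure(
    list(block_side = block_side, step = step, overlap = overlap,
         ax_centers = ax_centers, lat_centers = lat_centers, in_roi = in_roi),
    class = "window_plan"
  )
}

#' Block centers of a window plan
#'
#' @param plan A `window_plan`.
#' @param roi_only Keep only centers inside the combined ROI.
#' @return A data frame of `(axial, lateral)` centers in mm, enumerated
#'   row-major with axial as the major (outer) index.
#' @export
window_centers <- function(plan, roi_only = TRUE) {
  df <- expand.grid(lateral = plan$lat_centers, axial = plan$ax_centers,
                    KEEP.OUT.ATTRS = FALSE)[, c("axial", "lateral")]
  keep <- as.vector(t(plan$in_roi))
  if (roi_only) df[keep, , drop = FALSE] else df
}
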