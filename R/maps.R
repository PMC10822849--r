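# Parametric map assembly: run the spectral estimators block-by-block over a
# window plan and collect co-registered ASD/AAC/MBF/SS/SI maps, then render
# 224x224 map images for the feature extractor.

QUS_PARAMETERS <- c("ASD", "AAC", "MBF", "SS", "SI")

#' QUS analysis configuration
#'
#' @param alpha_sample Assumed tissue attenuation, dB/(MHz.cm). The default
#'   1.0 is a conventional literature value for breast tissue; synthetic
#'   recovery tests pass the simulator's true value instead.
#' @param phantom Reference [phantom_spec()] (supplies the reference
#'   attenuation and the analytic reference BSC).
#' @param max_fail_fraction Abort [build_maps()] when more than this fraction
#'   of in-ROI blocks fails.
#' @return A list of class `qus_config`.
#' @export
qus_config <- function(alpha_sample = 1.0, phantom = phantom_spec(),
                       max_fail_fraction = 0.5) {
  structure(list(alpha_sample = alpha_sample, phantom = phantom,
                 max_fail_fraction = max_fail_fraction),
            class = "qus_config")
}

#' Single parametric map
#'
#' Values of one QUS parameter on the window-plan block-center lattice, with
#' a validity mask (failed blocks are flagged, never silently zeroed).
#'
#' @param values Numeric matrix, axial rows x lateral columns.
#' @param valid Logical matrix of the same shape.
#' @param ax_centers,lat_centers Block-center coordinates, mm.
#' @param roi The `roi_mask` the map was computed over.
#' @param parameter One of `"ASD", "AAC", "MBF", "SS", "SI"`.
#' @return An object of class `parametric_map`.
#' @export
parametric_map <- function(values, valid, ax_centers, lat_centers, roi,
                           parameter = "SS") {
  stopifnot(all(dim(values) == dim(valid)),
            nrow(values) == length(ax_centers),
            ncol(values) == length(lat_centers))
  structure(
    list(values = values, valid = valid, ax_centers = ax_centers,
         lat_centers = lat_centers, roi = roi, parameter = parameter),
    class = "parametric_map"
  )
}

#' Build the five co-registered QUS parametric maps
#'
#' For every in-ROI block of the plan: gate the sample and (depth-matched,
#' same axial gates) reference RF, estimate the mean power spectrum, normalize
#' by the reference with attenuation compensation, fit MBF/SS/SI, transfer to
#' a backscatter coefficient and fit the spherical Gaussian form factor for
#' ASD/AAC. Per-block failures are recorded in the validity masks; the build
#' aborts only when more than `max_fail_fraction` of blocks fails.
#'
#' @param frame Sample [rf_frame()].
#' @param reference Reference-phantom [rf_frame()] on the same geometry.
#' @param roi An `roi_mask`.
#' @param plan A `window_plan` (see [plan_windows()]).
#' @param config A [qus_config()].
#' @return A list of class `parametric_maps`: one [parametric_map()] per
#'   parameter, sharing the plan's center lattice exactly.
#' @export
build_maps <- function(frame, reference, roi, plan, config = qus_config()) {
  if (!identical(dim(frame$samples), dim(reference$samples))) {
    stop_qus("sample and reference frames must share acquisition geometry",
             "qus_dimension_error")
  }
  pulse <- frame$pulse
  lat_pos <- geometry_lateral_positions(frame$geometry)
  ax_pos <- geometry_sample_depths(frame$geometry, pulse)
  half <- plan$block_side / 2
  n_ax <- length(plan$ax_centers); n_lat <- length(plan$lat_centers)

  vals <- lapply(QUS_PARAMETERS, function(p) matrix(NA_real_, n_ax, n_lat))
  names(vals) <- QUS_PARAMETERS
  valid <- lapply(QUS_PARAMETERS, function(p) matrix(FALSE, n_ax, n_lat))
  names(valid) <- QUS_PARAMETERS

  line_sel <- lapply(plan$lat_centers,
                     function(c0) which(abs(lat_pos - c0) <= half))
  samp_sel <- lapply(plan$ax_centers,
                     function(c0) which(abs(ax_pos - c0) <= half))
  ref_bsc_cache <- list()
  n_blocks <- 0L; n_failed <- 0L

  for (i in seq_len(n_ax)) {
    samp <- samp_sel[[i]]
    depth_cm <- plan$ax_centers[i] / 10
    for (j in seq_len(n_lat)) {
      if (!plan$in_roi[i, j]) next
      n_blocks <- n_blocks + 1L
      lines <- line_sel[[j]]
      ok <- tryCatch({
        sp_s <- block_power_spectrum(frame$samples[lines, samp, drop = FALSE],
                                     pulse, block_depth = depth_cm)
        sp_r <- block_power_spectrum(reference$samples[lines, samp, drop = FALSE],
                                     pulse, block_depth = depth_cm)
        nps <- normalize_spectrum(sp_s, sp_r,
                                  alpha_sample = config$alpha_sample,
                                  alpha_ref = config$phantom$attenuation_coefficient)
        sp_fit <- fit_spectral_params(nps, pulse)
        vals$MBF[i, j] <- sp_fit$MBF; valid$MBF[i, j] <- TRUE
        vals$SS[i, j] <- sp_fit$SS;  valid$SS[i, j] <- TRUE
        vals$SI[i, j] <- sp_fit$SI;  valid$SI[i, j] <- TRUE
        key <- as.character(length(nps$frequencies))
        if (is.null(ref_bsc_cache[[key]])) {
          ref_bsc_cache[[key]] <- reference_bsc(config$phantom, nps$frequencies)
        }
        sc <- fit_gaussian_form_factor(estimate_bsc(nps, ref_bsc_cache[[key]]),
                                       sound_speed = pulse$sound_speed,
                                       band = c(pulse$band_low, pulse$band_high))
        vals$ASD[i, j] <- sc$ASD; valid$ASD[i, j] <- TRUE
        vals$AAC[i, j] <- sc$AAC; valid$AAC[i, j] <- TRUE
        TRUE
      }, qus_error = function(e) FALSE)
      if (!ok) n_failed <- n_failed + 1L
    }
  }
  if (n_blocks > 0 && n_failed / n_blocks > config$max_fail_fraction) {
    stop_qus(sprintf("%d of %d analysis blocks failed", n_failed, n_blocks),
             "qus_map_failure_error")
  }
  maps <- lapply(QUS_PARAMETERS, function(p) {
    parametric_map(vals[[p]], valid[[p]], plan$ax_centers, plan$lat_centers,
                   roi, parameter = p)
  })
  names(maps) <- QUS_PARAMETERS
  structure(list(maps = maps, plan = plan, n_blocks = n_blocks,
                 n_failed = n_failed),
            class = "parametric_maps")
}

#' Render a parametric map as a 224 x 224 backbone input image
#'
#' Crops the map to the tight bounding box of the combined ROI, min-max
#' scales the valid block values to `[0, 1]`, zeroes everything outside the
#' ROI (and invalid blocks), and bilinearly resizes to 224 x 224. Channel
#' replication to the 3-channel backbone input happens in
#' [extract_features()].
#'
#' @param map A [parametric_map()] with at least one valid block.
#' @param roi Optional `roi_mask` override (defaults to the map's own).
#' @return An object of class `map_image`: `pixels` is a 224 x 224 matrix
#'   (axial rows) with finite values in `[0, 1]`.
#' @export
render_map_image <- function(map, roi = map$roi) {
  if (!any(map$valid)) {
    stop_qus("map has no valid block to render", "qus_render_error")
  }
  use <- map$valid
  v <- map$values
  rng <- range(v[use])
  scaled <- matrix(0, nrow(v), ncol(v))
  if (diff(rng) > 0) {
    scaled[use] <- (v[use] - rng[1]) / diff(rng)
  } else {
    scaled[use] <- 1
  }

  rows <- which(rowSums(use) > 0); cols <- which(colSums(use) > 0)
  rows <- min(rows):max(rows); cols <- min(cols):max(cols)
  cropped <- scaled[rows, cols, drop = FALSE]
  img <- EBImage::resize(EBImage::Image(cropped), w = 224, h = 224,
                         filter = "bilinear")
  px <- EBImage::imageData(img)
  # EBImage images are x (columns of the scene) by y; our matrix rows (axial)
  # land on the first dimension either way because we passed a plain matrix.
  px <- matrix(as.numeric(px), 224, 224)

  # zero out pixels whose physical location leaves the combined ROI
  ax_lo <- map$ax_centers[rows[1]]; ax_hi <- map$ax_centers[rows[length(rows)]]
  lat_lo <- map$lat_centers[cols[1]]; lat_hi <- map$lat_centers[cols[length(cols)]]
  ax_px <- ax_lo + (seq_len(224) - 0.5) / 224 * (ax_hi - ax_lo)
  lat_px <- lat_lo + (seq_len(224) - 0.5) / 224 * (lat_hi - lat_lo)
  if (!is.null(roi)) {
    samp_idx <- pmin(pmax(round((ax_px - roi$geometry$depth_offset) /
                                  roi$axial_spacing) + 1L, 1L),
                     ncol(roi$combined))
    line_idx <- pmin(pmax(round(lat_px / roi$lateral_spacing) + 1L, 1L),
                     nrow(roi$combined))
    inside <- roi$combined[line_idx, samp_idx, drop = FALSE]  # lat x ax
    px[!t(inside)] <- 0
  }
  px[!is.finite(px)] <- 0
  structure(list(pixels = px, parameter = map$parameter),
            class = "map_image")
}

#' Export block estimates as a CSV table
#'
#' @param maps A `parametric_maps` object from [build_maps()].
#' @param file Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_block_estimates <- function(maps, file) {
  plan <- maps$plan
  grid <- expand.grid(ax = seq_along(plan$ax_centers),
                      lat = seq_along(plan$lat_centers))
  keep <- plan$in_roi[cbind(grid$ax, grid$lat)]
  grid <- grid[keep, , drop = FALSE]
  df <- data.frame(
    block_id = seq_len(nrow(grid)),
    axial_mm = plan$ax_centers[grid$ax],
    lateral_mm = plan$lat_centers[grid$lat],
    depth_cm = plan$ax_centers[grid$ax] / 10
  )
  for (p in QUS_PARAMETERS) {
    df[[p]] <- maps$maps[[p]]$values[cbind(grid$ax, grid$lat)]
  }
  df$valid <- Reduce(`&`, lapply(maps$maps, function(m) {
    m$valid[cbind(grid$ax, grid$lat)]
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}
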