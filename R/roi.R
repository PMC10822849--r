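# Tumor ROI masks on the RF frame grid: an elliptical core plus a 5-mm
# morphological-dilation margin ring (Minkowski sum of the core with a 5-mm
# disc, minus the core), clipped at the frame edges.

#' Assemble an ROI mask from core and margin rasters
#'
#' Low-level constructor for arbitrary core/margin rasters on the RF grid
#' (scan lines x time samples); [ellipse_roi_mask()] is the usual entry
#' point. Core and margin must be disjoint.
#'
#' @param core,margin Logical matrices on the RF grid.
#' @param geometry A [scan_geometry()].
#' @param pulse A [pulse_spec()].
#' @return An object of class `roi_mask` (with the union in `combined`).
#' @export
roi_mask <- function(core, margin, geometry, pulse) {
  if (any(core & margin)) {
    stop_qus("core and margin must be disjoint", "qus_validation_error")
  }
  structure(
    list(core = core, margin = margin, combined = core | margin,
         geometry = geometry, pulse = pulse,
         axial_spacing = axial_spacing_mm(pulse),
         lateral_spacing = geometry$lateral_spacing),
    class = "roi_mask"
  )
}

#' Elliptical tumor ROI with a 5-mm margin ring
#'
#' Builds core and margin masks on the RF grid (scan lines x time samples).
#' The core is an axis-aligned ellipse; the margin is the set of pixels within
#' `margin_mm` (Euclidean, in physical mm) of the core, excluding the core —
#' i.e. a morphological dilation ring. Pixels outside the frame are clipped.
#'
#' @param geometry A [scan_geometry()].
#' @param pulse A [pulse_spec()] (fixes the axial sample grid).
#' @param center `c(lateral_mm, axial_mm)` ellipse center.
#' @param semi_axes `c(lateral_mm, axial_mm)` core semi-axes.
#' @param margin_mm Margin ring width in mm (default 5).
#' @return An object of class `roi_mask` with logical `core`, `margin` and
#'   `combined` rasters.
#' @export
ellipse_roi_mask <- function(geometry, pulse, center, semi_axes,
                             margin_mm = 5) {
  lat <- geometry_lateral_positions(geometry)
  ax <- geometry_sample_depths(geometry, pulse)
  x <- outer(lat - center[1], rep(1, length(ax)))      # n_lines x n_samples
  y <- outer(rep(1, length(lat)), ax - center[2])
  a <- semi_axes[1]; b <- semi_axes[2]
  ff <- (x / a)^2 + (y / b)^2
  core <- ff <= 1

  # Radial first guess at the distance to the ellipse, then an exact
  # boundary-sampling distance in the uncertain band around the ring edge.
  r <- sqrt(x^2 + y^2)
  r_ell <- ifelse(r > 0, r / sqrt(ff), Inf)
  d_approx <- r - r_ell
  band <- !core & d_approx > margin_mm - 1.5 & d_approx < margin_mm + 1.5
  inside_ring <- !core & d_approx <= margin_mm - 1.5
  if (any(band)) {
    theta <- seq(0, 2 * pi, length.out = 721L)[-721L]
    bx <- a * cos(theta); by <- b * sin(theta)
    px <- x[band]; py <- y[band]
    d_exact <- rep(Inf, length(px))
    for (i in seq_along(bx)) {
      d_exact <- pmin(d_exact, (px - bx[i])^2 + (py - by[i])^2)
    }
    inside_ring[band] <- sqrt(d_exact) <= margin_mm
  }
  roi_mask(core, inside_ring & !core, geometry, pulse)
}
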