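#' Transducer pulse specification
#'
#' Describes the imaging pulse: center frequency, sampling frequency, the
#' -6 dB analysis band, and the assumed tissue sound speed. Defaults follow a
#' clinical linear-array breast acquisition (6 MHz center, 3-8 MHz band,
#' 40 MHz sampling).
#'
#' @param center_frequency Pulse center frequency in MHz.
#' @param sampling_frequency RF sampling frequency in MHz. Must exceed twice
#'   the upper band edge (Nyquist).
#' @param band_low,band_high -6 dB band edges in MHz used for all spectral
#'   fits.
#' @param sound_speed Assumed sound speed in m/s (tissue default 1540).
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(center_frequency = 6, sampling_frequency = 40,
                       band_low = 3, band_high = 8, sound_speed = 1540) {
  if (!(band_low < center_frequency && center_frequency < band_high)) {
    stop_qus("band_low < center_frequency < band_high is required",
             "qus_validation_error")
  }
  if (sampling_frequency <= 2 * band_high) {
    stop_qus("sampling_frequency must exceed twice band_high (Nyquist)",
             "qus_validation_error")
  }
  structure(
    list(center_frequency = center_frequency,
         sampling_frequency = sampling_frequency,
         band_low = band_low, band_high = band_high,
         sound_speed = sound_speed),
    class = "pulse_spec"
  )
}

#' Reference phantom specification
#'
#' A tissue-mimicking calibration phantom with known attenuation, sound speed
#' and glass-bead microstructure. Defaults match a well-characterized
#' commercial calibration phantom (0.576 dB/MHz.cm, 1488 m/s).
#'
#' @param attenuation_coefficient Attenuation in dB/(MHz.cm); must be >= 0.
#' @param sound_speed Phantom sound speed in m/s.
#' @param bead_radius Effective bead radius in micrometers.
#' @param bead_density Bead number density per square millimeter.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(attenuation_coefficient = 0.576, sound_speed = 1488,
                         bead_radius = 12, bead_density = 60) {
  if (attenuation_coefficient < 0) {
    stop_qus("attenuation_coefficient must be >= 0", "qus_validation_error")
  }
  structure(
    list(attenuation_coefficient = attenuation_coefficient,
         sound_speed = sound_speed,
         bead_radius = bead_radius,
         bead_density = bead_density),
    class = "phantom_spec"
  )
}

#' Scan geometry
#'
#' Physical layout of an RF frame: scan-line count and pitch, and the axial
#' depth range covered by the recorded samples. Axial sample spacing is
#' `sound_speed / (2 * sampling_frequency)`.
#'
#' @param n_lines Number of scan lines (lateral beam positions).
#' @param lateral_spacing Scan-line pitch in mm.
#' @param depth_offset Depth of the first recorded sample, mm.
#' @param depth_max Depth of the deepest recorded sample, mm.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_lines = 96, lateral_spacing = 0.2,
                          depth_offset = 4, depth_max = 28) {
  if (n_lines < 1 || lateral_spacing <= 0 || depth_max <= depth_offset) {
    stop_qus("invalid scan geometry", "qus_validation_error")
  }
  structure(
    list(n_lines = as.integer(n_lines), lateral_spacing = lateral_spacing,
         depth_offset = depth_offset, depth_max = depth_max),
    class = "scan_geometry"
  )
}

geometry_lateral_positions <- function(geometry) {
  (seq_len(geometry$n_lines) - 1) * geometry$lateral_spacing
}

# Axial sample spacing (mm) implied by the pulse sampling rate and sound speed.
axial_spacing_mm <- function(pulse) {
  pulse$sound_speed * 1e3 / (2 * pulse$sampling_frequency * 1e6)
}

geometry_n_samples <- function(geometry, pulse) {
  dz <- axial_spacing_mm(pulse)
  as.integer(floor((geometry$depth_max - geometry$depth_offset) / dz)) + 1L
}

# Depths (mm from the transducer face) of each time sample.
geometry_sample_depths <- function(geometry, pulse) {
  dz <- axial_spacing_mm(pulse)
  geometry$depth_offset + (seq_len(geometry_n_samples(geometry, pulse)) - 1) * dz
}

#' RF frame container
#'
#' Raw backscattered echo samples on a scan-line grid. `samples` is a
#' scan-line-by-time-sample matrix (rows are scan lines).
#'
#' @param samples Numeric matrix, `n_lines x n_samples`.
#' @param geometry A [scan_geometry()].
#' @param pulse A [pulse_spec()].
#' @return An object of class `rf_frame`.
#' @export
rf_frame <- function(samples, geometry, pulse) {
  if (!is.matrix(samples) || !all(is.finite(samples))) {
    stop_qus("RF samples must be a finite numeric matrix", "qus_validation_error")
  }
  if (nrow(samples) != geometry$n_lines) {
    stop_qus("sample rows must equal the scan-line count", "qus_dimension_error")
  }
  structure(
    list(samples = samples,
         geometry = geometry,
         pulse = pulse,
         axial_spacing = axial_spacing_mm(pulse),
         lateral_spacing = geometry$lateral_spacing,
         depth_offset = geometry$depth_offset),
    class = "rf_frame"
  )
}

#' Point-scatterer field
#'
#' A sparse description of sub-resolution tissue microstructure: scatterer
#' positions, effective radii and relative impedance amplitudes. Estimator
#' recovery tests use the effective radius and the number density as the
#' ground truth behind ASD and AAC.
#'
#' @param axial,lateral Scatterer positions in mm (axial measured from the
#'   transducer face).
#' @param effective_radius Effective scatterer radius in micrometers; scalar
#'   (homogeneous field) or one value per scatterer.
#' @param amplitude Relative impedance amplitude; scalar or per scatterer.
#' @param number_density Scatterers per square millimeter (bookkeeping for the
#'   generating process; must be > 0 for non-empty fields).
#' @return An object of class `scatterer_field`.
#' @export
scatterer_field <- function(axial = numeric(), lateral = numeric(),
                            effective_radius = 15, amplitude = 1,
                            number_density = NA_real_) {
  n <- length(axial)
  if (length(lateral) != n) {
    stop_qus("axial and lateral position vectors must have equal length",
             "qus_validation_error")
  }
  if (n > 0 && !is.na(number_density) && number_density <= 0) {
    stop_qus("number_density must be > 0 for non-empty fields",
             "qus_validation_error")
  }
  structure(
    list(axial = as.numeric(axial), lateral = as.numeric(lateral),
         effective_radius = rep_len(effective_radius, max(n, 1L))[seq_len(n)],
         amplitude = rep_len(amplitude, max(n, 1L))[seq_len(n)],
         number_density = number_density),
    class = "scatterer_field"
  )
}

#' Uniform random homogeneous scatterer field
#'
#' Draws `round(density * area)` scatterers uniformly over the geometry's
#' field of view. The caller controls the RNG state (seed before calling).
#' The default impedance amplitude follows Rayleigh scattering (proportional
#' to scatterer volume, `a^3`, relative to a 15 um reference radius) so that
#' echo power carries the `n * a^6` factor the acoustic-concentration
#' estimate divides out.
#'
#' @param geometry A [scan_geometry()].
#' @param density Scatterers per square millimeter.
#' @param effective_radius Effective radius, micrometers.
#' @param amplitude Relative impedance amplitude.
#' @return A [scatterer_field()].
#' @export
random_field <- function(geometry, density, effective_radius,
                         amplitude = (effective_radius / 15)^3) {
  area <- (geometry$depth_max - geometry$depth_offset) *
    geometry$n_lines * geometry$lateral_spacing
  n <- max(round(density * area), 1L)
  scatterer_field(
    axial = stats::runif(n, geometry$depth_offset, geometry$depth_max),
    lateral = stats::runif(n, 0, (geometry$n_lines - 1) * geometry$lateral_spacing),
    effective_radius = effective_radius,
    amplitude = amplitude,
    number_density = density
  )
}
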