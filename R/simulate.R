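# RF speckle simulator: impulse-train + axial convolution model.
#
# Each scatterer contributes a Gaussian-modulated cosine echo at its
# round-trip delay, weighted laterally by a Gaussian beam profile. Echo
# spectra are shaped, per depth segment, by the frequency-dependent round-trip
# attenuation transfer 10^(-2*alpha*f*d/20) and, per radius group, by the
# spherical Gaussian form-factor amplitude exp(-0.827*k^2*a^2/2), so that echo
# POWER carries the form factor exp(-0.827*k^2*a^2) that the backscatter
# estimators assume. No elevational or nonlinear effects are modeled.

# Gaussian envelope std dev (seconds) from the -6 dB power bandwidth.
pulse_sigma_t <- function(pulse) {
  half_bw_hz <- (pulse$band_high - pulse$band_low) / 2 * 1e6
  sqrt(0.6 * log(10)) / (2 * pi * half_bw_hz)
}

# Zero-phase (wrap-around) pulse kernel spectrum on an n_fft grid.
pulse_spectrum <- function(pulse, n_fft) {
  dt <- 1 / (pulse$sampling_frequency * 1e6)
  sigma_t <- pulse_sigma_t(pulse)
  w <- ceiling(4 * sigma_t / dt)
  t <- c(0:w, -(w:1)) * dt
  p <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * pulse$center_frequency * 1e6 * t)
  kernel <- numeric(n_fft)
  kernel[c(1:(w + 1), (n_fft - w + 1):n_fft)] <- p
  list(spectrum = Re(stats::fft(kernel)), half_width = w)
}

# FFT-bin frequencies in MHz (magnitudes; two-sided grid folded at Nyquist).
fft_freqs_mhz <- function(n_fft, sampling_frequency) {
  f <- (seq_len(n_fft) - 1) / n_fft * sampling_frequency
  pmin(f, sampling_frequency - f)
}

# Form-factor amplitude filter for effective radius a (um) at frequency f (MHz).
form_factor_amplitude <- function(f_mhz, radius_um, sound_speed) {
  k <- 2 * pi * f_mhz * 1e6 / sound_speed
  exp(-0.827 * k^2 * (radius_um * 1e-6)^2 / 2)
}

#' Simulate one RF frame from a point-scatterer field
#'
#' Superposes Gaussian-modulated cosine echoes from every scatterer, with
#' Gaussian lateral beam weighting, frequency-dependent round-trip attenuation
#' and spherical Gaussian form-factor spectral shaping, plus additive white
#' Gaussian noise at a configurable SNR.
#'
#' @param field A [scatterer_field()]; positions must lie inside `geometry`.
#' @param pulse A [pulse_spec()].
#' @param geometry A [scan_geometry()].
#' @param attenuation Medium attenuation in dB/(MHz.cm), applied over the full
#'   round trip from the transducer face to each scatterer's depth.
#' @param seed Integer seed controlling the additive noise.
#' @param snr_db Signal-to-noise ratio in dB (`Inf` for noise-free). Must be
#'   non-negative.
#' @param beam_sigma Lateral beam Gaussian sigma in mm.
#' @return An [rf_frame()].
#' @export
simulate_rf_frame <- function(field, pulse, geometry, attenuation = 0,
                              seed = 1L, snr_db = 30, beam_sigma = 0.1) {
  if (!is.infinite(snr_db) && snr_db < 0) {
    stop_qus("snr_db must be non-negative", "qus_validation_error")
  }
  lat_max <- (geometry$n_lines - 1) * geometry$lateral_spacing
  n <- length(field$axial)
  if (n > 0 && (any(field$axial < geometry$depth_offset) ||
                any(field$axial > geometry$depth_max) ||
                any(field$lateral < 0) || any(field$lateral > lat_max))) {
    stop_qus("scatterer positions fall outside the scan geometry",
             "qus_dimension_error")
  }

  n_samp <- geometry_n_samples(geometry, pulse)
  dz <- axial_spacing_mm(pulse)
  sigma_t <- pulse_sigma_t(pulse)
  dt <- 1 / (pulse$sampling_frequency * 1e6)
  w <- ceiling(4 * sigma_t / dt)
  n_fft <- next_pow2(n_samp + 2L * w + 8L)
  ps <- pulse_spectrum(pulse, n_fft)
  freqs <- fft_freqs_mhz(n_fft, pulse$sampling_frequency)

  signal <- matrix(0, nrow = n_fft, ncol = geometry$n_lines)
  if (n > 0) {
    acc <- matrix(0 + 0i, nrow = n_fft, ncol = geometry$n_lines)
    lat_pos <- geometry_lateral_positions(geometry)
    cutoff <- 3 * beam_sigma
    # Expand scatterer x line pairs within the beam cutoff.
    l_min <- pmax(1L, ceiling((field$lateral - cutoff) / geometry$lateral_spacing) + 1L)
    l_max <- pmin(geometry$n_lines,
                  floor((field$lateral + cutoff) / geometry$lateral_spacing) + 1L)
    counts <- pmax(l_max - l_min + 1L, 0L)
    keep <- counts > 0L
    j <- rep(which(keep), counts[keep])
    line <- sequence(counts[keep]) - 1L + rep(l_min[keep], counts[keep])
    wgt <- exp(-(lat_pos[line] - field$lateral[j])^2 / (2 * beam_sigma^2))
    val <- field$amplitude[j] * wgt
    samp <- round((field$axial[j] - geometry$depth_offset) / dz) + 1L
    inside <- samp >= 1L & samp <= n_samp
    j <- j[inside]; line <- line[inside]; val <- val[inside]; samp <- samp[inside]

    seg_width <- 0.5  # mm; depth granularity of the attenuation transfer
    seg <- floor((field$axial[j] - geometry$depth_offset) / seg_width)
    radius_key <- match(signif(field$effective_radius[j], 6),
                        unique(signif(field$effective_radius, 6)))
    radii <- unique(signif(field$effective_radius, 6))
    group <- interaction(seg, radius_key, drop = TRUE)
    idx <- samp + (line - 1L) * n_fft
    for (g in levels(group)) {
      sel <- group == g
      impulses <- matrix(0, nrow = n_fft, ncol = geometry$n_lines)
      tab <- rowsum(val[sel], idx[sel])
      impulses[as.integer(rownames(tab))] <- tab
      d_cm <- (geometry$depth_offset + (seg[sel][1] + 0.5) * seg_width) / 10
      # amplitude transfer; echo POWER falls by 4*alpha*f*d dB round trip,
      # the convention the reference-phantom compensation assumes
      att <- 10^(-2 * attenuation * freqs * d_cm / 10)
      ff <- form_factor_amplitude(freqs, radii[radius_key[sel][1]], pulse$sound_speed)
      acc <- acc + stats::mvfft(impulses) * (att * ff)
    }
    signal <- Re(stats::mvfft(acc * ps$spectrum, inverse = TRUE)) / n_fft
  }

  rf <- t(signal[seq_len(n_samp), , drop = FALSE])
  if (is.finite(snr_db)) {
    noise_sd <- sqrt(mean(rf^2) / 10^(snr_db / 10))
    if (noise_sd > 0) {
      rf <- rf + with_local_seed(seed, {
        matrix(stats::rnorm(length(rf), sd = noise_sd), nrow = nrow(rf))
      })
    }
  }
  rf_frame(rf, geometry, pulse)
}

#' Simulate a reference-phantom RF frame
#'
#' Generates a homogeneous random bead field with the phantom's attenuation
#' and sound speed and simulates its RF frame. The analytic expected
#' backscatter coefficient of the phantom is available through
#' [reference_bsc()] for normalization and oracle use.
#'
#' @param phantom A [phantom_spec()].
#' @param pulse A [pulse_spec()]; its sound speed is replaced by the
#'   phantom's for this frame.
#' @param geometry A [scan_geometry()].
#' @param seed Integer seed (bead positions and noise).
#' @param snr_db Signal-to-noise ratio in dB.
#' @return An [rf_frame()].
#' @export
make_reference_frame <- function(phantom, pulse, geometry, seed = 1L,
                                 snr_db = 30) {
  ref_pulse <- pulse
  ref_pulse$sound_speed <- phantom$sound_speed
  # The phantom is recorded over the same TIME gate as the tissue frame; its
  # depth axis scales with its sound speed so that sample counts (and hence
  # block gates) align sample-for-sample with the tissue frame.
  ratio <- phantom$sound_speed / pulse$sound_speed
  ref_geometry <- geometry
  ref_geometry$depth_offset <- geometry$depth_offset * ratio
  ref_geometry$depth_max <- geometry$depth_max * ratio
  field <- with_local_seed(derive_seed(seed, 101L), {
    random_field(ref_geometry, phantom$bead_density, phantom$bead_radius)
  })
  simulate_rf_frame(field, ref_pulse, ref_geometry,
                    attenuation = phantom$attenuation_coefficient,
                    seed = derive_seed(seed, 202L), snr_db = snr_db)
}
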