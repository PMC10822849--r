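# Per-block spectral estimation: Hann-gated scan-line periodograms averaged
# into a mean power spectrum, reference-phantom normalization with round-trip
# attenuation compensation, and the linear-fit spectral parameters MBF/SS/SI.

DB_FLOOR <- -200

#' Power spectrum container
#'
#' @param frequencies Strictly increasing frequency grid, MHz.
#' @param values Spectrum values, dB.
#' @param block_depth Block depth, cm (metadata for attenuation
#'   compensation).
#' @param kind `"raw"` or `"normalized"`.
#' @param clamped Logical vector flagging bins that hit the -200 dB floor
#'   (defaults to `values <= -200`).
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(frequencies, values, block_depth = NA_real_,
                           kind = c("raw", "normalized"), clamped = NULL) {
  kind <- match.arg(kind)
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop_qus("frequency grid must be strictly increasing", "qus_validation_error")
  }
  if (is.null(clamped)) clamped <- values <= DB_FLOOR
  structure(
    list(frequencies = frequencies, values = values, block_depth = block_depth,
         kind = kind, clamped = clamped, floor_clamped = any(clamped)),
    class = "power_spectrum"
  )
}

#' Mean power spectrum of an RF block
#'
#' Applies a Hann taper to each scan-line segment, computes magnitude-squared
#' Fourier transforms zero-padded to at least four times the gate length, and
#' arithmetically averages the scan-line spectra before conversion to
#' decibels. Zero-power bins are clamped at -200 dB and flagged.
#'
#' @param block Numeric matrix of RF samples, scan lines in rows, with at
#'   least one line and 16 time samples.
#' @param pulse A [pulse_spec()] (supplies the sampling frequency).
#' @param block_depth Depth of the block center in cm (carried as metadata for
#'   attenuation compensation).
#' @return A `power_spectrum` of kind `"raw"` on the one-sided FFT grid (MHz).
#' @export
block_power_spectrum <- function(block, pulse, block_depth = NA_real_) {
  if (!is.matrix(block) || nrow(block) < 1 || ncol(block) < 16) {
    stop_qus("block must be a matrix with >= 1 scan line and >= 16 samples",
             "qus_validation_error")
  }
  n_gate <- ncol(block)
  n_fft <- next_pow2(4L * n_gate)
  taper <- as.numeric(signal::hanning(n_gate))
  gated <- t(block) * taper                 # samples x lines
  padded <- matrix(0, nrow = n_fft, ncol = ncol(gated))
  padded[seq_len(n_gate), ] <- gated
  spec <- Mod(stats::mvfft(padded))^2
  mean_power <- rowMeans(spec)[seq_len(n_fft / 2 + 1)]
  freqs <- (seq_len(n_fft / 2 + 1) - 1) / n_fft * pulse$sampling_frequency
  db <- ifelse(mean_power > 0, 10 * log10(mean_power), DB_FLOOR)
  db <- pmax(db, DB_FLOOR)
  power_spectrum(freqs, db, block_depth = block_depth, kind = "raw",
                 clamped = mean_power <= 0 | db <= DB_FLOOR)
}

#' Reference-phantom normalization of a power spectrum
#'
#' Divides (in dB: subtracts) the sample spectrum by the reference-phantom
#' spectrum measured over the same gate, cancelling the system transfer
#' function and beam effects, and compensates the round-trip attenuation
#' difference with `4 * (alpha_sample - alpha_ref) * f * depth` dB (f in MHz,
#' depth in cm).
#'
#' @param sample,reference `power_spectrum` objects on one common frequency
#'   grid and block depth.
#' @param alpha_sample,alpha_ref Attenuation coefficients in dB/(MHz.cm).
#' @param depth Block depth in cm; defaults to the sample's recorded depth.
#' @return A `power_spectrum` of kind `"normalized"`.
#' @export
normalize_spectrum <- function(sample, reference, alpha_sample, alpha_ref,
                               depth = NULL) {
  if (!isTRUE(all.equal(sample$frequencies, reference$frequencies))) {
    stop_qus("sample and reference must share one frequency grid",
             "qus_alignment_error")
  }
  if (is.null(depth)) depth <- sample$block_depth
  if (!is.finite(depth)) {
    stop_qus("a finite block depth (cm) is required", "qus_validation_error")
  }
  if (is.finite(reference$block_depth) && is.finite(sample$block_depth) &&
      !isTRUE(all.equal(sample$block_depth, reference$block_depth))) {
    stop_qus("sample and reference must share one block depth",
             "qus_alignment_error")
  }
  comp <- 4 * (alpha_sample - alpha_ref) * sample$frequencies * depth
  power_spectrum(sample$frequencies, sample$values - reference$values + comp,
                 block_depth = depth, kind = "normalized",
                 clamped = (sample$clamped %||% (sample$values <= DB_FLOOR)) |
                   (reference$clamped %||% (reference$values <= DB_FLOOR)))
}

spectral_params <- function(MBF, SS, SI) {
  structure(list(MBF = MBF, SS = SS, SI = SI), class = "spectral_params")
}

#' Linear-fit spectral parameters (MBF, SS, SI)
#'
#' Ordinary least squares of the normalized spectrum (dB) against frequency
#' (MHz), restricted to the -6 dB band. The spectral slope SS is the fitted
#' slope, the spectral intercept SI the 0 MHz intercept, and the midband fit
#' MBF the fitted value at the pulse center frequency, so that
#' `MBF = SI + SS * f_c` holds exactly.
#'
#' @param nps A `power_spectrum` of kind `"normalized"`.
#' @param pulse A [pulse_spec()]; its band edges delimit the fit.
#' @return A `spectral_params` object with fields `MBF` (dB), `SS` (dB/MHz)
#'   and `SI` (dB).
#' @export
fit_spectral_params <- function(nps, pulse) {
  if (!identical(nps$kind, "normalized")) {
    stop_qus("spectrum must be normalized before fitting", "qus_validation_error")
  }
  in_band <- nps$frequencies >= pulse$band_low & nps$frequencies <= pulse$band_high
  if (sum(in_band) < 3) {
    stop_qus("fewer than 3 frequency points inside the fit band",
             "qus_insufficient_support_error")
  }
  y <- nps$values[in_band]
  if (!all(is.finite(y)) || any(nps$clamped[in_band])) {
    stop_qus("non-finite or floor-clamped values inside the fit band",
             "qus_validation_error")
  }
  fit <- stats::lm.fit(cbind(1, nps$frequencies[in_band]), y)
  si <- unname(fit$coefficients[1])
  ss <- unname(fit$coefficients[2])
  spectral_params(MBF = si + ss * pulse$center_frequency, SS = ss, SI = si)
}
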