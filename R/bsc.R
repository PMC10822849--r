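# Backscatter-coefficient estimation and the spherical Gaussian form-factor
# fit yielding the scatterer parameters ASD (average scatterer diameter) and
# AAC (average acoustic concentration).
#
# Model: BSC(f) = C * f^4 * exp(-0.827 * k^2 * a_eff^2), k = 2*pi*f/c.
# With C parameterized as concentration * a_eff^6, the reported
# AAC = 10*log10(C / a_eff^6) tracks scatterer concentration on a dB scale.

#' Backscatter-coefficient curve container
#'
#' @param frequencies Strictly increasing frequency grid, MHz.
#' @param values Backscatter coefficient, linear scale.
#' @return An object of class `bsc_curve`.
#' @export
bsc_curve <- function(frequencies, values) {
  if (is.unsorted(frequencies, strictly = TRUE)) {
    stop_qus("frequency grid must be strictly increasing", "qus_validation_error")
  }
  structure(list(frequencies = frequencies, values = values),
            class = "bsc_curve")
}

#' Spherical Gaussian form-factor backscatter model
#'
#' Evaluates `concentration * a_eff^6 * f^4 * exp(-0.827 * k^2 * a_eff^2)`
#' with `k = 2*pi*f/c`; the Rayleigh `f^4` rise damped by Gaussian
#' form-factor decay. Used both as the analytic reference-phantom curve and
#' as the generating model in estimator recovery tests.
#'
#' @param frequencies Frequencies in MHz.
#' @param a_eff Effective scatterer radius in micrometers.
#' @param concentration Linear acoustic concentration (relative units).
#' @param sound_speed Sound speed in m/s.
#' @return A `bsc_curve` (linear scale, 1/(sr.cm) up to a fixed constant).
#' @export
bsc_model <- function(frequencies, a_eff, concentration = 1,
                      sound_speed = 1540) {
  k <- 2 * pi * frequencies * 1e6 / sound_speed
  vals <- concentration * a_eff^6 * frequencies^4 *
    exp(-0.827 * k^2 * (a_eff * 1e-6)^2)
  bsc_curve(frequencies, vals)
}

#' Analytic backscatter coefficient of the reference phantom
#'
#' The expected phantom BSC implied by its bead radius and density under the
#' spherical Gaussian form-factor model, used to transfer the normalized
#' spectrum onto an absolute (relative-unit) BSC scale.
#'
#' @param phantom A [phantom_spec()].
#' @param frequencies Frequencies in MHz.
#' @return A `bsc_curve`.
#' @export
reference_bsc <- function(phantom, frequencies) {
  bsc_model(frequencies, phantom$bead_radius, phantom$bead_density,
            phantom$sound_speed)
}

#' Backscatter coefficient via the reference-phantom method
#'
#' Transfers the normalized spectrum onto the reference BSC scale:
#' `BSC_sample(f) = BSC_ref(f) * 10^(NPS(f)/10)`.
#'
#' @param nps A normalized `power_spectrum`.
#' @param reference A `bsc_curve` on the same frequency grid (see
#'   [reference_bsc()]).
#' @return A `bsc_curve` for the sample.
#' @export
estimate_bsc <- function(nps, reference) {
  if (!identical(nps$kind, "normalized")) {
    stop_qus("spectrum must be normalized before BSC estimation",
             "qus_validation_error")
  }
  if (!isTRUE(all.equal(nps$frequencies, reference$frequencies))) {
    stop_qus("BSC reference grid does not match the spectrum grid",
             "qus_alignment_error")
  }
  bsc_curve(nps$frequencies, reference$values * 10^(nps$values / 10))
}

scatterer_params <- function(ASD, AAC, a_eff, concentration) {
  structure(list(ASD = ASD, AAC = AAC, a_eff = a_eff,
                 concentration = concentration),
            class = "scatterer_params")
}

#' Fit the spherical Gaussian form factor to a BSC curve
#'
#' Linearized least squares: `log(BSC/f^4)` is regressed on `k^2`; the slope
#' gives the effective radius (`ASD = 2 * a_eff`, micrometers) and the
#' intercept the amplitude factor `C`, reported as
#' `AAC = 10*log10(C / a_eff^6)` dB so that AAC tracks concentration.
#' A non-negative slope (no Gaussian decay with frequency) raises a fit
#' failure rather than returning a silent number.
#'
#' @param bsc A `bsc_curve`, strictly positive on the fit band.
#' @param sound_speed Sound speed in m/s used to convert frequency to
#'   wavenumber.
#' @param band Fit band in MHz (default the 3-8 MHz transducer band).
#' @return A `scatterer_params` object with `ASD` (micrometers) and `AAC` (dB).
#' @export
fit_gaussian_form_factor <- function(bsc, sound_speed = 1540, band = c(3, 8)) {
  sel <- bsc$frequencies >= band[1] & bsc$frequencies <= band[2] &
    bsc$frequencies > 0
  f <- bsc$frequencies[sel]
  v <- bsc$values[sel]
  if (length(f) < 3) {
    stop_qus("fewer than 3 frequency points inside the fit band",
             "qus_insufficient_support_error")
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop_qus("BSC must be strictly positive and finite on the fit band",
             "qus_validation_error")
  }
  k2 <- (2 * pi * f * 1e6 / sound_speed)^2
  y <- log(v / f^4)
  fit <- stats::lm.fit(cbind(1, k2), y)
  slope <- unname(fit$coefficients[2])
  if (!is.finite(slope) || slope >= 0) {
    stop_qus(sprintf(
      "form-factor fit failed: regression slope %.3g >= 0 (no Gaussian decay)",
      slope), "qus_fit_error")
  }
  a_eff_m <- sqrt(-slope / 0.827)
  a_eff_um <- a_eff_m * 1e6
  c_amp <- exp(unname(fit$coefficients[1]))
  scatterer_params(ASD = 2 * a_eff_um,
                   AAC = 10 * log10(c_amp / a_eff_um^6),
                   a_eff = a_eff_um,
                   concentration = c_amp / a_eff_um^6)
}
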