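test_that("a pure tone peaks at the nearest grid frequency", {
  fs <- 40; f0 <- 6
  t <- (0:255) / fs
  block <- matrix(cos(2 * pi * f0 * t), nrow = 1, byrow = TRUE)
  spec <- block_power_spectrum(block, std_pulse())
  f_peak <- spec$frequencies[which.max(spec$values)]
  expect_lt(abs(f_peak - f0), diff(spec$frequencies[1:2]))
})

test_that("degenerate blocks are clamped and refused downstream", {
  expect_error(block_power_spectrum(matrix(0, 0, 20), std_pulse()),
               class = "qus_validation_error")
  zero <- block_power_spectrum(matrix(0, 2, 64), std_pulse())
  expect_true(zero$floor_clamped)
  expect_true(all(zero$values == -200))
  nps <- normalize_spectrum(zero, zero, alpha_sample = 1, alpha_ref = 1,
                            depth = 1)
  expect_error(fit_spectral_params(nps, std_pulse()),
               class = "qus_validation_error")
})

test_that("averaging duplicated scan lines reproduces the single-line spectrum", {
  set.seed(3)
  line <- rnorm(128)
  one <- block_power_spectrum(matrix(line, nrow = 1, byrow = TRUE), std_pulse())
  two <- block_power_spectrum(rbind(line, line), std_pulse())
  expect_equal(two$values, one$values, tolerance = 1e-12)
})

test_that("normalization identities hold, including the +12 dB compensation", {
  set.seed(4)
  block <- matrix(rnorm(6 * 128), nrow = 6)
  sp <- block_power_spectrum(block, std_pulse(), block_depth = 1)
  same <- normalize_spectrum(sp, sp, alpha_sample = 0.7, alpha_ref = 0.7)
  expect_true(all(same$values == 0))

  # identical spectra, attenuation difference 0.5 dB/MHz.cm at 1 cm: the
  # compensation term alone, 4 * 0.5 * f * 1, must appear — 12 dB at 6 MHz
  freqs <- seq(2, 10, by = 0.5)
  flat <- power_spectrum(freqs, rep(-30, length(freqs)), block_depth = 1,
                         kind = "raw")
  comp <- normalize_spectrum(flat, flat, alpha_sample = 1.076,
                             alpha_ref = 0.576, depth = 1)
  expect_equal(comp$values[comp$frequencies == 6], 12)
  expect_equal(comp$values, 2 * freqs)

  other <- block_power_spectrum(block, std_pulse(), block_depth = 2)
  expect_error(normalize_spectrum(sp, other, 1, 1),
               class = "qus_alignment_error")
})

test_that("spectral-line fits recover slope, intercept and midband exactly", {
  fit <- fit_spectral_params(line_spectrum(2, 3), std_pulse())
  expect_equal(fit$SS, 2, tolerance = 1e-12)
  expect_equal(fit$SI, 3, tolerance = 1e-12)
  expect_equal(fit$MBF, 15, tolerance = 1e-12)

  flat <- fit_spectral_params(line_spectrum(0, -4.5), std_pulse())
  expect_equal(flat$SS, 0, tolerance = 1e-12)
  expect_equal(flat$SI, -4.5, tolerance = 1e-12)
  expect_equal(flat$MBF, -4.5, tolerance = 1e-12)

  sparse <- power_spectrum(c(1, 5, 9), c(0, 0, 0), kind = "normalized")
  expect_error(fit_spectral_params(sparse, std_pulse()),
               class = "qus_insufficient_support_error")
  raw <- power_spectrum(1:10, rep(0, 10), kind = "raw")
  expect_error(fit_spectral_params(raw, std_pulse()),
               class = "qus_validation_error")
})

test_that("the midband identity MBF = SI + SS * f_c holds for every fit", {
  set.seed(6)
  for (i in 1:20) {
    nps <- line_spectrum(runif(1, -3, 3), runif(1, -20, 20))
    nps$values <- nps$values + rnorm(length(nps$values), sd = 2)
    fit <- fit_spectral_params(nps, std_pulse())
    expect_identical(fit$MBF, fit$SI + fit$SS * 6)
  }
})

test_that("noisy-line slope estimates match the closed-form OLS error", {
  truth <- 1.5; sigma <- 0.8
  freqs <- seq(2, 10, by = 0.25)
  in_band <- freqs >= 3 & freqs <= 8
  se_slope <- sigma / sqrt(sum((freqs[in_band] - mean(freqs[in_band]))^2))
  set.seed(8)
  ss <- vapply(1:100, function(i) {
    nps <- line_spectrum(truth, -2)
    nps$values <- nps$values + rnorm(length(freqs), sd = sigma)
    fit_spectral_params(nps, std_pulse())$SS
  }, numeric(1))
  expect_lt(abs(mean(ss) - truth), 2 * se_slope / sqrt(100))
})

test_that("BSC transfer is exact for identity and decade shifts", {
  freqs <- seq(3, 8, by = 0.25)
  ref <- reference_bsc(std_phantom(), freqs)
  zero <- power_spectrum(freqs, rep(0, length(freqs)), kind = "normalized",
                         block_depth = 1)
  expect_equal(estimate_bsc(zero, ref)$values, ref$values)
  ten <- power_spectrum(freqs, rep(10, length(freqs)), kind = "normalized",
                        block_depth = 1)
  expect_equal(estimate_bsc(ten, ref)$values, 10 * ref$values)
  offgrid <- bsc_curve(freqs + 0.1, ref$values)
  expect_error(estimate_bsc(zero, offgrid), class = "qus_alignment_error")
})

test_that("form-factor refits of the generating model are exact", {
  freqs <- seq(3, 8, by = 0.1)
  bsc <- bsc_model(freqs, a_eff = 25, concentration = 40)
  fit <- fit_gaussian_form_factor(bsc, sound_speed = 1540)
  expect_equal(fit$ASD, 50, tolerance = 1e-9)
  expect_equal(fit$AAC, 10 * log10(40), tolerance = 1e-9)

  rayleigh <- bsc_curve(freqs, freqs^4)  # a_eff = 0: no Gaussian decay
  expect_error(fit_gaussian_form_factor(rayleigh, 1540),
               class = "qus_fit_error")
})

test_that("form-factor fits tolerate multiplicative noise (median within 10%)", {
  freqs <- seq(3, 8, by = 0.1)
  clean <- bsc_model(freqs, a_eff = 25, concentration = 40)
  set.seed(12)
  asd <- vapply(1:200, function(i) {
    noisy <- bsc_curve(freqs, clean$values * (1 + rnorm(length(freqs), sd = 0.05)))
    fit_gaussian_form_factor(noisy, 1540)$ASD
  }, numeric(1))
  expect_lt(abs(median(asd) - 50) / 50, 0.10)
})

test_that("a simulated block's BSC matches the analytic truth within 3 dB", {
  plan <- plan_windows(small_roi(), std_pulse(), overlap = 0.5)
  frame <- small_sample_frame()
  reffr <- small_reference()
  lat_pos <- qusresponse:::geometry_lateral_positions(frame$geometry)
  depths <- qusresponse:::geometry_sample_depths(frame$geometry, frame$pulse)
  half <- plan$block_side / 2
  centers <- window_centers(plan)
  mid <- centers[abs(centers$axial - 14) < 1.2 & abs(centers$lateral - 9.5) < 2, ]
  est <- NULL
  for (b in seq_len(nrow(mid))) {
    lines <- which(abs(lat_pos - mid$lateral[b]) <= half)
    samp <- which(abs(depths - mid$axial[b]) <= half)
    sp_s <- block_power_spectrum(frame$samples[lines, samp], std_pulse(),
                                 block_depth = mid$axial[b] / 10)
    sp_r <- block_power_spectrum(reffr$samples[lines, samp], std_pulse(),
                                 block_depth = mid$axial[b] / 10)
    nps <- normalize_spectrum(sp_s, sp_r, alpha_sample = 0.75,
                              alpha_ref = std_phantom()$attenuation_coefficient)
    bsc <- estimate_bsc(nps, reference_bsc(std_phantom(), nps$frequencies))
    est <- rbind(est, bsc$values)
  }
  med <- apply(est, 2, median)
  in_band <- bsc$frequencies >= 3 & bsc$frequencies <= 8
  truth <- bsc_model(bsc$frequencies, a_eff = 27, concentration = 50,
                     sound_speed = 1540)
  ratio_db <- 10 * log10(med[in_band] / truth$values[in_band])
  expect_lt(max(abs(ratio_db)), 3)
})

test_that("attenuation compensation flattens a known-attenuation sample", {
  # alpha = 0 phantom: the analytic compensation must remove the simulated
  # frequency-dependent attenuation up to the form-factor difference.
  g <- small_geometry()
  ph0 <- phantom_spec(attenuation_coefficient = 0, bead_radius = 27)
  field <- withr::with_seed(21, random_field(g, 50, 27))
  frame <- simulate_rf_frame(field, std_pulse(), g, attenuation = 0.8,
                             seed = 21, snr_db = Inf)
  reffr <- make_reference_frame(ph0, std_pulse(), g, seed = 22, snr_db = Inf)
  depths <- qusresponse:::geometry_sample_depths(g, std_pulse())
  vals <- NULL
  for (d0 in c(8, 10, 12, 14, 16, 18, 20)) {
    samp <- which(abs(depths - d0) <= 1.1)
    sp_s <- block_power_spectrum(frame$samples[, samp], std_pulse(),
                                 block_depth = d0 / 10)
    sp_r <- block_power_spectrum(reffr$samples[, samp], std_pulse(),
                                 block_depth = d0 / 10)
    nps <- normalize_spectrum(sp_s, sp_r, alpha_sample = 0.8, alpha_ref = 0)
    in_band <- nps$frequencies >= 3 & nps$frequencies <= 8
    # same bead radius as tissue: form factors cancel; residual is flat
    vals <- rbind(vals, nps$values[in_band])
  }
  med <- apply(vals, 2, median)
  expect_lt(max(med) - min(med), 2)
  fitp <- fit_spectral_params(
    power_spectrum(nps$frequencies[in_band], med, block_depth = 1,
                   kind = "normalized"), std_pulse())
  expect_lt(abs(fitp$SS), 0.2)
})

test_that("a scalar RF gain moves SI but never SS, and scales BSC by gain^2", {
  plan <- plan_windows(small_roi(), std_pulse(), overlap = 0.5)
  frame <- small_sample_frame()
  gained <- frame
  gained$samples <- frame$samples * 2
  reffr <- small_reference()
  depths <- qusresponse:::geometry_sample_depths(frame$geometry, frame$pulse)
  samp <- which(abs(depths - 14) <= 1.1)
  ref_sp <- block_power_spectrum(reffr$samples[, samp], std_pulse(),
                                 block_depth = 1.4)
  nps_of <- function(fr) {
    sp <- block_power_spectrum(fr$samples[, samp], std_pulse(),
                               block_depth = 1.4)
    normalize_spectrum(sp, ref_sp, alpha_sample = 0.75,
                       alpha_ref = std_phantom()$attenuation_coefficient)
  }
  n1 <- nps_of(frame); n2 <- nps_of(gained)
  f1 <- fit_spectral_params(n1, std_pulse())
  f2 <- fit_spectral_params(n2, std_pulse())
  expect_equal(f1$SS, f2$SS, tolerance = 1e-10)
  expect_equal(f2$SI - f1$SI, 20 * log10(2), tolerance = 1e-9)
  ref <- reference_bsc(std_phantom(), n1$frequencies)
  expect_equal(estimate_bsc(n2, ref)$values,
               4 * estimate_bsc(n1, ref)$values, tolerance = 1e-9)
})
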