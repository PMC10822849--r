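# Synthetic labeled cohorts: RF frames with known per-patient scatterer
# ground truth (for estimator recovery), plus a direct feature-level cohort
# simulator for classifier calibration at full cohort size.

#' Cohort generation configuration
#'
#' Defaults emulate the reference two-class cohort: 37 nonresponders (NR)
#' versus 137 responders (RR), 4-7 image planes per patient, 6 MHz pulse
#' sampled at 40 MHz, and the calibrated reference phantom
#' (0.576 dB/MHz.cm, 1488 m/s). Class separation is induced through
#' scatterer radius (NR larger) and number density (NR lower); the magnitudes
#' are stipulated, not measured, and give visibly separable spectral-slope
#' maps.
#'
#' @param n_nr,n_rr Class sizes (both must be positive).
#' @param frames_range Range of image planes per patient, within `[4, 7]`.
#' @param geometry,pulse,phantom Acquisition setup.
#' @param alpha_sample True simulated tissue attenuation, dB/(MHz.cm).
#' @param snr_db Additive-noise SNR.
#' @param nr,rr Per-class scatterer distributions: mean/sd of effective
#'   radius (micrometers) and of number density (per mm^2).
#' @param roi_semi_axes Tumor-core ellipse semi-axes `c(lateral, axial)`, mm.
#' @param margin_mm Margin ring width, mm.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_nr = 37L, n_rr = 137L, frames_range = c(4L, 7L),
                          geometry = scan_geometry(), pulse = pulse_spec(),
                          phantom = phantom_spec(), alpha_sample = 0.75,
                          snr_db = 30,
                          nr = list(radius_mean = 32, radius_sd = 3,
                                    density_mean = 35, density_sd = 4),
                          rr = list(radius_mean = 22, radius_sd = 3,
                                    density_mean = 60, density_sd = 6),
                          roi_semi_axes = c(3, 4), margin_mm = 5) {
  if (n_nr <= 0L || n_rr <= 0L) {
    stop_qus("class counts must be positive", "qus_validation_error")
  }
  if (frames_range[1] < 4L || frames_range[2] > 7L ||
      frames_range[1] > frames_range[2]) {
    stop_qus("frames_range must lie within [4, 7]", "qus_validation_error")
  }
  structure(
    list(n_nr = as.integer(n_nr), n_rr = as.integer(n_rr),
         frames_range = as.integer(frames_range), geometry = geometry,
         pulse = pulse, phantom = phantom, alpha_sample = alpha_sample,
         snr_db = snr_db, nr = nr, rr = rr, roi_semi_axes = roi_semi_axes,
         margin_mm = margin_mm),
    class = "cohort_config"
  )
}

#' Generate a labeled synthetic RF cohort
#'
#' Draws per-patient ground-truth scatterer radius and density from the
#' class distributions, simulates 4-7 RF frames per patient (independent
#' speckle realizations of the same patient truth), builds the shared
#' elliptical core + margin ROI, and simulates one reference-phantom frame.
#' Regeneration with the same seed is bit-identical.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_cohort` with `patients` (each holding
#'   `patient_id`, `label`, `truth`, `frames`, `roi`), the shared
#'   `reference` frame, and a ground-`truth` data frame.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  g <- config$geometry; p <- config$pulse
  labels <- c(rep("NR", config$n_nr), rep("RR", config$n_rr))
  n <- length(labels)
  draws <- with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      cls <- if (labels[i] == "NR") config$nr else config$rr
      list(radius = max(stats::rnorm(1, cls$radius_mean, cls$radius_sd), 2),
           density = max(stats::rnorm(1, cls$density_mean, cls$density_sd), 5),
           n_frames = config$frames_range[1] +
             sample.int(config$frames_range[2] - config$frames_range[1] + 1L,
                        1L) - 1L)
    })
  })
  roi_center <- c((g$n_lines - 1) * g$lateral_spacing / 2,
                  (g$depth_offset + g$depth_max) / 2)
  roi <- ellipse_roi_mask(g, p, roi_center, config$roi_semi_axes,
                          config$margin_mm)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    frames <- lapply(seq_len(d$n_frames), function(j) {
      fseed <- derive_seed(seed, i * 31L + j)
      field <- with_local_seed(fseed, {
        random_field(g, d$density, d$radius)
      })
      simulate_rf_frame(field, p, g, attenuation = config$alpha_sample,
                        seed = derive_seed(fseed, 1L), snr_db = config$snr_db)
    })
    patients[[i]] <- list(patient_id = sprintf("P%03d", i), label = labels[i],
                          truth = d, frames = frames, roi = roi)
  }
  truth <- data.frame(
    patient_id = vapply(patients, `[[`, character(1), "patient_id"),
    label = labels,
    n_frames = vapply(draws, `[[`, numeric(1), "n_frames"),
    radius = vapply(draws, `[[`, numeric(1), "radius"),
    density = vapply(draws, `[[`, numeric(1), "density")
  )
  structure(
    list(patients = patients,
         reference = make_reference_frame(config$phantom, p, g,
                                          seed = derive_seed(seed, 999983L),
                                          snr_db = config$snr_db),
         roi = roi, config = config, seed = seed, truth = truth),
    class = "synthetic_cohort"
  )
}

#' Patient-level backbone features for one QUS parameter
#'
#' Runs the full imaging chain for every patient: parametric maps per frame,
#' 224 x 224 map-image rendering, frozen-backbone feature extraction, and
#' per-tumor averaging across image planes.
#'
#' @param cohort A `synthetic_cohort`.
#' @param parameter One of `"ASD", "AAC", "MBF", "SS", "SI"`.
#' @param bb A `qus_backbone`.
#' @param overlap Sliding-window overlap for [plan_windows()].
#' @param block_side Analysis-block side, mm.
#' @param max_frames Cap on image planes used per patient (cost control;
#'   `Inf` uses all).
#' @return A list with the feature matrix `X` (patients x 100,352), labels
#'   `y`, and the `parameter`.
#' @export
cohort_features <- function(cohort, parameter = "SS",
                            bb = random_projection_backbone(),
                            overlap = 0.5, block_side = 2.2,
                            max_frames = Inf) {
  qcfg <- qus_config(alpha_sample = cohort$config$alpha_sample,
                     phantom = cohort$config$phantom)
  plan <- plan_windows(cohort$roi, cohort$config$pulse, overlap = overlap,
                       block_side = block_side)
  feats <- lapply(cohort$patients, function(pt) {
    use <- seq_len(min(length(pt$frames), max_frames))
    vecs <- lapply(pt$frames[use], function(fr) {
      maps <- build_maps(fr, cohort$reference, pt$roi, plan, qcfg)
      extract_features(render_map_image(maps$maps[[parameter]]), bb)
    })
    average_tumor_features(vecs)
  })
  list(X = do.call(rbind, feats),
       y = factor(vapply(cohort$patients, `[[`, character(1), "label"),
                  levels = c("NR", "RR")),
       parameter = parameter)
}

#' Feature-level synthetic cohort
#'
#' Generates a patients x features Gaussian feature table directly, with an
#' optional class effect: `n_informative` evenly spread columns are shifted
#' by `effect_size` standard deviations in the NR rows. `effect_size = 0`
#' gives a label-free null cohort for calibration; large values give a
#' strongly separated cohort.
#'
#' @param n_nr,n_rr Class sizes.
#' @param n_features Feature dimension (default the backbone's 100,352).
#' @param effect_size Class mean shift, in units of the feature SD.
#' @param n_informative Number of shifted columns.
#' @param seed Integer seed.
#' @return A list with `X`, `y` and the `informative` column indices.
#' @export
simulate_feature_cohort <- function(n_nr = 37L, n_rr = 137L,
                                    n_features = 100352L, effect_size = 0,
                                    n_informative = 64L, seed = 1L) {
  n <- n_nr + n_rr
  informative <- unique(round(seq(1, n_features, length.out = n_informative)))
  X <- with_local_seed(seed, {
    matrix(stats::rnorm(n * n_features), nrow = n)
  })
  y <- factor(c(rep("NR", n_nr), rep("RR", n_rr)), levels = c("NR", "RR"))
  if (effect_size != 0) {
    X[y == "NR", informative] <- X[y == "NR", informative] + effect_size
  }
  list(X = X, y = y, informative = informative)
}

#' Persist / restore a synthetic cohort
#'
#' Writes the cohort payload to `<dir>/cohort.rds` alongside a plain-text
#' `manifest.csv` (patient id, label, frame count, ground-truth parameters).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$truth, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  saveRDS(cohort, file.path(dir, "cohort.rds"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  readRDS(file.path(dir, "cohort.rds"))
}

#' Estimator recovery experiment on a synthetic two-arm cohort
#'
#' Builds a calibration cohort that isolates each scatterer parameter: a
#' radius arm (radius varied over >= 3 levels at fixed density, probing ASD
#' recovery) and a density arm (density varied over >= 3 levels at fixed
#' radius, probing AAC recovery). Each patient contributes `n_frames`
#' independent speckle realizations; per-patient block-median ASD and AAC are
#' reported with Spearman rank correlations against the ground truth.
#'
#' @param radius_levels Effective radii (micrometers) for the radius arm.
#' @param density_levels Number densities (per mm^2) for the density arm.
#' @param patients_per_level Patients simulated per level in each arm.
#' @param fixed_radius,fixed_density The held-constant value in the opposite
#'   arm.
#' @param n_frames Frames per patient.
#' @param seed Integer seed.
#' @param geometry,pulse,phantom Acquisition setup.
#' @param alpha_sample True simulated tissue attenuation, dB/(MHz.cm).
#' @param overlap Sliding-window overlap.
#' @return A list with the per-patient `table` (arm, truth, median ASD/AAC)
#'   and `rho_asd_radius`, `rho_aac_density` Spearman correlations.
#' @export
recovery_experiment <- function(radius_levels = c(18, 22, 26, 30, 34),
                                density_levels = c(20, 40, 60, 80, 100),
                                patients_per_level = 2L,
                                fixed_radius = 27, fixed_density = 50,
                                n_frames = 4L, seed = 1L,
                                geometry = scan_geometry(),
                                pulse = pulse_spec(),
                                phantom = phantom_spec(),
                                alpha_sample = 0.75, overlap = 0.5) {
  roi_center <- c((geometry$n_lines - 1) * geometry$lateral_spacing / 2,
                  (geometry$depth_offset + geometry$depth_max) / 2)
  roi <- ellipse_roi_mask(geometry, pulse, roi_center, c(3, 4))
  plan <- plan_windows(roi, pulse, overlap = overlap)
  qcfg <- qus_config(alpha_sample = alpha_sample, phantom = phantom)
  fref <- make_reference_frame(phantom, pulse, geometry,
                               seed = derive_seed(seed, 7919L))
  run_patient <- function(radius, density, pseed) {
    asd <- aac <- c()
    for (j in seq_len(n_frames)) {
      fseed <- derive_seed(pseed, j)
      field <- with_local_seed(fseed, random_field(geometry, density, radius))
      fr <- simulate_rf_frame(field, pulse, geometry,
                              attenuation = alpha_sample,
                              seed = derive_seed(fseed, 1L))
      m <- build_maps(fr, fref, roi, plan, qcfg)
      asd <- c(asd, m$maps$ASD$values[m$maps$ASD$valid])
      aac <- c(aac, m$maps$AAC$values[m$maps$AAC$valid])
    }
    c(stats::median(asd), stats::median(aac))
  }
  radii <- rep(radius_levels, each = patients_per_level)
  dens <- rep(density_levels, each = patients_per_level)
  rows <- list()
  for (i in seq_along(radii)) {
    est <- run_patient(radii[i], fixed_density, derive_seed(seed, 100L + i))
    rows[[length(rows) + 1L]] <- data.frame(
      arm = "radius", radius = radii[i], density = fixed_density,
      median_ASD = est[1], median_AAC = est[2])
  }
  for (i in seq_along(dens)) {
    est <- run_patient(fixed_radius, dens[i], derive_seed(seed, 500L + i))
    rows[[length(rows) + 1L]] <- data.frame(
      arm = "density", radius = fixed_radius, density = dens[i],
      median_ASD = est[1], median_AAC = est[2])
  }
  tab <- do.call(rbind, rows)
  ra <- tab[tab$arm == "radius", ]
  da <- tab[tab$arm == "density", ]
  list(table = tab,
       rho_asd_radius = stats::cor(ra$median_ASD, ra$radius,
                                   method = "spearman"),
       rho_aac_density = stats::cor(da$median_AAC, da$density,
                                    method = "spearman"))
}
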