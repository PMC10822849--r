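test_that("window plans follow the overlap/step arithmetic", {
  plan <- plan_windows(small_roi(), std_pulse(), overlap = 0.94,
                       block_side = 2.2)
  expect_equal(plan$step, 0.132, tolerance = 1e-12)
  expect_equal(plan$block_side, 2.2)
  # ten-wavelength rule at 6 MHz / 1540 m/s
  plan10 <- plan_windows(small_roi(), std_pulse(), overlap = 0.5,
                         block_side = NULL)
  expect_equal(plan10$block_side, 10 * 1540 / 6e6 * 1e3, tolerance = 1e-9)
  expect_error(plan_windows(small_roi(), std_pulse(), overlap = 1),
               class = "qus_validation_error")
})

test_that("a zero-overlap plan tiles a rectangular ROI exactly", {
  g <- scan_geometry(n_lines = 50, lateral_spacing = 0.2,
                     depth_offset = 4, depth_max = 15)
  p <- std_pulse()
  depths <- qusresponse:::geometry_sample_depths(g, p)
  core <- matrix(FALSE, g$n_lines, length(depths))
  core[, depths >= 4.5 & depths <= 14.5] <- TRUE  # 10 mm x 10 mm
  roi <- roi_mask(core, core & FALSE, g, p)
  plan <- plan_windows(roi, p, overlap = 0, block_side = 2)
  expect_equal(sum(plan$in_roi), 25)
  expect_error(plan_windows(roi, p, overlap = 0, block_side = 12),
               class = "qus_insufficient_roi_error")
})

test_that("every planned block footprint intersects the combined ROI", {
  roi <- small_roi()
  plan <- plan_windows(roi, std_pulse(), overlap = 0.5)
  centers <- window_centers(plan)
  lat_pos <- qusresponse:::geometry_lateral_positions(roi$geometry)
  depths <- qusresponse:::geometry_sample_depths(roi$geometry, roi$pulse)
  half <- plan$block_side / 2
  for (b in seq_len(nrow(centers))) {
    lines <- which(abs(lat_pos - centers$lateral[b]) <= half)
    samp <- which(abs(depths - centers$axial[b]) <= half)
    expect_true(any(roi$combined[lines, samp]))  # brute-force geometry check
  }
})

test_that("ellipse ROI margin ring is 5 mm wide and disjoint from the core", {
  roi <- small_roi()
  expect_false(any(roi$core & roi$margin))
  lat_pos <- qusresponse:::geometry_lateral_positions(roi$geometry)
  depths <- qusresponse:::geometry_sample_depths(roi$geometry, roi$pulse)
  # along the two principal axes the ring must end 5 mm beyond the core
  mid_line <- which.min(abs(lat_pos - 9.5))
  ax_extent <- range(depths[roi$combined[mid_line, ]])
  expect_equal(ax_extent[1], 14 - 4 - 5, tolerance = 0.25)
  expect_equal(ax_extent[2], 14 + 4 + 5, tolerance = 0.25)
  mid_samp <- which.min(abs(depths - 14))
  lat_extent <- range(lat_pos[roi$combined[, mid_samp]])
  expect_equal(lat_extent[1], 9.5 - 3 - 5, tolerance = 0.25)
  expect_equal(lat_extent[2], 9.5 + 3 + 5, tolerance = 0.25)
})

test_that("the five maps are co-registered and mostly valid", {
  maps <- small_maps()
  expect_named(maps$maps, c("ASD", "AAC", "MBF", "SS", "SI"))
  for (p in names(maps$maps)) {
    expect_identical(maps$maps[[p]]$ax_centers, maps$maps$ASD$ax_centers)
    expect_identical(maps$maps[[p]]$lat_centers, maps$maps$ASD$lat_centers)
    expect_identical(dim(maps$maps[[p]]$values), dim(maps$maps$ASD$values))
  }
  expect_lt(maps$n_failed / maps$n_blocks, 0.5)
  # invalid blocks are NA-flagged, never silently zero
  asd <- maps$maps$ASD
  expect_true(all(is.na(asd$values[!asd$valid])))
  # homogeneous tumor: in-ROI parameter spread is modest
  ss <- maps$maps$SS$values[maps$maps$SS$valid]
  expect_lt(stats::sd(ss), 1)        # dB/MHz; SS is near zero-mean
  asd <- maps$maps$ASD$values[maps$maps$ASD$valid]
  expect_lt(stats::sd(asd) / mean(asd), 0.45)
})

test_that("self-normalization propagates to an exactly-zero SS map", {
  roi <- small_roi()
  plan <- plan_windows(roi, std_pulse(), overlap = 0.5)
  reffr <- small_reference()
  self <- build_maps(reffr, reffr, roi, plan,
                     qus_config(alpha_sample = std_phantom()$attenuation_coefficient,
                                phantom = std_phantom()))
  ss <- self$maps$SS$values[self$maps$SS$valid]
  expect_lt(max(abs(ss)), 0.2)
  mbf <- self$maps$MBF$values[self$maps$MBF$valid]
  expect_lt(max(abs(mbf)), 1e-9)
  # the BSC reduces to the analytic phantom curve: ASD is the bead diameter
  asd <- self$maps$ASD$values[self$maps$ASD$valid]
  expect_equal(max(abs(asd - 2 * std_phantom()$bead_radius)), 0,
               tolerance = 1e-6)
})

test_that("a two-region tumor orders core and margin ASD correctly", {
  g <- small_geometry()
  roi <- small_roi()
  # core scatterers 32 um, margin/background 20 um
  lat_pos <- qusresponse:::geometry_lateral_positions(g)
  n_scat <- round(50 * 19.2 * 20)
  field <- withr::with_seed(31, {
    ax <- runif(n_scat, 4, 24); lat <- runif(n_scat, 0, max(lat_pos))
    inside <- ((lat - 9.5) / 3)^2 + ((ax - 14) / 4)^2 <= 1
    scatterer_field(ax, lat, effective_radius = ifelse(inside, 32, 20),
                    number_density = 50)
  })
  frame <- simulate_rf_frame(field, std_pulse(), g, attenuation = 0.75,
                             seed = 31)
  plan <- plan_windows(roi, std_pulse(), overlap = 0.5)
  maps <- build_maps(frame, small_reference(), roi, plan,
                     qus_config(alpha_sample = 0.75, phantom = std_phantom()))
  asd <- maps$maps$ASD
  centers <- expand.grid(ax = asd$ax_centers, lat = asd$lat_centers)
  ell <- matrix(((centers$lat - 9.5) / 3)^2 + ((centers$ax - 14) / 4)^2,
                nrow = length(asd$ax_centers))
  core_vals <- asd$values[asd$valid & ell <= 0.55]    # well inside the core
  margin_vals <- asd$values[asd$valid & ell >= 1.8]   # well outside it
  expect_gt(median(core_vals), median(margin_vals))
})

test_that("rendered map images are 224 x 224, in [0,1], zero outside the ROI", {
  maps <- small_maps()
  img <- render_map_image(maps$maps$SS)
  expect_identical(dim(img$pixels), c(224L, 224L))
  expect_true(all(is.finite(img$pixels)))
  expect_gte(min(img$pixels), 0)
  expect_lte(max(img$pixels), 1)
  # corners of the bounding box lie outside the elliptical ROI: must be 0
  expect_equal(img$pixels[1, 1], 0)
  expect_equal(img$pixels[1, 224], 0)
  expect_equal(img$pixels[224, 1], 0)
  expect_equal(img$pixels[224, 224], 0)
})

test_that("rendering a constant map yields a constant image", {
  vals <- matrix(7.3, 12, 10)
  m <- parametric_map(vals, matrix(TRUE, 12, 10), seq_len(12), seq_len(10),
                      roi = NULL, parameter = "MBF")
  img <- render_map_image(m, roi = NULL)
  expect_true(all(img$pixels == img$pixels[1, 1]))
  bad <- parametric_map(vals, matrix(FALSE, 12, 10), seq_len(12), seq_len(10),
                        roi = NULL)
  expect_error(render_map_image(bad, roi = NULL), class = "qus_render_error")
})

test_that("rendering is stable under 2x nearest-neighbour upsampling", {
  # a smooth map; the upsampled copy covers the same physical cell span
  # (each original cell splits into two half-width cells)
  vals <- outer(sin(seq(0, 14) / 4), cos(seq(0, 11) / 3)) / 2 + 0.5
  m1 <- parametric_map(vals, matrix(TRUE, 15, 12),
                       seq(0, 14), seq(0, 11), roi = NULL)
  up <- vals[rep(seq_len(15), each = 2), rep(seq_len(12), each = 2)]
  m2 <- parametric_map(up, matrix(TRUE, 30, 24),
                       seq(-0.25, 14.25, by = 0.5), seq(-0.25, 11.25, by = 0.5),
                       roi = NULL)
  i1 <- render_map_image(m1, roi = NULL)
  i2 <- render_map_image(m2, roi = NULL)
  expect_lt(max(abs(i1$pixels - i2$pixels)), 0.05)
})

test_that("block estimates export to a tidy CSV", {
  maps <- small_maps()
  csv <- withr::local_tempfile(fileext = ".csv")
  df <- export_block_estimates(maps, csv)
  back <- read.csv(csv)
  expect_equal(nrow(back), maps$n_blocks)
  expect_true(all(c("ASD", "AAC", "MBF", "SS", "SI", "valid") %in% names(back)))
})
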