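# Shared fixtures, memoized so expensive simulations are built once per run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

std_pulse <- function() pulse_spec()
std_phantom <- function() phantom_spec()

# Small but estimator-friendly geometry for map-level tests.
small_geometry <- function() {
  scan_geometry(n_lines = 96, lateral_spacing = 0.2,
                depth_offset = 4, depth_max = 24)
}

# Very small geometry for counting / determinism tests.
tiny_geometry <- function() {
  scan_geometry(n_lines = 24, lateral_spacing = 0.2,
                depth_offset = 4, depth_max = 12)
}

small_roi <- function() {
  fixture("small_roi", {
    ellipse_roi_mask(small_geometry(), std_pulse(), c(9.5, 14), c(3, 4))
  })
}

small_reference <- function() {
  fixture("small_reference", {
    make_reference_frame(std_phantom(), std_pulse(), small_geometry(),
                         seed = 404L)
  })
}

# One tissue frame: homogeneous 27 um / 50 mm^-2 field, alpha 0.75.
small_sample_frame <- function() {
  fixture("small_sample_frame", {
    field <- withr::with_seed(2024L, {
      random_field(small_geometry(), 50, 27)
    })
    simulate_rf_frame(field, std_pulse(), small_geometry(),
                      attenuation = 0.75, seed = 77L)
  })
}

small_maps <- function() {
  fixture("small_maps", {
    plan <- plan_windows(small_roi(), std_pulse(), overlap = 0.5)
    build_maps(small_sample_frame(), small_reference(), small_roi(), plan,
               qus_config(alpha_sample = 0.75, phantom = std_phantom()))
  })
}

# A flat-ish normalized spectrum fixture on an explicit grid.
line_spectrum <- function(slope, intercept, depth = 1,
                          freqs = seq(2, 10, by = 0.25)) {
  power_spectrum(freqs, slope * freqs + intercept, block_depth = depth,
                 kind = "normalized")
}
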