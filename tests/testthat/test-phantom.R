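test_that("simulation is deterministic given the seed", {
  ph <- make_preset_phantom("flow_bar")
  a <- simulate_volume(ph$spec, ph$source, ph$protocol, seed = 3)
  b <- simulate_volume(ph$spec, ph$source, ph$protocol, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$bulk_dz_um, b$truth$bulk_dz_um)
  c_ <- simulate_volume(ph$spec, ph$source, ph$protocol, seed = 4)
  expect_false(identical(a$samples, c_$samples))
})

test_that("a static noiseless phantom produces bit-identical repeats", {
  layers <- data.frame(center_um = c(80, 140), thickness_um = c(30, 30),
                       reflectivity = c(1e-3, 2e-3), density = c(6, 6))
  spec <- phantom_spec(layers, noise_sigma = 0)
  src <- source_model(n_samples = 256)
  proto <- scan_protocol(0.08, 0.02, 5, 5, repeats = 3, sweep_rate_hz = 1.7e6,
                         samples_per_ascan = 256, a_scans = 16, n_positions = 4)
  raw <- simulate_volume(spec, src, proto, seed = 1)
  expect_identical(raw$samples[, , 1, ], raw$samples[, , 2, ])
  expect_identical(raw$samples[, , 2, ], raw$samples[, , 3, ])
})

test_that("a single mirror reconstructs to one dominant peak at its depth", {
  r <- mirror_run()
  cv <- r$full
  z_true <- 150
  # brute-force DFT oracle on the analytic fringe at the uniform grid
  src <- r$ph$source
  g <- k_grid(src)
  n <- 1.33
  fr <- source_envelope(src, g$k_uniform) *
    exp(1i * 2 * n * g$k_uniform * z_true)
  z_eval <- seq(100, 200, by = 0.05)
  dft <- vapply(z_eval, function(z)
    Mod(sum(fr * exp(-1i * 2 * n * g$k_uniform * z))), numeric(1))
  z_oracle <- z_eval[which.max(dft)]
  mag <- Mod(cv$data[, 1, 1, 1])
  mag[1:60] <- 0   # DC/envelope line of the un-subtracted mirror fringe
  pk <- which.max(mag)
  expect_lte(abs((pk - 1) - round(z_oracle / cv$axial_pitch_um)), 1)
  # dominance: peak well above everything outside the PSF neighborhood
  side <- mag[-(pk + (-40:40))]
  expect_gt(mag[pk], 10 * max(side))
})

test_that("mean fringe power scales linearly with total reflectivity", {
  src <- source_model(n_samples = 512)
  proto <- scan_protocol(0.01, 0.01, 5, 5, repeats = 1, sweep_rate_hz = 1.7e6,
                         samples_per_ascan = 512, a_scans = 2, n_positions = 1)
  ac_power <- function(refl) {
    layers <- data.frame(center_um = c(150, 220, 300)[seq_along(refl)],
                         thickness_um = 0, reflectivity = refl, density = 1)
    spec <- phantom_spec(layers, noise_sigma = 0, dc_level = 0)
    raw <- simulate_volume(spec, src, proto, seed = 2, quantize = FALSE)
    mean(raw$samples^2)
  }
  # closed-form: E[power] = mean(env^2) * sum(4 r / 2) for separated reflectors
  env2 <- mean(source_envelope(src)^2)
  for (refl in list(1e-3, c(1e-3, 2e-3), c(1e-3, 2e-3, 4e-3))) {
    expect_equal(ac_power(refl), env2 * sum(2 * refl), tolerance = 0.05)
  }
  # doubling all reflectivities doubles the power
  expect_equal(ac_power(c(2e-3, 4e-3)) / ac_power(c(1e-3, 2e-3)), 2,
               tolerance = 0.02)
})

test_that("vessel flow gives per-repeat circular phase steps of sd ~ 2 n k0 sigma", {
  # Monte-Carlo at the vessel-center pixels of the flow-bar stacks
  r <- flowbar_run()
  src <- r$ph$source
  sigma_flow <- r$ph$spec$vessels$sigma_flow_um[1]
  expected_sd <- 2 * 1.33 * src$k0 * sigma_flow   # = pi/2 for lambda0/(8n)
  x <- r$cv$data
  vm <- r$vm
  steps <- c()
  for (p in seq_len(dim(x)[4])) for (i in seq_len(dim(x)[3] - 1)) {
    dp <- wrap_phase(Arg(x[, , i + 1, p]) - Arg(x[, , i, p]))
    steps <- c(steps, dp[vm[, , p] & r$an$mask[, , p]])
  }
  expect_gt(length(steps), 1e4)
  # circular standard deviation
  Rbar <- sqrt(mean(cos(steps))^2 + mean(sin(steps))^2)
  circ_sd <- sqrt(-2 * log(Rbar))
  # oracle: 1e4 draws of wrapped N(0, expected_sd), same estimator
  set.seed(123)
  d0 <- wrap_phase(stats::rnorm(1e4, 0, expected_sd))
  R0 <- sqrt(mean(cos(d0))^2 + mean(sin(d0))^2)
  expect_equal(circ_sd, sqrt(-2 * log(R0)), tolerance = 0.15)
})

test_that("calibration fringe spacing follows the wavenumber mapping", {
  src_lin <- source_model(n_samples = 512, chirp = 0)
  cal <- simulate_calibration_fringe(src_lin)
  # linear mapping: zero crossings equally spaced
  zc <- which(diff(sign(cal$fringe)) != 0)
  sp <- diff(zc)
  expect_lt(stats::sd(sp) / mean(sp), 0.08)

  src_q <- source_model(n_samples = 512, chirp = 0.4)
  calq <- simulate_calibration_fringe(src_q)
  # chirped mapping: instantaneous frequency (phase derivative) monotone
  dph <- diff(calq$phase)
  expect_true(all(diff(dph) < 0) || all(diff(dph) > 0))

  # recovered instantaneous phase matches the generating phase
  a <- analytic_signal(calq$fringe - mean(calq$fringe))
  psi <- unwrap_phase(Arg(a))
  interior <- 30:(512 - 30)
  gen <- calq$phase - calq$phase[interior[1]] + psi[interior[1]]
  expect_lt(max(abs(psi[interior] - gen[interior])), 1e-2)
})

test_that("phantom presets honour their construction contracts", {
  m <- make_preset_phantom("mirror")
  expect_identical(nrow(m$spec$vessels), 0L)
  expect_identical(nrow(m$spec$layers), 1L)

  f <- make_preset_phantom("flow_bar")
  expect_identical(nrow(f$spec$vessels), 1L)
  expect_gt(f$spec$vessels$sigma_flow_um, 0)

  r <- retina_run()
  # truth mask contains both vessel tubes as separate footprints
  fp <- r$raw$truth$vessel_footprint
  cols <- which(apply(fp, 1, any))
  expect_gt(max(diff(cols)), 5)   # two separated lateral bands
  expect_identical(nrow(r$ph$spec$vessels), 2L)

  expect_error(make_preset_phantom("nope"), "unknown")
})

test_that("a phantom deeper than the axial range is rejected", {
  src <- source_model(n_samples = 256)
  zmax <- axial_range_um(k_grid(src)$dk)
  layers <- data.frame(center_um = zmax + 50, thickness_um = 10,
                       reflectivity = 1e-3, density = 4)
  proto <- scan_protocol(0.02, 0.01, 5, 5, repeats = 1, sweep_rate_hz = 1.7e6,
                         samples_per_ascan = 256, a_scans = 4, n_positions = 2)
  expect_error(simulate_volume(phantom_spec(layers), src, proto, seed = 1),
               "axial range")
})
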