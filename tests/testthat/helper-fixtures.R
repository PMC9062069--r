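# Shared fixtures, memoized so expensive simulations run once per session.

.fix <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fix)) assign(key, force(expr), envir = .fix)
  get(key, envir = .fix)
}

# mirror preset simulated + reconstructed in several correction modes
mirror_run <- function() cached("mirror", {
  ph <- make_preset_phantom("mirror")
  raw <- simulate_volume(ph$spec, ph$source, ph$protocol, seed = 42)
  list(ph = ph, raw = raw,
       full = reconstruct_volume(raw, dispersion = "given", window = "rect",
                                 fixed_pattern = FALSE),
       no_disp = reconstruct_volume(raw, dispersion = "none", window = "rect",
                                    fixed_pattern = FALSE),
       no_resample = reconstruct_volume(raw, dispersion = "given",
                                        window = "rect", resample = FALSE,
                                        fixed_pattern = FALSE))
})

# flow-bar phantom through angiography
flowbar_run <- function() cached("flowbar", {
  ph <- make_preset_phantom("flow_bar", noise_sigma = 0.01)
  raw <- simulate_volume(ph$spec, ph$source, ph$protocol, seed = 7)
  cv <- reconstruct_volume(raw)
  an <- compute_angio(cv)
  list(ph = ph, raw = raw, cv = cv, an = an,
       vm = truth_vessel_mask(raw$truth, cv$axial_pitch_um, dim(cv$data)[1]))
})

# full-size retina_small preset through angiography (the end-to-end fixture)
retina_run <- function() cached("retina", {
  ph <- make_preset_phantom("retina_small")
  raw <- simulate_volume(ph$spec, ph$source, ph$protocol, seed = 5)
  cv <- reconstruct_volume(raw)
  an <- compute_angio(cv)
  an_uncorr <- compute_angio(cv, correct_bulk = FALSE)
  list(ph = ph, raw = raw, cv = cv, an = an, an_uncorr = an_uncorr,
       vm = truth_vessel_mask(raw$truth, cv$axial_pitch_um, dim(cv$data)[1]))
})

# narrow retina variant with injected saccades (32 x 64 positions)
saccade_run <- function() cached("saccade", {
  ph <- make_preset_phantom("retina_small", saccade_positions = c(12, 30, 47),
                            saccade_shift_steps = 2)
  ph$protocol <- scan_protocol(0.16, 0.32, 5, 5, repeats = 5,
                               sweep_rate_hz = 1.7e6, samples_per_ascan = 512,
                               a_scans = 32, n_positions = 64)
  raw <- simulate_volume(ph$spec, ph$source, ph$protocol, seed = 9)
  cv <- reconstruct_volume(raw)
  an <- compute_angio(cv)
  list(ph = ph, raw = raw, cv = cv, an = an)
})

# static two-layer phantom with an explicit per-B-scan bulk offset sequence
bulk_run <- function(beta_star, seed = 11, noise_sigma = 0.01) {
  key <- sprintf("bulk_%.4f_%g", beta_star, noise_sigma)
  cached(key, {
    n <- 1.33
    k0 <- source_model()$k0
    dz <- beta_star / (2 * n * k0)
    layers <- data.frame(center_um = c(150, 250), thickness_um = c(40, 40),
                         reflectivity = c(2e-3, 2e-3), density = c(10, 10))
    spec <- phantom_spec(layers, bulk_dz_um = rep(c(0, dz), 8),
                         noise_sigma = noise_sigma)
    src <- source_model(n_samples = 512, chirp = 0.1)
    proto <- scan_protocol(0.16, 0.04, 5, 5, repeats = 2,
                           sweep_rate_hz = 1.7e6, samples_per_ascan = 512,
                           a_scans = 32, n_positions = 8)
    raw <- simulate_volume(spec, src, proto, seed = seed)
    cv <- reconstruct_volume(raw)
    list(raw = raw, cv = cv,
         an = compute_angio(cv),
         an_uncorr = compute_angio(cv, correct_bulk = FALSE))
  })
}

# logical depth-band mask [depth, a_scan, position] for given um intervals
depth_band_mask <- function(dims, pitch, intervals) {
  z <- (seq_len(dims[1]) - 1) * pitch
  inb <- rep(FALSE, dims[1])
  for (iv in intervals) inb <- inb | (z > iv[1] & z < iv[2])
  array(inb, dims)
}

# curved, delta-thin RPE phantom: one deterministic reflector per column
curved_rpe_run <- function() cached("curved_rpe", {
  layers <- data.frame(center_um = 300, thickness_um = 0,
                       reflectivity = 5e-3, density = 1)
  spec <- phantom_spec(layers, curv_um = 30, noise_sigma = 0)
  src <- source_model(n_samples = 512)
  proto <- scan_protocol(0.16, 0.16, 5, 5, repeats = 1, sweep_rate_hz = 1.7e6,
                         samples_per_ascan = 512, a_scans = 32, n_positions = 32)
  raw <- simulate_volume(spec, src, proto, seed = 21)
  # columns differ through the curvature, so mean-spectrum subtraction only
  # removes the DC line, not the structure
  cv <- reconstruct_volume(raw, fixed_pattern = TRUE)
  d <- dim(cv$data)
  intensity <- array(Mod(cv$data)^2, dim = d[c(1, 2, 4)])
  list(raw = raw, cv = cv, intensity = intensity)
})
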