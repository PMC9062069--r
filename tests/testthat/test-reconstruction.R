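test_that("k-calibration recovers the sampling map", {
  # linear sweep: identity map
  src <- source_model(n_samples = 512, chirp = 0)
  cal <- simulate_calibration_fringe(src)
  cur <- calibrate_k(cal$fringe)
  expect_lt(max(abs(cur$map - (0:511))), 1e-3)

  # quadratic chirp: map inverts the generating polynomial
  srcq <- source_model(n_samples = 512, chirp = 0.25)
  calq <- simulate_calibration_fringe(srcq)
  curq <- calibrate_k(calq$fringe)
  g <- k_grid(srcq)
  k_targets <- seq(g$k[1], g$k[512], length.out = 512)
  map_true <- stats::approx(g$k, 0:511, xout = k_targets)$y
  expect_lt(max(abs(curq$map - map_true)), 0.05)

  # a sweep that folds back (non-monotone wavenumber) is rejected
  u <- seq(0, 1, length.out = 512)
  k_fold <- 5.9 + 1.33 * (u - 1.2 * u^2)   # rises then falls
  expect_error(calibrate_k(cos(2 * k_fold * 150)), "monotone")
  # too few cycles rejected
  expect_error(calibrate_k(cos(2 * pi * 2 * seq(0, 1, length.out = 512))),
               "cycles")
})

test_that("wavenumber resampling preserves signals and energy", {
  # exact identity map: output equals input at the sample nodes
  ident <- structure(list(psi = seq(0, 100, length.out = 512), map = 0:511,
                          n_samples = 512L), class = "calibration_curve")
  x <- sin(2 * pi * 17 * seq(0, 1, length.out = 512))
  expect_equal(resample_to_k(x, ident), x, tolerance = 1e-12)
  # calibrated linear sweep: near-identity within the map accuracy
  src <- source_model(n_samples = 512, chirp = 0)
  cur <- calibrate_k(simulate_calibration_fringe(src)$fringe)
  expect_equal(resample_to_k(x, cur), x, tolerance = 1e-3)

  # white noise: output variance within 20% of input variance
  set.seed(4)
  srcq <- source_model(n_samples = 512, chirp = 0.25)
  curq <- calibrate_k(simulate_calibration_fringe(srcq)$fringe)
  noise <- matrix(stats::rnorm(512 * 32), 512, 32)
  out <- resample_to_k(noise, curq)
  expect_lt(abs(stats::var(as.vector(out)) / stats::var(as.vector(noise)) - 1), 0.2)
})

test_that("resampling restores the transform-limited PSF of a chirped fringe", {
  r <- mirror_run()
  lim <- transform_limit_fwhm_um(r$ph$source)
  fw <- function(cv) {
    m <- Mod(cv$data[, 1, 1, 1]); m[1:20] <- 0
    pvocta:::fwhm_of_peak(m) * cv$axial_pitch_um
  }
  expect_lt(abs(fw(r$full) / lim - 1), 0.15)
  expect_gt(fw(r$no_resample) / lim, 2)
})

test_that("fixed-pattern removal cancels the pattern without biasing structure", {
  # constant pattern only -> all zero
  M <- 256
  pat <- pvocta:::fixed_pattern_spectrum(M, 1)
  vol <- matrix(rep(pat, 8), M, 8)
  expect_true(all(remove_fixed_pattern(vol) == 0))

  # pattern + per-column speckle: pattern suppressed >= 20 dB in depth space
  src <- source_model(n_samples = M)
  g <- k_grid(src)
  set.seed(9)
  A <- 256
  spec <- matrix(0, M, A)
  for (a in seq_len(A)) {
    z <- stats::runif(12, 140, 180)
    amp <- rep(2 * sqrt(1e-3 / 12), 12)
    spec[, a] <- source_envelope(src) *
      (cos(outer(2 * 1.33 * g$k_uniform, z)) %*% amp)
  }
  with_pat <- spec + pat
  cleaned <- remove_fixed_pattern(with_pat)
  rec_dirty <- Mod(fft_reconstruct(with_pat)$data)
  rec_clean <- Mod(fft_reconstruct(cleaned)$data)
  # pattern energy lives at low depth pixels (slow spectral structure)
  dc_band <- 1:30
  drop_db <- 20 * log10(mean(rec_dirty[dc_band, ]) / mean(rec_clean[dc_band, ]))
  expect_gt(drop_db, 20)
  # reflector band barely changed (mean over uncorrelated columns ~ 0)
  rec_ref <- Mod(fft_reconstruct(spec)$data)
  band <- 320:400   # the 140-180 um reflector band at ~0.44 um pitch
  expect_lt(abs(mean(rec_clean[band, ]) / mean(rec_ref[band, ]) - 1), 0.01)

  expect_error(remove_fixed_pattern(matrix(1, 4, 1)), ">= 2")
})

test_that("dispersion compensation is exact inverse of the injected phase", {
  src <- source_model(n_samples = 512)
  g <- k_grid(src)
  x <- source_envelope(src, g$k_uniform) *
    exp(1i * 2 * 1.33 * g$k_uniform * 150)
  # zero model: identity on complex input
  m0 <- dispersion_model(0, 0, src$k0)
  expect_equal(compensate_dispersion(x, m0, g$k_uniform), x)
  # exact cancellation of injected quadratic+cubic phase
  m1 <- dispersion_model(40, 15, src$k0)
  xd <- x * complex(modulus = 1,
                    argument = dispersion_phase(m1, g$k_uniform, src$k0))
  expect_equal(compensate_dispersion(xd, m1, g$k_uniform), x, tolerance = 1e-12)

  # mirror preset: compensation restores the PSF; wrong sign doubles the blur
  r <- mirror_run()
  lim <- transform_limit_fwhm_um(r$ph$source)
  fw <- function(cv) {
    m <- Mod(cv$data[, 1, 1, 1]); m[1:120] <- 0   # clear of DC line and tails
    pvocta:::fwhm_of_peak(m) * cv$axial_pitch_um
  }
  expect_lt(abs(fw(r$full) / lim - 1), 0.15)
  expect_gt(fw(r$no_disp) / lim, 2)
  wrong <- reconstruct_volume(r$raw, window = "rect", fixed_pattern = FALSE,
                              dispersion = dispersion_model(-r$ph$source$a2, 0,
                                                            r$ph$source$k0))
  expect_gt(fw(wrong), 1.8 * fw(r$no_disp))
})

test_that("entropy optimization recovers injected dispersion coefficients", {
  r <- mirror_run()
  src <- r$ph$source
  g <- k_grid(src)
  b <- resample_to_k(r$raw$samples[, , 1, 1],
                     calibrate_k(r$raw$calibration$fringe))
  mdl <- optimize_dispersion(b, g$k_uniform, src$k0)
  expect_lt(abs(mdl$a2 / src$a2 - 1), 0.1)
  ent <- attr(mdl, "entropy")
  expect_lte(ent[["optimum"]], ent[["at_zero"]])

  # zero-dispersion input: recovered |a2| below the coarse grid resolution
  src0 <- source_model(n_samples = 512, chirp = 0, a2 = 0)
  g0 <- k_grid(src0)
  x0 <- Re(source_envelope(src0) * exp(1i * 2 * 1.33 * g0$k_uniform * 150))
  mdl0 <- optimize_dispersion(x0, g0$k_uniform, src0$k0)
  expect_lt(abs(mdl0$a2), 10)

  expect_warning(mz <- optimize_dispersion(matrix(0, 512, 4), g0$k_uniform,
                                           src0$k0), "empty")
  expect_identical(mz$a2, 0)
})

test_that("spectral shaping controls sidelobes at a bounded resolution cost", {
  M <- 512
  src <- source_model(n_samples = M, envelope = "flat")
  g <- k_grid(src)
  pitch <- axial_pitch_um(g$dk, 4 * M)
  z0 <- 200 * pitch   # land exactly on a depth pixel
  fr <- exp(1i * 2 * 1.33 * g$k_uniform * z0)
  expect_equal(shape_spectrum(fr, "rect"), fr)

  rec_r <- Mod(fft_reconstruct(fr)$data)
  rec_h <- Mod(fft_reconstruct(shape_spectrum(fr, "hann"))$data)
  pk <- which.max(rec_h)
  main <- pk + (-16:16)   # hann main lobe: +/- 2 unpadded bins = 8 padded
  sidelobe_db <- 20 * log10(max(rec_h[-main]) / rec_h[pk])
  expect_lte(sidelobe_db, -31)

  # main-lobe broadening vs rectangular matches the windowed-DFT oracle
  fwhm_ratio <- pvocta:::fwhm_of_peak(rec_h) / pvocta:::fwhm_of_peak(rec_r)
  # oracle: fine DFT of the two windows
  zf <- seq(-6, 6, by = 0.001)   # in unpadded-bin units
  m <- 0:(M - 1)
  dft_mag <- function(w) vapply(zf, function(f)
    Mod(sum(w * exp(-2i * pi * f * m / M))), numeric(1))
  oracle <- pvocta:::fwhm_of_peak(dft_mag(pvocta:::spectral_window("hann", M)), zf) /
    pvocta:::fwhm_of_peak(dft_mag(pvocta:::spectral_window("rect", M)), zf)
  expect_equal(fwhm_ratio, oracle, tolerance = 0.02)

  expect_error(shape_spectrum(fr, rep(1, 10)), "length")
})

test_that("Fourier reconstruction keeps the one-sided transform exactly", {
  M <- 256
  expect_true(all(fft_reconstruct(numeric(M))$data == 0))
  set.seed(5)
  x <- stats::rnorm(M)
  out <- fft_reconstruct(x)$data
  full <- stats::fft(c(x, numeric(3 * M)))
  expect_equal(out, full[seq_len(2 * M)])
  # Parseval on the full padded transform
  expect_equal(sum(Mod(full)^2), 4 * M * sum(x^2), tolerance = 1e-9)

  # mirror peak lands at round(z / pitch) +/- 1
  src <- source_model(n_samples = M)
  g <- k_grid(src)
  z0 <- 123.4
  fr <- Re(source_envelope(src, g$k_uniform) *
             exp(1i * 2 * 1.33 * g$k_uniform * z0))
  rec <- fft_reconstruct(fr, dk = g$dk)
  mag <- Mod(rec$data); mag[1:10] <- 0
  expect_lte(abs(which.max(mag) - 1 - round(z0 / rec$axial_pitch_um)), 1)
})

test_that("the reconstruction chain is linear before quantization", {
  src <- source_model(n_samples = 256, chirp = 0.2)
  cur <- calibrate_k(simulate_calibration_fringe(src)$fringe)
  g <- k_grid(src)
  mdl <- dispersion_model(25, 5, src$k0)
  chain <- function(x) {
    y <- resample_to_k(x, cur)
    y <- compensate_dispersion(y, mdl, g$k_uniform)
    y <- shape_spectrum(y, "hann")
    fft_reconstruct(y)$data
  }
  set.seed(6)
  I <- matrix(stats::rnorm(256 * 4), 256, 4)
  J <- matrix(stats::rnorm(256 * 4), 256, 4)
  lhs <- chain(2.5 * I - 1.25 * J)
  rhs <- 2.5 * chain(I) - 1.25 * chain(J)
  expect_lt(max(Mod(lhs - rhs)) / max(Mod(rhs)), 1e-6)
})

test_that("static noiseless repeats reconstruct with exactly equal phase", {
  layers <- data.frame(center_um = c(80, 140), thickness_um = c(30, 30),
                       reflectivity = c(1e-3, 2e-3), density = c(6, 6))
  spec <- phantom_spec(layers, noise_sigma = 0)
  src <- source_model(n_samples = 256)
  proto <- scan_protocol(0.08, 0.02, 5, 5, repeats = 2, sweep_rate_hz = 1.7e6,
                         samples_per_ascan = 256, a_scans = 16, n_positions = 4)
  raw <- simulate_volume(spec, src, proto, seed = 1)
  cv <- reconstruct_volume(raw)
  expect_identical(Arg(cv$data[, , 1, ]), Arg(cv$data[, , 2, ]))
})
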