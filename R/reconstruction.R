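#' Calibrate the sample-index-to-wavenumber mapping from a k-clock fringe
#'
#' Extracts the instantaneous phase of a single-reflector calibration fringe
#' (analytic-signal method), unwraps it, and smooths it with an
#' envelope-weighted polynomial fit (the boundary samples of the analytic
#' signal carry leakage artifacts and are excluded). Since the calibration
#' phase is `2 k(m) z_cal`, inverting the fitted phase to a uniform grid gives
#' the fractional sample positions at which the spectrum is uniform in
#' wavenumber.
#'
#' @param fringe Numeric vector: the recorded calibration fringe.
#' @param poly_degree Degree of the smoothing polynomial (default 7; the fit
#'   must be able to represent the sweep nonlinearity).
#' @param edge_frac Fraction of samples dropped at each end for the fit
#'   (default 0.05).
#' @return Object of class `calibration_curve`: `psi` (fitted unwrapped phase
#'   per sample), `map` (fractional sample index for each uniform-wavenumber
#'   target), `n_samples`.
#' @export
calibrate_k <- function(fringe, poly_degree = 7, edge_frac = 0.05) {
  M <- length(fringe)
  if (M < 64) stopf("calibrate_k: fringe too short")
  a <- analytic_signal(fringe - mean(fringe))
  psi_raw <- unwrap_phase(Arg(a))
  cycles <- abs(psi_raw[M] - psi_raw[1]) / (2 * pi)
  if (cycles < 10)
    stopf("calibrate_k: only %.1f fringe cycles; need >= 10", cycles)
  m <- seq_len(M) - 1
  edge <- max(2L, ceiling(edge_frac * M))
  keep <- seq(edge + 1L, M - edge)
  # a sweep that folds back shows up as a collapse of the instantaneous
  # frequency (the phase direction itself is unobservable in a real fringe)
  freq <- stats::runmed(diff(psi_raw[keep]), 9)
  if (min(freq) < 0.2 * stats::median(freq))
    stopf("calibrate_k: instantaneous frequency collapses; sweep is not strictly monotone in wavenumber")
  w <- abs(a)[keep]
  fit <- stats::lm(psi_raw[keep] ~ stats::poly(m[keep], poly_degree, raw = TRUE),
                   weights = w)
  cf <- stats::coef(fit)
  cf[is.na(cf)] <- 0
  psi <- drop(cbind(1, stats::poly(m, poly_degree, raw = TRUE)) %*% cf)
  dpsi <- diff(psi)
  if (any(dpsi <= 0)) {
    if (all(dpsi < 0))
      stopf("calibrate_k: calibration phase decreases with sample index; fringe has reversed monotonicity")
    stopf("calibrate_k: calibration phase is not strictly monotone")
  }
  targets <- seq(psi[1], psi[M], length.out = M)
  map <- stats::approx(psi, m, xout = targets, rule = 2)$y
  structure(list(psi = psi, map = map, n_samples = M), class = "calibration_curve")
}

#' Resample spectra to uniform wavenumber spacing
#'
#' Cubic-spline interpolation of each spectrum at the fractional sample
#' positions of a [calibrate_k()] map; edge positions are clamped to the
#' sampled range.
#'
#' @param spectra Numeric vector, matrix (samples x A-scans), or array with
#'   the spectral dimension first.
#' @param curve A `calibration_curve`.
#' @return Object of the same shape, uniform in wavenumber.
#' @export
resample_to_k <- function(spectra, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  map <- pmin(pmax(curve$map, 0), curve$n_samples - 1)
  m <- seq_len(curve$n_samples) - 1
  resample_one <- function(v) {
    stats::spline(m, v, xout = map, method = "fmm")$y
  }
  apply_spectral(spectra, curve$n_samples, resample_one)
}

# Apply fn over the first (spectral) dimension of vector/matrix/array input.
apply_spectral <- function(spectra, M, fn, out_len = M, complex_out = FALSE) {
  if (is.null(dim(spectra))) {
    if (length(spectra) != M) stopf("spectral length %d != expected %d", length(spectra), M)
    return(fn(spectra))
  }
  d <- dim(spectra)
  if (d[1] != M) stopf("spectral dimension %d != expected %d", d[1], M)
  mat <- matrix(spectra, nrow = M)
  out <- matrix(if (complex_out) 0i else 0, nrow = out_len, ncol = ncol(mat))
  for (j in seq_len(ncol(mat))) out[, j] <- fn(mat[, j])
  dim(out) <- c(out_len, d[-1])
  out
}

#' Remove fixed-pattern noise by mean-spectrum subtraction
#'
#' Estimates the fixed (A-scan-invariant) spectral pattern as the mean
#' interference spectrum within each B-scan and subtracts it from every
#' A-scan of that B-scan. Removes both the fixed-pattern artifact and the
#' non-interferometric DC line.
#'
#' @param spectra Matrix (samples x A-scans, one B-scan) or array
#'   `[sample, a_scan, ...]` where each trailing slice is a B-scan.
#' @return Same shape with the per-B-scan mean spectrum subtracted.
#' @export
remove_fixed_pattern <- function(spectra) {
  if (is.null(dim(spectra))) stopf("remove_fixed_pattern: need >= 2 spectra")
  d <- dim(spectra)
  if (length(d) == 2) {
    if (d[2] < 2) stopf("remove_fixed_pattern: need >= 2 spectra")
    return(spectra - rowMeans(spectra))
  }
  nb <- prod(d[-(1:2)])
  mat <- array(spectra, dim = c(d[1], d[2], nb))
  for (b in seq_len(nb)) mat[, , b] <- mat[, , b] - rowMeans(mat[, , b])
  array(mat, dim = d)
}

#' Residual dispersion model
#'
#' Quadratic/cubic spectral phase about the band center, cancelled by
#' multiplying the analytic spectrum with `exp(-i theta(k))`,
#' `theta(k) = a2 (k-k0)^2 + a3 (k-k0)^3`.
#'
#' @param a2,a3 Phase coefficients (rad per (rad/um)^2, ^3).
#' @param k0 Band center (rad/um).
#' @return Object of class `dispersion_model`.
#' @export
dispersion_model <- function(a2 = 0, a3 = 0, k0) {
  if (!all(is.finite(c(a2, a3, k0)))) stopf("dispersion_model: coefficients must be finite")
  structure(list(a2 = a2, a3 = a3, k0 = k0), class = "dispersion_model")
}

#' Compensate residual dispersion
#'
#' Multiplies each (analytic) spectrum by `exp(-i theta(k))`. Real input is
#' first converted to its analytic signal; complex input is used as is.
#'
#' @param spectra Real or complex spectra (spectral dimension first), already
#'   uniform in wavenumber.
#' @param model A [dispersion_model()].
#' @param k Uniform wavenumber grid (rad/um) of the spectral samples.
#' @return Complex spectra of the same shape.
#' @export
compensate_dispersion <- function(spectra, model, k) {
  stopifnot(inherits(model, "dispersion_model"))
  M <- if (is.null(dim(spectra))) length(spectra) else dim(spectra)[1]
  if (length(k) != M) stopf("compensate_dispersion: k grid length mismatch")
  corr <- complex(modulus = 1, argument = -dispersion_phase(model, k, model$k0))
  fn <- function(v) {
    if (!is.complex(v)) v <- analytic_signal(v)
    v * corr
  }
  apply_spectral(spectra, M, fn, complex_out = TRUE)
}

#' Spectral shaping (apodization)
#'
#' Multiplies each spectrum by a unit-peak apodization window to suppress
#' axial point-spread-function sidelobes. A Hann window takes the first
#' sidelobe of a flat-envelope reflector below -31 dB at the cost of ~1.44x
#' main-lobe broadening; `"rect"` is the identity.
#'
#' @param spectra Real or complex spectra, spectral dimension first.
#' @param window `"hann"`, `"hamming"`, `"rect"`, or a numeric vector of
#'   window values (length = spectral samples).
#' @return Shaped spectra, same shape and mode as the input.
#' @export
shape_spectrum <- function(spectra, window = "hann") {
  M <- if (is.null(dim(spectra))) length(spectra) else dim(spectra)[1]
  w <- spectral_window(window, M)
  if (is.null(dim(spectra))) return(spectra * w)
  spectra * array(w, dim = dim(spectra))
}

spectral_window <- function(window, M) {
  if (is.numeric(window)) {
    if (length(window) != M) stopf("window length %d != %d samples", length(window), M)
    return(window / max(window))
  }
  m <- seq_len(M) - 1
  switch(window,
    rect = rep(1, M),
    hann = 0.5 - 0.5 * cos(2 * pi * m / (M - 1)),
    hamming = 0.54 - 0.46 * cos(2 * pi * m / (M - 1)),
    stopf("unknown window '%s'", window))
}

#' Fourier reconstruction of complex A-scans
#'
#' Zero-pads each spectrum to `pad_factor` times its length (4x, matching the
#' 1024-sample / 4096-point full-scale configuration), Fourier transforms, and
#' keeps the one-sided positive-depth half. Depth pixel 0 is zero optical path
#' difference; the complex-conjugate ambiguity is unresolved.
#'
#' @param spectra Real or complex spectra, spectral dimension first.
#' @param dk Uniform wavenumber sample spacing (rad/um), used for the axial
#'   pitch; optional (pitch is `NA` when absent).
#' @param n Refractive index (default 1.33).
#' @param pad_factor Zero-padding factor (default 4).
#' @param n_pad Explicit padded length overriding `pad_factor`.
#' @return Object of class `complex_volume`: `data` (complex, depth first,
#'   `n_pad/2` depth pixels), `axial_pitch_um`, `n_pad`, `n`.
#' @export
fft_reconstruct <- function(spectra, dk = NULL, n = 1.33, pad_factor = 4,
                            n_pad = NULL) {
  M <- if (is.null(dim(spectra))) length(spectra) else dim(spectra)[1]
  n_pad <- n_pad %||% (pad_factor * M)
  if (n_pad < M) stopf("fft_reconstruct: padded length < spectrum length")
  n_depth <- n_pad %/% 2
  fn <- function(v) {
    vz <- c(v, rep(if (is.complex(v)) 0i else 0, n_pad - M))
    stats::fft(vz)[seq_len(n_depth)]
  }
  out <- apply_spectral(spectra, M, fn, out_len = n_depth, complex_out = TRUE)
  pitch <- if (is.null(dk)) NA_real_ else axial_pitch_um(dk, n_pad, n)
  structure(list(data = out, axial_pitch_um = pitch, n_pad = n_pad, n = n),
            class = "complex_volume")
}

#' Estimate dispersion coefficients by image-sharpness optimization
#'
#' Searches for `(a2, a3)` minimizing the Shannon entropy of the normalized
#' reconstructed B-scan magnitude (sharper images have lower entropy): a
#' coarse grid over `a2` followed by Nelder-Mead refinement over both
#' coefficients. Deterministic for a fixed grid.
#'
#' @param bscan Real or complex uniform-wavenumber spectra of one B-scan
#'   (samples x A-scans), fixed pattern already removed.
#' @param k Uniform wavenumber grid (rad/um).
#' @param k0 Band center (default mean of `k`).
#' @param a2_range Coarse search range for `a2` (default `c(-150, 150)`).
#' @param n_grid Coarse grid size (default 31).
#' @param window Apodization used during the metric evaluation.
#' @param dc_exclude_frac Fraction of the shallowest depth pixels excluded
#'   from the sharpness metric (default 0.04), so the non-interferometric
#'   DC/envelope line does not dominate the entropy.
#' @return A [dispersion_model()] with an `entropy` attribute
#'   (`c(optimum, at_zero)`).
#' @export
optimize_dispersion <- function(bscan, k, k0 = mean(range(k)),
                                a2_range = c(-150, 150), n_grid = 31,
                                window = "hann", dc_exclude_frac = 0.04) {
  if (is.null(dim(bscan))) bscan <- matrix(bscan, ncol = 1)
  if (max(abs(bscan)) == 0) {
    warnf("optimize_dispersion: empty B-scan; returning zero coefficients")
    return(dispersion_model(0, 0, k0))
  }
  ana <- if (is.complex(bscan)) bscan else analytic_signal(bscan)
  ana <- shape_spectrum(ana, window)
  entropy_at <- function(par) {
    mdl <- dispersion_model(par[1], par[2], k0)
    rec <- fft_reconstruct(compensate_dispersion(ana, mdl, k))
    I <- Mod(rec$data)^2
    drop_dc <- seq_len(max(1L, ceiling(dc_exclude_frac * dim(I)[1])))
    I <- if (is.matrix(I)) I[-drop_dc, , drop = FALSE] else I[-drop_dc]
    p <- I / sum(I)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  grid <- seq(a2_range[1], a2_range[2], length.out = n_grid)
  ent <- vapply(grid, function(a2) entropy_at(c(a2, 0)), numeric(1))
  a2_0 <- grid[which.min(ent)]
  opt <- stats::optim(c(a2_0, 0), entropy_at, method = "Nelder-Mead",
                      control = list(reltol = 1e-8, maxit = 400))
  mdl <- dispersion_model(opt$par[1], opt$par[2], k0)
  attr(mdl, "entropy") <- c(optimum = opt$value, at_zero = entropy_at(c(0, 0)))
  mdl
}

#' Reconstruct a raw spectral volume into complex A-scans
#'
#' Full spectral-reconstruction chain for a simulated or loaded raw volume:
#' wavenumber calibration from the volume's k-clock fringe, per-B-scan
#' fixed-pattern removal, resampling to uniform wavenumber, dispersion
#' compensation, spectral shaping, and zero-padded Fourier reconstruction.
#'
#' @param raw A `raw_spectra_volume` (see [simulate_volume()] or
#'   [read_raw_volume()]).
#' @param dispersion `"given"` (use the source model's `a2`, `a3`; default),
#'   `"optimize"` (estimate from the central B-scan via
#'   [optimize_dispersion()]), `"none"`, or a [dispersion_model()].
#' @param window Apodization window (default `"hann"`).
#' @param pad_factor Zero-padding factor (default 4).
#' @param resample Apply wavenumber resampling (default TRUE; disable to
#'   study the effect of skipping calibration).
#' @param fixed_pattern Apply per-B-scan mean-spectrum subtraction (default
#'   TRUE).
#' @return Object of class `complex_volume` whose `data` is
#'   `[depth, a_scan, repeat, position]`, with `dispersion` and `calibration`
#'   records attached.
#' @export
reconstruct_volume <- function(raw, dispersion = "given", window = "hann",
                               pad_factor = 4, resample = TRUE,
                               fixed_pattern = TRUE) {
  stopifnot(inherits(raw, "raw_spectra_volume"))
  src <- raw$meta$source
  d <- dim(raw$samples)
  M <- d[1]
  curve <- calibrate_k(raw$calibration$fringe)
  g <- k_grid(src)
  k_unif <- g$k_uniform
  if (inherits(dispersion, "dispersion_model")) {
    mdl <- dispersion
  } else if (identical(dispersion, "given")) {
    mdl <- dispersion_model(src$a2, src$a3, src$k0)
  } else if (identical(dispersion, "none")) {
    mdl <- dispersion_model(0, 0, src$k0)
  } else if (identical(dispersion, "optimize")) {
    mid <- ceiling(d[4] / 2)
    b <- raw$samples[, , 1, mid]
    b <- b - rowMeans(b)
    if (resample) b <- resample_to_k(b, curve)
    mdl <- optimize_dispersion(b, k_unif, src$k0, window = window)
  } else stopf("unknown dispersion mode")

  n_pad <- pad_factor * M
  n_depth <- n_pad %/% 2
  out <- array(0i, dim = c(n_depth, d[2], d[3], d[4]))
  spec <- raw$samples
  if (fixed_pattern) spec <- remove_fixed_pattern(spec)
  for (p in seq_len(d[4])) for (r in seq_len(d[3])) {
    b <- spec[, , r, p]
    if (resample) b <- resample_to_k(b, curve)
    b <- compensate_dispersion(b, mdl, k_unif)
    b <- shape_spectrum(b, window)
    rec <- fft_reconstruct(b, dk = g$dk, n = raw$meta$n, n_pad = n_pad)
    out[, , r, p] <- rec$data
  }
  structure(list(data = out,
                 axial_pitch_um = axial_pitch_um(g$dk, n_pad, raw$meta$n),
                 n_pad = n_pad, n = raw$meta$n,
                 dispersion = mdl, calibration = curve),
            class = "complex_volume")
}
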