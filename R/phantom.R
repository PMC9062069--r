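#' Layered reflectivity phantom specification
#'
#' Describes a synthetic retina-like object for the interferogram simulator:
#' a stack of scattering layers that follow a smooth curved reference surface
#' (the phantom's RPE), parametric vessel tubes whose scatterers are
#' re-positioned axially between B-scan repeats (phase decorrelation by flow),
#' per-B-scan bulk axial motion, optional saccades, additive detection noise
#' and a fixed spectral pattern.
#'
#' All depths are in micrometres below the zero-delay line. Layers and vessels
#' ride on the curved surface: the curvature offset
#' `curv_um * (X^2 + Y^2)` (with X, Y the lateral coordinates normalized to
#' `[-1, 1]`) is added to every layer center and vessel depth, so the whole
#' stack is curved like a fundus.
#'
#' @param layers Data frame with columns `center_um`, `thickness_um`,
#'   `reflectivity`, `density` (scatterers per A-scan). The brightest layer is
#'   conventionally the RPE.
#' @param rpe_layer Index (into `layers`) of the layer acting as the RPE
#'   reference surface.
#' @param curv_um Peak-to-center curvature sag of the reference surface (um).
#' @param vessels Data frame (possibly 0-row) with columns `x_frac` (lateral
#'   center as fraction of the fast-axis extent), `depth_um`, `radius_um`,
#'   `reflectivity`, `density`, `sigma_flow_um` (per-repeat axial jitter SD).
#' @param bulk_sigma_um Per-B-scan random-walk step SD of bulk axial motion
#'   (um); 0 disables bulk motion.
#' @param bulk_dz_um Optional explicit per-B-scan axial displacement sequence
#'   (um), position-major (recycled to `repeats * n_positions`); overrides
#'   the random walk.
#' @param saccade_positions Integer vector of BM-position indices affected by
#'   saccadic motion. During the event the object moves between repeats
#'   (per-repeat decorrelating axial jumps and a fresh speckle realization,
#'   as the beam samples shifted tissue), and all subsequent positions are
#'   laterally displaced.
#' @param saccade_shift_steps Lateral displacement (in scan steps) applied
#'   from each saccade position onward.
#' @param noise_sigma Additive Gaussian detection-noise SD (fringe units).
#' @param fixed_pattern_amplitude Amplitude of the deterministic fixed-pattern
#'   spectral structure (fringe units).
#' @param dc_level Non-interferometric DC level of the fringe (fringe units).
#' @param n Refractive index of the phantom medium (default 1.33).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(layers,
                         rpe_layer = which.max(layers$reflectivity),
                         curv_um = 0,
                         vessels = NULL,
                         bulk_sigma_um = 0,
                         bulk_dz_um = NULL,
                         saccade_positions = integer(0),
                         saccade_shift_steps = 0,
                         noise_sigma = 0,
                         fixed_pattern_amplitude = 0,
                         dc_level = 2,
                         n = 1.33) {
  need <- c("center_um", "thickness_um", "reflectivity", "density")
  if (!all(need %in% names(layers)))
    stopf("phantom_spec: layers must have columns %s", paste(need, collapse = ", "))
  if (any(layers$center_um <= 0) || any(layers$reflectivity < 0))
    stopf("phantom_spec: layer depths must be positive, reflectivities non-negative")
  if (is.null(vessels))
    vessels <- data.frame(x_frac = numeric(0), depth_um = numeric(0),
                          radius_um = numeric(0), reflectivity = numeric(0),
                          density = numeric(0), sigma_flow_um = numeric(0))
  if (nrow(vessels) && any(vessels$sigma_flow_um < 0))
    stopf("phantom_spec: sigma_flow_um must be >= 0")
  if (bulk_sigma_um < 0 || noise_sigma < 0)
    stopf("phantom_spec: noise/motion sigmas must be >= 0")
  structure(list(
    layers = layers, rpe_layer = as.integer(rpe_layer), curv_um = curv_um,
    vessels = vessels, bulk_sigma_um = bulk_sigma_um,
    bulk_dz_um = bulk_dz_um,
    saccade_positions = as.integer(saccade_positions),
    saccade_shift_steps = saccade_shift_steps,
    noise_sigma = noise_sigma,
    fixed_pattern_amplitude = fixed_pattern_amplitude,
    dc_level = dc_level, n = n
  ), class = "phantom_spec")
}

# Deterministic fixed-pattern spectrum (same for every A-scan).
fixed_pattern_spectrum <- function(M, amplitude) {
  if (amplitude == 0) return(numeric(M))
  u <- seq(0, 1, length.out = M)
  amplitude * (0.6 * sin(2 * pi * 3.7 * u) + 0.4 * cos(2 * pi * 9.3 * u) + 0.5)
}

#' Simulate a calibration fringe (k-clock)
#'
#' Interference fringe of a single fixed reflector recorded with the same
#' sample-index-to-wavenumber mapping as the imaging data:
#' `envelope(k(m)) * cos(2 k(m) z_cal)` (reflector in air, n = 1).
#'
#' @param source A [source_model()].
#' @param z_cal_um Reflector depth (um). Default places ~`n_samples/8` fringe
#'   cycles across the sweep.
#' @return List with `fringe` (numeric vector), `z_cal_um`, and `phase`
#'   (the generating phase `2 k(m) z_cal`, for validation).
#' @export
simulate_calibration_fringe <- function(source, z_cal_um = NULL) {
  g <- k_grid(source)
  if (is.null(z_cal_um)) {
    cycles <- source$n_samples / 8
    z_cal_um <- cycles * pi / source$k_span
  }
  cycles <- source$k_span * z_cal_um / pi
  if (cycles < 10)
    stopf("calibration reflector too shallow: %.1f fringe cycles (need >= 10)", cycles)
  phase <- 2 * g$k * z_cal_um
  list(fringe = source_envelope(source, g$k) * cos(phase),
       z_cal_um = z_cal_um, phase = phase)
}

#' Simulate a raw spectral-fringe OCTA volume with ground truth
#'
#' Forward model of a repeated-B-scan acquisition. Each A-scan fringe is
#' `S(k_m) * (DC + sum_j 2 sqrt(r_j) cos(2 n k_m z_j + theta(k_m)))` plus a
#' fixed spectral pattern and Gaussian detection noise, sampled at the
#' source's (possibly nonlinear) wavenumbers `k_m`. Scatterers inside vessel
#' tubes random-walk axially between repeats with per-repeat step SD
#' `sigma_flow_um`, so consecutive repeats see circular phase steps of
#' SD ~ `2 n k0 sigma_flow` (flow-induced phase decorrelation); bulk
#' axial motion displaces the whole object per B-scan; saccade positions get
#' per-repeat decorrelating axial jumps and shift all later positions
#' laterally. Fringes are finally scaled to 90% of full scale and quantized
#' to 12-bit unsigned samples.
#'
#' @param spec A [phantom_spec()].
#' @param source A [source_model()].
#' @param protocol A [scan_protocol()]; `samples_per_ascan` must equal the
#'   source's `n_samples`.
#' @param seed Integer RNG seed (required; same seed gives identical output).
#' @param quantize Quantize to 12-bit integers (default TRUE). Disable for
#'   noise-calibration experiments needing exact float fringes.
#' @return List of class `raw_spectra_volume` with elements
#'   `samples` (array `[sample, a_scan, repeat, position]`),
#'   `calibration` (see [simulate_calibration_fringe()]),
#'   `meta` (protocol, source, spec, seed, quantization scale), and
#'   `truth` (class `phantom_truth`: `rpe_depth_um [a_scan, position]`,
#'   `vessel_footprint [a_scan, position]`, `vessel_depths` per-column list,
#'   `bulk_dz_um [repeat, position]`, `bulk_phase_rad`, `saccade_positions`).
#' @export
simulate_volume <- function(spec, source, protocol, seed, quantize = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(source, "source_model"),
            inherits(protocol, "scan_protocol"))
  if (missing(seed)) stopf("simulate_volume: a seed is required for reproducibility")
  if (protocol$samples_per_ascan != source$n_samples)
    stopf("protocol samples_per_ascan (%d) != source n_samples (%d)",
          protocol$samples_per_ascan, source$n_samples)
  g <- k_grid(source)
  M <- source$n_samples
  A <- protocol$a_scans
  R <- protocol$repeats
  P <- protocol$n_positions
  n <- spec$n
  zmax <- axial_range_um(g$dk, n)
  max_depth <- max(spec$layers$center_um + spec$layers$thickness_um / 2 + abs(spec$curv_um),
                   if (nrow(spec$vessels)) max(spec$vessels$depth_um + spec$vessels$radius_um + abs(spec$curv_um)) else 0)
  if (max_depth >= zmax)
    stopf("phantom extends to %.0f um, beyond the axial range %.0f um", max_depth, zmax)

  set.seed(as.integer(seed))
  env <- source_envelope(source, g$k)
  theta <- dispersion_phase(source, g$k)
  phase_corr <- complex(modulus = 1, argument = theta)  # e^{i theta(k)}
  two_nk <- 2 * n * g$k
  fp <- fixed_pattern_spectrum(M, spec$fixed_pattern_amplitude)

  x_um <- (seq_len(A) - 1) * protocol$step_um_x
  y_um <- (seq_len(P) - 1) * protocol$step_um_y
  fov_x <- max(x_um) + protocol$step_um_x
  Xn <- if (A > 1) 2 * (x_um - mean(x_um)) / (max(x_um) - min(x_um)) else 0 * x_um
  Yn <- if (P > 1) 2 * (y_um - mean(y_um)) / (max(y_um) - min(y_um)) else 0 * y_um

  # bulk motion: random walk over B-scan index (position-major, repeat-minor)
  n_b <- R * P
  bulk_dz <- if (!is.null(spec$bulk_dz_um)) rep_len(spec$bulk_dz_um, n_b)
    else if (spec$bulk_sigma_um > 0)
      cumsum(stats::rnorm(n_b, 0, spec$bulk_sigma_um)) else numeric(n_b)
  bulk_dz <- matrix(bulk_dz, nrow = R, ncol = P)
  # saccade: decorrelating per-repeat axial jumps at affected positions
  sacc <- spec$saccade_positions
  if (length(sacc)) {
    for (p in sacc)
      bulk_dz[, p] <- bulk_dz[, p] + stats::runif(R, -pi, pi) / (2 * n * source$k0)
  }
  bulk_phase <- wrap_phase(2 * n * source$k0 * bulk_dz)

  # cumulative lateral shift from saccades (in um), per position
  lat_shift <- numeric(P)
  if (length(sacc) && spec$saccade_shift_steps != 0) {
    for (p in sacc)
      lat_shift[seq(min(p, P), P)] <- lat_shift[seq(min(p, P), P)] +
        spec$saccade_shift_steps * protocol$step_um_x
  }

  samples <- array(0, dim = c(M, A, R, P))
  rpe_depth <- matrix(0, A, P)
  vessel_fp <- matrix(FALSE, A, P)
  vessel_depths <- vector("list", P)
  L <- spec$layers
  V <- spec$vessels
  rpe_center <- L$center_um[spec$rpe_layer]

  for (p in seq_len(P)) {
    curv_p <- spec$curv_um * (Xn^2 + Yn[p]^2)   # per-column curvature offset
    rpe_depth[, p] <- rpe_center + curv_p
    # effective lateral coordinate of the object under this position's shift
    x_eff <- x_um + lat_shift[p]
    vcol <- vector("list", A)
    # static scatterers per column
    stat_z <- vector("list", A)
    stat_amp <- vector("list", A)
    for (a in seq_len(A)) {
      zs <- numeric(0); as_ <- numeric(0)
      for (li in seq_len(nrow(L))) {
        nd <- L$density[li]
        if (nd < 1 || L$reflectivity[li] <= 0) next
        z <- L$center_um[li] + curv_p[a] +
          stats::runif(nd, -L$thickness_um[li] / 2, L$thickness_um[li] / 2)
        zs <- c(zs, z)
        as_ <- c(as_, rep(2 * sqrt(L$reflectivity[li] / nd), nd))
      }
      stat_z[[a]] <- zs; stat_amp[[a]] <- as_
      # vessel geometry for this column
      if (nrow(V)) {
        vrows <- list()
        for (vi in seq_len(nrow(V))) {
          xc <- V$x_frac[vi] * fov_x
          dx <- x_eff[a] - xc
          if (abs(dx) < V$radius_um[vi]) {
            h <- sqrt(V$radius_um[vi]^2 - dx^2)
            zc <- V$depth_um[vi] + curv_p[a]
            vrows[[length(vrows) + 1]] <- list(
              z_lo = zc - h, z_hi = zc + h,
              amp = 2 * sqrt(V$reflectivity[vi] / max(1, V$density[vi])),
              nd = max(1, V$density[vi]),
              sigma = V$sigma_flow_um[vi])
            vessel_fp[a, p] <- TRUE
          }
        }
        vcol[[a]] <- vrows
      }
    }
    vessel_depths[[p]] <- vcol
    # complex static spectra per column: C[m, a]
    Cstat <- matrix(0 + 0i, M, A)
    for (a in seq_len(A)) {
      if (length(stat_z[[a]]))
        Cstat[, a] <- exp(1i * outer(two_nk, stat_z[[a]])) %*% stat_amp[[a]]
    }
    # vessel scatterer base positions (drawn once, then random-walked per repeat)
    vstate <- vector("list", A)
    if (nrow(V)) {
      for (a in seq_len(A)) {
        vstate[[a]] <- lapply(vcol[[a]], function(vr)
          stats::runif(vr$nd, vr$z_lo, vr$z_hi))
      }
    }
    in_saccade <- p %in% sacc
    for (r in seq_len(R)) {
      dz <- bulk_dz[r, p]
      ramp <- exp(1i * two_nk * dz)
      if (in_saccade && r > 1) {
        # the beam lands on laterally shifted tissue: new speckle realization
        for (a in seq_len(A)) {
          if (length(stat_z[[a]])) {
            zs <- numeric(0)
            for (li in seq_len(nrow(L))) {
              nd <- L$density[li]
              if (nd < 1 || L$reflectivity[li] <= 0) next
              zs <- c(zs, L$center_um[li] + curv_p[a] +
                stats::runif(nd, -L$thickness_um[li] / 2, L$thickness_um[li] / 2))
            }
            Cstat[, a] <- exp(1i * outer(two_nk, zs)) %*% stat_amp[[a]]
          }
        }
      }
      Cr <- Cstat * ramp
      # vessel scatterers: axial random walk across repeats (flow decorrelation)
      if (nrow(V)) {
        for (a in seq_len(A)) {
          for (vi in seq_along(vcol[[a]])) {
            vr <- vcol[[a]][[vi]]
            if (r > 1)
              vstate[[a]][[vi]] <- vstate[[a]][[vi]] +
                stats::rnorm(vr$nd, 0, vr$sigma)
            zv <- vstate[[a]][[vi]] + dz
            Cr[, a] <- Cr[, a] +
              exp(1i * outer(two_nk, zv)) %*% rep(vr$amp, vr$nd)
          }
        }
      }
      fr <- env * (spec$dc_level + Re(phase_corr * Cr)) + fp
      if (spec$noise_sigma > 0)
        fr <- fr + stats::rnorm(length(fr), 0, spec$noise_sigma)
      samples[, , r, p] <- fr
    }
  }

  quant_scale <- NA_real_
  if (quantize) {
    quant_scale <- 0.9 * 4095 / max(samples)
    samples <- round(pmin(pmax(samples * quant_scale, 0), 4095))
  }

  truth <- structure(list(
    rpe_depth_um = rpe_depth,
    vessel_footprint = vessel_fp,
    vessel_depths = vessel_depths,
    bulk_dz_um = bulk_dz,
    bulk_phase_rad = bulk_phase,
    saccade_positions = sacc
  ), class = "phantom_truth")

  structure(list(
    samples = samples,
    calibration = simulate_calibration_fringe(source),
    meta = list(protocol = protocol, source = source, spec = spec,
                seed = as.integer(seed), quant_scale = quant_scale,
                n = n, dk = g$dk),
    truth = truth
  ), class = "raw_spectra_volume")
}

#' Ground-truth vessel mask on the reconstruction depth grid
#'
#' Expands the simulator's per-column vessel depth intervals into a logical
#' mask `[depth, a_scan, position]` at a given axial pixel pitch.
#'
#' @param truth `phantom_truth` from [simulate_volume()].
#' @param axial_pitch_um Depth pixel pitch (um) of the reconstructed volume.
#' @param n_depth Number of depth pixels.
#' @param pad_um Dilation of each interval (um) to absorb PSF blur (default 5).
#' @return Logical array `[n_depth, a_scan, position]`.
#' @export
truth_vessel_mask <- function(truth, axial_pitch_um, n_depth, pad_um = 5) {
  A <- nrow(truth$rpe_depth_um); P <- ncol(truth$rpe_depth_um)
  m <- array(FALSE, dim = c(n_depth, A, P))
  for (p in seq_len(P)) for (a in seq_len(A)) {
    for (vr in truth$vessel_depths[[p]][[a]]) {
      lo <- max(1L, 1L + floor((vr$z_lo - pad_um) / axial_pitch_um))
      hi <- min(n_depth, 1L + ceiling((vr$z_hi + pad_um) / axial_pitch_um))
      if (hi >= lo) m[lo:hi, a, p] <- TRUE
    }
  }
  m
}

#' Preset phantoms
#'
#' Ready-made (phantom, source, protocol) triples:
#' * `"mirror"`: a single reflector at 150 um, no vessels, with injected
#'   wavenumber-sampling nonlinearity (`chirp = 0.25`) and quadratic
#'   dispersion (`a2 = 60`), for PSF and calibration-recovery tests.
#' * `"flow_bar"`: one rectangular slab of decorrelating (flowing) scatterers
#'   over a static layer, for phase-variance calibration.
#' * `"retina_small"`: a 64 x 64-position, 5-repeat, 512-sample miniature
#'   retina with three layers, a curved RPE, two vessel tubes, bulk
#'   random-walk motion and detection noise.
#'
#' @param name Preset name.
#' @param ... Overrides passed to the underlying [source_model()] (`chirp`,
#'   `a2`, `a3`, `envelope`) or phantom (`bulk_sigma_um`, `noise_sigma`,
#'   `saccade_positions`, `saccade_shift_steps`, `sigma_flow_um`).
#' @return List with `spec`, `source`, `protocol`.
#' @export
make_preset_phantom <- function(name, ...) {
  ov <- list(...)
  pick <- function(nm, default) if (nm %in% names(ov)) ov[[nm]] else default
  lambda0_um <- 1.065
  if (name == "mirror") {
    source <- source_model(n_samples = 512, envelope = pick("envelope", "gaussian"),
                           chirp = pick("chirp", 0.25), a2 = pick("a2", 60),
                           a3 = pick("a3", 0))
    protocol <- scan_protocol(0.08, 0.01, 5, 5, repeats = 2, sweep_rate_hz = 1.7e6,
                              samples_per_ascan = 512, a_scans = 16, n_positions = 2)
    layers <- data.frame(center_um = 150, thickness_um = 0, reflectivity = 1,
                         density = 1)
    spec <- phantom_spec(layers, curv_um = 0,
                         bulk_sigma_um = pick("bulk_sigma_um", 0),
                         noise_sigma = pick("noise_sigma", 0),
                         fixed_pattern_amplitude = pick("fixed_pattern_amplitude", 0),
                         dc_level = 2)
  } else if (name == "flow_bar") {
    source <- source_model(n_samples = 512, chirp = pick("chirp", 0),
                           a2 = pick("a2", 0))
    protocol <- scan_protocol(0.16, 0.04, 5, 5, repeats = 5, sweep_rate_hz = 1.7e6,
                              samples_per_ascan = 512, a_scans = 32, n_positions = 8)
    layers <- data.frame(center_um = c(250), thickness_um = c(30),
                         reflectivity = c(2e-3), density = c(8))
    sflow <- pick("sigma_flow_um", lambda0_um / (8 * 1.33))
    vessels <- data.frame(x_frac = 0.5, depth_um = 170, radius_um = 42,
                          reflectivity = 2e-3, density = 8,
                          sigma_flow_um = sflow)
    spec <- phantom_spec(layers, vessels = vessels,
                         bulk_sigma_um = pick("bulk_sigma_um", 0),
                         noise_sigma = pick("noise_sigma", 0),
                         dc_level = 2)
  } else if (name == "retina_small") {
    source <- source_model(n_samples = 512, chirp = pick("chirp", 0.15),
                           a2 = pick("a2", 20), a3 = pick("a3", 0))
    protocol <- scan_protocol(0.32, 0.32, 5, 5, repeats = 5, sweep_rate_hz = 1.7e6,
                              samples_per_ascan = 512, a_scans = 64, n_positions = 64)
    layers <- data.frame(
      center_um    = c(120, 200, 330),
      thickness_um = c(30, 40, 14),
      reflectivity = c(1e-3, 1.2e-3, 6e-3),  # third layer is the bright RPE
      density      = c(8, 8, 8))
    sflow <- pick("sigma_flow_um", lambda0_um / (8 * 1.33))
    vessels <- data.frame(x_frac = c(0.3, 0.7), depth_um = c(185, 230),
                          radius_um = c(12, 12), reflectivity = c(2e-3, 2e-3),
                          density = c(6, 6), sigma_flow_um = sflow)
    spec <- phantom_spec(layers, rpe_layer = 3, curv_um = 25, vessels = vessels,
                         bulk_sigma_um = pick("bulk_sigma_um", lambda0_um / 16),
                         saccade_positions = pick("saccade_positions", integer(0)),
                         saccade_shift_steps = pick("saccade_shift_steps", 0),
                         noise_sigma = pick("noise_sigma", 0.01),
                         fixed_pattern_amplitude = pick("fixed_pattern_amplitude", 0.05),
                         dc_level = 2)
  } else {
    stopf("unknown phantom preset '%s'", name)
  }
  list(spec = spec, source = source, protocol = protocol)
}
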