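#' Swept-source spectral model
#'
#' Describes the light source and digitizer sampling of a swept-source OCT
#' system: center wavelength, optical bandwidth, spectral envelope shape, the
#' (possibly nonlinear) mapping from digitizer sample index to optical
#' wavenumber, and residual interferometer dispersion.
#'
#' The sampled wavenumber band spans `k_span_factor` times the FWHM bandwidth
#' (in wavenumber), centered on `k0`. Sample-index-to-wavenumber nonlinearity
#' is a smooth monotone quadratic warp: with `u = m/(M-1)`,
#' `k(m) = k_min + span * (u + chirp * u * (1 - u))`; `|chirp| < 1` guarantees
#' strict monotonicity. Residual dispersion adds the spectral phase
#' `theta(k) = a2 * (k - k0)^2 + a3 * (k - k0)^3` to every interference fringe.
#'
#' @param center_wavelength_nm Center wavelength (nm), default 1065.
#' @param bandwidth_fwhm_nm FWHM optical bandwidth (nm), default 80.
#' @param n_samples Spectral samples per sweep.
#' @param envelope `"gaussian"` (default) or `"flat"` spectral envelope.
#' @param k_span_factor Sampled span as a multiple of the FWHM wavenumber
#'   bandwidth (default 3, so a Gaussian envelope decays to ~0.2% at the band
#'   edges).
#' @param chirp Quadratic sampling-nonlinearity coefficient, `|chirp| < 1`.
#' @param a2,a3 Dispersion coefficients (rad per (rad/um)^2 and ^3) about `k0`.
#' @return Object of class `source_model` with derived fields `k0` (rad/um),
#'   `dk_fwhm` (rad/um) and `k_span` (rad/um).
#' @examples
#' src <- source_model(n_samples = 512, chirp = 0.2)
#' k <- k_grid(src)
#' all(diff(k$k) > 0)
#' @export
source_model <- function(center_wavelength_nm = 1065,
                         bandwidth_fwhm_nm = 80,
                         n_samples = 1024,
                         envelope = c("gaussian", "flat"),
                         k_span_factor = 3,
                         chirp = 0,
                         a2 = 0, a3 = 0) {
  envelope <- match.arg(envelope)
  if (abs(chirp) >= 1)
    stopf("source_model: |chirp| must be < 1 for a monotone wavenumber mapping")
  if (n_samples < 16) stopf("source_model: n_samples too small")
  lambda0 <- center_wavelength_nm / 1000   # um
  dlambda <- bandwidth_fwhm_nm / 1000      # um
  k0 <- 2 * pi / lambda0                   # rad/um
  dk_fwhm <- 2 * pi * dlambda / lambda0^2  # rad/um
  structure(list(
    center_wavelength_nm = center_wavelength_nm,
    bandwidth_fwhm_nm = bandwidth_fwhm_nm,
    n_samples = as.integer(n_samples),
    envelope = envelope,
    k_span_factor = k_span_factor,
    chirp = chirp, a2 = a2, a3 = a3,
    k0 = k0, dk_fwhm = dk_fwhm,
    k_span = k_span_factor * dk_fwhm
  ), class = "source_model")
}

#' Wavenumber sampling grids of a source model
#'
#' @param source A [source_model()].
#' @return List with `k` (actual, possibly warped, sampled wavenumbers,
#'   rad/um), `k_uniform` (the ideal linear grid over the same span), `dk`
#'   (uniform sample spacing) and `u` (normalized sample index).
#' @export
k_grid <- function(source) {
  M <- source$n_samples
  u <- seq(0, 1, length.out = M)
  k_min <- source$k0 - source$k_span / 2
  k_uniform <- k_min + source$k_span * u
  uw <- u + source$chirp * u * (1 - u)
  k <- k_min + source$k_span * uw
  list(k = k, k_uniform = k_uniform, dk = source$k_span / (M - 1), u = u)
}

#' Spectral envelope evaluated at given wavenumbers
#'
#' @param source A [source_model()].
#' @param k Wavenumbers (rad/um); defaults to the source's sampled grid.
#' @return Non-negative envelope values (unit peak).
#' @export
source_envelope <- function(source, k = k_grid(source)$k) {
  if (source$envelope == "flat") return(rep(1, length(k)))
  sigma <- source$dk_fwhm / (2 * sqrt(2 * log(2)))
  exp(-(k - source$k0)^2 / (2 * sigma^2))
}

#' Dispersion phase of a source model
#'
#' `theta(k) = a2 (k - k0)^2 + a3 (k - k0)^3`.
#'
#' @param source A [source_model()] (or a [dispersion_model()]).
#' @param k Wavenumbers (rad/um).
#' @param k0 Band center; defaults to the model's `k0`.
#' @return Phase in radians.
#' @export
dispersion_phase <- function(source, k, k0 = source$k0) {
  dk <- k - k0
  source$a2 * dk^2 + source$a3 * dk^3
}

#' Transform-limited axial resolution of a Gaussian source
#'
#' FWHM of the reconstructed point-spread magnitude for a Gaussian spectral
#' envelope: `(2 ln 2 / pi) * lambda0^2 / (n * dlambda)`.
#'
#' @param source A [source_model()].
#' @param n Refractive index of the medium (default 1.33).
#' @return FWHM in micrometres.
#' @export
transform_limit_fwhm_um <- function(source, n = 1.33) {
  lambda0 <- source$center_wavelength_nm / 1000
  dlambda <- source$bandwidth_fwhm_nm / 1000
  (2 * log(2) / pi) * lambda0^2 / (n * dlambda)
}

#' Axial pixel pitch of the reconstructed A-scan
#'
#' With uniform wavenumber spacing `dk` and a zero-padded transform of length
#' `n_pad`, depth pixel `p` corresponds to `z = p * pi / (n * n_pad * dk)`.
#'
#' @param dk Uniform wavenumber sample spacing (rad/um).
#' @param n_pad Zero-padded transform length.
#' @param n Refractive index (default 1.33).
#' @return Pitch in micrometres per depth pixel.
#' @export
axial_pitch_um <- function(dk, n_pad, n = 1.33) {
  pi / (n * n_pad * dk)
}

#' One-sided axial imaging range
#'
#' `z_max = pi / (2 n dk)`: the depth of the last one-sided pixel, set by the
#' wavenumber sample spacing alone.
#'
#' @inheritParams axial_pitch_um
#' @return Range in micrometres.
#' @export
axial_range_um <- function(dk, n = 1.33) {
  pi / (2 * n * dk)
}
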