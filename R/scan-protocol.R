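#' Define an OCTA raster scan protocol
#'
#' A scan protocol fixes the geometry and timing of a repeated-B-scan (BM-scan)
#' raster acquisition: field of view, scan step, number of B-scan repeats per
#' slow-scanner position, spectral samples per A-scan, and sweep rate.
#'
#' A-scan and slow-position counts are normally derived from extent/step by
#' truncation toward zero (9 mm at 7 um steps gives 1285 A-scans per B-scan).
#' Instrument protocols often use hardware round numbers instead (1024 A-scans
#' over a nominal 5 mm at 5 um); pass `a_scans`/`n_positions` explicitly to
#' override the derivation.
#'
#' @param fov_mm_x,fov_mm_y Scan extent in mm (fast, slow axis).
#' @param step_um_x,step_um_y Scan step in micrometres.
#' @param repeats B-scans per BM-scan (integer >= 1).
#' @param sweep_rate_hz Source sweep rate (A-scans per second).
#' @param samples_per_ascan Spectral samples per A-scan.
#' @param beam_diameter_um 1/e^2 beam spot diameter at the retina (um).
#' @param bscan_period_ms Optional B-scan repetition time including fly-back
#'   (ms). When absent, timing derives from `a_scans / sweep_rate` with zero
#'   fly-back.
#' @param bytes_per_sample Storage bytes per spectral sample (default 2, i.e.
#'   12-bit samples in 16-bit containers).
#' @param a_scans,n_positions Optional explicit counts overriding the
#'   extent/step derivation.
#' @return An object of class `scan_protocol`.
#' @examples
#' p <- scan_protocol(9, 9, 7, 7, repeats = 4, sweep_rate_hz = 1e5)
#' plan_acquisition(p)
#' @export
scan_protocol <- function(fov_mm_x, fov_mm_y, step_um_x, step_um_y,
                          repeats, sweep_rate_hz,
                          samples_per_ascan = 1024,
                          beam_diameter_um = 14,
                          bscan_period_ms = NULL,
                          bytes_per_sample = 2,
                          a_scans = NULL, n_positions = NULL) {
  for (nm in c("fov_mm_x", "fov_mm_y", "step_um_x", "step_um_y",
               "sweep_rate_hz", "samples_per_ascan", "beam_diameter_um",
               "bytes_per_sample")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stopf("scan_protocol: '%s' must be a single positive number", nm)
  }
  if (!is.numeric(repeats) || repeats < 1 || repeats != round(repeats))
    stopf("scan_protocol: 'repeats' must be an integer >= 1")
  if (!is.null(bscan_period_ms) && (!is.numeric(bscan_period_ms) || bscan_period_ms <= 0))
    stopf("scan_protocol: 'bscan_period_ms' must be positive when given")
  a_scans <- a_scans %||% max(1L, as.integer(trunc(fov_mm_x * 1000 / step_um_x)))
  n_positions <- n_positions %||% max(1L, as.integer(trunc(fov_mm_y * 1000 / step_um_y)))
  structure(list(
    fov_mm_x = fov_mm_x, fov_mm_y = fov_mm_y,
    step_um_x = step_um_x, step_um_y = step_um_y,
    repeats = as.integer(repeats),
    sweep_rate_hz = sweep_rate_hz,
    samples_per_ascan = as.integer(samples_per_ascan),
    beam_diameter_um = beam_diameter_um,
    bscan_period_ms = bscan_period_ms,
    bytes_per_sample = bytes_per_sample,
    a_scans = as.integer(a_scans),
    n_positions = as.integer(n_positions)
  ), class = "scan_protocol")
}

#' Named scan-protocol presets
#'
#' `fdml1`/`fdml2` are the two 1.7-MHz FDML swept-source OCTA raster protocols
#' (5 mm / 5 um and 9 mm / 8 um isotropic steps, 5 repeats, 1024 spectral
#' samples); `angioplex1`/`angioplex2` are the 68-kHz commercial SD-OCT
#' protocols (3 mm / 12 um with 4 repeats, 6 mm / 17 um with 2 repeats).
#'
#' @param name One of `"fdml1"`, `"fdml2"`, `"angioplex1"`, `"angioplex2"`.
#' @return A [scan_protocol()].
#' @export
protocol_preset <- function(name) {
  switch(name,
    fdml1 = scan_protocol(5, 5, 5, 5, repeats = 5, sweep_rate_hz = 1.7e6,
                          samples_per_ascan = 1024, beam_diameter_um = 14,
                          bscan_period_ms = 1.2,
                          a_scans = 1024, n_positions = 1024),
    fdml2 = scan_protocol(9, 9, 8, 8, repeats = 5, sweep_rate_hz = 1.7e6,
                          samples_per_ascan = 1024, beam_diameter_um = 14,
                          bscan_period_ms = 1.35,
                          a_scans = 1152, n_positions = 1152),
    angioplex1 = scan_protocol(3, 3, 12, 12, repeats = 4, sweep_rate_hz = 68e3,
                               samples_per_ascan = 1024, beam_diameter_um = 15,
                               bscan_period_ms = 3.8,
                               a_scans = 245, n_positions = 245),
    angioplex2 = scan_protocol(6, 6, 17, 17, repeats = 2, sweep_rate_hz = 68e3,
                               samples_per_ascan = 1024, beam_diameter_um = 15,
                               bscan_period_ms = 5,
                               a_scans = 350, n_positions = 350),
    stopf("unknown protocol preset '%s'", name)
  )
}

#' Plan an acquisition: counts, time, data size, sampling ratios
#'
#' Computes the arithmetic of a raster OCTA acquisition: A-scans per B-scan,
#' slow-scanner positions, total B-scans, volume acquisition time, raw data
#' size in decimal gigabytes, and the step-to-spot sampling ratio on each axis.
#'
#' Acquisition time uses the B-scan repetition period (which includes fly-back)
#' when the protocol specifies one, otherwise `a_scans / sweep_rate` per B-scan
#' with zero fly-back. Reported values follow instrument-table conventions:
#' minutes to 1 decimal, seconds to the nearest integer, gigabytes (1e9 bytes)
#' to the nearest integer.
#'
#' @param protocol A [scan_protocol()].
#' @return An object of class `acquisition_plan` (also a list) with fields
#'   `a_scans_per_bscan`, `n_positions`, `total_bscans`, `volume_time_s`,
#'   `volume_time_min`, `volume_time_s_reported`, `volume_time_min_reported`,
#'   `data_size_gb`, `data_size_gb_reported`, `sampling_ratio_x`,
#'   `sampling_ratio_y`, `undersampled_x`, `undersampled_y`.
#' @export
plan_acquisition <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  p <- protocol
  total_bscans <- p$repeats * p$n_positions
  if (!is.null(p$bscan_period_ms)) {
    t_s <- total_bscans * p$bscan_period_ms / 1000
  } else {
    t_s <- total_bscans * p$a_scans / p$sweep_rate_hz
  }
  gb <- data_size_gb(p)
  srx <- sampling_ratio(p$step_um_x, p$beam_diameter_um)
  sry <- sampling_ratio(p$step_um_y, p$beam_diameter_um)
  structure(list(
    a_scans_per_bscan = p$a_scans,
    n_positions = p$n_positions,
    total_bscans = total_bscans,
    volume_time_s = t_s,
    volume_time_min = t_s / 60,
    volume_time_s_reported = round(t_s),
    volume_time_min_reported = round(t_s / 60, 1),
    data_size_gb = gb,
    data_size_gb_reported = round(gb),
    sampling_ratio_x = srx$ratio,
    sampling_ratio_y = sry$ratio,
    undersampled_x = srx$undersampled,
    undersampled_y = sry$undersampled
  ), class = "acquisition_plan")
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat("OCTA acquisition plan\n")
  cat(sprintf("  A-scans per B-scan : %d\n", x$a_scans_per_bscan))
  cat(sprintf("  slow positions     : %d\n", x$n_positions))
  cat(sprintf("  total B-scans      : %d\n", x$total_bscans))
  cat(sprintf("  volume time        : %.2f s%s\n", x$volume_time_s,
              if (x$volume_time_s >= 60)
                sprintf(" (%.1f min)", x$volume_time_min_reported) else ""))
  cat(sprintf("  data size          : %.2f GB (~%d GB)\n",
              x$data_size_gb, x$data_size_gb_reported))
  cat(sprintf("  sampling ratio x/y : %.2f / %.2f%s\n",
              x$sampling_ratio_x, x$sampling_ratio_y,
              if (x$undersampled_x || x$undersampled_y)
                "  [step > half spot: undersampled]" else ""))
  invisible(x)
}

#' @export
as.data.frame.acquisition_plan <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Volume acquisition time from the B-scan repetition period
#'
#' @param protocol A [scan_protocol()] with `bscan_period_ms` set.
#' @return List with `seconds` (exact) and `seconds_reported` (nearest integer).
#' @export
volume_time_from_period <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (is.null(protocol$bscan_period_ms)) {
    message("no B-scan period given; deriving time without fly-back from sweep rate")
    s <- protocol$repeats * protocol$n_positions *
      protocol$a_scans / protocol$sweep_rate_hz
  } else {
    s <- protocol$repeats * protocol$n_positions * protocol$bscan_period_ms / 1000
  }
  list(seconds = s, seconds_reported = round(s))
}

#' Raw data size of an acquisition in decimal gigabytes
#'
#' `total_bscans * a_scans * samples_per_ascan * bytes_per_sample / 1e9`.
#' Instrument tables round this to the nearest integer GB.
#'
#' @param protocol A [scan_protocol()].
#' @return Size in decimal GB (numeric, unrounded).
#' @export
data_size_gb <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  p <- protocol
  as.numeric(p$repeats) * p$n_positions * p$a_scans * p$samples_per_ascan *
    p$bytes_per_sample / 1e9
}

#' Spatial sampling ratio of scan step to beam spot
#'
#' Ratio of the scan step to the 1/e^2 beam spot diameter at the retina.
#' A step exceeding half the spot diameter undersamples the optical
#' resolution (half-spot criterion).
#'
#' @param step_um Scan step (um).
#' @param beam_diameter_um 1/e^2 spot diameter (um).
#' @return List with `ratio` (exact), `ratio_reported` (2 decimals) and
#'   logical `undersampled` (step > beam/2).
#' @export
sampling_ratio <- function(step_um, beam_diameter_um) {
  if (step_um <= 0 || beam_diameter_um <= 0)
    stopf("sampling_ratio: step and beam diameter must be positive")
  r <- step_um / beam_diameter_um
  list(ratio = r, ratio_reported = round(r, 2),
       undersampled = step_um > beam_diameter_um / 2)
}
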