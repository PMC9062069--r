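#' Write a raw spectral volume as binary + JSON sidecar
#'
#' Samples are written little-endian 16-bit, sample-fastest then A-scan,
#' repeat, BM-position (the raw file stays headerless); dimensions, protocol,
#' source model, calibration fringe, quantization scale and seed go into the
#' JSON sidecar `<prefix>.json`.
#'
#' @param raw A `raw_spectra_volume`.
#' @param prefix Output path prefix (writes `<prefix>.raw`, `<prefix>.json`).
#' @return Invisibly, the two file paths.
#' @export
write_raw_volume <- function(raw, prefix) {
  stopifnot(inherits(raw, "raw_spectra_volume"))
  bin <- paste0(prefix, ".raw")
  side <- paste0(prefix, ".json")
  con <- file(bin, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(raw$samples), con, size = 2, endian = "little")
  meta <- list(
    dims = dim(raw$samples),
    order = "sample,a_scan,repeat,position",
    endian = "little", bits = 12, container_bits = 16,
    protocol = serialize_protocol(raw$meta$protocol),
    source = serialize_source(raw$meta$source),
    calibration_fringe = raw$calibration$fringe,
    calibration_z_um = raw$calibration$z_cal_um,
    seed = raw$meta$seed,
    quant_scale = raw$meta$quant_scale,
    n = raw$meta$n
  )
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(bin, side))
}

serialize_protocol <- function(p) {
  unclass(p)
}

deserialize_protocol <- function(l) {
  period <- l$bscan_period_ms
  if (length(period) == 0) period <- NULL   # JSON null round-trips as list()
  scan_protocol(l$fov_mm_x, l$fov_mm_y, l$step_um_x, l$step_um_y,
                repeats = l$repeats, sweep_rate_hz = l$sweep_rate_hz,
                samples_per_ascan = l$samples_per_ascan,
                beam_diameter_um = l$beam_diameter_um,
                bscan_period_ms = period,
                bytes_per_sample = l$bytes_per_sample,
                a_scans = l$a_scans, n_positions = l$n_positions)
}

serialize_source <- function(s) {
  s[c("center_wavelength_nm", "bandwidth_fwhm_nm", "n_samples", "envelope",
      "k_span_factor", "chirp", "a2", "a3")]
}

deserialize_source <- function(l) {
  source_model(l$center_wavelength_nm, l$bandwidth_fwhm_nm, l$n_samples,
               l$envelope, l$k_span_factor, l$chirp, l$a2, l$a3)
}

#' Read a raw spectral volume written by [write_raw_volume()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `raw_spectra_volume` (without ground truth).
#' @export
read_raw_volume <- function(prefix) {
  bin <- paste0(prefix, ".raw")
  side <- paste0(prefix, ".json")
  if (!file.exists(bin) || !file.exists(side))
    stopf("read_raw_volume: missing %s or %s", bin, side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dims <- as.integer(meta$dims)
  n_expected <- prod(dims)
  n_bytes <- file.size(bin)
  if (n_bytes != 2 * n_expected)
    stopf("read_raw_volume: %s has %d bytes, expected %d (%s samples)",
          bin, n_bytes, 2 * n_expected, paste(dims, collapse = "x"))
  con <- file(bin, "rb")
  on.exit(close(con), add = TRUE)
  v <- readBin(con, integer(), n = n_expected, size = 2, endian = "little",
               signed = TRUE)
  source <- deserialize_source(meta$source)
  structure(list(
    samples = array(as.numeric(v), dim = dims),
    calibration = list(fringe = as.numeric(meta$calibration_fringe),
                       z_cal_um = meta$calibration_z_um),
    meta = list(protocol = deserialize_protocol(as.list(meta$protocol)),
                source = source,
                seed = meta$seed, quant_scale = meta$quant_scale,
                n = meta$n, dk = k_grid(source)$dk),
    truth = NULL
  ), class = "raw_spectra_volume")
}

#' Write an angiography volume as 32-bit float TIFF stacks + JSON
#'
#' Writes `<prefix>_pv.tif` and `<prefix>_intensity.tif` (one slice per
#' BM-position, values scaled to [0, 1] with the scale recorded in the
#' sidecar) and `<prefix>.json` with bulk offsets, mask statistics and axial
#' pitch. PV uses the fixed scale `pi^2` (its theoretical maximum).
#'
#' @param angio An `angio_volume`.
#' @param prefix Output path prefix.
#' @return Invisibly, the file paths.
#' @export
write_angio <- function(angio, prefix) {
  stopifnot(inherits(angio, "angio_volume"))
  pv_f <- paste0(prefix, "_pv.tif")
  it_f <- paste0(prefix, "_intensity.tif")
  side <- paste0(prefix, ".json")
  P <- dim(angio$pv)[3]
  i_scale <- max(angio$intensity)
  slices <- function(a, s) lapply(seq_len(P), function(p) a[, , p] / s)
  tiff::writeTIFF(slices(angio$pv, pi^2), pv_f, bits.per.sample = 32,
                  reduce = FALSE)
  tiff::writeTIFF(slices(angio$intensity, i_scale), it_f,
                  bits.per.sample = 32, reduce = FALSE)
  meta <- list(dims = dim(angio$pv),
               axial_pitch_um = angio$axial_pitch_um,
               pv_scale = pi^2, intensity_scale = i_scale,
               threshold = angio$threshold, kappa = angio$kappa,
               noise = angio$noise[c("mu", "sigma")],
               mask_fraction = mean(angio$mask),
               beta_stats = list(mean_abs = mean(abs(angio$beta)),
                                 max_abs = max(abs(angio$beta))))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(pv_f, it_f, side))
}

#' Read back an angiography volume written by [write_angio()]
#'
#' @param prefix Path prefix used at write time.
#' @return List with `pv` and `intensity` arrays (values restored to
#'   physical scale, 32-bit float precision) and the sidecar `meta`.
#' @export
read_angio <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  stack_of <- function(f, s) {
    sl <- tiff::readTIFF(f, all = TRUE)
    a <- array(0, dim = meta$dims)
    for (p in seq_along(sl)) a[, , p] <- sl[[p]] * s
    a
  }
  list(pv = stack_of(paste0(prefix, "_pv.tif"), meta$pv_scale),
       intensity = stack_of(paste0(prefix, "_intensity.tif"),
                            meta$intensity_scale),
       meta = meta)
}

#' Write an en face projection as 16-bit TIFF and 8-bit PNG preview
#'
#' Intensities are stretched between the 0.5 and 99.5 percentiles; the
#' stretch bounds are recorded in the JSON sidecar so non-clipped pixel
#' values are recoverable.
#'
#' @param proj An `enface_projection` (or numeric matrix).
#' @param prefix Output path prefix.
#' @param probs Stretch percentiles (default `c(0.005, 0.995)`).
#' @return Invisibly, the file paths; sidecar records the stretch.
#' @export
write_projection <- function(proj, prefix, probs = c(0.005, 0.995)) {
  img <- if (inherits(proj, "enface_projection")) proj$image else proj
  q <- stats::quantile(img, probs, names = FALSE)
  if (q[2] <= q[1]) q[2] <- q[1] + 1
  norm <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
  tif <- paste0(prefix, ".tif")
  pngf <- paste0(prefix, ".png")
  side <- paste0(prefix, ".json")
  tiff::writeTIFF(norm, tif, bits.per.sample = 16)
  png::writePNG(t(norm), pngf)   # transpose: fast axis across image rows
  meta <- list(stretch_lo = q[1], stretch_hi = q[2], probs = probs,
               dims = dim(img),
               window = if (inherits(proj, "enface_projection"))
                 unclass(proj$window) else NULL,
               rejected = if (inherits(proj, "enface_projection"))
                 proj$rejected else NULL)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(tif, pngf, side))
}

#' Read back a projection written by [write_projection()]
#'
#' Re-applies the recorded stretch to recover physical values (exact up to
#' 16-bit quantization on non-clipped pixels).
#'
#' @param prefix Path prefix used at write time.
#' @return Numeric matrix.
#' @export
read_projection <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  norm <- tiff::readTIFF(paste0(prefix, ".tif"))
  norm * (meta$stretch_hi - meta$stretch_lo) + meta$stretch_lo
}
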