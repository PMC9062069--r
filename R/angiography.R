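#' Noise statistics from a structure-free depth band
#'
#' Mean and standard deviation of the reconstructed magnitude inside a depth
#' band assumed free of object structure (default: the deepest 10% of the
#' axial range). Used to set the intensity threshold that excludes noise
#' pixels from phase-variance computation.
#'
#' @param volume A `complex_volume` or a complex/numeric array (depth first).
#' @param band Integer depth-pixel range (vector of indices), or NULL for the
#'   deepest 10%.
#' @return List with `mu`, `sigma`, and the `band` used.
#' @export
estimate_noise_stats <- function(volume, band = NULL) {
  x <- if (inherits(volume, "complex_volume")) volume$data else volume
  D <- dim(x)[1] %||% length(x)
  if (is.null(band)) band <- seq(ceiling(0.9 * D), D)
  mag <- abs(if (is.null(dim(x))) x[band] else
    array(x, dim = c(D, length(x) / D))[band, ])
  list(mu = mean(mag), sigma = stats::sd(as.vector(mag)), band = band)
}

#' Intensity noise mask
#'
#' TRUE where the magnitude exceeds `mu + kappa * sigma` of the noise floor.
#'
#' @param magnitude Numeric array of magnitudes.
#' @param noise List from [estimate_noise_stats()].
#' @param kappa Threshold multiplier (default 3).
#' @return Logical array of the same shape; attribute `threshold` carries T.
#' @export
noise_mask <- function(magnitude, noise, kappa = 3) {
  T <- noise$mu + kappa * noise$sigma
  structure(magnitude > T, threshold = T)
}

#' Bulk axial-motion phase offset by shifted-histogram analysis
#'
#' Estimates, for each A-scan column of a wrapped phase-difference frame, the
#' global phase offset caused by bulk axial eye motion. The estimator builds
#' `n_shifts` intensity-weighted circular histograms of the phase differences
#' with bin width `2 pi / n_bins`, each shifted by a fraction of a bin,
#' averages them, and takes the circular position of the maximum (the mode),
#' refined by intensity-weighted mean-shift iterations about the mode
#' (triangular kernel spanning +/- 8 coarse bins, run to convergence; wide
#' enough for low variance on concentrated static phase, narrow enough that
#' decorrelated flow pixels do not bias the mode). Columns with fewer masked pixels than
#' `min_pixels` inherit the offset of the nearest valid column.
#'
#' @param dphi Wrapped phase-difference frame `[depth, a_scan]` (radians).
#' @param weights Non-negative weights, same shape (typically masked
#'   intensity: magnitude where the noise mask is TRUE, 0 elsewhere).
#' @param n_bins Coarse histogram bins over `[-pi, pi)` (default 64).
#' @param n_shifts Number of shifted histograms (default 4).
#' @param min_pixels Minimum weighted pixels for a valid column (default 8).
#' @return Numeric vector `beta` of per-column offsets (radians, in
#'   `[-pi, pi)`), with attribute `valid` (logical per column).
#' @export
bulk_phase_offset <- function(dphi, weights, n_bins = 64, n_shifts = 4,
                              min_pixels = 8) {
  stopifnot(identical(dim(dphi), dim(weights)))
  A <- ncol(dphi)
  n_fine <- n_bins * n_shifts
  wfine <- 2 * pi / n_fine
  beta <- rep(NA_real_, A)
  valid <- logical(A)
  for (a in seq_len(A)) {
    w <- weights[, a]
    use <- w > 0
    if (sum(use) < min_pixels) next
    ph <- dphi[use, a]
    wv <- w[use]
    # fine circular histogram, then average of the n_shifts coarse histograms
    cell <- floor((ph + pi) / wfine)
    cell[cell >= n_fine] <- n_fine - 1
    fine <- numeric(n_fine)
    agg <- rowsum(wv, cell)
    fine[as.integer(rownames(agg)) + 1] <- agg
    ash <- numeric(n_fine)
    for (s in 0:(n_shifts - 1)) {
      # coarse histogram with bins shifted by s fine cells (circular)
      coarse <- rowsum(c(fine[(s + 1):n_fine], if (s > 0) fine[1:s]),
                       rep(seq_len(n_bins), each = n_shifts))
      # value seen at each fine cell under this shift
      shifted <- rep(coarse[, 1], each = n_shifts)
      shifted <- c(if (s > 0) shifted[(n_fine - s + 1):n_fine], shifted[1:(n_fine - s)])
      ash <- ash + shifted
    }
    b <- -pi + (which.max(ash) - 0.5) * wfine
    # mean-shift refinement about the mode with a triangular kernel over
    # +/- 4 coarse bins (soft edges avoid truncation-boundary noise), run to
    # convergence
    halfwin <- 8 * 2 * pi / n_bins
    for (it in 1:30) {
      res <- wrap_phase(ph - b)
      kw <- wv * pmax(0, 1 - abs(res) / halfwin)
      sw <- sum(kw)
      if (sw <= 0) break
      shift <- sum(kw * res) / sw
      b <- b + shift
      if (abs(shift) < 1e-4) break
    }
    beta[a] <- wrap_phase(b)
    valid[a] <- TRUE
  }
  if (!any(valid)) stopf("bulk_phase_offset: no column has enough masked pixels")
  if (any(!valid)) {
    iv <- which(valid)
    for (a in which(!valid)) beta[a] <- beta[iv[which.min(abs(iv - a))]]
  }
  structure(beta, valid = valid)
}

#' Phase-variance B-scan from a BM-scan stack
#'
#' Computes the phase-variance flow-contrast cross-section from the N
#' repeated complex B-scans of one slow-scanner position. The N-1 wrapped
#' inter-repeat phase-difference frames are corrected for bulk axial motion
#' (per-column shifted-histogram offsets) and the variance is the mean of the
#' squared wrapped corrected differences,
#' `PV = (1/(N-1)) sum_i wrap(dphi_i - beta_i)^2`,
#' which is `pi^2/3` in expectation for fully decorrelated phases and 0 for
#' identical repeats. `center = "circular"` additionally subtracts the
#' per-pixel circular mean of the corrected differences before squaring.
#' Pixels excluded by the noise mask are set to 0.
#'
#' @param stack Complex array `[depth, a_scan, repeat]` (N >= 2).
#' @param mask Logical `[depth, a_scan]` noise mask (TRUE = keep), or NULL.
#' @param correct_bulk Apply bulk-motion correction (default TRUE).
#' @param center `"none"` (default) or `"circular"`.
#' @param n_bins,n_shifts,min_pixels Passed to [bulk_phase_offset()].
#' @return Numeric matrix `[depth, a_scan]` of phase variances in
#'   `[0, pi^2]`, with attribute `beta` (offsets `[a_scan, pair]`).
#' @export
phase_variance <- function(stack, mask = NULL, correct_bulk = TRUE,
                           center = c("none", "circular"),
                           n_bins = 64, n_shifts = 4, min_pixels = 8) {
  center <- match.arg(center)
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2)
    stopf("phase_variance: need a [depth, a_scan, repeat] stack with >= 2 repeats")
  N <- d[3]
  if (N < 3 && center == "circular") {
    message("phase_variance: N < 3; falling back to uncentered squared difference")
    center <- "none"
  }
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  ph <- Arg(stack)
  mag <- Mod(stack)
  w <- mean_over_repeats(mag^2) * mask   # intensity weights (~inverse phase variance)
  npair <- N - 1
  dphis <- array(0, dim = c(d[1], d[2], npair))
  betas <- matrix(0, d[2], npair)
  for (i in seq_len(npair)) {
    dp <- wrap_phase(ph[, , i + 1] - ph[, , i])
    if (correct_bulk) {
      b <- bulk_phase_offset(dp, w, n_bins, n_shifts, min_pixels)
      dp <- wrap_phase(sweep(dp, 2, as.numeric(b)))
      betas[, i] <- as.numeric(b)
    }
    dphis[, , i] <- dp
  }
  if (center == "circular") {
    cm <- atan2(mean_over_repeats(sin(dphis)), mean_over_repeats(cos(dphis)))
    for (i in seq_len(npair)) dphis[, , i] <- wrap_phase(dphis[, , i] - cm)
  }
  pv <- mean_over_repeats(dphis^2)
  pv[!mask] <- 0
  structure(pv, beta = betas)
}

#' Mean-intensity B-scan of a BM-scan stack
#'
#' Pixel-wise mean of the magnitude-squared over the repeats.
#'
#' @param stack Complex (or numeric magnitude) array `[depth, a_scan, repeat]`.
#' @return Numeric matrix `[depth, a_scan]`.
#' @export
mean_intensity <- function(stack) {
  d <- dim(stack)
  if (length(d) == 2) return(Mod(stack)^2)
  mean_over_repeats(Mod(stack)^2)
}

# mean over the 3rd dimension of a [d1, d2, r] array, returned as [d1, d2]
mean_over_repeats <- function(x) {
  d <- dim(x)
  matrix(rowMeans(matrix(x, d[1] * d[2], d[3])), d[1], d[2])
}

#' Compute the angiography volume from reconstructed complex data
#'
#' For every BM-position: mean-intensity B-scan and bulk-motion-corrected
#' phase-variance B-scan, using a global noise threshold estimated from a
#' structure-free depth band.
#'
#' @param cvol A `complex_volume` from [reconstruct_volume()], with `data`
#'   `[depth, a_scan, repeat, position]`.
#' @param kappa Noise threshold multiplier (default 3).
#' @param correct_bulk Apply bulk-motion correction (default TRUE).
#' @param noise_band Depth band for noise estimation (NULL = deepest 10%).
#' @param ... Passed to [phase_variance()].
#' @return Object of class `angio_volume`: `pv` and `intensity` arrays
#'   `[depth, a_scan, position]`, `mask` (same shape), `beta`
#'   `[a_scan, pair, position]`, `noise` stats, `threshold`,
#'   `axial_pitch_um`.
#' @export
compute_angio <- function(cvol, kappa = 3, correct_bulk = TRUE,
                          noise_band = NULL, ...) {
  stopifnot(inherits(cvol, "complex_volume"))
  x <- cvol$data
  d <- dim(x)
  if (length(d) != 4) stopf("compute_angio: expected [depth, a_scan, repeat, position] data")
  noise <- estimate_noise_stats(cvol, band = noise_band)
  thr <- noise$mu + kappa * noise$sigma
  pv <- array(0, dim = d[c(1, 2, 4)])
  it <- array(0, dim = d[c(1, 2, 4)])
  mk <- array(FALSE, dim = d[c(1, 2, 4)])
  beta <- array(0, dim = c(d[2], d[3] - 1, d[4]))
  for (p in seq_len(d[4])) {
    stack <- x[, , , p, drop = FALSE]
    dim(stack) <- d[1:3]
    mi <- mean_intensity(stack)
    m <- sqrt(mi) > thr
    pvb <- phase_variance(stack, mask = m, correct_bulk = correct_bulk, ...)
    pv[, , p] <- pvb
    it[, , p] <- mi
    mk[, , p] <- m
    beta[, , p] <- attr(pvb, "beta")
  }
  structure(list(pv = pv, intensity = it, mask = mk, beta = beta,
                 noise = noise, threshold = thr, kappa = kappa,
                 axial_pitch_um = cvol$axial_pitch_um),
            class = "angio_volume")
}
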