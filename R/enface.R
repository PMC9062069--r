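#' Segment the RPE in mean-intensity B-scans
#'
#' Per A-scan, the RPE depth estimate is the argmax of the axially
#' median-smoothed intensity profile within a posterior search band. The
#' estimate's confidence is the peak prominence (peak minus the band median
#' of the smoothed profile); columns whose prominence falls below an adaptive
#' floor (a fraction of the median prominence across columns) are marked
#' missing, emulating segmentation dropout over atrophic retina.
#'
#' @param intensity Numeric array `[depth, a_scan, position]` of
#'   mean-intensity B-scans (or a single `[depth, a_scan]` matrix).
#' @param band Integer depth range to search (default: full depth).
#' @param smooth Odd median-smoothing window in depth pixels (default 5).
#' @param prominence_frac Missing-column floor as a fraction of the median
#'   prominence (default 0.1).
#' @return List of class `rpe_segmentation`: `depth_px` matrix
#'   `[a_scan, position]` with NA for missing columns, `prominence`,
#'   `missing` (logical matrix).
#' @export
segment_rpe <- function(intensity, band = NULL, smooth = 5,
                        prominence_frac = 0.1) {
  if (length(dim(intensity)) == 2) dim(intensity) <- c(dim(intensity), 1)
  d <- dim(intensity)
  if (is.null(band)) band <- seq_len(d[1])
  depth <- matrix(NA_real_, d[2], d[3])
  prom <- matrix(0, d[2], d[3])
  for (p in seq_len(d[3])) for (a in seq_len(d[2])) {
    prof <- intensity[band, a, p]
    if (length(prof) >= smooth) prof <- stats::runmed(prof, smooth)
    i <- which.max(prof)
    depth[a, p] <- band[i]
    prom[a, p] <- prof[i] - stats::median(prof)
  }
  floor_ <- prominence_frac * stats::median(prom)
  missing <- prom <= floor_
  depth[missing] <- NA_real_
  if (all(missing))
    stopf("segment_rpe: no column shows a distinct posterior peak (featureless volume?)")
  structure(list(depth_px = depth, prominence = prom, missing = missing),
            class = "rpe_segmentation")
}

#' Flatten a volume to a fitted RPE surface
#'
#' Shifts every A-scan axially by an integer number of pixels so the fitted
#' RPE depth maps to a common reference index. Shifts are integer (no axial
#' interpolation), preserving intensity and phase-variance values exactly;
#' samples shifted past the volume edge are zero-filled, not wrapped. The
#' same shift map applies identically to intensity and PV volumes.
#'
#' @param volume Numeric (or complex) array `[depth, a_scan, position]`.
#' @param surface An `rpe_surface` from [fit_zernike()], in depth pixels.
#' @param reference Target depth index for the RPE (default: rounded median
#'   of the fitted surface).
#' @return Array of the same shape; attributes `shift_map`
#'   (`[a_scan, position]`, pixels, = round(fitted) - reference) and
#'   `reference`.
#' @export
flatten_volume <- function(volume, surface, reference = NULL) {
  stopifnot(inherits(surface, "rpe_surface"))
  d <- dim(volume)
  f <- surface$fitted
  reference <- reference %||% round(stats::median(f))
  shift <- round(f) - reference     # positive: structure deeper than reference
  out <- volume
  out[] <- 0
  D <- d[1]
  for (p in seq_len(d[3])) for (a in seq_len(d[2])) {
    s <- shift[a, p]                # shift column up by s pixels
    src <- seq_len(D) + s
    okk <- src >= 1 & src <= D
    out[which(okk), a, p] <- volume[src[okk], a, p]
  }
  attr(out, "shift_map") <- shift
  attr(out, "reference") <- reference
  out
}

#' Undo a flattening shift
#'
#' Inverse of [flatten_volume()] given its recorded shift map; exact away
#' from the zero-filled edges.
#'
#' @param volume Flattened array `[depth, a_scan, position]`.
#' @param shift_map Matrix of per-column shifts from [flatten_volume()].
#' @return Unflattened array.
#' @export
unflatten_volume <- function(volume, shift_map) {
  d <- dim(volume)
  out <- volume
  out[] <- 0
  D <- d[1]
  for (p in seq_len(d[3])) for (a in seq_len(d[2])) {
    s <- -shift_map[a, p]
    src <- seq_len(D) + s
    okk <- src >= 1 & src <= D
    out[which(okk), a, p] <- volume[src[okk], a, p]
  }
  out
}

#' RPE reference index of a flattened volume
#'
#' The global argmax of the volume-mean axial intensity profile ("RPE peak"),
#' used as the depth origin for en face projection windows.
#'
#' @param intensity Array `[depth, a_scan, position]`.
#' @return Integer depth index.
#' @export
rpe_reference_index <- function(intensity) {
  d <- dim(intensity)
  which.max(rowMeans(matrix(intensity, d[1], prod(d[-1]))))
}

#' Depth window for en face projection
#'
#' A square axial summation window placed relative to the RPE peak. Negative
#' offsets are anterior (toward the vitreous, smaller depth index).
#'
#' @param offset_um Signed window-center offset from the RPE peak (um).
#' @param width_um Window width (um).
#' @return Object of class `depth_window`.
#' @export
depth_window <- function(offset_um, width_um) {
  if (width_um <= 0) stopf("depth_window: width must be positive")
  structure(list(offset_um = offset_um, width_um = width_um),
            class = "depth_window")
}

#' Standard en face window presets
#'
#' The three windows used for vascular layer visualization: joint retinal
#' layers (~90 um anterior to the RPE peak, ~138 um wide), choroid 1 /
#' choriocapillaris band (~12 um posterior, ~28-39 um wide) and choroid 2
#' (~127 um posterior, ~120-180 um wide). Ranged widths default to their
#' midpoint; pass `width_um` to override.
#'
#' @param name `"retina"`, `"chrd1"` or `"chrd2"`.
#' @param width_um Optional width override (um).
#' @return A [depth_window()].
#' @export
window_preset <- function(name, width_um = NULL) {
  w <- switch(name,
    retina = depth_window(-90, width_um %||% 138),
    chrd1 = depth_window(12, width_um %||% mean(c(28, 39))),
    chrd2 = depth_window(127, width_um %||% mean(c(120, 180))),
    stopf("unknown window preset '%s'", name))
  w
}

#' Reject motion-corrupted BM-positions
#'
#' A BM-position is rejected when the median phase variance over its masked
#' pixels exceeds `median + c * MAD` of the per-position medians across the
#' volume, flagging saccade-affected rows of uniformly high flow signal.
#'
#' @param angio An `angio_volume` from [compute_angio()].
#' @param c_mad Rejection threshold multiple (default 5).
#' @return List: `kept`, `rejected` (position indices), `score` (per-position
#'   median masked PV), `threshold`.
#' @export
reject_motion_bscans <- function(angio, c_mad = 5) {
  stopifnot(inherits(angio, "angio_volume"))
  P <- dim(angio$pv)[3]
  score <- vapply(seq_len(P), function(p) {
    v <- angio$pv[, , p][angio$mask[, , p]]
    if (!length(v)) 0 else stats::median(v)
  }, numeric(1))
  thr <- stats::median(score) + c_mad * stats::mad(score)
  rejected <- which(score > thr)
  if (length(rejected) > 0.3 * P)
    warnf("reject_motion_bscans: %d of %d BM-positions rejected; volume may be unusable",
          length(rejected), P)
  list(kept = setdiff(seq_len(P), rejected), rejected = rejected,
       score = score, threshold = thr)
}

#' Depth-windowed en face projection
#'
#' Axial summation of a flattened volume over a depth window positioned
#' relative to the RPE reference index. The window covers the half-open
#' interval `[center - width/2, center + width/2)` in micrometres, converted
#' to pixels via the axial pitch. Rejected BM-positions are either dropped
#' (removed rows) or nearest-neighbour filled.
#'
#' @param volume Flattened array `[depth, a_scan, position]` (PV or
#'   intensity).
#' @param window A [depth_window()].
#' @param axial_pitch_um Depth pixel pitch (um).
#' @param rpe_index RPE reference depth index (e.g.
#'   [rpe_reference_index()] of the flattened intensity).
#' @param rejected Integer positions to exclude.
#' @param fill `"neighbor"` (default) replaces rejected rows by the nearest
#'   kept row; `"drop"` removes them.
#' @return Object of class `enface_projection`: `image`
#'   (`[a_scan, position]`), `window`, `depth_range_px`, `rejected`, `fill`.
#' @export
enface_projection <- function(volume, window, axial_pitch_um, rpe_index,
                              rejected = integer(0),
                              fill = c("neighbor", "drop")) {
  stopifnot(inherits(window, "depth_window"))
  fill <- match.arg(fill)
  d <- dim(volume)
  center <- rpe_index + window$offset_um / axial_pitch_um
  half <- window$width_um / 2 / axial_pitch_um
  lo <- ceiling(center - half)
  hi <- ceiling(center + half) - 1   # half-open [center-half, center+half)
  lo <- max(1L, lo); hi <- min(d[1], hi)
  if (hi < lo)
    stopf("enface_projection: window [%g, %g] um does not intersect the volume",
          window$offset_um - window$width_um / 2, window$offset_um + window$width_um / 2)
  img <- matrix(colSums(matrix(volume[lo:hi, , ], hi - lo + 1L, d[2] * d[3])),
                d[2], d[3])
  if (length(rejected)) {
    kept <- setdiff(seq_len(d[3]), rejected)
    if (!length(kept)) stopf("enface_projection: all positions rejected")
    if (fill == "drop") {
      img <- img[, kept, drop = FALSE]
    } else {
      for (p in rejected) img[, p] <- img[, kept[which.min(abs(kept - p))]]
    }
  }
  structure(list(image = img, window = window,
                 depth_range_px = c(lo, hi), rejected = rejected, fill = fill),
            class = "enface_projection")
}

#' Median + Gaussian filtering of an en face projection
#'
#' Residual-noise removal: a 2-D median filter followed by a Gaussian blur,
#' in that order.
#'
#' @param image Numeric matrix (or `enface_projection`).
#' @param median_radius Median filter radius in pixels (default 1, i.e. 3x3).
#' @param gaussian_sigma Gaussian blur SD in pixels (default 1).
#' @return Filtered matrix (or projection with filtered image and a
#'   `filters` provenance field).
#' @export
filter_projection <- function(image, median_radius = 1, gaussian_sigma = 1) {
  proj <- NULL
  if (inherits(image, "enface_projection")) {
    proj <- image
    image <- image$image
  }
  out <- image
  if (median_radius > 0) {
    rng <- range(out)
    if (diff(rng) > 0) {
      # EBImage's constant-time median works on [0, 1]-scaled data
      sc <- (out - rng[1]) / diff(rng)
      sc <- EBImage::medianFilter(sc, median_radius)
      out <- sc * diff(rng) + rng[1]
    }
  }
  if (gaussian_sigma > 0) {
    sz <- 2 * ceiling(3 * gaussian_sigma) + 1
    brush <- EBImage::makeBrush(sz, shape = "Gaussian", sigma = gaussian_sigma)
    out <- EBImage::filter2(out, brush, boundary = "replicate")
  }
  out <- matrix(as.numeric(out), nrow(image), ncol(image))
  if (!is.null(proj)) {
    proj$image <- out
    proj$filters <- list(median_radius = median_radius,
                         gaussian_sigma = gaussian_sigma)
    return(proj)
  }
  out
}

#' Mosaic en face projections by translation registration
#'
#' Registers each tile to the running mosaic by normalized cross-correlation
#' over integer shifts around its nominal offset, then blends overlaps with
#' linear feathering (weights ramping from the tile edges).
#'
#' @param tiles List of numeric matrices (>= 2).
#' @param offsets Matrix `n x 2` of nominal (row, col) offsets of each tile's
#'   upper-left corner (first tile at `c(0, 0)`).
#' @param search Integer search radius around the nominal offset (default 10).
#' @param min_corr Correlation floor below which the nominal offset is used
#'   with a warning (default 0.3).
#' @return List: `image` (blended mosaic), `offsets` (refined, n x 2).
#' @export
mosaic <- function(tiles, offsets, search = 10, min_corr = 0.3) {
  stopifnot(length(tiles) >= 2, nrow(offsets) == length(tiles))
  refined <- offsets
  for (i in 2:length(tiles)) {
    best <- register_translation(tiles[[1]], tiles[[i]], offsets[i, ], search)
    if (best$corr < min_corr) {
      warnf("mosaic: weak correlation (%.2f) for tile %d; using nominal offset",
            best$corr, i)
      refined[i, ] <- offsets[i, ]
    } else refined[i, ] <- best$offset
  }
  blend_tiles(tiles, refined)
}

register_translation <- function(ref, tile, nominal, search) {
  best <- list(corr = -Inf, offset = nominal)
  for (dr in -search:search) for (dc in -search:search) {
    off <- nominal + c(dr, dc)
    ov <- overlap_region(dim(ref), dim(tile), off)
    if (is.null(ov) || prod(ov$n) < 0.1 * length(tile)) next
    a <- ref[ov$r1, ov$c1]
    b <- tile[ov$r2, ov$c2]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    cc <- stats::cor(as.vector(a), as.vector(b))
    if (cc > best$corr) best <- list(corr = cc, offset = off)
  }
  best
}

overlap_region <- function(dref, dtile, off) {
  r0 <- max(1, 1 + off[1]); r1 <- min(dref[1], dtile[1] + off[1])
  c0 <- max(1, 1 + off[2]); c1 <- min(dref[2], dtile[2] + off[2])
  if (r1 < r0 || c1 < c0) return(NULL)
  list(r1 = r0:r1, c1 = c0:c1, r2 = (r0:r1) - off[1], c2 = (c0:c1) - off[2],
       n = c(r1 - r0 + 1, c1 - c0 + 1))
}

blend_tiles <- function(tiles, offsets) {
  lo <- apply(offsets, 2, min)
  hi <- sapply(seq_along(tiles), function(i) offsets[i, ] + dim(tiles[[i]]))
  sz <- apply(hi, 1, max) - lo
  acc <- matrix(0, sz[1], sz[2])
  wacc <- matrix(0, sz[1], sz[2])
  for (i in seq_along(tiles)) {
    t_ <- tiles[[i]]
    d <- dim(t_)
    # feather weight: linear ramp from each edge
    wr <- pmin(seq_len(d[1]), rev(seq_len(d[1])))
    wc <- pmin(seq_len(d[2]), rev(seq_len(d[2])))
    w <- outer(wr, wc, pmin)
    rr <- (offsets[i, 1] - lo[1]) + seq_len(d[1])
    cc <- (offsets[i, 2] - lo[2]) + seq_len(d[2])
    acc[rr, cc] <- acc[rr, cc] + w * t_
    wacc[rr, cc] <- wacc[rr, cc] + w
  }
  img <- acc
  nz <- wacc > 0
  img[nz] <- acc[nz] / wacc[nz]
  list(image = img, offsets = offsets)
}
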