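test_that("Zernike fitting recovers generating surfaces", {
  # constant depth map: only the piston term
  cst <- matrix(37.5, 24, 24)
  f <- fit_zernike(cst)
  expect_lt(max(abs(f$coefficients[-1])), 1e-6)
  expect_equal(max(abs(f$fitted - 37.5)), 0, tolerance = 1e-8)

  # paraboloid forward-generated from a known defocus coefficient
  A <- 32; P <- 32
  xi <- seq(-1, 1, length.out = A); yi <- seq(-1, 1, length.out = P)
  G <- expand.grid(X = xi, Y = yi)
  B <- zernike_basis(G$X, G$Y, order = 4)
  nm <- attr(B, "nm")
  j_def <- which(nm[, "n"] == 2 & nm[, "m"] == 0)
  c_true <- numeric(ncol(B)); c_true[1] <- 200; c_true[j_def] <- 12
  depth <- matrix(B %*% c_true, A, P)
  fit <- fit_zernike(depth)
  expect_lt(abs(fit$coefficients[j_def] / 12 - 1), 0.01)
  expect_lt(fit$residual_rms, 0.1)

  # 5% gross outliers: fitted map still within 0.5 pixel of the truth
  set.seed(33)
  noisy <- depth + matrix(stats::rnorm(A * P, 0, 0.1), A, P)
  idx <- sample(A * P, round(0.05 * A * P))
  noisy[idx] <- noisy[idx] + stats::runif(length(idx), 40, 80)
  fit2 <- fit_zernike(noisy)
  expect_lt(max(abs(fit2$fitted - depth)), 0.5)

  # too few points: order reduced with a warning
  sparse <- matrix(NA_real_, 24, 24)
  sparse[1:10] <- 100
  expect_warning(fit_zernike(sparse, order = 4), "reducing order")
})

test_that("RPE segmentation finds a delta-thin bright surface to pixel accuracy", {
  r <- curved_rpe_run()
  seg <- segment_rpe(r$intensity)
  truth_px <- r$raw$truth$rpe_depth_um / r$cv$axial_pitch_um + 1
  err <- abs(seg$depth_px - truth_px)
  expect_gte(mean(err <= 2, na.rm = TRUE), 0.95)

  # featureless volume: every column missing, error raised
  expect_error(segment_rpe(array(1, dim = c(64, 8, 4))), "featureless")

  # zeroed columns (simulated atrophy) flagged missing, not fitted
  intens <- r$intensity
  drop_cols <- seq(1, 32, by = 10)
  intens[, drop_cols, 2] <- 0
  seg2 <- segment_rpe(intens)
  expect_true(all(seg2$missing[drop_cols, 2]))
  expect_true(all(is.na(seg2$depth_px[drop_cols, 2])))
})

test_that("flattening aligns the RPE and round-trips exactly", {
  r <- curved_rpe_run()
  seg <- segment_rpe(r$intensity)
  surf <- fit_zernike(seg$depth_px)
  flat <- flatten_volume(r$intensity, surf)
  expect_identical(attr(flat, "shift_map"),
                   round(surf$fitted) - attr(flat, "reference"))
  seg2 <- segment_rpe(flat)
  expect_lt(stats::sd(seg2$depth_px, na.rm = TRUE), 1)

  # already-flat surface: identity
  flat_surf <- fit_zernike(matrix(200, 32, 32))
  same <- flatten_volume(r$intensity, flat_surf, reference = 200)
  expect_equal(as.numeric(same), as.numeric(r$intensity))

  # round trip: exact away from the zero-filled edges
  back <- unflatten_volume(flat, attr(flat, "shift_map"))
  sm <- attr(flat, "shift_map")
  D <- dim(r$intensity)[1]
  for (p in c(1, 16, 32)) for (a in c(1, 16, 32)) {
    s <- abs(sm[a, p])
    keep <- (s + 1):(D - s)
    expect_identical(back[keep, a, p], r$intensity[keep, a, p])
  }
})

test_that("motion-corrupted BM-positions are rejected exactly", {
  # all-static synthetic volume with one fully decorrelated frame
  set.seed(35)
  P <- 40
  pv <- array(stats::rexp(200 * 8 * P, rate = 50), dim = c(200, 8, P))
  pv[, , 23] <- stats::runif(200 * 8, 0, pi^2 / 2)
  an <- structure(list(pv = pv, mask = array(TRUE, dim(pv))),
                  class = "angio_volume")
  rej <- reject_motion_bscans(an)
  expect_identical(rej$rejected, 23L)

  # no-saccade phantom: zero rejections
  r <- retina_run()
  expect_identical(length(reject_motion_bscans(r$an)$rejected), 0L)

  # injected saccades: exactly those positions rejected
  s <- saccade_run()
  expect_identical(reject_motion_bscans(s$an)$rejected, c(12L, 30L, 47L))
})

test_that("depth windows parse, convert with pitch, and project correctly", {
  w <- window_preset("retina")
  expect_equal(c(w$offset_um, w$width_um), c(-90, 138))
  expect_equal(window_preset("chrd1")$offset_um, 12)
  expect_equal(window_preset("chrd1")$width_um, 33.5)
  expect_equal(window_preset("chrd2")$offset_um, 127)
  expect_equal(window_preset("chrd2")$width_um, 150)
  expect_error(depth_window(0, 0), "positive")

  # pixel conversion scales inversely with the axial pitch
  vol <- array(1, dim = c(400, 4, 4))
  p1 <- enface_projection(vol, w, axial_pitch_um = 1, rpe_index = 350)
  p2 <- enface_projection(vol, w, axial_pitch_um = 0.5, rpe_index = 350)
  n1 <- diff(p1$depth_range_px) + 1
  n2 <- diff(p2$depth_range_px) + 1
  expect_equal(n2 / n1, 2, tolerance = 0.02)

  # projection is linear and window tiling conserves the axial sum
  set.seed(36)
  va <- array(stats::runif(400 * 4 * 4), dim = c(400, 4, 4))
  vb <- array(stats::runif(400 * 4 * 4), dim = c(400, 4, 4))
  wq <- depth_window(0, 40)
  expect_equal(enface_projection(va + vb, wq, 1, 200)$image,
               enface_projection(va, wq, 1, 200)$image +
                 enface_projection(vb, wq, 1, 200)$image)
  tiles <- lapply(0:9, function(i) depth_window(-200 + 40 * i + 20, 40))
  tiled <- Reduce(`+`, lapply(tiles, function(ww)
    enface_projection(va, ww, 1, 201)$image))
  expect_equal(tiled, apply(va, c(2, 3), sum))

  # out-of-range window errors
  expect_error(enface_projection(va, depth_window(5000, 10), 1, 200),
               "does not intersect")
})

test_that("retina-window projection of the flattened PV recovers vessels", {
  r <- retina_run()
  an <- r$an
  seg <- segment_rpe(an$intensity)
  surf <- fit_zernike(seg$depth_px)
  flat_pv <- flatten_volume(an$pv, surf)
  flat_i <- flatten_volume(an$intensity, surf)
  ref <- rpe_reference_index(flat_i)
  pr <- enface_projection(flat_pv, window_preset("retina"),
                          an$axial_pitch_um, ref)
  prf <- filter_projection(pr)
  fp <- r$raw$truth$vessel_footprint
  expect_gt(mean(prf$image[fp]) / mean(prf$image[!fp]), 5)
})

test_that("median-then-Gaussian filtering behaves like the direct kernels", {
  cst <- matrix(4.2, 32, 32)
  expect_equal(filter_projection(cst), cst, tolerance = 1e-6)

  # single hot pixel removed by the 3x3 median
  hot <- matrix(0, 32, 32); hot[16, 16] <- 100
  med_only <- filter_projection(hot, median_radius = 1, gaussian_sigma = 0)
  expect_lt(max(med_only), 1e-6 * 100)

  # Gaussian of a delta matches the discrete kernel exactly
  delta <- matrix(0, 33, 33); delta[17, 17] <- 1
  g <- filter_projection(delta, median_radius = 0, gaussian_sigma = 1)
  brush <- EBImage::makeBrush(7, shape = "Gaussian", sigma = 1)
  ctr <- 17 + seq(-3, 3)
  expect_equal(g[ctr, ctr], matrix(brush, 7, 7), tolerance = 1e-6)
  expect_equal(max(g), max(brush), tolerance = 1e-6)
})

test_that("mosaicking registers and feather-blends tiles", {
  set.seed(37)
  base <- matrix(stats::runif(80 * 80), 80, 80)
  base <- filter_projection(base, median_radius = 0, gaussian_sigma = 2)

  # identical tiles at zero offset: output equals the tile
  m0 <- mosaic(list(base, base), rbind(c(0, 0), c(0, 0)), search = 3)
  expect_equal(m0$image, base, tolerance = 1e-10)

  # known 20-px shift recovered within 1 px from a perturbed nominal offset
  tile2 <- base[21:80, ]
  m1 <- mosaic(list(base, tile2), rbind(c(0, 0), c(17, 0)), search = 6)
  expect_lte(max(abs(m1$offsets[2, ] - c(20, 0))), 1)

  # blended overlap of two constant tiles stays constant
  c1 <- matrix(3, 40, 40); c2 <- matrix(3, 40, 40)
  mb <- pvocta:::blend_tiles(list(c1, c2), rbind(c(0, 0), c(15, 0)))
  expect_true(all(abs(mb$image[mb$image != 0] - 3) < 1e-12))
})
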