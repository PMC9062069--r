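#' Zernike polynomial basis over the inscribed unit disk
#'
#' Evaluates the OSA/ANSI-ordered Zernike polynomials up to radial order R at
#' given normalized coordinates. The radial polynomials are ordinary
#' polynomials, so points outside the unit disk (the corners of a square scan
#' field) are evaluated by natural polynomial extrapolation.
#'
#' @param X,Y Numeric vectors of lateral coordinates normalized so that the
#'   inscribed disk is `X^2 + Y^2 <= 1`.
#' @param order Maximum radial order R; the basis has `(R+1)(R+2)/2` terms.
#' @return Matrix `length(X) x n_terms`; attribute `nm` gives the `(n, m)`
#'   index pairs.
#' @export
zernike_basis <- function(X, Y, order = 4) {
  rho <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  nm <- list()
  cols <- list()
  for (n in 0:order) for (m in seq(-n, n, by = 2)) {
    R <- zernike_radial(n, abs(m), rho)
    norm <- sqrt(2 * (n + 1) / (1 + (m == 0)))
    z <- if (m > 0) norm * R * cos(m * th)
         else if (m < 0) norm * R * sin(-m * th)
         else norm * R
    cols[[length(cols) + 1]] <- z
    nm[[length(nm) + 1]] <- c(n = n, m = m)
  }
  B <- do.call(cbind, cols)
  attr(B, "nm") <- do.call(rbind, nm)
  B
}

zernike_radial <- function(n, m, rho) {
  out <- numeric(length(rho))
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  out
}

#' Fit a smooth Zernike surface to raw RPE depth estimates
#'
#' Least squares on the Zernike basis over the inscribed unit disk of the
#' scan field, with one round of outlier rejection at 3x the residual MAD
#' followed by a refit. Missing estimates (NA) are excluded.
#'
#' @param depth Matrix `[a_scan, position]` of raw depth estimates (pixels);
#'   NA marks columns where segmentation failed.
#' @param order Maximum Zernike radial order (default 4, 15 terms).
#' @param mad_mult Outlier rejection multiple of the residual MAD (default 3).
#' @return Object of class `rpe_surface`: `fitted` (full smooth map, same
#'   shape), `coefficients` (named by "Z n,m"), `order`, `outliers` (logical
#'   matrix), `residual_rms` (inliers), `raw`.
#' @export
fit_zernike <- function(depth, order = 4, mad_mult = 3) {
  A <- nrow(depth); P <- ncol(depth)
  n_terms <- (order + 1) * (order + 2) / 2
  xi <- if (A > 1) seq(-1, 1, length.out = A) else 0
  yi <- if (P > 1) seq(-1, 1, length.out = P) else 0
  G <- expand.grid(X = xi, Y = yi)
  B <- zernike_basis(G$X, G$Y, order)
  v <- as.vector(depth)
  ok <- is.finite(v)
  if (sum(ok) < n_terms) {
    if (sum(ok) >= 3) {
      order <- max(0, floor((sqrt(8 * sum(ok) + 1) - 3) / 2) - 1)
      warnf("fit_zernike: too few valid points; reducing order to %d", order)
      return(fit_zernike(depth, order = order, mad_mult = mad_mult))
    }
    stopf("fit_zernike: only %d valid depth estimates for %d terms", sum(ok), n_terms)
  }
  fit1 <- stats::lm.fit(B[ok, , drop = FALSE], v[ok])
  res <- fit1$residuals
  s <- stats::mad(res)
  out <- if (s > 0) abs(res) > mad_mult * s else rep(FALSE, length(res))
  keep <- which(ok)[!out]
  fit2 <- stats::lm.fit(B[keep, , drop = FALSE], v[keep])
  cf <- fit2$coefficients
  cf[is.na(cf)] <- 0
  fitted <- matrix(B %*% cf, A, P)
  outliers <- matrix(FALSE, A, P)
  outliers[which(ok)[out]] <- TRUE
  nm <- attr(B, "nm")
  names(cf) <- sprintf("Z%d,%d", nm[, 1], nm[, 2])
  structure(list(fitted = fitted, coefficients = cf, order = order,
                 outliers = outliers,
                 residual_rms = sqrt(mean(fit2$residuals^2)),
                 raw = depth),
            class = "rpe_surface")
}
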