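#' Spatial receptive-field model of a simple cell
#'
#' A scale-normalized m-th order directional derivative of an affine
#' Gaussian kernel,
#' \deqn{T(x_1, x_2) = \sigma_1^m \, \partial_\varphi^m \,
#'       g(x_1, x_2; \Sigma_\varphi),}
#' with the directional derivative
#' \eqn{\partial_\varphi = \cos\varphi\,\partial_{x_1} +
#' \sin\varphi\,\partial_{x_2}} taken along the preferred direction
#' \eqn{\varphi}, which is also the eigendirection of \eqn{\Sigma_\varphi}
#' with eigenvalue \eqn{\sigma_1^2}.  The normalization factor
#' \eqn{\sigma_1^m} makes response magnitudes comparable across scales.
#' Order 0 is the plain affine Gaussian.
#'
#' @param shape An [rf_shape()].
#' @param order_m Integer derivative order, 0 to 4.
#' @return An object of class `spatial_rf`.
#' @export
spatial_rf <- function(shape, order_m = 1L) {
  stopifnot(inherits(shape, "rf_shape"))
  if (!is.numeric(order_m) || length(order_m) != 1L ||
      order_m != round(order_m) || order_m < 0)
    stop("'order_m' must be a non-negative integer", call. = FALSE)
  if (order_m > 4)
    stop("derivative orders above 4 are not supported", call. = FALSE)
  structure(list(shape = shape, order_m = as.integer(order_m)),
            class = "spatial_rf")
}

#' @export
print.spatial_rf <- function(x, ...) {
  cat(sprintf("spatial_rf: order m = %d, sigma1 = %g, sigma2 = %g, phi = %g rad\n",
              x$order_m, x$shape$sigma1, x$shape$sigma2, x$shape$phi))
  invisible(x)
}

#' Spatio-temporal receptive-field model of a simple cell
#'
#' Extends [spatial_rf()] with a temporal Gaussian of standard deviation
#' `sigma_t`, a preferred image velocity `v` parallel to the spatial
#' preferred direction, and an n-th order velocity-adapted temporal
#' derivative \eqn{\partial_{\bar t} = \partial_t + v_1 \partial_{x_1} +
#' v_2 \partial_{x_2}}, scale-normalized by \eqn{\sigma_t^n}:
#' \deqn{T(x_1, x_2, t) = \sigma_1^m \sigma_t^n \, \partial_\varphi^m
#'   \partial_{\bar t}^n \left( g(x_1 - v_1 t, x_2 - v_2 t; \Sigma_\varphi)
#'   \, h(t; \sigma_t) \right).}
#'
#' @param spatial A [spatial_rf()] giving the spatial component.
#' @param sigma_t Temporal standard deviation, `> 0`.
#' @param speed Scalar speed; the velocity vector is
#'   `speed * (cos(phi), sin(phi))`, parallel to the preferred direction.
#' @param order_n Non-negative integer temporal derivative order.
#' @return An object of class `spatiotemporal_rf`.
#' @export
spatiotemporal_rf <- function(spatial, sigma_t, speed = 0, order_n = 0L) {
  stopifnot(inherits(spatial, "spatial_rf"))
  if (!is.finite(sigma_t) || sigma_t <= 0)
    stop("'sigma_t' must be positive", call. = FALSE)
  if (!is.numeric(order_n) || order_n != round(order_n) || order_n < 0)
    stop("'order_n' must be a non-negative integer", call. = FALSE)
  if (order_n > 4)
    stop("temporal derivative orders above 4 are not supported", call. = FALSE)
  phi <- spatial$shape$phi
  structure(list(spatial = spatial, sigma_t = sigma_t,
                 velocity = speed * c(cos(phi), sin(phi)),
                 speed = speed, order_n = as.integer(order_n)),
            class = "spatiotemporal_rf")
}

# Analytic scale-normalized directional-derivative kernel, vectorized over
# coordinates.  In coordinates rotated by phi the affine Gaussian separates,
# so the m-th directional derivative is a Hermite polynomial along the
# preferred axis times the Gaussian:
#   sigma1^m d^m/dxi^m g = (-1)^m He_m(xi / sigma1) g(x; Sigma).
eval_spatial_kernel <- function(rf, x1, x2) {
  sh <- rf$shape
  m <- rf$order_m
  xi <- cos(sh$phi) * x1 + sin(sh$phi) * x2
  g <- affine_gaussian(x1, x2, make_covariance(sh))
  (-1)^m * hermite_he(m, xi / sh$sigma1) * g
}

# Default cell-centered sampling grid for a shape: symmetric about the
# origin, extent +/- 4 max(sigma1, sigma2), step sigma1 / 8.
default_grid <- function(shape, step = NULL, extent = NULL) {
  if (is.null(step)) step <- shape$sigma1 / 8
  if (is.null(extent)) extent <- 4 * max(shape$sigma1, shape$sigma2)
  if (step <= 0 || extent <= 0)
    stop("'step' and 'extent' must be positive", call. = FALSE)
  n_half <- ceiling(extent / step)
  list(x = step * seq(-n_half, n_half), step = step)
}

#' Sample a spatial receptive field on a grid
#'
#' Evaluates the analytic kernel (Hermite polynomial times Gaussian; no
#' finite differencing) on a cell-centered grid with the origin at the grid
#' center.
#'
#' @param rf A [spatial_rf()].
#' @param step Grid step; default `sigma1 / 8`.  A step coarser than
#'   `sigma1 / 4` triggers a warning.
#' @param extent Half-width of the grid; default
#'   `4 * max(sigma1, sigma2)`.
#' @return A list with fields `x1`, `x2` (coordinate vectors), `z` (matrix
#'   of kernel values, `z[i, j]` at `(x1[i], x2[j])`), `step`, and `rf`.
#' @export
sample_spatial_rf <- function(rf, step = NULL, extent = NULL) {
  stopifnot(inherits(rf, "spatial_rf"))
  g <- default_grid(rf$shape, step, extent)
  if (g$step > rf$shape$sigma1 / 4 + 1e-12)
    warning("grid step exceeds sigma1 / 4; sampled kernel may be inaccurate",
            call. = FALSE)
  x <- g$x
  z <- outer(x, x, function(a, b) eval_spatial_kernel(rf, a, b))
  list(x1 = x, x2 = x, z = z, step = g$step, rf = rf)
}

#' Sample a spatio-temporal receptive field on a space-time grid
#'
#' The velocity-adapted temporal derivative acts only on the temporal
#' Gaussian once the spatial argument moves with the kernel velocity
#' (\eqn{\partial_{\bar t}} annihilates the moving spatial factor), so the
#' sampled kernel is the spatial derivative kernel evaluated at
#' `(x1 - v1 t, x2 - v2 t)` times the scale-normalized n-th temporal
#' Gaussian derivative.
#'
#' @param rf A [spatiotemporal_rf()].
#' @param step,extent Spatial grid controls as in [sample_spatial_rf()].
#' @param t_step Temporal step; default `sigma_t / 8`.
#' @param t_extent Temporal half-width; default `4 * sigma_t`.
#' @return A list with fields `x1`, `x2`, `t`, `z` (3-d array indexed
#'   `[x1, x2, t]`), `step`, `t_step`, and `rf`.
#' @export
sample_spatiotemporal_rf <- function(rf, step = NULL, extent = NULL,
                                     t_step = NULL, t_extent = NULL) {
  stopifnot(inherits(rf, "spatiotemporal_rf"))
  sp <- rf$spatial
  g <- default_grid(sp$shape, step, extent)
  if (is.null(t_step)) t_step <- rf$sigma_t / 8
  if (is.null(t_extent)) t_extent <- 4 * rf$sigma_t
  nt <- ceiling(t_extent / t_step)
  tt <- t_step * seq(-nt, nt)
  x <- g$x
  n <- length(x)
  z <- array(0, dim = c(n, n, length(tt)))
  v <- rf$velocity
  temporal <- (-1)^rf$order_n *
    hermite_he(rf$order_n, tt / rf$sigma_t) * stats::dnorm(tt, sd = rf$sigma_t)
  for (k in seq_along(tt)) {
    z[, , k] <- outer(x, x, function(a, b)
      eval_spatial_kernel(sp, a - v[1] * tt[k], b - v[2] * tt[k])) * temporal[k]
  }
  list(x1 = x, x2 = x, t = tt, z = z, step = g$step, t_step = t_step, rf = rf)
}

# 2-d circular convolution via FFT of two same-sized grids; `ker` is
# centered on the grid and shifted so its origin lands at index [1, 1].
conv2_fft <- function(f, ker, step) {
  n <- nrow(f)
  stopifnot(ncol(f) == n, all(dim(ker) == c(n, n)), n %% 2L == 1L)
  ic <- (n + 1L) %/% 2L  # index of the origin sample (odd n, centered grid)
  # circular shift putting the kernel origin first
  ord <- c(ic:n, seq_len(ic - 1L))
  ks <- ker[ord, ord]
  Re(stats::fft(stats::fft(f) * stats::fft(ks), inverse = TRUE)) / n^2 * step^2
}

# Bilinear interpolation of a grid z (z[i, j] at (x[i], y[j])) at query
# points (xq, yq); NA outside the grid.
interp2 <- function(x, y, z, xq, yq) {
  nx <- length(x); ny <- length(y)
  dx <- x[2] - x[1]; dy <- y[2] - y[1]
  fi <- (xq - x[1]) / dx; fj <- (yq - y[1]) / dy
  i <- floor(fi); j <- floor(fj)
  ok <- i >= 0 & i <= nx - 2 & j >= 0 & j <= ny - 2
  out <- rep(NA_real_, length(xq))
  i1 <- pmin(pmax(i[ok], 0), nx - 2); j1 <- pmin(pmax(j[ok], 0), ny - 2)
  u <- fi[ok] - i1; v <- fj[ok] - j1
  idx <- cbind(i1 + 1L, j1 + 1L)
  out[ok] <- (1 - u) * (1 - v) * z[idx] +
    u * (1 - v) * z[idx + matrix(c(1L, 0L), nrow(idx), 2, byrow = TRUE)] +
    (1 - u) * v * z[idx + matrix(c(0L, 1L), nrow(idx), 2, byrow = TRUE)] +
    u * v * z[idx + matrix(c(1L, 1L), nrow(idx), 2, byrow = TRUE)]
  out
}

#' Numerical test of affine covariance of the Gaussian smoothing family
#'
#' For a non-singular matrix `A`, affine covariance states that smoothing
#' the affinely warped image with the transformed covariance
#' \eqn{A \Sigma A^T} equals warping the result of smoothing the original
#' image with \eqn{\Sigma}.  This routine checks the identity numerically on
#' a sampled Gaussian-blob test image: both paths are computed by discrete
#' FFT convolution, the warp on the output side by bilinear interpolation,
#' and the maximum absolute discrepancy (relative to the peak of the
#' reference path) over the interior of the grid is returned.
#'
#' @param cov 2x2 covariance of the smoothing kernel applied to the
#'   original image.
#' @param A Non-singular 2x2 matrix.
#' @param blob_sigma Standard deviation of the isotropic Gaussian test
#'   image (default 1.5).
#' @param n Grid points per axis (odd; default 281).
#' @param L Grid half-width (default 14).
#' @return Maximum relative discrepancy (a single number).
#' @export
check_affine_covariance <- function(cov, A, blob_sigma = 1.5, n = 281L, L = 14) {
  check_covariance(cov)
  if (!is.matrix(A) || !all(dim(A) == c(2L, 2L)) || abs(det(A)) < 1e-12)
    stop("'A' must be a non-singular 2x2 matrix", call. = FALSE)
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(-L, L, length.out = n)
  step <- x[2] - x[1]
  Ainv <- solve(A)
  blob <- function(x1, x2) affine_gaussian(x1, x2, diag(blob_sigma^2, 2))

  # path 1: warp the image, then smooth with the transformed covariance
  fw <- outer(x, x, function(a, b)
    blob(Ainv[1, 1] * a + Ainv[1, 2] * b, Ainv[2, 1] * a + Ainv[2, 2] * b))
  covA <- A %*% cov %*% t(A)
  kerA <- outer(x, x, function(a, b) affine_gaussian(a, b, covA))
  path1 <- conv2_fft(fw, kerA, step)

  # path 2: smooth the original with cov, then warp the output
  f0 <- outer(x, x, blob)
  ker <- outer(x, x, function(a, b) affine_gaussian(a, b, cov))
  sm <- conv2_fft(f0, ker, step)
  gq <- expand.grid(x1 = x, x2 = x)
  xq <- Ainv[1, 1] * gq$x1 + Ainv[1, 2] * gq$x2
  yq <- Ainv[2, 1] * gq$x1 + Ainv[2, 2] * gq$x2
  path2 <- matrix(interp2(x, x, sm, xq, yq), n, n)

  # compare away from the border, where both paths are supported
  m <- ceiling(n / 8)
  idx <- (m + 1):(n - m)
  d <- abs(path1[idx, idx] - path2[idx, idx])
  max(d, na.rm = TRUE) / max(abs(path1), na.rm = TRUE)
}
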