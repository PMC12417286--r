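#' Receptive-field shape
#'
#' An anisotropic Gaussian receptive-field shape, described by the standard
#' deviation `sigma1` along the preferred direction `phi`, the standard
#' deviation `sigma2` orthogonal to it, and the preferred orientation `phi`
#' itself (radians).  The scale-parameter ratio `kappa = sigma2 / sigma1`
#' measures the elongation of the field orthogonal to its preferred
#' direction; the eccentricity `epsilon = 1 / kappa` equals 1 for an
#' isotropic field and tends to 0 as the field becomes more elongated.
#'
#' @param sigma1 Standard deviation along the preferred direction; `> 0`.
#' @param sigma2 Standard deviation orthogonal to the preferred direction;
#'   `> 0`.
#' @param phi Preferred orientation in radians.
#' @return An object of class `rf_shape` with fields `sigma1`, `sigma2`,
#'   `phi`, `kappa` and `eccentricity`.
#' @examples
#' sh <- rf_shape(1, 2, 0)
#' sh$kappa        # 2
#' sh$eccentricity # 0.5
#' @export
rf_shape <- function(sigma1, sigma2, phi = 0) {
  stopifnot(is.numeric(sigma1), is.numeric(sigma2), is.numeric(phi),
            length(sigma1) == 1L, length(sigma2) == 1L, length(phi) == 1L)
  if (!is.finite(sigma1) || sigma1 <= 0 || !is.finite(sigma2) || sigma2 <= 0)
    stop("scale parameters 'sigma1' and 'sigma2' must be positive", call. = FALSE)
  structure(
    list(sigma1 = sigma1, sigma2 = sigma2, phi = phi,
         kappa = sigma2 / sigma1, eccentricity = sigma1 / sigma2),
    class = "rf_shape")
}

#' @export
print.rf_shape <- function(x, ...) {
  cat(sprintf("rf_shape: sigma1 = %g, sigma2 = %g, phi = %g rad (kappa = %g, eccentricity = %g)\n",
              x$sigma1, x$sigma2, x$phi, x$kappa, x$eccentricity))
  invisible(x)
}

#' Spatial covariance matrix of an anisotropic Gaussian
#'
#' Builds the symmetric positive-definite 2x2 covariance matrix whose
#' eigenvalues are `sigma1^2` and `sigma2^2`, with the `sigma1^2`
#' eigenvector along the direction `phi`:
#' \deqn{C_{11} = \sigma_1^2 \cos^2\varphi + \sigma_2^2 \sin^2\varphi,\quad
#'       C_{12} = (\sigma_1^2 - \sigma_2^2)\cos\varphi\sin\varphi,\quad
#'       C_{22} = \sigma_1^2 \sin^2\varphi + \sigma_2^2 \cos^2\varphi.}
#'
#' @param sigma1,sigma2 Positive standard deviations (along / orthogonal to
#'   `phi`).
#' @param phi Orientation in radians.
#' @return A 2x2 numeric matrix.
#' @examples
#' make_covariance(1, 2, 0)      # diag(1, 4)
#' make_covariance(1, 2, pi / 2) # diag(4, 1)
#' @export
make_covariance <- function(sigma1, sigma2, phi = 0) {
  if (inherits(sigma1, "rf_shape")) {
    sh <- sigma1
    sigma1 <- sh$sigma1; sigma2 <- sh$sigma2; phi <- sh$phi
  }
  if (!is.finite(sigma1) || sigma1 <= 0 || !is.finite(sigma2) || sigma2 <= 0)
    stop("scale parameters 'sigma1' and 'sigma2' must be positive", call. = FALSE)
  c2 <- cos(phi)^2; s2 <- sin(phi)^2; cs <- cos(phi) * sin(phi)
  v1 <- sigma1^2; v2 <- sigma2^2
  matrix(c(v1 * c2 + v2 * s2, (v1 - v2) * cs,
           (v1 - v2) * cs,    v1 * s2 + v2 * c2),
         nrow = 2L, byrow = TRUE)
}

# Validate a covariance matrix: symmetric positive definite 2x2.
check_covariance <- function(cov) {
  if (!is.matrix(cov) || !all(dim(cov) == c(2L, 2L)))
    stop("'cov' must be a 2x2 matrix", call. = FALSE)
  if (abs(cov[1, 2] - cov[2, 1]) > 1e-12 * (abs(cov[1, 2]) + 1))
    stop("'cov' must be symmetric", call. = FALSE)
  if (cov[1, 1] <= 0 || det(cov) <= 0)
    stop("'cov' must be positive definite", call. = FALSE)
  invisible(cov)
}

#' Affine Gaussian density
#'
#' Evaluates the zero-mean bivariate Gaussian
#' \eqn{g(x; \Sigma) = \exp(-x^T \Sigma^{-1} x / 2) / (2\pi\sqrt{\det\Sigma})}
#' used as the smoothing kernel of the receptive-field models.
#'
#' @param x1,x2 Numeric vectors of coordinates (recycled against each other).
#' @param cov 2x2 symmetric positive-definite covariance matrix, e.g. from
#'   [make_covariance()].
#' @return Numeric vector of density values.
#' @examples
#' affine_gaussian(0, 0, diag(c(1, 4)))  # 1 / (4 * pi)
#' @export
affine_gaussian <- function(x1, x2, cov) {
  check_covariance(cov)
  dt <- det(cov)
  # inverse of a 2x2 symmetric matrix, explicit
  i11 <- cov[2, 2] / dt; i22 <- cov[1, 1] / dt; i12 <- -cov[1, 2] / dt
  q <- i11 * x1^2 + 2 * i12 * x1 * x2 + i22 * x2^2
  exp(-q / 2) / (2 * pi * sqrt(dt))
}

# Probabilists' Hermite polynomial He_m(z), m <= 4 (closed forms).
hermite_he <- function(m, z) {
  switch(as.character(m),
         "0" = rep(1, length(z)),
         "1" = z,
         "2" = z^2 - 1,
         "3" = z^3 - 3 * z,
         "4" = z^4 - 6 * z^2 + 3,
         stop("derivative order 'm' must be an integer in 0..4", call. = FALSE))
}
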