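#' Sine-grating probe
#'
#' A static or moving sine grating
#' \eqn{f(x_1, x_2) = \sin(\omega\cos\theta\,x_1 + \omega\sin\theta\,x_2 +
#' \beta)}, used to probe receptive-field models.  For a moving probe the
#' velocity vector is `speed_u * (cos(theta), sin(theta))`, parallel to the
#' grating normal.
#'
#' @param omega Spatial angular frequency, `> 0`.
#' @param theta Inclination angle of the grating, radians.
#' @param beta Phase, radians.
#' @param speed_u Scalar speed, `>= 0` (0 for a static probe).
#' @return An object of class `sine_probe`.
#' @export
sine_probe <- function(omega, theta, beta = 0, speed_u = 0) {
  if (!is.finite(omega) || omega <= 0)
    stop("'omega' must be positive", call. = FALSE)
  if (speed_u < 0) stop("'speed_u' must be non-negative", call. = FALSE)
  structure(list(omega = omega, theta = theta, beta = beta, speed_u = speed_u),
            class = "sine_probe")
}

# Variance of the covariance matrix in the probe direction:
# s(theta) = u^T Sigma u for u = (cos theta, sin theta).
direction_variance <- function(shape, theta) {
  cv <- make_covariance(shape)
  ct <- cos(theta); st <- sin(theta)
  cv[1, 1] * ct^2 + 2 * cv[1, 2] * ct * st + cv[2, 2] * st^2
}

#' Response amplitude of a receptive field to a sine grating
#'
#' The steady-state output of a linear receptive field driven by a sine
#' grating is a sinusoid; this returns its amplitude.  For the spatial
#' model of order m the amplitude has the analytic form
#' \deqn{|\sigma_1 \omega \cos(\theta - \varphi)|^m \,
#'       e^{-\omega^2 s(\theta)/2},}
#' with \eqn{s(\theta)} the variance of \eqn{\Sigma_\varphi} in the probe
#' direction.  For the spatio-temporal model an additional temporal factor
#' \eqn{|\sigma_t \omega\,(u - p\cdot v)|^n \exp(-\sigma_t^2 \omega^2
#' (u - p\cdot v)^2 / 2)} applies, where `u` is the probe speed and
#' \eqn{p\cdot v} the projection of the field velocity on the grating
#' normal.  With `method = "grid"` the amplitude is instead measured from
#' the discrete convolution of the sampled kernel with the sampled grating
#' (i.e. the modulus of the kernel's discrete Fourier integral at the
#' grating frequency).
#'
#' @param rf A [spatial_rf()] or [spatiotemporal_rf()].
#' @param probe A [sine_probe()].
#' @param method `"analytic"` (default) or `"grid"`.
#' @param kernel Optional pre-sampled kernel from [sample_spatial_rf()]
#'   (grid method only; re-used across calls for speed).
#' @return The (non-negative) response amplitude.  Independent of the
#'   probe phase `beta`.
#' @export
response_amplitude <- function(rf, probe, method = c("analytic", "grid"),
                               kernel = NULL) {
  stopifnot(inherits(probe, "sine_probe"))
  method <- match.arg(method)
  if (inherits(rf, "spatiotemporal_rf")) {
    sp <- rf$spatial
    a <- response_amplitude(sp, sine_probe(probe$omega, probe$theta), method,
                            kernel)
    du <- probe$speed_u -
      (cos(probe$theta) * rf$velocity[1] + sin(probe$theta) * rf$velocity[2])
    wt <- rf$sigma_t * probe$omega * du
    return(a * abs(wt)^rf$order_n * exp(-wt^2 / 2))
  }
  stopifnot(inherits(rf, "spatial_rf"))
  sh <- rf$shape
  if (method == "analytic") {
    s <- direction_variance(sh, probe$theta)
    return(abs(sh$sigma1 * probe$omega * cos(probe$theta - sh$phi))^rf$order_m *
             exp(-probe$omega^2 * s / 2))
  }
  if (is.null(kernel)) kernel <- sample_spatial_rf(rf)
  if (probe$omega >= pi / kernel$step)
    stop("grating frequency exceeds the Nyquist limit of the kernel grid",
         call. = FALSE)
  p <- outer(kernel$x1 * cos(probe$theta), kernel$x2 * sin(probe$theta), "+")
  re <- sum(kernel$z * cos(probe$omega * p))
  im <- sum(kernel$z * sin(probe$omega * p))
  sqrt(re^2 + im^2) * kernel$step^2
}

#' Orientation-tuning curve container
#'
#' Holds sampled values of a normalized orientation-selectivity curve
#' r(theta) over angles in `[-pi/2, pi/2]`, together with model metadata.
#'
#' @param thetas Angles in radians.
#' @param values Responses, `>= 0`, normalized so that the value at
#'   `theta = 0` (when present) equals 1.
#' @param meta Named list of model metadata (e.g. `model`, `order`,
#'   `lambda`, `kappa`).
#' @return An object of class `tuning_curve`.
#' @export
tuning_curve <- function(thetas, values, meta = list()) {
  stopifnot(length(thetas) == length(values))
  if (any(values < -1e-12)) stop("tuning-curve values must be non-negative",
                                 call. = FALSE)
  structure(list(thetas = as.numeric(thetas),
                 values = pmax(as.numeric(values), 0), meta = meta),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  m <- x$meta
  lab <- if (length(m)) paste(names(m), unlist(m), sep = "=", collapse = ", ")
         else "no metadata"
  cat(sprintf("tuning_curve: %d angles in [%.3f, %.3f] (%s)\n",
              length(x$thetas), min(x$thetas), max(x$thetas), lab))
  invisible(x)
}

# Map a model specification to the exponent lambda of the power family.
model_lambda <- function(model, order = NULL, lambda = NULL) {
  switch(model,
    simple = {
      if (is.null(order) || !order %in% 1:4)
        stop("simple-cell model requires 'order' in 1..4", call. = FALSE)
      as.numeric(order)
    },
    complex = 3 / 2,
    power = {
      if (is.null(lambda) || !is.finite(lambda) || lambda <= 0)
        stop("power model requires a positive 'lambda'", call. = FALSE)
      lambda
    },
    stop(sprintf("unknown model class '%s'", model), call. = FALSE))
}

#' Closed-form orientation-selectivity curves
#'
#' Evaluates the generalized power-family selectivity curve
#' \deqn{r_\lambda(\theta) = \left( \frac{|\cos\theta|}
#'       {\sqrt{\cos^2\theta + \kappa^2 \sin^2\theta}} \right)^\lambda,}
#' which for `model = "simple"` and integer `order` m reproduces the
#' selectivity curves of m-th order simple cells (exponent m) and for
#' `model = "complex"` the quasi-quadrature complex-cell curve (exponent
#' 3/2).  All curves equal 1 at `theta = 0` and are even in `theta`.
#'
#' @param model One of `"simple"`, `"complex"`, `"power"`.
#' @param kappa Scale-parameter ratio `sigma2 / sigma1`, `> 0`.
#' @param theta Angle(s) in radians.
#' @param order Derivative order (1..4) for `model = "simple"`.
#' @param lambda Exponent for `model = "power"`.
#' @return Numeric vector of selectivity values in `[0, 1]`.
#' @examples
#' tuning_closed_form("simple", kappa = 2, theta = pi / 4, order = 2)  # 0.2
#' @export
tuning_closed_form <- function(model, kappa, theta, order = NULL,
                               lambda = NULL) {
  if (!is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be positive", call. = FALSE)
  lam <- model_lambda(model, order, lambda)
  (abs(cos(theta)) / sqrt(cos(theta)^2 + kappa^2 * sin(theta)^2))^lam
}

# Default angle grid: 181 uniform angles on [-pi/2, pi/2].
default_thetas <- function(n = 181L) seq(-pi / 2, pi / 2, length.out = n)

#' Orientation-tuning curve computed from a receptive-field model
#'
#' For each grating angle theta the response amplitude is maximized over
#' the grating frequency omega and divided by the value at `theta = 0`,
#' giving the normalized selectivity curve.  The field's preferred
#' orientation must be `phi = 0`.  With `method = "analytic"` the analytic
#' amplitude is evaluated at the closed-form optimum
#' \eqn{\omega_*^2 = m / s(\theta)}; with `method = "grid"` the amplitude
#' is measured from the sampled kernel and maximized numerically over
#' omega.  For spatio-temporal fields the probe speed is matched to the
#' projection of the field velocity on the grating normal.
#'
#' @param rf A [spatial_rf()] or [spatiotemporal_rf()] with `phi = 0` and
#'   spatial order m in 1..4.
#' @param thetas Angle grid; default 181 uniform angles on
#'   `[-pi/2, pi/2]`.
#' @param method `"analytic"` (default) or `"grid"`.
#' @param step,extent Kernel sampling controls (grid method).
#' @return A [tuning_curve()].
#' @export
tuning_numeric <- function(rf, thetas = default_thetas(),
                           method = c("analytic", "grid"),
                           step = NULL, extent = NULL) {
  method <- match.arg(method)
  sp <- if (inherits(rf, "spatiotemporal_rf")) rf$spatial else rf
  stopifnot(inherits(sp, "spatial_rf"))
  if (abs(sp$shape$phi) > 1e-12)
    stop("tuning curves are defined for a field with preferred orientation phi = 0",
         call. = FALSE)
  if (sp$order_m < 1)
    stop("tuning curves require spatial order m >= 1", call. = FALSE)
  amp <- function(theta) {
    speed <- if (inherits(rf, "spatiotemporal_rf"))
      cos(theta) * rf$velocity[1] + sin(theta) * rf$velocity[2] else 0
    s <- direction_variance(sp$shape, theta)
    w_star <- sqrt(sp$order_m / s)
    if (method == "analytic") {
      pr <- sine_probe(w_star, theta, speed_u = abs(speed))
      return(response_amplitude(rf, pr, "analytic"))
    }
    kern <- get("kernel", envir = env)
    upper <- min(4 * w_star, 0.95 * pi / kern$step)
    opt <- stats::optimize(function(w)
      response_amplitude(sp, sine_probe(w, theta), "grid", kernel = kern),
      lower = w_star / 4, upper = upper, maximum = TRUE, tol = 1e-6)
    opt$objective
  }
  env <- new.env()
  if (method == "grid")
    assign("kernel", sample_spatial_rf(sp, step = step, extent = extent),
           envir = env)
  vals <- vapply(thetas, amp, numeric(1))
  v0 <- amp(0)
  if (v0 <= 0) stop("numerical optimization failed: zero response at theta = 0",
                    call. = FALSE)
  tuning_curve(thetas, vals / v0,
               meta = list(model = "simple", order = sp$order_m,
                           kappa = sp$shape$kappa, method = method))
}

#' Quasi-quadrature (energy) response of a complex-cell model
#'
#' Combines the amplitudes of the first- and second-order directional
#' derivative responses at a common grating frequency into the
#' phase-aggregated energy measure
#' \deqn{Q = \sqrt{A_1^2 + C_\varphi A_2^2},}
#' the affine-Gaussian-derivative analogue of the classical energy model
#' of complex cells.  `c_phi` weights second- against first-order
#' information; the default is \eqn{1/\sqrt{2}}.
#'
#' @param shape An [rf_shape()].
#' @param probe A [sine_probe()].
#' @param c_phi Positive weight; default `1 / sqrt(2)`.
#' @return The scalar quasi-quadrature response.
#' @export
quasi_quadrature_response <- function(shape, probe, c_phi = 1 / sqrt(2)) {
  stopifnot(inherits(shape, "rf_shape"))
  if (!is.finite(c_phi) || c_phi < 0)
    stop("'c_phi' must be non-negative", call. = FALSE)
  a1 <- response_amplitude(spatial_rf(shape, 1L), probe)
  a2 <- response_amplitude(spatial_rf(shape, 2L), probe)
  sqrt(a1^2 + c_phi * a2^2)
}

#' Orientation-tuning curve of the quasi-quadrature complex-cell model
#'
#' Maximizes the quasi-quadrature measure over the grating frequency at
#' each angle and normalizes by the value at `theta = 0`.  The exact
#' closed form of the complex-cell curve is the geometric mean
#' \eqn{\sqrt{r_1 r_2}} of the first- and second-order simple-cell curves
#' (exponent 3/2 in the power family); the numerically optimized energy
#' measure tracks it closely but not exactly, since the energy combines
#' two orders whose individually optimal frequencies differ.
#'
#' @param shape An [rf_shape()] with `phi = 0`.
#' @param thetas Angle grid; default 181 uniform angles.
#' @param c_phi Weight between first- and second-order information.
#' @return A [tuning_curve()].
#' @export
tuning_quadrature <- function(shape, thetas = default_thetas(),
                              c_phi = 1 / sqrt(2)) {
  stopifnot(inherits(shape, "rf_shape"))
  if (abs(shape$phi) > 1e-12)
    stop("tuning curves are defined for phi = 0", call. = FALSE)
  qmax <- function(theta) {
    s <- direction_variance(shape, theta)
    w_ref <- sqrt(2 / s)  # bracket around the order-1/2 optima
    opt <- stats::optimize(function(w)
      quasi_quadrature_response(shape, sine_probe(w, theta), c_phi),
      lower = w_ref / 8, upper = 4 * w_ref, maximum = TRUE, tol = 1e-9)
    opt$objective
  }
  vals <- vapply(thetas, qmax, numeric(1))
  tuning_curve(thetas, vals / qmax(0),
               meta = list(model = "complex", kappa = shape$kappa,
                           c_phi = c_phi))
}
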