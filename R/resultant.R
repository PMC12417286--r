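#' Circular resultant of an orientation-tuning curve
#'
#' Computes the complex-valued resultant
#' \deqn{R = \frac{\int_{-\pi}^{\pi} r(\theta)\, e^{2i\theta}\, d\theta}
#'           {\int_{-\pi}^{\pi} r(\theta)\, d\theta}}
#' of a pi-periodic, non-negative tuning curve by adaptive quadrature.
#' Its modulus lies in `[0, 1]`: values near 1 indicate sharp orientation
#' tuning, values near 0 broad tuning (1 - |R| is the circular variance).
#' For even curves the imaginary part vanishes.
#'
#' @param curve Either a vectorized function `r(theta)` defined on the
#'   full circle (adaptive quadrature), or a [tuning_curve()] (composite
#'   trapezoid on its sample grid, using pi-periodicity).
#' @return A list of class `resultant_value` with fields `resultant`
#'   (complex) and `modulus`.
#' @examples
#' resultant_numeric(function(th) cos(th)^2)$modulus  # 0.5
#' @export
resultant_numeric <- function(curve) {
  if (inherits(curve, "tuning_curve")) {
    # sampled curve: composite trapezoid on its own grid over one period,
    # exploiting pi-periodicity (adaptive quadrature is wasted on a
    # piecewise-linear interpolant)
    o <- order(curve$thetas)
    th <- curve$thetas[o]; v <- curve$values[o]
    trap <- function(y) sum(diff(th) * (utils::head(y, -1) + y[-1]) / 2)
    den <- trap(v)
    if (!is.finite(den) || den <= 1e-300)
      stop("degenerate tuning curve: integral over the circle is zero",
           call. = FALSE)
    R <- complex(real = trap(v * cos(2 * th)) / den,
                 imaginary = trap(v * sin(2 * th)) / den)
    return(structure(list(resultant = R, modulus = Mod(R)),
                     class = "resultant_value"))
  }
  r <- curve
  stopifnot(is.function(r))
  quad <- function(f) stats::integrate(f, -pi, pi, subdivisions = 400L,
                                       rel.tol = 1e-10,
                                       abs.tol = 1e-12)$value
  den <- quad(r)
  if (!is.finite(den) || den <= 1e-300)
    stop("degenerate tuning curve: integral over the circle is zero",
         call. = FALSE)
  num_re <- quad(function(th) r(th) * cos(2 * th))
  num_im <- quad(function(th) r(th) * sin(2 * th))
  R <- complex(real = num_re / den, imaginary = num_im / den)
  structure(list(resultant = R, modulus = Mod(R)), class = "resultant_value")
}

#' @export
print.resultant_value <- function(x, ...) {
  cat(sprintf("resultant: %.6f%+.2ei, |R| = %.6f\n",
              Re(x$resultant), Im(x$resultant), x$modulus))
  invisible(x)
}

# Power-family resultant modulus, scalar kappa.  Closed forms from the
# analytic evaluation of the resultant integrals for integer exponents;
# kappa < 1 uses the arccos continuation of acosh and sqrt(kappa^2 - 1)
# (the imaginary units cancel).  Near kappa = 1 the closed forms are
# 0/0-degenerate and adaptive quadrature is used instead.
resultant_power_scalar <- function(lambda, kappa) {
  if (!is.finite(kappa) || kappa <= 0)
    stop("'kappa' must be positive", call. = FALSE)
  if (lambda %in% c(1, 2, 3, 4) && abs(kappa - 1) >= 1e-4) {
    if (lambda == 2) return(kappa / (kappa + 1))
    if (lambda == 4) return(kappa * (kappa + 3) / ((kappa + 1) * (kappa + 2)))
    if (kappa > 1) {
      ach <- acosh(kappa); sq <- sqrt(kappa^2 - 1)
    } else {
      ach <- acos(kappa); sq <- sqrt(1 - kappa^2)
    }
    if (lambda == 1)
      return(kappa * (kappa * ach - sq) / ((kappa^2 - 1) * ach))
    # lambda == 3
    return(kappa * (sq * (kappa^2 + 2) - 3 * kappa * ach) /
             ((kappa^2 - 1) * (kappa * sq - ach)))
  }
  resultant_numeric(function(th) tuning_closed_form("power", kappa, th,
                                                    lambda = lambda))$modulus
}

#' Resultant modulus of the model tuning curves
#'
#' Returns |R| of the closed-form selectivity curve of the given model.
#' For simple cells of integer order the analytic expressions are used:
#' order 1 and 3 involve inverse hyperbolic cosines (continued through
#' arccos for `kappa < 1`), order 2 gives
#' \eqn{\kappa / (\kappa + 1)} and order 4
#' \eqn{\kappa(\kappa + 3) / ((\kappa + 1)(\kappa + 2))}.  The
#' complex-cell curve (exponent 3/2) and non-integer power exponents are
#' evaluated by adaptive quadrature of the resultant integral.
#'
#' @param model One of `"simple"`, `"complex"`, `"power"`.
#' @param kappa Scale-parameter ratio(s), `> 0` (vectorized).
#' @param order Derivative order (1..4) for `model = "simple"`.
#' @param lambda Exponent for `model = "power"`.
#' @return Numeric vector of moduli in `[0, 1]`.
#' @examples
#' resultant_closed_form("simple", 2, order = 2)  # 2/3
#' @export
resultant_closed_form <- function(model, kappa, order = NULL, lambda = NULL) {
  lam <- model_lambda(model, order, lambda)
  vapply(kappa, function(k) resultant_power_scalar(lam, k), numeric(1))
}

#' Resultant as a function of elongation
#'
#' Evaluates |R| for one or more models over a grid of scale-parameter
#' ratios, returning a long table with the logarithmic parameterization
#' `K = log(kappa)` alongside, suitable for plotting resultant-versus-
#' elongation curves.
#'
#' @param models Character vector naming the models; entries `"simple1"`
#'   to `"simple4"`, `"complex"`, or `"power"` (the latter requires
#'   `lambda`).
#' @param kappas Vector of ratios, all `> 0`; alternatively supply
#'   `K_range` and `n` for a log-spaced grid.
#' @param K_range Range of `K = log(kappa)` for the grid.
#' @param n Number of grid points when `K_range` is used.
#' @param lambda Exponent for `"power"` entries.
#' @return A data.frame with columns `model`, `kappa`, `log_kappa`,
#'   `resultant`.
#' @export
resultant_curve <- function(models = c("simple1", "simple2", "complex",
                                       "simple3", "simple4"),
                            kappas = NULL, K_range = c(-log(8), log(8)),
                            n = 201L, lambda = NULL) {
  if (is.null(kappas)) kappas <- exp(seq(K_range[1], K_range[2],
                                         length.out = n))
  if (any(kappas <= 0)) stop("'kappas' must be positive", call. = FALSE)
  one <- function(mname) {
    if (grepl("^simple[1-4]$", mname)) {
      ord <- as.integer(substring(mname, 7))
      v <- resultant_closed_form("simple", kappas, order = ord)
    } else if (mname == "complex") {
      v <- resultant_closed_form("complex", kappas)
    } else if (mname == "power") {
      v <- resultant_closed_form("power", kappas, lambda = lambda)
    } else stop(sprintf("unknown model '%s'", mname), call. = FALSE)
    data.frame(model = mname, kappa = kappas, log_kappa = log(kappas),
               resultant = v)
  }
  do.call(rbind, lapply(models, one))
}
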