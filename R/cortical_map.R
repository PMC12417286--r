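#' Generate a synthetic pinwheel orientation-preference map
#'
#' Builds a square lattice of cortical sites whose preferred orientation
#' is the half-argument of a superposition of half-winding singularities
#' (pinwheels) with signs +/- 1/2, placed at randomized positions: around
#' a single positive center, the orientation at polar angle alpha equals
#' `(alpha / 2) mod pi`.  Each site is also assigned an elongation ratio
#' `kappa` via a radial profile of the distance `d` to the nearest
#' pinwheel center, with `kappa = 1` (eccentricity 1, isotropic) at the
#' centers; the default profile increases linearly to `kappa_max` at the
#' most distant site.  This is a synthetic stand-in for recorded
#' orientation maps, meant to exercise measurement logic, not a model of
#' map development.
#'
#' @param grid_size Lattice side length, `>= 16`.
#' @param n_pinwheels Number of pinwheel centers (ignored when `centers`
#'   is supplied).
#' @param kappa_max Elongation at the site farthest from any center
#'   (linear profile), `>= 1`.
#' @param kappa_profile Optional function `kappa(d, d_max)` mapping
#'   distances to ratios; must satisfy `kappa(0, .) = 1`.
#' @param centers Optional matrix/data.frame with columns `x`, `y` and
#'   optionally `sign` (+1 or -1), overriding random placement.
#' @param seed Integer seed for the randomized placement.
#' @return An object of class `cortical_map`: `sites` (data.frame with
#'   `x`, `y`, `orientation` in `[0, pi)`, `d`, `kappa`, `eccentricity`),
#'   `centers` (data.frame `x`, `y`, `sign`), and `grid_size`.
#' @export
generate_pinwheel_map <- function(grid_size = 64L, n_pinwheels = 4L,
                                  kappa_max = 8, kappa_profile = NULL,
                                  centers = NULL, seed = NULL) {
  if (grid_size < 16L) stop("'grid_size' must be at least 16", call. = FALSE)
  if (kappa_max < 1) stop("'kappa_max' must be at least 1", call. = FALSE)
  if (is.null(centers)) {
    if (!is.null(seed)) set.seed(seed)
    for (try in 1:100) {
      cx <- stats::runif(n_pinwheels, 1, grid_size)
      cy <- stats::runif(n_pinwheels, 1, grid_size)
      if (n_pinwheels == 1L ||
          min(stats::dist(cbind(cx, cy))) >= 2) break
      if (try == 100)
        stop("could not place pinwheel centers at least 2 lattice steps apart",
             call. = FALSE)
    }
    sgn <- rep_len(c(1, -1), n_pinwheels)
    if (n_pinwheels > 1L) sgn <- sample(sgn)
    centers <- data.frame(x = cx, y = cy, sign = sgn)
  } else {
    centers <- as.data.frame(centers)
    if (is.null(centers$sign)) centers$sign <- rep_len(c(1, -1), nrow(centers))
    if (nrow(centers) > 1L && min(stats::dist(centers[, c("x", "y")])) < 2)
      stop("pinwheel centers closer than 2 lattice steps", call. = FALSE)
  }

  g <- expand.grid(x = seq_len(grid_size), y = seq_len(grid_size))
  total <- rep(0, nrow(g))
  d2min <- rep(Inf, nrow(g))
  for (i in seq_len(nrow(centers))) {
    dx <- g$x - centers$x[i]; dy <- g$y - centers$y[i]
    total <- total + centers$sign[i] * atan2(dy, dx)
    d2min <- pmin(d2min, dx^2 + dy^2)
  }
  g$orientation <- (total / 2) %% pi
  g$d <- sqrt(d2min)
  d_max <- max(g$d)
  if (is.null(kappa_profile))
    kappa_profile <- function(d, d_max) 1 + (kappa_max - 1) * d / d_max
  g$kappa <- kappa_profile(g$d, d_max)
  if (any(g$kappa < 1 - 1e-9) || abs(kappa_profile(0, d_max) - 1) > 1e-9)
    stop("'kappa_profile' must map distance 0 to kappa = 1 and stay >= 1",
         call. = FALSE)
  g$eccentricity <- 1 / g$kappa
  structure(list(sites = g, centers = centers,
                 grid_size = as.integer(grid_size)),
            class = "cortical_map")
}

#' @export
print.cortical_map <- function(x, ...) {
  cat(sprintf("cortical_map: %dx%d lattice, %d pinwheel center(s), kappa in [%.3g, %.3g]\n",
              x$grid_size, x$grid_size, nrow(x$centers),
              min(x$sites$kappa), max(x$sites$kappa)))
  invisible(x)
}

#' Orientation homogeneity around a site
#'
#' The homogeneity H of the orientation preference surrounding a site is
#' the modulus of the mean of the unit complex numbers
#' \eqn{e^{2i\varphi_j}} over the neighboring sites within the given
#' radius (the site itself excluded).  The double-angle mapping collapses
#' opposite orientations, respecting the pi-periodicity of orientation:
#' H = 1 when all neighbors share one orientation, H = 0 when neighbor
#' orientations cancel (e.g. two equal groups a quarter-turn apart, or a
#' uniform spread over `[0, pi)`).
#'
#' @param map A [generate_pinwheel_map()] result.
#' @param site Row index of the site in `map$sites`, or a length-2 vector
#'   of lattice coordinates `(x, y)`.
#' @param radius Neighborhood radius in lattice units, `>= 1`.
#' @return H in `[0, 1]`.
#' @export
orientation_homogeneity <- function(map, site, radius = 3) {
  stopifnot(inherits(map, "cortical_map"))
  if (radius < 1) stop("'radius' must be at least 1 lattice step", call. = FALSE)
  s <- map$sites
  idx <- if (length(site) == 2L) which(s$x == site[1] & s$y == site[2])
         else as.integer(site)
  if (length(idx) != 1L || is.na(idx) || idx < 1L || idx > nrow(s))
    stop("'site' does not identify a lattice site", call. = FALSE)
  d2 <- (s$x - s$x[idx])^2 + (s$y - s$y[idx])^2
  nb <- which(d2 <= radius^2 & d2 > 0)
  if (!length(nb))
    stop("no neighbors within the given radius", call. = FALSE)
  Mod(mean(exp(2i * s$orientation[nb])))
}

#' Per-site diagnostics of a synthetic orientation map
#'
#' Computes, for every lattice site: the distance to the nearest pinwheel
#' center, the eccentricity, the local orientation homogeneity H within
#' `radius`, and the orientation-selectivity measure |R| implied by the
#' site's elongation under the power-family tuning model with exponent
#' `lambda`.  This is the joint measurement table relating selectivity,
#' eccentricity, homogeneity, and pinwheel geometry.
#'
#' @param map A [generate_pinwheel_map()] result.
#' @param lambda Tuning exponent for the selectivity column; default 2.
#' @param radius Neighborhood radius for H; default 3.
#' @return A data.frame with columns `site`, `x`, `y`, `d`, `kappa`,
#'   `eccentricity`, `H`, `selectivity`.
#' @export
measure_map <- function(map, lambda = 2, radius = 3) {
  stopifnot(inherits(map, "cortical_map"))
  s <- map$sites
  n <- map$grid_size
  # neighborhood offsets within the radius, once
  r <- ceiling(radius)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 &
               !(off$dx == 0 & off$dy == 0), ]
  zmat <- matrix(exp(2i * s$orientation), n, n)  # [x, y]
  H <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    xs <- s$x[i] + off$dx; ys <- s$y[i] + off$dy
    ok <- xs >= 1 & xs <= n & ys >= 1 & ys <= n
    H[i] <- Mod(mean(zmat[cbind(xs[ok], ys[ok])]))
  }
  # selectivity via the monotone kappa -> |R| map, on unique kappa values
  uk <- sort(unique(s$kappa))
  rv <- resultant_closed_form("power", uk, lambda = lambda)
  sel <- rv[match(s$kappa, uk)]
  data.frame(site = seq_len(nrow(s)), x = s$x, y = s$y, d = s$d,
             kappa = s$kappa, eccentricity = s$eccentricity,
             H = H, selectivity = sel)
}

#' Orientation winding around a lattice loop
#'
#' Sums the wrapped increments of preferred orientation along a closed
#' square loop of lattice sites centered on a point.  Each increment is
#' reduced to `(-pi/2, pi/2]` (orientation is pi-periodic); a loop
#' enclosing exactly one pinwheel center sums to +/- pi (half winding),
#' and to 0 when no center is enclosed.
#'
#' @param map A [generate_pinwheel_map()] result.
#' @param center Length-2 vector, loop center in lattice coordinates.
#' @param half_width Half side-length of the square loop, `>= 1`.
#' @return Total winding in radians.
#' @export
loop_winding <- function(map, center, half_width = 3L) {
  stopifnot(inherits(map, "cortical_map"))
  n <- map$grid_size
  cx <- round(center[1]); cy <- round(center[2]); h <- round(half_width)
  if (cx - h < 1 || cx + h > n || cy - h < 1 || cy + h > n)
    stop("loop extends outside the lattice", call. = FALSE)
  xs <- c((cx - h):(cx + h), rep(cx + h, 2 * h - 1), (cx + h):(cx - h),
          rep(cx - h, 2 * h - 1))
  ys <- c(rep(cy - h, 2 * h + 1), (cy - h + 1):(cy + h - 1),
          rep(cy + h, 2 * h + 1), (cy + h - 1):(cy - h + 1))
  ori <- matrix(map$sites$orientation, n, n)[cbind(xs, ys)]
  ori <- c(ori, ori[1])
  inc <- diff(ori)
  inc <- ((inc + pi / 2) %% pi) - pi / 2
  sum(inc)
}
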