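test_that("covariance parameterization matches the stated closed form", {
  expect_equal(make_covariance(1, 2, 0), diag(c(1, 4)))
  expect_equal(make_covariance(1, 2, pi / 2), diag(c(4, 1)), tolerance = 1e-12)
  cv <- make_covariance(1, 2, pi / 4)
  expect_equal(cv, matrix(c(2.5, -1.5, -1.5, 2.5), 2), tolerance = 1e-12)
  ev <- eigen(cv)
  expect_equal(sort(ev$values), c(1, 4))
  v <- ev$vectors[, ev$values == 1]
  expect_equal(abs(sum(v * c(1, 1) / sqrt(2))), 1, tolerance = 1e-12)
})

test_that("covariance eigenstructure holds for random shapes", {
  set.seed(11)
  for (i in 1:20) {
    s1 <- runif(1, 0.3, 3); s2 <- runif(1, 0.3, 3); phi <- runif(1, -pi, pi)
    cv <- make_covariance(s1, s2, phi)
    ev <- eigen(cv)
    expect_equal(sort(ev$values), sort(c(s1^2, s2^2)), tolerance = 1e-10)
    u <- c(cos(phi), sin(phi))
    expect_equal(as.numeric(cv %*% u), s1^2 * u, tolerance = 1e-10)
  }
  expect_error(make_covariance(-1, 1), "positive")
  expect_error(make_covariance(1, 0), "positive")
})

test_that("affine Gaussian density has the right values and unit mass", {
  expect_equal(affine_gaussian(0, 0, diag(c(1, 4))), 1 / (4 * pi))
  expect_equal(affine_gaussian(1, 0, diag(2)), exp(-1 / 2) / (2 * pi))
  expect_error(affine_gaussian(0, 0, matrix(c(1, 1, 1, 1), 2)), "definite")
  # quadrature oracle: mass on [-8 sigma, 8 sigma]^2
  cv <- make_covariance(1, 2, pi / 6)
  x <- seq(-16, 16, by = 0.05)
  z <- outer(x, x, function(a, b) affine_gaussian(a, b, cv))
  expect_equal(sum(z) * 0.05^2, 1, tolerance = 1e-6)
})

test_that("sampled derivative kernels match finite differences of the Gaussian", {
  sh <- rf_shape(1, 2, pi / 5)
  h <- sh$sigma1 / 16
  g0 <- function(x1, x2) affine_gaussian(x1, x2, make_covariance(sh))
  pts <- expand.grid(x1 = seq(-2, 2, by = 0.5), x2 = seq(-2, 2, by = 0.5))
  cph <- cos(sh$phi); sph <- sin(sh$phi)
  # fourth-order-accurate central stencil, nested m times
  dirderiv_fd <- function(f, m) {
    if (m == 0) return(f)
    fd <- function(x1, x2)
      (-f(x1 + 2 * h * cph, x2 + 2 * h * sph) +
         8 * f(x1 + h * cph, x2 + h * sph) -
         8 * f(x1 - h * cph, x2 - h * sph) +
         f(x1 - 2 * h * cph, x2 - 2 * h * sph)) / (12 * h)
    dirderiv_fd(fd, m - 1)
  }
  for (m in 0:4) {
    rf <- spatial_rf(sh, m)
    analytic <- affrf:::eval_spatial_kernel(rf, pts$x1, pts$x2)
    fd <- sh$sigma1^m * dirderiv_fd(g0, m)(pts$x1, pts$x2)
    expect_equal(analytic, fd, tolerance = 1e-4,
                 label = sprintf("order %d kernel", m))
  }
})

test_that("kernel parity and normalization follow the derivative order", {
  k0 <- sample_spatial_rf(spatial_rf(rf_shape(1, 2, pi / 7), 0), extent = 12)
  expect_true(all(k0$z >= 0))
  expect_equal(sum(k0$z) * k0$step^2, 1, tolerance = 1e-6)
  for (m in 1:4) {
    k <- sample_spatial_rf(spatial_rf(rf_shape(1, 1.5, pi / 7), m))
    flipped <- k$z[rev(seq_along(k$x1)), rev(seq_along(k$x2))]
    expect_equal(k$z, (-1)^m * flipped, tolerance = 1e-12,
                 label = sprintf("order %d parity", m))
  }
  # first-derivative extremum at one sigma on the x1 axis
  k1 <- sample_spatial_rf(spatial_rf(rf_shape(1, 1, 0), 1))
  on_axis <- abs(k1$z[, which(k1$x2 == 0)])
  expect_equal(abs(k1$x1[which.max(on_axis)]), 1, tolerance = k1$step)
  expect_error(spatial_rf(rf_shape(1, 1, 0), 5), "order")
  expect_warning(sample_spatial_rf(spatial_rf(rf_shape(1, 1, 0), 1),
                                   step = 0.5), "step")
})

test_that("spatio-temporal kernels separate, differentiate and shift correctly", {
  sp <- spatial_rf(rf_shape(1, 2, 0), 1)
  st0 <- sample_spatiotemporal_rf(spatiotemporal_rf(sp, 1, 0, 0L),
                                  t_step = 0.5)
  ks <- sample_spatial_rf(sp)
  sep <- outer(ks$z, dnorm(st0$t), "*")
  expect_equal(st0$z, sep, tolerance = 1e-14)
  # n = 1, v = 0: temporal profile is the first Gaussian derivative in t
  st1 <- sample_spatiotemporal_rf(spatiotemporal_rf(sp, 1, 0, 1L),
                                  t_step = 0.5)
  prof <- st1$z[73, 65, ] / ks$z[73, 65]  # off-axis point, kernel nonzero
  expect_equal(prof, -st1$t * dnorm(st1$t), tolerance = 1e-12)
  # Galilean shift: kernel at speed u equals the static kernel at x1 - u t
  u <- 0.75
  stv <- sample_spatiotemporal_rf(spatiotemporal_rf(sp, 1, u, 0L),
                                  t_step = 0.5)
  for (k in seq_along(stv$t)) {
    shifted <- outer(stv$x1, stv$x2, function(a, b)
      affrf:::eval_spatial_kernel(sp, a - u * stv$t[k], b)) *
      dnorm(stv$t[k])
    expect_equal(stv$z[, , k], shifted, tolerance = 1e-14)
  }
})

test_that("smoothing commutes with affine warping within grid tolerance", {
  expect_lt(check_affine_covariance(diag(c(1, 2)), diag(2), n = 65L), 1e-12)
  cov <- make_covariance(1, sqrt(2), 0)
  mats <- list(scaling = diag(c(2, 1)),
               rotation = matrix(c(cos(0.5), sin(0.5),
                                   -sin(0.5), cos(0.5)), 2),
               shear = matrix(c(1, 0, 0.5, 1), 2))
  for (nm in names(mats))
    expect_lt(check_affine_covariance(cov, mats[[nm]]), 1e-3,
              label = sprintf("%s discrepancy", nm))
  expect_error(check_affine_covariance(cov, matrix(0, 2, 2)), "singular")
  # rotating the frame is the same as rotating phi in the shape
  phi <- 0.7
  cv_rot <- make_covariance(1, 2, phi)
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
  expect_equal(R %*% make_covariance(1, 2, 0) %*% t(R), cv_rot,
               tolerance = 1e-12)
})
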