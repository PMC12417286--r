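test_that("grating response amplitude matches its analytic form", {
  rf1 <- spatial_rf(rf_shape(1, 1, 0), 1)
  expect_equal(response_amplitude(rf1, sine_probe(1, 0)), exp(-1 / 2))
  # odd order orthogonal to the grating gives no response
  rf3 <- spatial_rf(rf_shape(1, 2, 0), 3)
  expect_equal(response_amplitude(rf3, sine_probe(1, pi / 2)), 0)
  # amplitude does not depend on phase
  expect_equal(response_amplitude(rf1, sine_probe(1.3, 0.4, beta = 0)),
               response_amplitude(rf1, sine_probe(1.3, 0.4, beta = 2)))
  # discrete convolution of the sampled kernel agrees with the closed form
  kern <- sample_spatial_rf(rf3)
  for (th in c(0, 0.3, 1.1)) {
    pr <- sine_probe(1.2, th)
    expect_equal(response_amplitude(rf3, pr, "grid", kernel = kern),
                 response_amplitude(rf3, pr), tolerance = 1e-3)
  }
  expect_error(response_amplitude(rf3, sine_probe(100, 0), "grid",
                                  kernel = kern), "Nyquist")
})

test_that("closed-form selectivity curves reproduce the printed values", {
  expect_equal(tuning_closed_form("simple", 2, pi / 4, order = 2), 0.2)
  expect_equal(tuning_closed_form("simple", 2, pi / 4, order = 1), 1 / sqrt(5))
  expect_equal(tuning_closed_form("simple", 2, pi / 4, order = 4), 0.04)
  # isotropic second order is cos^2
  th <- default_thetas(41)
  expect_equal(tuning_closed_form("simple", 1, th, order = 2), cos(th)^2)
  expect_error(tuning_closed_form("gabor", 1, 0), "unknown model")
  expect_error(tuning_closed_form("simple", -1, 0, order = 2), "positive")
})

test_that("power-family identities hold to machine precision", {
  set.seed(21)
  th <- runif(40, -pi / 2, pi / 2)
  for (kappa in c(0.5, 1, 2, 4, 8)) {
    r <- lapply(1:4, function(m)
      tuning_closed_form("simple", kappa, th, order = m))
    rc <- tuning_closed_form("complex", kappa, th)
    expect_equal(r[[3]], r[[1]] * r[[2]], tolerance = 1e-12)
    expect_equal(r[[4]], r[[2]]^2, tolerance = 1e-12)
    expect_equal(rc, sqrt(r[[1]] * r[[2]]), tolerance = 1e-12)
    lam <- 2.7
    expect_equal(tuning_closed_form("power", kappa, th, lambda = lam),
                 r[[1]]^lam, tolerance = 1e-12)
  }
})

test_that("tuning curves are even, normalized, vanish at pi/2 and sharpen", {
  th <- default_thetas(91)
  for (m in 1:4) for (kappa in c(1, 2, 4, 8)) {
    r <- tuning_closed_form("simple", kappa, th, order = m)
    expect_equal(r[th == 0], 1)
    expect_equal(r, rev(r), tolerance = 1e-12)
    expect_lt(max(abs(r[abs(abs(th) - pi / 2) < 1e-9])), 1e-12)
    half <- r[th >= 0]
    expect_true(all(diff(half) <= 1e-12))
  }
  # strictly decreasing in kappa and in order at fixed theta != 0
  th0 <- pi / 6
  for (m in 1:4) {
    vals <- sapply(c(1, 2, 4, 8), function(k)
      tuning_closed_form("simple", k, th0, order = m))
    expect_true(all(diff(vals) < 0))
  }
  ords <- sapply(1:4, function(m)
    tuning_closed_form("simple", 2, th0, order = m))
  expect_true(all(diff(ords) < 0))
})

test_that("frequency-maximized curves agree with the closed forms", {
  th <- default_thetas(25)
  for (m in 1:4) for (kappa in c(1, 2, 4, 8)) {
    tc <- tuning_numeric(spatial_rf(rf_shape(1, kappa, 0), m), th)
    cf <- tuning_closed_form("simple", kappa, th, order = m)
    expect_equal(tc$values, cf, tolerance = 1e-9,
                 label = sprintf("analytic curve m=%d kappa=%g", m, kappa))
  }
  # sampled-kernel route: grid convolution, numeric omega search
  for (m in c(1, 3)) for (kappa in c(1, 2)) {
    tc <- tuning_numeric(spatial_rf(rf_shape(1, kappa, 0), m),
                         default_thetas(13), method = "grid")
    cf <- tuning_closed_form("simple", kappa, tc$thetas, order = m)
    expect_lt(max(abs(tc$values - cf)), 1e-2)
  }
  expect_error(tuning_numeric(spatial_rf(rf_shape(1, 2, 1), 2)), "phi = 0")
})

test_that("spatio-temporal curves with matched velocity equal the spatial ones", {
  th <- default_thetas(25)
  for (kappa in c(1, 2)) {
    sp <- spatial_rf(rf_shape(1, kappa, 0), 2)
    strf <- spatiotemporal_rf(sp, sigma_t = 0.8, speed = 1.5, order_n = 0L)
    expect_equal(tuning_numeric(strf, th)$values,
                 tuning_numeric(sp, th)$values, tolerance = 1e-12)
  }
})

test_that("quasi-quadrature energy behaves like the complex-cell model", {
  sh <- rf_shape(1, 2, 0)
  pr <- sine_probe(1, pi / 2)  # odd/even orders both respond zero off axis?
  # degenerate weight returns the first-order amplitude
  pr2 <- sine_probe(1, 0.3)
  a1 <- response_amplitude(spatial_rf(sh, 1L), pr2)
  expect_equal(quasi_quadrature_response(sh, pr2, c_phi = 0), a1)
  # zero second-order amplitude reduces to the first order
  prq <- sine_probe(1, pi / 2)
  expect_equal(quasi_quadrature_response(sh, prq),
               response_amplitude(spatial_rf(sh, 1L), prq))
  # the omega-optimized, normalized energy curve tracks the closed form
  th <- default_thetas(25)
  for (kappa in c(1, 2, 4)) {
    tq <- tuning_quadrature(sh <- rf_shape(1, kappa, 0), th)
    cf <- tuning_closed_form("complex", kappa, th)
    expect_lt(max(abs(tq$values - cf)), 0.07)
  }
})
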