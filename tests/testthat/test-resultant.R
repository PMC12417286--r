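# Gamma-function oracle for the resultant of |cos|^a curves (kappa = 1):
# R = 2 I(a + 2) / I(a) - 1 with I(a) the cosine-power moment integral.
cos_power_resultant <- function(a) {
  I <- function(p) sqrt(pi) * gamma((p + 1) / 2) / (2 * gamma(p / 2 + 1))
  2 * I(a + 2) / I(a) - 1
}

test_that("numerical resultant handles flat, cosine-power and degenerate curves", {
  expect_equal(resultant_numeric(function(th) rep(1, length(th)))$modulus, 0,
               tolerance = 1e-10)
  rv <- resultant_numeric(function(th) cos(th)^2)
  expect_equal(rv$modulus, 0.5, tolerance = 1e-10)
  expect_lt(abs(Im(rv$resultant)), 1e-10)
  # complex-cell curve at kappa = 1 is |cos|^{3/2}: gamma oracle gives 3/7
  rc <- resultant_numeric(function(th)
    tuning_closed_form("complex", 1, th))$modulus
  expect_equal(cos_power_resultant(3 / 2), 3 / 7, tolerance = 1e-12)
  expect_equal(rc, 3 / 7, tolerance = 1e-8)
  expect_error(resultant_numeric(function(th) rep(0, length(th))),
               "degenerate")
  # sampled tuning-curve input agrees with the function route
  th <- default_thetas(721)
  tc <- tuning_curve(th, tuning_closed_form("simple", 2, th, order = 2))
  expect_equal(resultant_numeric(tc)$modulus, 2 / 3, tolerance = 1e-4)
})

test_that("closed-form resultants match the printed expressions and quadrature", {
  expect_equal(resultant_closed_form("simple", 2, order = 2), 2 / 3)
  expect_equal(resultant_closed_form("simple", 2, order = 4), 5 / 6)
  expect_equal(resultant_closed_form("simple", 8, order = 2), 8 / 9)
  # order 1 at kappa = 2 via cosh^-1(2) = log(2 + sqrt(3))
  l2 <- log(2 + sqrt(3))
  expect_equal(resultant_closed_form("simple", 2, order = 1),
               2 * (2 * l2 - sqrt(3)) / (3 * l2), tolerance = 1e-12)
  for (kappa in c(0.25, 0.5, 1.01, 2, 4, 8)) {
    for (m in 1:4) {
      quad <- resultant_numeric(function(th)
        tuning_closed_form("simple", kappa, th, order = m))$modulus
      expect_equal(resultant_closed_form("simple", kappa, order = m), quad,
                   tolerance = 1e-6,
                   label = sprintf("order %d kappa %g", m, kappa))
    }
    quadc <- resultant_numeric(function(th)
      tuning_closed_form("complex", kappa, th))$modulus
    expect_equal(resultant_closed_form("complex", kappa), quadc,
                 tolerance = 1e-6)
  }
  expect_error(resultant_closed_form("simple", -2, order = 2), "positive")
})

test_that("kappa -> 1 limits equal lambda / (lambda + 2)", {
  lams <- c(1, 3 / 2, 2, 3, 4)
  expect_equal(resultant_closed_form("power", 1, lambda = lams[1]), 1 / 3,
               tolerance = 1e-8)
  expected <- c(1 / 3, 3 / 7, 1 / 2, 3 / 5, 2 / 3)
  for (i in seq_along(lams)) {
    expect_equal(cos_power_resultant(lams[i]), expected[i], tolerance = 1e-12)
    expect_equal(resultant_closed_form("power", 1, lambda = lams[i]),
                 expected[i], tolerance = 1e-8)
  }
  # approaching the removable singularity from both sides
  for (kappa in c(1 - 1e-5, 1 + 1e-5))
    expect_equal(resultant_closed_form("simple", kappa, order = 1), 1 / 3,
                 tolerance = 1e-4)
})

test_that("resultant curves are monotone, ordered and bounded", {
  expect_equal(resultant_closed_form("simple", c(1, 2, 8), order = 2),
               c(1 / 2, 2 / 3, 8 / 9), tolerance = 1e-12)
  tab <- resultant_curve(kappas = exp(seq(0, log(8), length.out = 60)))
  for (m in unique(tab$model)) {
    v <- tab$resultant[tab$model == m]
    expect_true(all(diff(v) > 0), label = sprintf("%s increasing", m))
    expect_true(all(v >= 0 & v <= 1))
  }
  # pairwise ordering R1 < Rcomplex < R2 < R3 < R4 on kappa > 1
  wide <- matrix(tab$resultant, ncol = 5)
  colnames(wide) <- unique(tab$model)
  interior <- wide[-1, ]  # drop kappa = 1 where orderings touch
  expect_true(all(interior[, "simple1"] < interior[, "complex"]))
  expect_true(all(interior[, "complex"] < interior[, "simple2"]))
  expect_true(all(interior[, "simple2"] < interior[, "simple3"]))
  expect_true(all(interior[, "simple3"] < interior[, "simple4"]))
  # high-elongation limits approach 1
  expect_equal(resultant_closed_form("simple", 1e6, order = 2), 1,
               tolerance = 1e-5)
  expect_equal(resultant_closed_form("simple", 1e6, order = 4), 1,
               tolerance = 1e-5)
  # kappa < 1 branch continuation agrees with quadrature (orders 1, 3)
  for (kappa in c(0.1, 0.4, 0.9)) for (m in c(1, 3)) {
    quad <- resultant_numeric(function(th)
      tuning_closed_form("simple", kappa, th, order = m))$modulus
    expect_equal(resultant_closed_form("simple", kappa, order = m), quad,
                 tolerance = 1e-6)
  }
})
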