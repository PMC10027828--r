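test_that("hematocrit correlation matches its closed form and is monotone", {
  # independent oracle: evaluate the correlation formulas directly
  for (H in c(0.35, 0.40, 0.45)) {
    p <- params_from_hematocrit(H)
    expect_equal(p$tau_y, 0.1 * (0.625 * H)^3, tolerance = 1e-15)
    expect_equal(p$mu_inf, 0.00145 * (1 - H)^(-2.5), tolerance = 1e-15)
  }
  p35 <- params_from_hematocrit(0.35)
  p40 <- params_from_hematocrit(0.40)
  p45 <- params_from_hematocrit(0.45)
  expect_gt(p45$tau_y, p35$tau_y)
  expect_gt(p45$mu_inf, p40$mu_inf)
  expect_gt(p40$tau_y, p35$tau_y)
  expect_identical(p40$hematocrit, 0.40)
  expect_error(params_from_hematocrit(0), "between 0 and 1")
  expect_error(params_from_hematocrit(1.2), "between 0 and 1")
})

test_that("apparent viscosity follows the regularized Casson law", {
  p <- casson_params(tau_y = 0.01, mu_inf = 0.0035)
  # direct formula evaluation as oracle
  expect_equal(apparent_viscosity(1, p), (sqrt(0.01) + sqrt(0.0035))^2,
               tolerance = 1e-15)
  expect_equal(apparent_viscosity(1, p), 0.0253322, tolerance = 1e-5)
  # Newtonian limit is exact (bitwise), including at zero shear
  pn <- casson_params(tau_y = 0, mu_inf = 0.0035)
  expect_identical(apparent_viscosity(c(0, 1, 1e6), pn), rep(0.0035, 3))
  # asymptotic limit
  expect_lt(abs(apparent_viscosity(1e6, p) / p$mu_inf - 1), 0.01)
  # finite at zero shear through the floor
  expect_identical(apparent_viscosity(0, p),
                   apparent_viscosity(p$gamma_dot_min, p))
  expect_true(is.finite(apparent_viscosity(0, p)))
})

test_that("apparent viscosity is shear-thinning and bounded below by mu_inf", {
  p <- params_from_hematocrit(0.45)
  g <- 10^seq(-3, 6, length.out = 200)
  mu <- apparent_viscosity(g, p)
  expect_true(all(diff(mu) <= 0))
  expect_true(all(mu >= p$mu_inf))
})

test_that("shear rate is the second invariant of the strain rate", {
  expect_identical(shear_rate(matrix(0, 2, 2)), 0)
  # pure shear du/dy = s gives |s|
  s <- -3.7
  expect_equal(shear_rate(matrix(c(0, 0, s, 0), 2, 2)), abs(s),
               tolerance = 1e-15)
  # random tensors against the brute-force component sum
  set.seed(42)
  for (i in 1:20) {
    gmat <- matrix(rnorm(4), 2, 2)
    D <- 0.5 * (gmat + t(gmat))
    brute <- sqrt(2 * sum(D^2))
    expect_equal(shear_rate(gmat), brute, tolerance = 1e-12)
  }
})
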