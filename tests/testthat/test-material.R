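# Ogden + Prony constitutive model: relaxation curve, scaling, stress update.

simple_shear_F <- function(gamma) {
  F <- diag(3); F[1, 2] <- gamma; F
}

test_that("shear relaxation modulus hits its series limits and single-term value", {
  m <- material_model(rho = 1e-3, ogden_mu = 0.01, ogden_alpha = 2,
                      bulk_K = 50, prony_g = c(0.5, 0.3),
                      prony_tau = c(0.08, 0.8))
  g0 <- instantaneous_shear_modulus(m)
  expect_equal(shear_relaxation(m, 0), g0, tolerance = 1e-12)
  expect_equal(g0, 0.01, tolerance = 1e-12)        # sum mu*alpha/2
  ginf <- long_term_shear_modulus(m)
  expect_equal(shear_relaxation(m, 1e6 * 0.8), ginf, tolerance = 1e-9)

  m1 <- material_model(rho = 1e-3, ogden_mu = 0.01, ogden_alpha = 2,
                       bulk_K = 50, prony_g = 0.6, prony_tau = 0.5)
  # direct exponential evaluation at t = tau
  expect_equal(shear_relaxation(m1, 0.5),
               0.004 + 0.006 * exp(-1), tolerance = 1e-12)
  expect_error(shear_relaxation(m1, -0.1), "negative")
  # monotone non-increasing
  ts <- seq(0, 5, by = 0.05)
  expect_true(all(diff(shear_relaxation(m, ts)) <= 0))
})

test_that("relaxation-spectrum scaling is linear, composable, and leaves tau/K/rho alone", {
  m <- default_materials()$grey
  expect_equal(scale_relaxation(m, 1), m)
  half <- scale_relaxation(m, 0.5)
  for (t in c(0, 0.08, 0.8)) {
    expect_equal(shear_relaxation(half, t), shear_relaxation(m, t) / 2,
                 tolerance = 1e-12)
  }
  expect_identical(half$prony_tau, m$prony_tau)
  expect_identical(half$bulk_K, m$bulk_K)
  expect_identical(half$rho, m$rho)
  ab <- scale_relaxation(scale_relaxation(m, 0.7), 2)
  ab2 <- scale_relaxation(m, 1.4)
  expect_equal(ab$ogden_mu, ab2$ogden_mu, tolerance = 1e-12)
  expect_error(scale_relaxation(m, 0), "> 0")
})

test_that("reference configuration carries zero stress and inverted F errors", {
  m <- default_materials()$grey
  out <- cauchy_stress(m, diag(3), NULL, dt = 0.001)
  expect_equal(out$stress, matrix(0, 3, 3), tolerance = 1e-14)
  Fbad <- diag(c(-1, 1, 1))
  expect_error(cauchy_stress(m, Fbad), "inverted")
})

test_that("instantaneous small shear linearises to sigma12 = G0 * gamma", {
  m <- default_materials()$grey
  gam <- 1e-4
  out <- cauchy_stress(m, simple_shear_F(gam), NULL, dt = 1e-7)
  g0 <- instantaneous_shear_modulus(m)
  expect_equal(out$stress[1, 2], g0 * gam, tolerance = 1e-3)
  # deviatoric part traceless
  dev <- out$stress - diag(mean(diag(out$stress)), 3)
  expect_lt(abs(sum(diag(dev))), 1e-10)
})

test_that("held step shear relaxes along G(t)/G0 (analytic hereditary integral)", {
  m <- default_materials()$grey
  F <- simple_shear_F(0.2)
  dt <- 5e-4
  st <- NULL
  s0 <- NULL
  targets <- c(0.1, 1, 10)
  got <- numeric(0)
  t <- 0
  while (t < max(targets) + dt / 2) {
    out <- cauchy_stress(m, F, st, dt = dt)
    st <- out$state
    t <- t + dt
    if (is.null(s0)) s0 <- out$stress[1, 2]
    if (any(abs(t - targets) < dt / 2)) got <- c(got, out$stress[1, 2])
  }
  expected <- shear_relaxation(m, targets) / instantaneous_shear_modulus(m)
  expect_equal(got / s0, expected, tolerance = 0.01)
})

test_that("stress is objective under superposed rotation", {
  m <- material_model(rho = 1e-3, ogden_mu = c(0.008, 0.002),
                      ogden_alpha = c(3, -2), bulk_K = 50,
                      prony_g = 0.4, prony_tau = 0.2)
  set.seed(11)
  F <- diag(3) + matrix(rnorm(9, sd = 0.08), 3, 3)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  s1 <- cauchy_stress(m, F, NULL, dt = 1e-4)$stress
  s2 <- cauchy_stress(m, R %*% F, NULL, dt = 1e-4)$stress
  expect_equal(s2, R %*% s1 %*% t(R), tolerance = 1e-8)
})

test_that("peak stress in a constant-rate shear ramp increases with rate", {
  m <- default_materials()$grey
  peaks <- vapply(c(0.1, 1, 10), function(rate) {
    dt <- min(0.3 / rate / 200, 0.01)
    st <- NULL; peak <- 0; gam <- 0
    while (gam < 0.3) {
      gam <- min(gam + rate * dt, 0.3)
      out <- cauchy_stress(m, simple_shear_F(gam), st, dt = dt)
      st <- out$state
      peak <- max(peak, out$stress[1, 2])
    }
    peak
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("isochoric uniaxial stretch matches the closed-form Ogden solution", {
  mu <- c(0.008, 0.002); al <- c(3, -2)
  m <- material_model(rho = 1e-3, ogden_mu = mu, ogden_alpha = al,
                      bulk_K = 50)
  for (lam in c(0.8, 1.1, 1.3)) {
    F <- diag(c(lam, lam^-0.5, lam^-0.5))
    s <- cauchy_stress(m, F, NULL, dt = 1e-3)$stress
    closed <- sum(mu * (lam^al - lam^(-al / 2)))
    expect_equal(s[1, 1] - s[2, 2], closed, tolerance = 1e-10)
  }
})

test_that("grey and white matter defaults are identical; CSF is 100x softer", {
  mats <- default_materials()
  expect_identical(mats$grey[setdiff(names(mats$grey), "name")],
                   mats$white[setdiff(names(mats$white), "name")])
  expect_equal(instantaneous_shear_modulus(mats$grey) /
                 instantaneous_shear_modulus(mats$csf), 100, tolerance = 1e-12)
  expect_equal(mats$csf$bulk_K, mats$grey$bulk_K)
})

test_that("even-exponent deviatoric stress equals the closed polynomial form", {
  # mu * dev(bbar^2) / J must match the principal-stretch route at alpha = 4
  m <- material_model(rho = 1e-3, ogden_mu = 0.005, ogden_alpha = 4,
                      bulk_K = 50)
  set.seed(8)
  for (i in 1:10) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.2), 3, 3)
    if (det(F) <= 0.2) next
    J <- det(F)
    bbar <- J^(-2 / 3) * (F %*% t(F))
    poly <- 0.005 * (bbar %*% bbar -
                       diag(sum(diag(bbar %*% bbar)) / 3, 3)) / J
    spectral <- ccistrain:::.ogden_deviatoric(m, F)
    expect_equal(poly, spectral, tolerance = 1e-10)
  }
})
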