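test_that("discretisation reproduces weights, Neumann stencil and its order", {
  m <- nf_fixture("hopf2")
  s3 <- discretize(m, 3)
  expect_equal(s3$xi, c(0.5, 1, 0.5))
  expect_equal(s3$delta, 1)
  expect_error(discretize(m, 2), "at least 3")
  # constant vectors are annihilated, including at the boundary rows
  s <- discretize(m, 50)
  expect_equal(as.vector(s$L %*% rep(1, 50)), rep(0, 50), tolerance = 1e-12)
  # Neumann eigenfunctions cos(k pi (x+1)/2): second-order convergence fixes
  # the d/delta^2 prefactor (the "halved" variant carries half the
  # diffusion instead)
  for (k in 1:2) {
    errs <- vapply(c(50, 100, 200), function(nx) {
      sys <- discretize(m, nx)
      u <- cos(k * pi * (sys$x + 1) / 2)
      max(abs(as.vector(sys$L %*% u) + m$d * (k * pi / 2)^2 * u))
    }, numeric(1))
    rates <- log2(errs[-3] / errs[-1])
    expect_true(all(rates > 1.8 & rates < 2.2))
    sys <- discretize(m, 200, laplacian = "halved")
    u <- cos(k * pi * (sys$x + 1) / 2)
    expect_lt(max(abs(as.vector(sys$L %*% u) +
                        0.5 * m$d * (k * pi / 2)^2 * u)) / max(abs(u)),
              2e-3)
  }
  expect_true(all(s$tau == t(s$tau)))
  expect_equal(diag(s$tau), rep(m$tau0, 50))
  # row sums of the weighted kernel approximate the kernel integral
  direct <- vapply(s$x, function(xi) {
    integrate(function(xp) 12.5 * exp(-2 * abs(xi - xp)) -
                10 * exp(-abs(xi - xp)), -1, 1)$value
  }, numeric(1))
  expect_lt(max(abs(rowSums(s$Jw) / m$alpha - direct)), 5e-3)
})

test_that("the integrator holds the trivial equilibrium and self-converges at order 4", {
  m <- wizard_model(3, d = 0.2)
  sys <- discretize(m, 20)
  tr0 <- integrate_dde(sys, m, function(theta, x) rep(0, length(x)), 5)
  expect_equal(max(abs(tr0$u)), 0)
  expect_error(integrate_dde(sys, m, ic_phi1, 5, dt = 0.5), "tau0")
  # Richardson self-convergence at order 4 while the solution is smooth:
  # with a time-dependent smooth history and t_end below the minimal delay
  # every lookup stays in the exact history, so no breakpoints intervene
  hist_smooth <- function(theta, x) 0.2 * cos(pi * x) * (1 + 0.5 * sin(2 * theta))
  errs <- vapply(c(0.05, 0.025, 0.0125), function(dt) {
    a <- integrate_dde(sys, m, hist_smooth, 0.7, dt = dt)
    b <- integrate_dde(sys, m, hist_smooth, 0.7, dt = dt / 2)
    max(abs(a$u[nrow(a$u), ] - b$u[nrow(b$u), ]))
  }, numeric(1))
  rates <- log2(errs[-3] / errs[-1])
  expect_true(all(rates > 3.3 & rates < 4.7))
  # past the first delay horizon, derivative discontinuities propagating
  # from t = 0 (a discontinuous history/solution junction, standard for
  # delay equations) limit the observable order; convergence persists
  errs_long <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    a <- integrate_dde(sys, m, ic_phi2, 3, dt = dt)
    b <- integrate_dde(sys, m, ic_phi2, 3, dt = dt / 2)
    max(abs(a$u[nrow(a$u), ] - b$u[nrow(b$u), ]))
  }, numeric(1))
  rates_long <- log2(errs_long[-3] / errs_long[-1])
  expect_true(all(rates_long > 1.5))
})

test_that("subcritical gain sends both histories to the trivial state", {
  m <- wizard_model(3, d = 0.2)
  sys <- discretize(m, 50)
  for (ic in list(ic_phi1, ic_phi2)) {
    tr <- integrate_dde(sys, m, ic, 200, dt = 0.05)
    cl <- classify_attractor(tr)
    expect_identical(cl$class, "trivial_equilibrium")
    expect_lt(cl$sup_norm, 1e-3)
  }
})

test_that("attractor classification separates the three outcomes", {
  m <- wizard_model(3, d = 0.2)
  sys <- discretize(m, 5)
  mk <- function(vals) {
    structure(list(t = seq(0, 100, by = 0.1),
                   u = vals, system = sys, model = m, dt = 0.1),
              class = "nf_trajectory")
  }
  tt <- seq(0, 100, by = 0.1)
  zero <- mk(matrix(0, length(tt), 5))
  expect_identical(classify_attractor(zero)$class, "trivial_equilibrium")
  flat <- mk(matrix(0.4, length(tt), 5))
  expect_identical(classify_attractor(flat)$class, "nontrivial_equilibrium")
  osc <- mk(outer(sin(2 * pi * tt / 5), rep(1, 5)))
  co <- classify_attractor(osc)
  expect_identical(co$class, "oscillation")
  expect_equal(co$period, 5, tolerance = 1e-3)
  expect_equal(co$amplitude, 2, tolerance = 5e-3)  # sampled extrema
  expect_error(classify_attractor(zero, window = 1000), "window")
})
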