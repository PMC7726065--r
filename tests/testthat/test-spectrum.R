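test_that("characteristic polynomial matches its product form and is even", {
  # N = 1, d = 0: direct closed form (alpha + z)(k1^2 - s) - 2 c1 k1
  m1 <- nf_model(1.3, 0, 0.4, eta = 2, mu = 1.5, gamma = 3)
  z <- 0.2 + 0.7i
  kc <- kz_cz(m1, z)
  cf <- char_poly_coeffs(m1, z)
  expect_equal(cf,
               c((m1$alpha + z) * kc$k[1]^2 - 2 * kc$c[1] * kc$k[1],
                 -(m1$alpha + z)),
               tolerance = 1e-13)
  # random fixtures: expanded coefficients agree with product-form
  # evaluation, and P is even in rho
  for (seed in 1:6) {
    m <- random_fixture(seed, N = sample(1:2, 1))
    z <- complex(real = stats::runif(1, -2, 1),
                 imaginary = stats::runif(1, -3, 3))
    cf <- char_poly_coeffs(m, z)
    rho <- complex(real = stats::rnorm(3), imaginary = stats::rnorm(3))
    via_coeffs <- vapply(rho, function(r) {
      sum(cf * (r^2)^(seq_along(cf) - 1L))
    }, complex(1))
    direct <- neurofield:::char_poly_eval(m, z, rho)
    expect_equal(via_coeffs, direct, tolerance = 1e-10)
    expect_equal(direct, neurofield:::char_poly_eval(m, z, -rho),
                 tolerance = 1e-12)
  }
})

test_that("branch roots reproduce the reference Hopf-point roots and kill P", {
  m1 <- nf_fixture("hopf1")
  r1 <- branch_roots(m1, complex(imaginary = ref$hopf1$omega))
  expect_equal(length(r1), 2L)                  # d = 0: N roots
  expect_lt(min(Mod(r1 - ref$hopf1$rho1)), 5e-4)
  m2 <- nf_fixture("hopf2")
  r2 <- branch_roots(m2, complex(imaginary = ref$hopf2$omega))
  expect_equal(length(r2), 3L)                  # d > 0: N + 1 roots
  expect_lt(min(Mod(r2 - ref$hopf2$rho1)), 5e-4)
  for (r in list(r1, r2)) {
    expect_true(all(Re(r) > 0 | (Re(r) == 0 & Im(r) >= 0)))
  }
  pv <- neurofield:::char_poly_eval(m2, complex(imaginary = ref$hopf2$omega),
                                    c(r2, -r2))
  expect_lt(max(Mod(pv)), 1e-8)
})

test_that("parity matrices obey Schwarz reflection and the hand-built N=1 form", {
  m <- nf_model(1.2, 0.3, 0.5, eta = 3, mu = 2, gamma = 2.5)
  z <- 0.4 + 1.1i
  fr <- char_frame(m, z)
  frc <- char_frame(m, Conj(z))
  expect_equal(frc$S_even, Conj(fr$S_even), tolerance = 1e-12)
  expect_equal(frc$S_odd, Conj(fr$S_odd), tolerance = 1e-12)
  # hand expansion of the 2x2 matrices from the entry formulas
  k1 <- fr$k[1]
  rho <- fr$rho
  hand_even <- rbind((k1 * cosh(rho) + rho * sinh(rho)) / (k1^2 - rho^2),
                     rho * sinh(rho))
  hand_odd <- rbind((rho * cosh(rho) + k1 * sinh(rho)) / (k1^2 - rho^2),
                    rho * cosh(rho))
  expect_equal(fr$S_even, hand_even, tolerance = 1e-13)
  expect_equal(fr$S_odd, hand_odd, tolerance = 1e-13)
})

test_that("characteristic determinant vanishes only at the critical pair", {
  m1 <- nf_fixture("hopf1")
  lam <- complex(imaginary = ref$hopf1$omega)
  fr <- char_frame(m1, lam)
  scale_e <- neurofield:::frame_scale(fr$S_even)
  scale_o <- neurofield:::frame_scale(fr$S_odd)
  expect_lt(Mod(char_det(m1, lam, "even")) / scale_e, 1e-4)
  expect_gt(Mod(char_det(m1, lam, "odd")) / scale_o, 1e-2)
  # far in the right half-plane the determinant is bounded away from zero
  zfar <- 5 + 0i
  frf <- char_frame(m1, zfar)
  expect_gt(Mod(char_det(m1, zfar, "even")) /
              neurofield:::frame_scale(frf$S_even), 1e-6)
  # continuity in z, sampled along a shrinking offset
  z0 <- 0.3 + 0.9i
  f0 <- char_det(m1, z0, "even", frame = char_frame(m1, z0))
  hs <- 10^(-(2:5))
  diffs <- vapply(hs, function(h) {
    Mod(neurofield:::char_det_matched(m1, z0 + h, "even",
                                      char_frame(m1, z0)$rho) - f0)
  }, numeric(1))
  expect_true(all(diff(diffs) < 0))
  expect_lt(diffs[length(diffs)], 1e-3 * max(1, Mod(f0)))
})

test_that("degeneracy detection flags collisions, zero roots and clean points", {
  # duplicated kernel decay rates collide at every z
  mdup <- nf_model(1, 0.1, 0.5, eta = c(2, 3), mu = c(1.5, 1.5), gamma = 2)
  dg <- degeneracy_check(mdup, 0.3 + 0.2i)
  expect_false(dg$clean)
  expect_true("k_collision" %in% dg$reason)
  # z = -mu_j makes k_j vanish
  m <- nf_fixture("hopf2")
  dg0 <- degeneracy_check(m, -2 + 0i)
  expect_false(dg0$clean)
  expect_true("zero_root" %in% dg0$reason)
  # the critical points of the worked example are clean
  expect_true(degeneracy_check(nf_fixture("hopf1"),
                               complex(imaginary = ref$hopf1$omega))$clean)
  expect_true(degeneracy_check(m, complex(imaginary = ref$hopf2$omega))$clean)
})

test_that("essential spectrum is empty with diffusion and -alpha without", {
  expect_identical(essential_spectrum(nf_model(1, 0.2, 0.5, 1, 1, gamma = 2)),
                   numeric(0))
  expect_identical(essential_spectrum(nf_model(1, 0, 0.5, 1, 1, gamma = 2)),
                   -1)
  expect_identical(essential_spectrum(nf_model(2.5, 0, 0.5, 1, 1, gamma = 2)),
                   -2.5)
})

test_that("eigenvectors reproduce the reference coefficients and solve the field equation", {
  m1 <- nf_fixture("hopf1")
  ep1 <- eigenvector(m1, complex(imaginary = ref$hopf1$omega), "even",
                     det_tol = 1e-3)
  expect_equal(sum(Mod(ep1$coeff)^2), 1, tolerance = 1e-12)
  expect_lt(max(Mod(ep1$coeff - ref$hopf1$coeff)), 5e-4)
  # residual of the continuum eigen-equation under independent quadrature
  op <- apply_continuum_operator(m1, ep1$lambda, ep1$q, d2q = ep1$d2q)
  xs <- seq(-1, 1, length.out = 9)
  expect_lt(max(Mod(op(xs))), 1e-4 * max(Mod(ep1$q(xs))))  # gamma known to 4dp
  # at an exactly-located eigenvalue the residual tightens to the
  # quadrature level, and with diffusion the no-flux condition holds
  # analytically
  m2 <- nf_fixture("hopf2")
  sol <- neurofield:::newton_det(m2, complex(imaginary = ref$hopf2$omega),
                                 "even")
  epx <- eigenvector(m2, sol$z, "even")
  opx <- apply_continuum_operator(m2, epx$lambda, epx$q, d2q = epx$d2q)
  expect_lt(max(Mod(opx(xs))), 1e-6 * max(Mod(epx$q(xs))))
  expect_lt(Mod(epx$dq(1)), 1e-8)
  expect_lt(Mod(epx$dq(-1)), 1e-8)
})

test_that("the eigenvalue sweep is conjugate-closed and matches the small-gain limit", {
  m2 <- nf_fixture("hopf2")
  sp <- find_eigenvalues(m2, c(-1.5, 0.5), c(-5, 5), grid_density = 30)
  expect_gt(nrow(sp$table), 4)
  lams <- complex(real = sp$table$re, imaginary = sp$table$im)
  off <- lams[abs(Im(lams)) > 1e-8]
  for (l in off) expect_lt(min(Mod(Conj(l) - off)), 1e-8)
  # the critical pair is present
  expect_lt(min(Mod(lams - complex(imaginary = ref$hopf2$omega))), 1e-3)
  # gamma -> 0: eigenvalues approach the Neumann diffusion spectrum
  msmall <- set_param(m2, "gamma", 1e-4)
  spb <- find_eigenvalues(msmall, c(-3.2, 0.3), c(-0.5, 0.5),
                          grid_density = 30)
  neumann <- -1 - 0.2 * (1:2 * pi / 2)^2
  for (ev in neumann) {
    expect_lt(min(abs(spb$table$re - ev)), 0.01)
  }
})

test_that("eigenvalues vary continuously as diffusion is switched off", {
  lam0 <- complex(imaginary = ref$hopf1$omega)   # d = 0 critical pair
  prev <- lam0
  for (d in c(1e-3, 1e-2, 1e-1)) {
    m <- wizard_model(3.3482, d = d)
    sol <- neurofield:::newton_det(m, lam0, "even")
    expect_false(is.null(sol))
    expect_lt(Mod(sol$z - lam0), 0.05)
    expect_true(Mod(sol$z - lam0) >= Mod(prev - lam0) - 1e-9)
    prev <- sol$z
  }
})
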