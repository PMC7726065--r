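test_that("Fréchet derivatives collapse delays to exponential factors", {
  m <- nf_fixture("hopf2")
  lam <- complex(imaginary = ref$hopf2$omega)
  ep <- eigenvector(m, lam, "even", det_tol = 1e-3)
  # k = 2 vanishes identically for the odd sigmoid
  f2 <- frechet_k(m, 2L, list(ep$q, ep$q), c(lam, lam))
  expect_equal(f2(c(-0.5, 0, 0.5)), rep(0 + 0i, 3))
  # k = 1 on the eigenprofile is the linearised coupling operator K^lambda q
  f1 <- frechet_k(m, 1L, list(ep$q), lam)
  kc <- kz_cz(m, lam)
  direct <- vapply(c(-0.6, 0.1, 0.8), function(xi) {
    neurofield:::quad_split(function(xp) {
      colSums(kc$c * exp(-outer(kc$k, abs(xi - xp)))) * ep$q(xp)
    }, xi, 64L)
  }, complex(1))
  expect_equal(f1(c(-0.6, 0.1, 0.8)), direct, tolerance = 1e-8)
  # k = 3: against a direct dense-trapezoid evaluation of the defining
  # integral with psi(theta)(x) = e^{i omega theta} q(x)
  f3 <- frechet_k(m, 3L, list(ep$q, ep$q, function(x) Conj(ep$q(x))),
                  c(lam, lam, -lam))
  S3 <- activation_derivatives(m, 3L)
  for (xi in c(-0.4, 0.3)) {
    direct3 <- trap_quad(function(xp) {
      ke <- kernel_eval(m, rep(xi, length(xp)), xp)
      # psi(-tau)^2 conj(psi(-tau)) = e^{-lam tau} q^2 qbar for lam = i omega
      m$alpha * S3 * ke$J * exp(-lam * ke$tau) * ep$q(xp)^2 * Conj(ep$q(xp))
    }, n = 6000L)
    expect_equal(f3(xi), direct3, tolerance = 1e-6)
  }
})

test_that("quadratic centre coefficients vanish for odd activations", {
  m <- nf_fixture("hopf1")
  ep <- eigenvector(m, complex(imaginary = ref$hopf1$omega), "even",
                    det_tol = 1e-3)
  cc <- centre_coefficients(m, ep)
  expect_true(cc$zero)
  xs <- seq(-1, 1, length.out = 5)
  expect_equal(cc$h20(xs), rep(0 + 0i, 5))
  expect_equal(cc$h11(xs), rep(0 + 0i, 5))
})

test_that("quadratic centre profiles solve their homological systems", {
  # a non-odd activation supplied as a derivative table
  act <- activation_table(function(u) tanh(u) + 0.3 * u^2,
                          c(0, 1, 0.6, -2, 0, 0))
  m <- nf_model(1, 0.2, 0.75, c(12.5, -10), c(2, 1), activation = act)
  sol <- neurofield:::newton_det(m, 0 + 1.1i, "even")
  ep <- eigenvector(m, sol$z, "even")
  omega <- Im(ep$lambda)
  cc <- centre_coefficients(m, ep)
  expect_false(cc$zero)
  xs <- seq(-0.8, 0.8, length.out = 5)
  op20 <- apply_continuum_operator(m, cc$w20, cc$h20,
                                   d2q = cc$h20_field$d2q)
  resid20 <- max(Mod(op20(xs) - cc$y20(xs)))
  expect_lt(resid20, 1e-6 * max(1, max(Mod(cc$y20(xs)))))
  op11 <- apply_continuum_operator(m, cc$w11, cc$h11,
                                   d2q = cc$h11_field$d2q)
  resid11 <- max(Mod(op11(xs) - cc$y11(xs)))
  expect_lt(resid11, 1e-6 * max(1, max(Mod(cc$y11(xs)))))
  # bilinearity: doubling the eigenvector quadruples the quadratic forcings
  ep2 <- ep
  ep2$q <- function(x) 2 * ep$q(x)
  cc2 <- centre_coefficients(m, ep2)
  expect_equal(cc2$y20(xs), 4 * cc$y20(xs), tolerance = 1e-8)
  expect_equal(cc2$h11(xs), 4 * cc$h11(xs), tolerance = 1e-6)
})

test_that("the residue projection is linear and matches a Dunford contour", {
  m <- nf_fixture("hopf2")
  lam <- neurofield:::newton_det(
    m, complex(imaginary = ref$hopf2$omega), "even")$z
  ep <- eigenvector(m, lam, "even")
  y0 <- function(x) rep(0 + 0i, length(x))
  expect_equal(as.complex(residue_projection(m, lam, "even", y0,
                                             coeff = ep$coeff)), 0 + 0i)
  ya <- function(x) exp(0.3 * x) * (1 + 0.5i * x)
  yb <- function(x) cos(2 * x) + 0i
  na <- as.complex(residue_projection(m, lam, "even", ya, coeff = ep$coeff))
  nb <- as.complex(residue_projection(m, lam, "even", yb, coeff = ep$coeff))
  nab <- as.complex(residue_projection(
    m, lam, "even", function(x) 2 * ya(x) - 0.7i * yb(x), coeff = ep$coeff))
  expect_equal(nab, 2 * na - 0.7i * nb, tolerance = 1e-8)
  # 16-point trapezoid Dunford integral on a radius-0.01 circle
  th <- 2 * pi * (0:15 + 0.5) / 16
  xs <- seq(-0.9, 0.9, length.out = 5)
  acc <- rep(0 + 0i, length(xs))
  for (zz in lam + 0.01 * exp(1i * th)) {
    acc <- acc + delta_inverse(m, zz, ya)$q(xs) * (zz - lam)
  }
  contour_vals <- acc / 16
  expect_lt(max(Mod(contour_vals - na * ep$q(xs))) / max(Mod(contour_vals)),
            1e-4)
})

test_that("c1 is invariant under eigenvector phase and scales quadratically", {
  m <- nf_fixture("hopf1")
  lam <- neurofield:::newton_det(
    m, complex(imaginary = ref$hopf1$omega), "even")$z
  ep <- eigenvector(m, lam, "even")
  base <- lyapunov_coefficient(m, ep)
  expect_equal(base$l1, Re(base$c1) / base$omega)
  # rotate the eigenvector by a phase: c1 unchanged
  phi <- exp(0.7i)
  epr <- ep
  epr$coeff <- ep$coeff * phi
  epr$q <- function(x) phi * ep$q(x)
  rot <- lyapunov_coefficient(m, epr)
  expect_equal(rot$c1, base$c1, tolerance = 1e-8)
  # scale by a real factor r: c1 scales by r^2
  r <- 1.7
  eps <- ep
  eps$coeff <- ep$coeff * r
  eps$q <- function(x) r * ep$q(x)
  scl <- lyapunov_coefficient(m, eps)
  expect_equal(scl$c1, r^2 * base$c1, tolerance = 1e-7)
  # sign robustness under quadrature-order doubling
  fine <- lyapunov_coefficient(m, ep, n = 128L)
  expect_equal(fine$c1, base$c1, tolerance = 1e-6)
  expect_identical(sign(fine$l1), sign(base$l1))
})
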