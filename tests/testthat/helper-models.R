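# Shared fixtures and small oracles for the test-suite.

# reference values of the worked example (wizard-hat kernel, sigmoid gain)
ref <- list(
  hopf1 = list(gamma = 3.3482, omega = 1.2403, l1 = -0.9123,
               c1 = complex(real = -1.132, imaginary = -0.282),
               rho1 = complex(real = 0.2770, imaginary = -0.8878),
               coeff = c(complex(real = 0.9998),
                         complex(real = -0.0178, imaginary = 0.0050))),
  hopf2 = list(gamma = 3.3094, omega = 1.2379, l1 = -0.9314,
               c1 = complex(real = -1.153, imaginary = -0.258),
               rho1 = complex(real = 0.2535, imaginary = -0.8490))
)

# wizard-hat model at arbitrary gain/diffusion
wizard_model <- function(gamma, d = 0) {
  nf_model(alpha = 1, d = d, tau0 = 0.75, eta = c(12.5, -10), mu = c(2, 1),
           gamma = gamma)
}

# trapezoid quadrature on a fine uniform grid; the independent quadrature
# oracle used against the Gauss-Legendre machinery
trap_quad <- function(f, n = 4000L) {
  xs <- seq(-1, 1, length.out = n)
  w <- rep(2 / (n - 1), n)
  w[c(1, n)] <- 1 / (n - 1)
  sum(w * f(xs))
}

# dense finite-difference solve of (z + alpha) q - d q'' = y with Neumann
# conditions (one-sided ghost reflection); independent oracle for the
# Green's-function resolvent
fd_neumann_solve <- function(model, z, y, n = 2000L) {
  x <- seq(-1, 1, length.out = n)
  h <- 2 / (n - 1)
  main <- rep(z + model$alpha + 2 * model$d / h^2, n)
  A <- diag(main)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- -model$d / h^2
    A[i, i + 1] <- -model$d / h^2
  }
  A[1, 2] <- -2 * model$d / h^2
  A[n, n - 1] <- -2 * model$d / h^2
  list(x = x, q = solve(A, y(x) + 0i))
}
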