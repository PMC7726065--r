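# Brute-force finite-dimensional validation backend: the discretised
# characteristic matrix Delta_N(z) built on the same grid, trapezoid weights
# and ghost-point Laplacian as the simulator, its roots (discrete
# eigenvalues), the discrete resolvent solve, and direct quadrature
# application of the continuum operator for residual checks.

#' Discretised characteristic matrix
#'
#' `Delta_N(z) = (z + alpha) I - L - M(z)` with
#' `M(z)_{nm} = alpha delta xi_m S'(0) J(x_n, x_m) e^{-z tau_nm}`: the
#' linearisation of the discretised field evaluated on exponential solutions
#' `e^{z t}`. Shares the grid assembly with [discretize()], so spectrum
#' validation and time-domain simulation test the same discretisation.
#'
#' @param model an `nf_model`.
#' @param nx grid size (or an `nf_discrete` built from the same model).
#' @param z complex point.
#' @param laplacian stencil variant, see [discretize()].
#' @return list with complex matrices `Delta` and `dDelta` (its
#'   z-derivative) and the underlying `nf_discrete`.
#' @export
discrete_char_matrix <- function(model, nx, z,
                                 laplacian = c("standard", "halved")) {
  laplacian <- match.arg(laplacian)
  sys <- if (inherits(nx, "nf_discrete")) nx else
    discretize(model, nx, laplacian)
  n <- sys$nx
  Mz <- activation_derivatives(model, 1L) * sys$Jw * exp(-z * sys$tau)
  Delta <- diag(n) * (z + model$alpha) - sys$L - Mz
  dDelta <- diag(n) + sys$tau * Mz
  list(Delta = Delta, dDelta = dDelta, system = sys)
}

#' Roots of the discretised characteristic matrix
#'
#' Newton iteration on the log-determinant,
#' `z <- z - 1 / tr(Delta_N(z)^{-1} Delta_N'(z))`, from the supplied seeds
#' (or a grid over a rectangle). Each iteration costs one dense complex
#' solve; no determinant is ever formed, which avoids overflow for large
#' grids. Non-convergent seeds are skipped, converged roots deduplicated.
#'
#' @param model an `nf_model`.
#' @param nx grid size.
#' @param seeds complex starting points. If missing, a grid over the
#'   rectangle is used.
#' @param re_lim,im_lim rectangle for grid seeding / filtering (applied with
#'   a small margin when given).
#' @param grid_density seeds per axis when seeding from the rectangle.
#' @param laplacian stencil variant.
#' @param tol relative step-size convergence tolerance.
#' @param max_iter Newton cap per seed.
#' @param cluster_radius deduplication radius.
#' @return complex vector of roots.
#' @export
discrete_eigenvalues <- function(model, nx, seeds = NULL,
                                 re_lim = c(-3, 0.5), im_lim = c(-6, 6),
                                 grid_density = 8L,
                                 laplacian = c("standard", "halved"),
                                 tol = 1e-11, max_iter = 30L,
                                 cluster_radius = 1e-6) {
  laplacian <- match.arg(laplacian)
  sys <- discretize(model, nx, laplacian)
  if (is.null(seeds)) {
    seeds <- as.vector(outer(seq(re_lim[1], re_lim[2], length.out = grid_density),
                             1i * seq(im_lim[1], im_lim[2],
                                      length.out = grid_density), "+"))
  }
  margin <- 0.05 * max(1, abs(c(re_lim, im_lim)))
  roots <- complex(0)
  for (z0 in seeds) {
    z <- as.complex(z0)
    ok <- FALSE
    last_step <- Inf
    for (it in seq_len(max_iter)) {
      cm <- discrete_char_matrix(model, sys, z)
      tr <- sum(diag(tryCatch(solve(cm$Delta, cm$dDelta),
                              error = function(e) matrix(NA_complex_, 1, 1))))
      if (is.na(tr) || Mod(tr) == 0) {
        # a singular solve right after a small step means z sits
        # (numerically) exactly on a root
        if (last_step <= 1e-6 * max(1, Mod(z))) ok <- TRUE
        break
      }
      step <- 1 / tr
      if (Mod(step) > 1) step <- step / Mod(step)
      z <- z - step
      last_step <- Mod(step)
      if (last_step <= tol * max(1, Mod(z))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) next
    if (Re(z) < re_lim[1] - margin || Re(z) > re_lim[2] + margin ||
        Im(z) < im_lim[1] - margin || Im(z) > im_lim[2] + margin) next
    if (length(roots) && min(Mod(roots - z)) < cluster_radius) next
    roots <- c(roots, z)
  }
  roots[lex_order(roots)]
}

#' Discrete resolvent solve
#'
#' Direct linear solve `Delta_N(z) q = y` on the grid; the brute-force
#' counterpart of [delta_inverse()].
#'
#' @param model an `nf_model`.
#' @param nx grid size.
#' @param z complex point (not a discrete eigenvalue).
#' @param y forcing: vectorised function or a vector of grid values.
#' @param laplacian stencil variant.
#' @return list with `x` (grid) and `q` (complex solution values).
#' @export
discrete_resolve <- function(model, nx, z, y,
                             laplacian = c("standard", "halved")) {
  laplacian <- match.arg(laplacian)
  cm <- discrete_char_matrix(model, nx, z, laplacian)
  yg <- if (is.function(y)) y(cm$system$x) else y
  stopifnot(length(yg) == cm$system$nx)
  q <- tryCatch(solve(cm$Delta, as.complex(yg)),
                error = function(e) stop("Delta_N(z) is singular: z is ",
                                         "(numerically) a discrete eigenvalue"))
  list(x = cm$system$x, q = as.vector(q))
}

# second derivative of a black-box function by a local degree-4 polynomial
# fit; the stencil is shifted inward near the boundary so all sample points
# stay in [-1, 1]
fd_second_derivative <- function(f, x, h = 1e-3) {
  vapply(x, function(xi) {
    ctr <- min(max(xi, -1 + 2 * h), 1 - 2 * h)
    pts <- ctr + h * (-2:2)
    vals <- f(pts)
    V <- outer(pts - xi, 0:4, "^")
    cf <- solve(V, vals)
    2 * cf[3]
  }, complex(1))
}

#' Apply the continuum characteristic operator
#'
#' Returns the function `x -> (z + alpha) q(x) - d q''(x) - K^z q(x)` with
#' the delayed-coupling operator
#' `K^z q(x) = sum_j c_j(z) Int e^{-k_j(z) |x - x'|} q(x') dx'` applied by
#' quadrature split at the kink. This is the residual oracle used to verify
#' eigenpairs (result ~ 0) and the resolvent (result ~ y).
#'
#' @param model an `nf_model`.
#' @param z complex point.
#' @param q vectorised function on `[-1, 1]`.
#' @param d2q optional analytic second derivative of `q`; when missing (and
#'   `d > 0`) it is obtained by a local polynomial fit.
#' @param n quadrature nodes per smooth piece.
#' @return vectorised complex function of x.
#' @export
apply_continuum_operator <- function(model, z, q, d2q = NULL, n = 64L) {
  kc <- kz_cz(model, z)
  z <- as.complex(z)
  Kq <- function(x) {
    vapply(x, function(xi) {
      quad_split(function(xp) {
        colSums(kc$c * exp(-outer(kc$k, abs(xi - xp)))) * q(xp)
      }, xi, n)
    }, complex(1))
  }
  function(x) {
    diff_term <- if (model$d == 0) 0 + 0i else {
      model$d * (if (is.null(d2q)) fd_second_derivative(q, x) else d2q(x))
    }
    (z + model$alpha) * q(x) - diff_term - Kq(x)
  }
}
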