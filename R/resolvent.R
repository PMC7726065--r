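# Resolvent machinery: the diffusion-operator resolvent R(z, B) via the
# Neumann Green's function, the hat-matrix workspace, and the explicit
# characteristic-operator resolvent q = Delta^{-1}(z) y by the
# variation-of-constants construction
#
#   q(x) = R(z,B)y(x) + sum_m [a_m(x) cosh(rho_m x) + b_m(x) sinh(rho_m x)],
#
# with a(x), b(x) given by sgn-split integrals of (S-hat, C-hat) K-hat^{-1}
# R-hat y plus coupling through (S^even)^{-1} S^odd and (S^odd)^{-1} S^even.

#' Resolvent of the diffusion-decay operator
#'
#' Solves `(z + alpha) q - d q'' = y` with no-flux conditions `q'(+-1) = 0`.
#' For `d = 0` this is simply `y / (z + alpha)`. For `d > 0` the Neumann
#' Green's function with `beta = sqrt((z + alpha)/d)` (principal branch; the
#' kernel is even in `beta`, so the branch choice is immaterial) is
#'
#'   `G(x, x') = cosh(beta (1 + x_<)) cosh(beta (1 - x_>)) /
#'               (d beta sinh(2 beta))`,
#'
#' applied by Gauss-Legendre quadrature split at the kink `x' = x`.
#'
#' @param model an `nf_model`.
#' @param z complex point with `z` outside the spectrum of B
#'   (`{-alpha - d (k pi / 2)^2}` for `d > 0`, `{-alpha}` for `d = 0`).
#' @param y vectorised function on `[-1, 1]` (may be complex-valued).
#' @param n quadrature nodes per smooth piece.
#' @return vectorised function `q(x)`.
#' @export
diffusion_resolvent <- function(model, z, y, n = 64L) {
  stopifnot(inherits(model, "nf_model"), is.function(y))
  z <- as.complex(z)
  if (model$d == 0) {
    if (Mod(z + model$alpha) < 1e-12) {
      stop("z is in the spectrum of B (z = -alpha)")
    }
    force(y)
    return(function(x) y(x) / (z + model$alpha))
  }
  beta <- sqrt((z + model$alpha) / model$d)
  sh2b <- sinh(2 * beta)
  if (Mod(sh2b) < 1e-12 * max(1, Mod(exp(2 * Re(beta))))) {
    stop("z is (numerically) in the spectrum of B")
  }
  green_resolvent(model, z, y, n)$f
}

#' Hat-matrix workspace of the resolvent construction
#'
#' Builds the Cauchy-like matrix `Q-hat` (`1/(k_j^2 - rho_m^2)` for the
#' kernel rows, ones for the boundary row present when `d > 0`, with the
#' convention `k_{N+1} = 1`), its row/column scalings `M-hat` (rows by `k_j`)
#' and `K-hat` (columns by `rho_m`), and the diagonal hyperbolic matrices
#' `C-hat(x)`, `S-hat(x)` returned as vector-valued functions. The
#' determinant identities `det(M-hat) = det(Q-hat) prod k_j` and
#' `det(K-hat) = det(Q-hat) prod rho_m` hold by construction and are
#' asserted in the test-suite.
#'
#' @param frame an `nf_frame` (not degenerate).
#' @return list with `Qhat`, `Khat`, `Mhat`, `kvec`, `rho`, and functions
#'   `Chat(x)`, `Shat(x)` returning the diagonal vectors.
#' @export
hat_matrices <- function(frame) {
  stopifnot(inherits(frame, "nf_frame"))
  if (frame$degenerate) stop("degenerate frame: hat matrices are singular")
  rho <- frame$rho
  M <- length(rho)
  N <- length(frame$k)
  Qhat <- matrix(0 + 0i, M, M)
  for (j in seq_len(N)) Qhat[j, ] <- 1 / (frame$k[j]^2 - rho^2)
  kvec <- frame$k
  if (M == N + 1L) {                  # boundary row (d > 0), k_{N+1} := 1
    Qhat[M, ] <- 1 + 0i
    kvec <- c(frame$k, 1 + 0i)
  }
  Khat <- Qhat * matrix(rho, M, M, byrow = TRUE)
  Mhat <- Qhat * kvec
  list(Qhat = Qhat, Khat = Khat, Mhat = Mhat, kvec = kvec, rho = rho,
       Chat = function(x) cosh(rho * x), Shat = function(x) sinh(rho * x))
}

# Green's-function evaluation of R(z,B)y together with its first derivative;
# the second derivative follows exactly from (z + alpha) Ry - d Ry'' = y
green_resolvent <- function(model, z, y, n = 64L) {
  beta <- sqrt((z + model$alpha) / model$d)
  sh2b <- sinh(2 * beta)
  denom_f <- model$d * beta * sh2b
  denom_d <- model$d * sh2b
  eval_LR <- function(xi) {
    L <- if (xi > -1) {
      g <- gl_nodes(n, -1, xi)
      sum(g$w * cosh(beta * (1 + g$x)) * y(g$x))
    } else 0 + 0i
    R <- if (xi < 1) {
      g <- gl_nodes(n, xi, 1)
      sum(g$w * cosh(beta * (1 - g$x)) * y(g$x))
    } else 0 + 0i
    c(L, R)
  }
  list(
    f = function(x) vapply(x, function(xi) {
      lr <- eval_LR(xi)
      (cosh(beta * (1 - xi)) * lr[1] + cosh(beta * (1 + xi)) * lr[2]) / denom_f
    }, complex(1)),
    df = function(x) vapply(x, function(xi) {
      lr <- eval_LR(xi)
      (-sinh(beta * (1 - xi)) * lr[1] + sinh(beta * (1 + xi)) * lr[2]) / denom_d
    }, complex(1))
  )
}

# shared set-up for delta_inverse and residue_projection: frame, hat
# workspace, the constant direction u = K-hat^{-1} w0 (the x-dependence of
# R-hat y factorises as R(z,B)y(x) * w0), and R(z,B)y with its derivatives
# (value and slope splined on a fine grid when d > 0 so repeated evaluation
# is O(1); the curvature comes exactly from the defining ODE and is immune
# to spline differentiation error)
resolvent_workspace <- function(model, z, y, n = 64L, spline_grid = 401L) {
  frame <- char_frame(model, z)
  if (frame$degenerate) {
    stop("z is in the degeneracy set: ",
         paste(frame$degeneracy$reason, collapse = ", "))
  }
  if (model$d > 0) {
    gr <- green_resolvent(model, z, y, n)
    xs <- seq(-1, 1, length.out = spline_grid)
    vals <- gr$f(xs)
    dvals <- gr$df(xs)
    fre <- stats::splinefun(xs, Re(vals))
    fim <- stats::splinefun(xs, Im(vals))
    dre <- stats::splinefun(xs, Re(dvals))
    dim_ <- stats::splinefun(xs, Im(dvals))
    Ry <- function(x) complex(real = fre(x), imaginary = fim(x))
    dRy <- function(x) complex(real = dre(x), imaginary = dim_(x))
    d2Ry <- function(x) ((z + model$alpha) * Ry(x) - y(x)) / model$d
  } else {
    if (Mod(z + model$alpha) < 1e-12) stop("z is in the spectrum of B")
    Ry <- function(x) y(x) / (z + model$alpha)
    dRy <- NULL
    d2Ry <- NULL
  }
  hat <- hat_matrices(frame)
  M <- length(frame$rho)
  w0 <- rep(1 + 0i, M)
  if (model$d > 0) w0[M] <- 0 + 0i
  u <- solve(hat$Khat, w0)
  list(frame = frame, hat = hat, u = u, Ry = Ry, dRy = dRy, d2Ry = d2Ry)
}

#' Explicit resolvent of the characteristic operator
#'
#' Computes `q = Delta^{-1}(z) y`, the unique solution of
#' `(z + alpha) q - d q'' - K^z q = y` in the domain of B, for `z` in the
#' resolvent set and outside the degeneracy set. The coefficient functions
#' are
#'
#'   `a(x) = 1/2 Int [sgn(x - x') S-hat(x')
#'            + (S^even)^{-1} S^odd C-hat(x')] K-hat^{-1} R-hat y(x') dx'`
#'
#' and the sign-flipped counterpart for `b(x)`; the sgn factor is handled by
#' splitting the quadrature at `x`.
#'
#' @param model an `nf_model`.
#' @param z complex point in the resolvent set, not degenerate.
#' @param y vectorised function on `[-1, 1]`.
#' @param n quadrature nodes per smooth piece.
#' @param det_tol relative determinant tolerance below which `z` is treated
#'   as an eigenvalue and refused.
#' @return object of class `nf_resolvent_field`: vectorised functions `q`,
#'   `a`, `b` (the latter two return a matrix with one column per
#'   evaluation point), the `frame`, and the moment vectors `IC`, `IS`.
#' @export
delta_inverse <- function(model, z, y, n = 64L, det_tol = 1e-10) {
  ws <- resolvent_workspace(model, z, y, n)
  frame <- ws$frame
  for (parity in c("even", "odd")) {
    S <- if (parity == "even") frame$S_even else frame$S_odd
    if (Mod(cdet(S)) / frame_scale(S) < det_tol) {
      stop("z is (numerically) an eigenvalue (singular S^{z,", parity,
           "}); the resolvent does not exist")
    }
  }
  rho <- frame$rho
  u <- ws$u
  Ry <- ws$Ry
  E_even <- solve(frame$S_even, frame$S_odd)
  E_odd <- solve(frame$S_odd, frame$S_even)
  g <- gl_nodes(n, -1, 1)
  wRy <- g$w * Ry(g$x)
  IC <- as.vector(cosh(outer(rho, g$x)) %*% wRy) * u
  IS <- as.vector(sinh(outer(rho, g$x)) %*% wRy) * u
  half_int <- function(xi, hyp) {
    # integral over [-1, xi] minus integral over [xi, 1] of hyp(rho x') u Ry
    lo <- if (xi > -1) {
      gg <- gl_nodes(n, -1, xi)
      as.vector(hyp(outer(rho, gg$x)) %*% (gg$w * Ry(gg$x))) * u
    } else rep(0 + 0i, length(rho))
    hi <- if (xi < 1) {
      gg <- gl_nodes(n, xi, 1)
      as.vector(hyp(outer(rho, gg$x)) %*% (gg$w * Ry(gg$x))) * u
    } else rep(0 + 0i, length(rho))
    lo - hi
  }
  afun <- function(x) {
    vapply(x, function(xi) 0.5 * (half_int(xi, sinh) + as.vector(E_even %*% IC)),
           complex(length(rho)))
  }
  bfun <- function(x) {
    vapply(x, function(xi) -0.5 * (half_int(xi, cosh) + as.vector(E_odd %*% IS)),
           complex(length(rho)))
  }
  qfun <- function(x) {
    a <- matrix(afun(x), nrow = length(rho))
    b <- matrix(bfun(x), nrow = length(rho))
    ch <- cosh(outer(rho, x))
    sh <- sinh(outer(rho, x))
    Ry(x) + colSums(a * ch) + colSums(b * sh)
  }
  # first and second derivatives in closed form: the a'(x), b'(x) relations
  # make sum(a' cosh + b' sinh) vanish and collapse the remaining derivative
  # terms to -Ry(x) sum(rho_m u_m)
  dqfun <- if (model$d > 0) function(x) {
    a <- matrix(afun(x), nrow = length(rho))
    b <- matrix(bfun(x), nrow = length(rho))
    ch <- cosh(outer(rho, x))
    sh <- sinh(outer(rho, x))
    ws$dRy(x) + colSums((rho * a) * sh) + colSums((rho * b) * ch)
  } else NULL
  d2qfun <- if (model$d > 0) function(x) {
    a <- matrix(afun(x), nrow = length(rho))
    b <- matrix(bfun(x), nrow = length(rho))
    ch <- cosh(outer(rho, x))
    sh <- sinh(outer(rho, x))
    ws$d2Ry(x) + colSums((rho^2 * a) * ch) + colSums((rho^2 * b) * sh) -
      Ry(x) * sum(rho * u)
  } else NULL
  structure(list(q = qfun, dq = dqfun, d2q = d2qfun, a = afun, b = bfun,
                 frame = frame, IC = IC, IS = IS, Ry = Ry),
            class = "nf_resolvent_field")
}
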