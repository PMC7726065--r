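# Method-of-steps simulator for the spatially discretised field.
#
# The domain is discretised on an equidistant grid with trapezoid quadrature
# weights for the coupling integral and a ghost-point (reflection) central
# difference for the Neumann Laplacian. The resulting set of nx delay
# differential equations is integrated with a fixed-step 4-stage Lawson
# (integrating-factor) Runge-Kutta scheme: the stiff linear part L - alpha I
# is propagated exactly through precomputed matrix exponentials, so the step
# size is not limited by the diffusion CFL constraint, while the smooth
# delayed coupling is handled by the classical RK4 tableau at full fourth
# order. Delayed values are read from a cubic-Hermite dense interpolant of
# the stored trajectory, which matches the O(dt^4) accuracy of the
# integrator. Because the minimal delay is tau0, any dt <= tau0 keeps all
# delayed lookups strictly behind the current step (method of steps).

#' Spatial discretisation of the model
#'
#' Builds the equidistant grid on `[-1, 1]`, the trapezoid weights
#' (`1/2` at both ends, `1` inside), the delay matrix
#' `tau0 + |x_n - x_m|`, the weighted kernel matrix and the Neumann
#' Laplacian stencil with ghost-point reflection (boundary rows
#' `2 (u_neighbour - u_self)`).
#'
#' The Laplacian prefactor is `d / delta^2` for `laplacian = "standard"`
#' (the second-order stencil consistent with the continuum operator, the
#' default) or `d / (2 delta^2)` for `laplacian = "halved"`; the latter
#' halves the effective diffusion and is retained as a switch for
#' comparison. A convergence test against the Neumann eigenfunctions
#' discriminates between the two.
#'
#' @param model an `nf_model`.
#' @param nx grid size, at least 3.
#' @param laplacian `"standard"` or `"halved"` prefactor variant.
#' @return object of class `nf_discrete`: `x`, `delta`, `xi`, `J`, `tau`,
#'   `L` (Laplacian including the `d` prefactor), `Jw` (coupling weights
#'   `alpha delta xi_m J(x_n, x_m)`), `lag_index`, `nx`, `laplacian`.
#' @export
discretize <- function(model, nx, laplacian = c("standard", "halved")) {
  laplacian <- match.arg(laplacian)
  stopifnot(inherits(model, "nf_model"))
  if (nx < 3L) stop("nx must be at least 3")
  x <- seq(-1, 1, length.out = nx)
  delta <- 2 / (nx - 1)
  xi <- rep(1, nx)
  xi[c(1L, nx)] <- 0.5
  r <- abs(outer(x, x, "-"))
  J <- matrix(0, nx, nx)
  for (j in seq_len(model$N)) J <- J + model$eta[j] * exp(-model$mu[j] * r)
  tau <- model$tau0 + r
  scale <- if (laplacian == "standard") model$d / delta^2 else
    model$d / (2 * delta^2)
  L <- matrix(0, nx, nx)
  for (i in 2:(nx - 1L)) {
    L[i, i - 1L] <- scale
    L[i, i] <- -2 * scale
    L[i, i + 1L] <- scale
  }
  L[1L, 1L] <- -2 * scale
  L[1L, 2L] <- 2 * scale
  L[nx, nx] <- -2 * scale
  L[nx, nx - 1L] <- 2 * scale
  Jw <- model$alpha * delta * J * matrix(xi, nx, nx, byrow = TRUE)
  lag <- abs(outer(seq_len(nx), seq_len(nx), "-"))     # delay = tau0 + delta*lag
  lag_index <- lag + 1L + (col(lag) - 1L) * nx         # linear index into V
  structure(list(x = x, delta = delta, xi = xi, J = J, tau = tau, L = L,
                 Jw = Jw, lag_index = lag_index, nx = nx,
                 laplacian = laplacian, model = model),
            class = "nf_discrete")
}

#' Built-in initial histories
#'
#' The odd history `phi1 = sin(pi x / 2) / 5`, the even history
#' `phi2 = cos(pi x) / 5` and their sum `phi3`, all constant in the time
#' argument.
#'
#' @param theta time argument in `[-h, 0]` (unused; the histories are
#'   constant in time).
#' @param x positions.
#' @return numeric vector of the history values.
#' @export
ic_phi1 <- function(theta, x) 0.2 * sin(0.5 * pi * x)

#' @rdname ic_phi1
#' @export
ic_phi2 <- function(theta, x) 0.2 * cos(pi * x)

#' @rdname ic_phi1
#' @export
ic_phi3 <- function(theta, x) ic_phi1(theta, x) + ic_phi2(theta, x)

#' Integrate the discretised delay system
#'
#' Fixed-step 4-stage Lawson (integrating-factor) Runge-Kutta with exact
#' propagation of the linear diffusion-decay part and cubic-Hermite dense
#' output for delayed lookups. The step must satisfy `dt <= tau0 / 2` so
#' that all delayed evaluations fall strictly into the stored history
#' (method of steps); the default is `min(0.05, tau0 / 4)`.
#'
#' @param system an `nf_discrete`.
#' @param model the `nf_model` the system was built from (activation and
#'   decay are read from here, so gain sweeps can reuse one discretisation
#'   of the same kernel geometry).
#' @param history function `phi(theta, x)` on `[-h, 0]`, vectorised in `x`.
#' @param t_end final time, positive.
#' @param dt step size.
#' @return object of class `nf_trajectory`: times `t`, state matrix `u`
#'   (rows = times), derivative matrix `f`, plus `system`, `model`, `dt`,
#'   `history`.
#' @export
integrate_dde <- function(system, model, history, t_end,
                          dt = min(0.05, model$tau0 / 4)) {
  stopifnot(inherits(system, "nf_discrete"), is.function(history),
            t_end > 0, dt > 0)
  if (model$tau0 <= 0) {
    stop("the method-of-steps integrator requires tau0 > 0")
  }
  if (dt > model$tau0 / 2 + 1e-12) {
    stop("dt must not exceed tau0 / 2 (method of steps)")
  }
  nx <- system$nx
  x <- system$x
  Sfun <- model$activation$fun
  alpha <- model$alpha
  L <- system$L
  Jw <- system$Jw
  lag_index <- system$lag_index
  taus <- model$tau0 + system$delta * (seq_len(nx) - 1L)
  nsteps <- ceiling(t_end / dt - 1e-9)
  U <- matrix(NA_real_, nsteps + 1L, nx)
  F <- matrix(NA_real_, nsteps + 1L, nx)
  # lagged full-state vectors at times s = t - tau_k for all distinct lags
  lagged_states <- function(t, k_now) {
    s <- t - taus
    V <- matrix(0, nx, nx)                 # row k: state at lag (k-1)*delta
    neg <- s <= 1e-12
    if (any(neg)) {
      for (k in which(neg)) V[k, ] <- history(s[k], x)
    }
    if (any(!neg)) {
      k <- which(!neg)
      i <- pmin(pmax(floor(s[k] / dt + 1e-12), 0), k_now - 1L)
      th <- s[k] / dt - i
      h00 <- (1 + 2 * th) * (1 - th)^2
      h10 <- th * (1 - th)^2
      h01 <- th^2 * (3 - 2 * th)
      h11 <- th^2 * (th - 1)
      V[k, ] <- h00 * U[i + 1L, , drop = FALSE] +
        h01 * U[i + 2L, , drop = FALSE] +
        dt * (h10 * F[i + 1L, , drop = FALSE] +
                h11 * F[i + 2L, , drop = FALSE])
    }
    V
  }
  # delayed coupling g(t, .); the full derivative A u + g is what gets stored
  # for the Hermite interpolant
  gfun <- function(t, k_now) {
    V <- lagged_states(t, k_now)
    D <- matrix(V[lag_index], nx, nx)      # D[n, m] = u(t - tau_nm, x_m)
    rowSums(Jw * Sfun(D))
  }
  A <- L - alpha * diag(nx)
  E1 <- as.matrix(Matrix::expm(A * (dt / 2)))
  E2 <- E1 %*% E1
  U[1L, ] <- history(0, x)
  F[1L, ] <- as.vector(A %*% U[1L, ]) + gfun(0, 0L)
  for (k in seq_len(nsteps)) {
    t0 <- (k - 1L) * dt
    u0 <- U[k, ]
    g1 <- F[k, ] - as.vector(A %*% u0)
    g2 <- gfun(t0 + dt / 2, k - 1L)        # the coupling depends on history
    g3 <- g2                               # only, so stages 2 and 3 coincide
    g4 <- gfun(t0 + dt, k - 1L)
    u1 <- as.vector(E2 %*% (u0 + dt / 6 * g1) +
                      E1 %*% ((dt / 6) * (2 * g2 + 2 * g3)) +
                      (dt / 6) * g4)
    if (any(!is.finite(u1))) {
      stop("solution blew up at t = ", format(t0 + dt))
    }
    U[k + 1L, ] <- u1
    F[k + 1L, ] <- as.vector(A %*% u1) + gfun(t0 + dt, k)
  }
  structure(list(t = dt * (0:nsteps), u = U, f = F, system = system,
                 model = model, dt = dt, history = history),
            class = "nf_trajectory")
}

#' Classify the long-time attractor of a trajectory
#'
#' Over the final `window` time units: a trajectory with sup-norm below
#' `eq_tol` is at the trivial equilibrium; one whose temporal oscillation
#' amplitude (max minus min per node, maximised over nodes) stays below
#' `drift_tol` while the sup-norm does not is at a nontrivial equilibrium;
#' anything else is classified as an oscillation, with the amplitude and
#' the dominant period (mean spacing of upward zero crossings of the
#' mean-removed signal at the most active node) reported.
#'
#' @param traj an `nf_trajectory`.
#' @param window length of the classification window (time units).
#' @param eq_tol sup-norm tolerance for the trivial equilibrium.
#' @param drift_tol amplitude tolerance for a (nontrivial) equilibrium.
#' @return list with `class` (one of `"trivial_equilibrium"`,
#'   `"nontrivial_equilibrium"`, `"oscillation"`), `sup_norm`, `amplitude`,
#'   `period` (NA unless oscillating).
#' @export
classify_attractor <- function(traj, window = 20, eq_tol = 1e-3,
                               drift_tol = 1e-3) {
  stopifnot(inherits(traj, "nf_trajectory"))
  t_end <- traj$t[length(traj$t)]
  if (window > t_end) stop("window longer than the trajectory")
  sel <- traj$t >= t_end - window
  uw <- traj$u[sel, , drop = FALSE]
  sup <- max(abs(uw))
  amps <- apply(uw, 2L, function(col) max(col) - min(col))
  amplitude <- max(amps)
  if (sup < eq_tol) {
    return(list(class = "trivial_equilibrium", sup_norm = sup,
                amplitude = amplitude, period = NA_real_))
  }
  if (amplitude < drift_tol) {
    return(list(class = "nontrivial_equilibrium", sup_norm = sup,
                amplitude = amplitude, period = NA_real_))
  }
  node <- which.max(amps)
  yy <- uw[, node] - mean(uw[, node])
  tt <- traj$t[sel]
  up <- which(yy[-length(yy)] < 0 & yy[-1] >= 0)
  period <- if (length(up) >= 2L) {
    # refine crossing times by linear interpolation
    tc <- tt[up] + (tt[up + 1L] - tt[up]) * (-yy[up]) / (yy[up + 1L] - yy[up])
    mean(diff(tc))
  } else NA_real_
  list(class = "oscillation", sup_norm = sup, amplitude = amplitude,
       period = period)
}
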