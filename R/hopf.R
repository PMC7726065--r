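# Hopf-point location: damped Newton on the two real equations
# Re det S^{i omega, parity} = Im det S^{i omega, parity} = 0 in the pair
# (free parameter, omega), followed by eigenvector construction, the centre
# coefficients and the first Lyapunov coefficient. Also natural-parameter
# continuation of eigenvalue branches.

# scaled determinant at (param value p, frequency omega); NA when degenerate
hopf_F <- function(model, free_param, p, omega, parity) {
  mp <- tryCatch(set_param(model, free_param, p), error = function(e) NULL)
  if (is.null(mp)) return(NA_complex_)
  fr <- tryCatch(char_frame(mp, complex(imaginary = omega)),
                 error = function(e) NULL)
  if (is.null(fr) || fr$degenerate) return(NA_complex_)
  S <- if (parity == "even") fr$S_even else fr$S_odd
  cdet(S) / frame_scale(S)
}

#' Locate a Hopf point in one free parameter
#'
#' Solves `det S^{i omega, parity} = 0` jointly for the free parameter and
#' the frequency `omega` by damped Newton iteration (Jacobian by central
#' differences, step halving up to 8 times). On convergence the critical
#' eigenpair is built, the quadratic centre coefficients and the first
#' Lyapunov coefficient are computed, and the transversality speed
#' `d Re(lambda) / d p` is estimated by continuing the critical eigenvalue
#' to `p* +- dp`.
#'
#' @param model an `nf_model` (base parameter values).
#' @param free_param one of `"gamma"`, `"d"`, `"tau0"`, `"alpha"`,
#'   `"eta<j>"`, `"mu<j>"`.
#' @param guess numeric length-2: initial `(parameter, omega)`.
#' @param parity parity of the vanishing determinant (user-declared; even
#'   and odd determinants can vanish at different nearby parameters).
#' @param tol convergence tolerance on the scaled determinant.
#' @param max_iter Newton iteration cap.
#' @param dp offset used for the transversality estimate.
#' @return object of class `nf_hopf`: `free_param`, `value`, `omega`,
#'   `model` (at the critical parameter), `eigenpair`, `centre`, `c1`, `l1`,
#'   `transversality`, `iterations`, `residual`.
#' @export
hopf_find <- function(model, free_param = "gamma", guess = c(3, 1),
                      parity = c("even", "odd"), tol = 1e-10,
                      max_iter = 60L, dp = 1e-2) {
  parity <- match.arg(parity)
  p <- guess[1]
  omega <- guess[2]
  f <- hopf_F(model, free_param, p, omega, parity)
  if (is.na(f)) stop("initial guess lies in the degeneracy set")
  trace <- data.frame(iter = 0L, p = p, omega = omega, fnorm = Mod(f))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    hp <- 1e-6 * max(1, abs(p))
    hw <- 1e-6 * max(1, abs(omega))
    dfp <- (hopf_F(model, free_param, p + hp, omega, parity) -
              hopf_F(model, free_param, p - hp, omega, parity)) / (2 * hp)
    dfw <- (hopf_F(model, free_param, p, omega + hw, parity) -
              hopf_F(model, free_param, p, omega - hw, parity)) / (2 * hw)
    J <- matrix(c(Re(dfp), Re(dfw), Im(dfp), Im(dfw)), 2L, 2L, byrow = TRUE)
    rhs <- -c(Re(f), Im(f))
    step <- tryCatch(solve(J, rhs), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      stop("singular Jacobian in the Hopf Newton iteration; trace:\n",
           paste(utils::capture.output(print(trace)), collapse = "\n"))
    }
    lam_ok <- FALSE
    for (halving in 0:8) {                    # damping by step halving
      pn <- p + step[1] / 2^halving
      wn <- omega + step[2] / 2^halving
      fn <- hopf_F(model, free_param, pn, wn, parity)
      if (!is.na(fn) && Mod(fn) < Mod(f)) {
        lam_ok <- TRUE
        break
      }
    }
    if (!lam_ok) {                            # accept the full step once near
      pn <- p + step[1]
      wn <- omega + step[2]
      fn <- hopf_F(model, free_param, pn, wn, parity)
      if (is.na(fn)) {
        stop("Hopf Newton iteration diverged into the degeneracy set; ",
             "trace:\n",
             paste(utils::capture.output(print(trace)), collapse = "\n"))
      }
    }
    p <- pn
    omega <- wn
    f <- fn
    trace <- rbind(trace, data.frame(iter = it, p = p, omega = omega,
                                     fnorm = Mod(f)))
    if (Mod(f) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop("Hopf Newton iteration did not converge; trace:\n",
         paste(utils::capture.output(print(trace)), collapse = "\n"))
  }
  if (abs(omega) < 1e-6) {
    warning("omega collapsed to 0: this is a fold, not a Hopf point")
  }
  omega <- abs(omega)
  mstar <- set_param(model, free_param, p)
  ep <- eigenvector(mstar, complex(imaginary = omega), parity)
  centre <- centre_coefficients(mstar, ep)
  ly <- lyapunov_coefficient(mstar, ep, centre)
  # transversality: continue the critical eigenvalue across p*
  lam_side <- function(pp) {
    sol <- newton_det(set_param(model, free_param, pp),
                      complex(imaginary = omega), parity)
    if (is.null(sol)) NA_complex_ else sol$z
  }
  lp <- lam_side(p + dp)
  lm <- lam_side(p - dp)
  transversality <- if (is.na(lp) || is.na(lm)) NA_real_ else
    (Re(lp) - Re(lm)) / (2 * dp)
  structure(list(free_param = free_param, value = p, omega = omega,
                 model = mstar, eigenpair = ep, centre = centre,
                 c1 = ly$c1, l1 = ly$l1, transversality = transversality,
                 iterations = it, residual = Mod(f), trace = trace),
            class = "nf_hopf")
}

#' @export
print.nf_hopf <- function(x, ...) {
  cat(sprintf("Hopf point: %s = %.6f, omega = %.6f (lambda = %si)\n",
              x$free_param, x$value, x$omega, format(x$omega, digits = 6)))
  cat(sprintf("  c1 = %s, l1 = %.6f (%s)\n", format(x$c1, digits = 5), x$l1,
              if (x$l1 < 0) "supercritical" else "subcritical"))
  cat(sprintf("  transversality d Re(lambda)/d %s = %s\n", x$free_param,
              format(x$transversality, digits = 4)))
  invisible(x)
}

#' Continuation of eigenvalue branches across a parameter grid
#'
#' Natural-parameter continuation: eigenvalues found in a rectangle at the
#' first grid value are followed across the grid by Newton refinement
#' seeded at the previous value, with nearest-root matching. A branch that
#' fails to converge (or jumps beyond the matching radius) records a gap
#' (NA row) and is dropped from further continuation; this is never fatal.
#'
#' @param model an `nf_model`.
#' @param free_param parameter name as in [set_param()].
#' @param param_grid numeric vector of parameter values.
#' @param re_lim,im_lim rectangle used for the initial eigenvalue sweep.
#' @param grid_density seed density of the initial sweep.
#' @param match_radius maximal step between consecutive branch points.
#' @return data.frame with columns `param`, `branch`, `re`, `im`, `parity`.
#' @export
eigenvalue_branch <- function(model, free_param, param_grid,
                              re_lim = c(-3, 0.5), im_lim = c(-6, 6),
                              grid_density = 10L, match_radius = 0.5) {
  if (length(param_grid) == 0L) {
    return(data.frame(param = numeric(0), branch = integer(0),
                      re = numeric(0), im = numeric(0),
                      parity = character(0)))
  }
  m1 <- set_param(model, free_param, param_grid[1])
  sp <- find_eigenvalues(m1, re_lim, im_lim, grid_density)
  if (!nrow(sp$table)) {
    return(data.frame(param = numeric(0), branch = integer(0),
                      re = numeric(0), im = numeric(0),
                      parity = character(0)))
  }
  lambdas <- complex(real = sp$table$re, imaginary = sp$table$im)
  parities <- sp$table$parity
  rows <- data.frame(param = param_grid[1], branch = seq_along(lambdas),
                     re = Re(lambdas), im = Im(lambdas), parity = parities)
  alive <- rep(TRUE, length(lambdas))
  for (pv in param_grid[-1]) {
    mp <- set_param(model, free_param, pv)
    for (b in which(alive)) {
      sol <- newton_det(mp, lambdas[b], parities[b])
      if (is.null(sol) || Mod(sol$z - lambdas[b]) > match_radius) {
        rows <- rbind(rows, data.frame(param = pv, branch = b, re = NA_real_,
                                       im = NA_real_, parity = parities[b]))
        alive[b] <- FALSE
      } else {
        lambdas[b] <- sol$z
        rows <- rbind(rows, data.frame(param = pv, branch = b,
                                       re = Re(sol$z), im = Im(sol$z),
                                       parity = parities[b]))
      }
    }
  }
  rows
}
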