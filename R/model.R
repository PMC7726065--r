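# Model definition: continuum neural field on Omega = [-1, 1]
#
#   du/dt = d u_xx - alpha u + alpha Int J(x,x') S(u(t - tau(x,x'), x')) dx'
#
# with no-flux (Neumann) boundary conditions when d > 0, connectivity kernel
# J(x,x') = sum_j eta_j exp(-mu_j |x - x'|), distance-dependent delay
# tau(x,x') = tau0 + |x - x'| (propagation speed normalised to 1), and a
# smooth activation S with S(0) = 0.

#' Shifted sigmoid activation
#'
#' The activation `S(u) = 1/(1 + exp(-gamma u)) - 1/2 = tanh(gamma u / 2) / 2`,
#' an odd function with `S(0) = 0`, `S'(0) = gamma/4`, `S''(0) = 0`,
#' `S'''(0) = -gamma^3/8`. The gain `gamma` is the standard bifurcation
#' parameter of the model.
#'
#' @param gamma sigmoid gain, positive.
#' @return object of class `nf_activation`: list with the callable `fun`,
#'   the derivative values `derivs` (orders 0..5 at 0) and `gamma`.
#' @export
#' @examples
#' act <- sigmoid_activation(4)
#' act$fun(0)                      # 0
#' activation_derivatives(act, 1)  # gamma / 4 = 1
sigmoid_activation <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma), gamma > 0)
  structure(
    list(
      fun = function(u) 0.5 * tanh(gamma * u / 2),
      derivs = c(0, gamma / 4, 0, -gamma^3 / 8, 0, gamma^5 / 4),
      gamma = gamma
    ),
    class = "nf_activation"
  )
}

#' General smooth activation from a derivative table
#'
#' Accepts any smooth activation with `S(0) = 0` as a callable plus its
#' derivative values at 0, so the spectral and normal-form machinery is not
#' tied to the sigmoid. Activations with a nonzero second derivative produce
#' nonzero quadratic centre-manifold terms.
#'
#' @param fun callable `S(u)`.
#' @param derivs numeric vector of `S^(k)(0)` for `k = 0, ..., length - 1`;
#'   at least orders 0..3, `derivs[1]` must be 0 and `derivs[2]` nonzero.
#' @return object of class `nf_activation`.
#' @export
activation_table <- function(fun, derivs) {
  stopifnot(is.function(fun), is.numeric(derivs), length(derivs) >= 4L)
  if (derivs[1] != 0) stop("activation must satisfy S(0) = 0")
  if (derivs[2] == 0) stop("activation must satisfy S'(0) != 0")
  structure(list(fun = fun, derivs = derivs, gamma = NA_real_),
            class = "nf_activation")
}

#' Derivative of the activation at the resting state
#'
#' @param act an `nf_activation` (or an `nf_model`, whose activation is used).
#' @param order derivative order, within the stored table (0..5 for the
#'   sigmoid).
#' @return `S^(order)(0)`.
#' @export
activation_derivatives <- function(act, order) {
  if (inherits(act, "nf_model")) act <- act$activation
  stopifnot(inherits(act, "nf_activation"))
  if (!(order %in% (seq_along(act$derivs) - 1L))) {
    stop("unsupported derivative order ", order)
  }
  act$derivs[order + 1L]
}

#' Neural field model specification
#'
#' Bundles the decay rate `alpha`, diffusion coefficient `d`, baseline delay
#' `tau0`, the sum-of-exponentials kernel amplitudes `eta` and decay rates
#' `mu`, and the activation. The total delay horizon is `h = tau0 + 2`
#' (baseline delay plus the diameter of the domain `[-1, 1]`).
#'
#' @param alpha decay rate, positive.
#' @param d diffusion coefficient, nonnegative.
#' @param tau0 baseline delay, nonnegative.
#' @param eta kernel amplitudes, all nonzero; length N >= 1.
#' @param mu kernel spatial decay rates, same length as `eta`, finite.
#' @param gamma sigmoid gain; ignored when `activation` is supplied.
#' @param activation optional `nf_activation` overriding the sigmoid.
#' @return object of class `nf_model`.
#' @export
#' @examples
#' m <- nf_model(alpha = 1, d = 0.2, tau0 = 0.75,
#'               eta = c(12.5, -10), mu = c(2, 1), gamma = 3.3094)
#' m$h  # delay horizon tau0 + 2
nf_model <- function(alpha, d, tau0, eta, mu, gamma = NULL, activation = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0) stop("alpha must be positive")
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d))
  if (d < 0) stop("d must be nonnegative")
  stopifnot(is.numeric(tau0), length(tau0) == 1L, is.finite(tau0))
  if (tau0 < 0) stop("tau0 must be nonnegative")
  stopifnot(is.numeric(eta), is.numeric(mu), length(eta) >= 1L,
            length(eta) == length(mu), all(is.finite(eta)), all(is.finite(mu)))
  if (any(eta == 0)) stop("kernel amplitudes eta must be nonzero")
  if (is.null(activation)) {
    if (is.null(gamma)) stop("supply either gamma or an activation")
    activation <- sigmoid_activation(gamma)
  }
  stopifnot(inherits(activation, "nf_activation"))
  structure(
    list(alpha = alpha, d = d, tau0 = tau0,
         eta = as.numeric(eta), mu = as.numeric(mu), N = length(eta),
         activation = activation, h = tau0 + 2),
    class = "nf_model"
  )
}

#' @export
print.nf_model <- function(x, ...) {
  cat("Neural field model on [-1, 1]\n")
  cat(sprintf("  alpha = %g, d = %g, tau0 = %g (delay horizon h = %g)\n",
              x$alpha, x$d, x$tau0, x$h))
  cat(sprintf("  kernel: %d exponential term(s)\n", x$N))
  for (j in seq_len(x$N)) {
    cat(sprintf("    eta_%d = %g, mu_%d = %g\n", j, x$eta[j], j, x$mu[j]))
  }
  if (is.na(x$activation$gamma)) {
    cat("  activation: user-supplied derivative table\n")
  } else {
    cat(sprintf("  activation: sigmoid with gain gamma = %g\n",
                x$activation$gamma))
  }
  invisible(x)
}

#' Evaluate the connectivity kernel and delay
#'
#' `J(x, x') = sum_j eta_j exp(-mu_j |x - x'|)` and
#' `tau(x, x') = tau0 + |x - x'|`. Vectorised over `x`/`xp` of equal length
#' (or one scalar).
#'
#' @param model an `nf_model`.
#' @param x,xp positions in `[-1, 1]`.
#' @return list with components `J` and `tau`.
#' @export
kernel_eval <- function(model, x, xp) {
  stopifnot(inherits(model, "nf_model"))
  if (any(x < -1 | x > 1) || any(xp < -1 | xp > 1)) {
    stop("positions must lie in [-1, 1]")
  }
  r <- abs(x - xp)
  J <- colSums(model$eta * exp(-outer(model$mu, r)))
  list(J = as.numeric(J), tau = model$tau0 + r)
}

#' The z-dependent scalar families k_j(z) and c_j(z)
#'
#' `k_j(z) = mu_j + z` and `c_j(z) = S'(0) alpha eta_j exp(-tau0 z)`; these
#' are the only places the kernel and delay enter the characteristic
#' machinery.
#'
#' @param model an `nf_model`.
#' @param z complex point.
#' @return list with complex vectors `k` and `c` of length N.
#' @export
kz_cz <- function(model, z) {
  stopifnot(inherits(model, "nf_model"), length(z) == 1L)
  z <- as.complex(z)
  list(k = model$mu + z,
       c = activation_derivatives(model, 1L) * model$alpha * model$eta *
         exp(-model$tau0 * z))
}

#' Replace a single scalar parameter of a model
#'
#' Used by the Hopf locator and branch continuation. Valid names are
#' `"gamma"`, `"d"`, `"tau0"`, `"alpha"`, `"eta<j>"`, `"mu<j>"` (e.g.
#' `"eta2"`). Setting `gamma` rebuilds the sigmoid activation; it is an error
#' for models with a user-supplied activation table.
#'
#' @param model an `nf_model`.
#' @param name parameter name.
#' @param value new numeric value.
#' @return the updated `nf_model`.
#' @export
set_param <- function(model, name, value) {
  stopifnot(inherits(model, "nf_model"), is.numeric(value), length(value) == 1L)
  if (name == "gamma") {
    if (is.na(model$activation$gamma)) {
      stop("model has a user-supplied activation; gamma is not a free parameter")
    }
    return(nf_model(model$alpha, model$d, model$tau0, model$eta, model$mu,
                    gamma = value))
  }
  if (name %in% c("d", "tau0", "alpha")) {
    args <- list(alpha = model$alpha, d = model$d, tau0 = model$tau0,
                 eta = model$eta, mu = model$mu, activation = model$activation)
    args[[name]] <- value
    return(do.call(nf_model, args))
  }
  mt <- regmatches(name, regexec("^(eta|mu)([0-9]+)$", name))[[1]]
  if (length(mt) == 3L) {
    j <- as.integer(mt[3])
    if (j < 1L || j > model$N) stop("kernel term index out of range: ", name)
    eta <- model$eta
    mu <- model$mu
    if (mt[2] == "eta") eta[j] <- value else mu[j] <- value
    return(nf_model(model$alpha, model$d, model$tau0, eta, mu,
                    activation = model$activation))
  }
  stop("unknown parameter: ", name)
}
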