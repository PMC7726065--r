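# Characteristic machinery: the even polynomial P^z(rho), its canonical branch
# roots, the (N+1)x(N+1) parity matrices S^{z,even} / S^{z,odd}, determinant
# based eigenvalue search and eigenvector construction.
#
# Without diffusion (d = 0) the polynomial degree in s = rho^2 drops from N+1
# to N and the frame is handled as a first-class N-root case: the parity
# matrices lose their boundary row (there is no Neumann condition when B is a
# multiple of the identity) and are NxN.

# multiply two polynomials given as ascending coefficient vectors
poly_mul <- function(a, b) {
  out <- rep(0 + 0i, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

#' Coefficients of the characteristic polynomial in s = rho^2
#'
#' The exponential ansatz `e^{rho x}` for the ODE obtained by applying the
#' kernel-annihilating operators to the characteristic equation yields the
#' even polynomial
#' `P^z(rho) = (alpha + z - d rho^2) prod_p (k_p^2 - rho^2)
#'  - 2 sum_j c_j k_j prod_{p != j} (k_p^2 - rho^2)`.
#' Since only even powers occur, it is represented as a polynomial in
#' `s = rho^2`, of degree N+1 when `d > 0` and degree N when `d = 0`. The
#' expansion is performed by exact coefficient convolution of the product
#' terms.
#'
#' @param model an `nf_model`.
#' @param z complex point.
#' @return complex coefficient vector, ascending powers of `s`.
#' @export
char_poly_coeffs <- function(model, z) {
  kc <- kz_cz(model, z)
  k2 <- kc$k^2
  N <- model$N
  # prod_p (k_p^2 - s) and the deleted products
  full <- 1 + 0i
  for (p in seq_len(N)) full <- poly_mul(full, c(k2[p], -1 + 0i))
  acc <- poly_mul(c(model$alpha + z, -model$d + 0i), full)
  for (j in seq_len(N)) {
    del <- 1 + 0i
    for (p in seq_len(N)) if (p != j) del <- poly_mul(del, c(k2[p], -1 + 0i))
    del <- c(del, 0 + 0i)                      # pad to common length
    length(del) <- length(acc)
    del[is.na(del)] <- 0 + 0i
    acc <- acc - 2 * kc$c[j] * kc$k[j] * del
  }
  # drop an exactly-zero leading coefficient in the diffusionless case
  if (model$d == 0) acc <- acc[seq_len(N + 1L)]
  acc
}

# evaluate P^z(rho) through its product form; independent of the expanded
# coefficients, used for Newton polishing and as a cross-check in tests
char_poly_eval <- function(model, z, rho) {
  kc <- kz_cz(model, z)
  k2 <- kc$k^2
  s <- rho^2
  out <- (model$alpha + z - model$d * s)
  for (p in seq_len(model$N)) out <- out * (k2[p] - s)
  for (j in seq_len(model$N)) {
    del <- 2 * kc$c[j] * kc$k[j]
    for (p in seq_len(model$N)) if (p != j) del <- del * (k2[p] - s)
    out <- out - del
  }
  out
}

#' Canonical branch roots of the characteristic polynomial
#'
#' Roots of the degree-(N+1) (or N, when `d = 0`) polynomial in `s = rho^2`,
#' polished by Newton iteration on the polynomial in `s`, then mapped to the
#' canonical square-root branch `Re rho > 0` (tie: `Re rho = 0, Im rho >= 0`)
#' and sorted lexicographically by `(Re, Im)` so that downstream matrix
#' indexing is reproducible.
#'
#' @param model an `nf_model`.
#' @param z complex point.
#' @return complex vector of N+1 (d > 0) or N (d = 0) branch representatives.
#' @export
branch_roots <- function(model, z) {
  cf <- char_poly_coeffs(model, z)
  s <- polyroot(cf)
  dcf <- cf[-1L] * seq_len(length(cf) - 1L)
  for (it in 1:8) {                            # Newton polish on the s-polynomial
    num <- vapply(s, function(si) sum(cf * si^(seq_along(cf) - 1L)), complex(1))
    den <- vapply(s, function(si) sum(dcf * si^(seq_along(dcf) - 1L)), complex(1))
    ok <- Mod(den) > 0
    s[ok] <- s[ok] - num[ok] / den[ok]
  }
  rho <- sqrt(s)                               # principal branch: Re >= 0
  flip <- Re(rho) < 0 | (Re(rho) == 0 & Im(rho) < 0)
  rho[flip] <- -rho[flip]
  rho[lex_order(rho)]
}

#' Degeneracy check at a complex point
#'
#' Flags `z` when the characteristic frame is unusable: two branch roots
#' coincide (`repeated_roots`), some `k_j^2` equals another `k_p^2` or some
#' `rho_m^2` (`k_collision`, the set where the hyperbolic basis functions
#' become linearly dependent), or some `k_j` or `rho_m` vanishes
#' (`zero_root`). These are the isolated points excluded by the resolvent
#' and residue constructions.
#'
#' @param model an `nf_model`.
#' @param z complex point.
#' @param tol relative collision tolerance.
#' @return list with `clean` (logical), `reason` (character vector) and
#'   `witnesses` (list of offending index pairs).
#' @export
degeneracy_check <- function(model, z, tol = 1e-8) {
  kc <- kz_cz(model, z)
  rho <- branch_roots(model, z)
  reason <- character(0)
  wit <- list()
  scl <- max(1, Mod(kc$k)^2, Mod(rho)^2)
  M <- length(rho)
  if (M >= 2L) {
    for (a in seq_len(M - 1L)) {
      for (b in (a + 1L):M) {
        if (Mod(rho[a]^2 - rho[b]^2) <= tol * scl) {
          reason <- c(reason, "repeated_roots")
          wit <- c(wit, list(c(a, b)))
        }
      }
    }
  }
  if (model$N >= 2L) {
    for (a in seq_len(model$N - 1L)) {
      for (b in (a + 1L):model$N) {
        if (Mod(kc$k[a]^2 - kc$k[b]^2) <= tol * scl) {
          reason <- c(reason, "k_collision")
          wit <- c(wit, list(c(a, b)))
        }
      }
    }
  }
  for (j in seq_len(model$N)) {
    for (m in seq_len(M)) {
      if (Mod(kc$k[j]^2 - rho[m]^2) <= tol * scl) {
        reason <- c(reason, "k_collision")
        wit <- c(wit, list(c(j, m)))
      }
    }
  }
  if (any(Mod(kc$k) <= tol * sqrt(scl)) || any(Mod(rho) <= tol * sqrt(scl))) {
    reason <- c(reason, "zero_root")
    wit <- c(wit, list(c(which(Mod(kc$k) <= tol * sqrt(scl)),
                         which(Mod(rho) <= tol * sqrt(scl)))))
  }
  list(clean = length(reason) == 0L, reason = unique(reason), witnesses = wit)
}

#' Characteristic frame at a complex point
#'
#' Everything attached to `z`: the scalar families `k`, `c`, the canonical
#' branch roots `rho` and the parity matrices. Rows `1..N` of the even/odd
#' matrices are the kernel compatibility conditions
#' `(k_j cosh rho_m + rho_m sinh rho_m) / (k_j^2 - rho_m^2)` and
#' `(rho_m cosh rho_m + k_j sinh rho_m) / (k_j^2 - rho_m^2)`; when `d > 0`
#' the final row `rho_m sinh rho_m` / `rho_m cosh rho_m` encodes the no-flux
#' boundary condition.
#'
#' @param model an `nf_model`.
#' @param z complex point.
#' @param tol degeneracy tolerance.
#' @param ref_rho optional reference roots; when given, the computed roots
#'   (and matrix columns) are permuted to match them nearest-neighbour, which
#'   keeps determinants continuous along paths in `z`.
#' @return object of class `nf_frame`: list with `z`, `k`, `c`, `rho`,
#'   `S_even`, `S_odd`, `degenerate`, `degeneracy`.
#' @export
char_frame <- function(model, z, tol = 1e-8, ref_rho = NULL) {
  kc <- kz_cz(model, z)
  rho <- branch_roots(model, z)
  if (!is.null(ref_rho)) rho <- rho[match_nearest(rho, ref_rho)]
  deg <- degeneracy_check(model, z, tol)
  M <- length(rho)
  N <- model$N
  S_even <- matrix(0 + 0i, M, M)
  S_odd <- matrix(0 + 0i, M, M)
  ch <- cosh(rho)
  sh <- sinh(rho)
  for (j in seq_len(N)) {
    den <- kc$k[j]^2 - rho^2
    S_even[j, ] <- (kc$k[j] * ch + rho * sh) / den
    S_odd[j, ] <- (rho * ch + kc$k[j] * sh) / den
  }
  if (model$d > 0) {
    S_even[M, ] <- rho * sh
    S_odd[M, ] <- rho * ch
  }
  structure(list(z = as.complex(z), k = kc$k, c = kc$c, rho = rho,
                 S_even = S_even, S_odd = S_odd,
                 degenerate = !deg$clean, degeneracy = deg),
            class = "nf_frame")
}

# magnitude scale of a parity matrix (product of row 2-norms, a Hadamard
# bound for |det|); relative determinant tolerances are taken against this
frame_scale <- function(S) {
  prod(pmax(sqrt(rowSums(Mod(S)^2)), .Machine$double.xmin))
}

#' Characteristic determinant
#'
#' `det S^{z,even}` or `det S^{z,odd}`; its zeros in `z` (away from the
#' degeneracy set) are exactly the eigenvalues of the linearisation, with
#' even (cosh-sum) or odd (sinh-sum) eigenfunctions.
#'
#' @param model an `nf_model`.
#' @param z complex point.
#' @param parity `"even"` or `"odd"`.
#' @param frame optionally a precomputed `nf_frame` at `z`.
#' @return complex determinant.
#' @export
char_det <- function(model, z, parity = c("even", "odd"), frame = NULL) {
  parity <- match.arg(parity)
  if (is.null(frame)) frame <- char_frame(model, z)
  if (frame$degenerate) {
    stop(structure(
      class = c("nf_degeneracy_error", "error", "condition"),
      list(message = paste0("degenerate frame at z = ", format(frame$z), " (",
                            paste(frame$degeneracy$reason, collapse = ", "), ")"),
           call = sys.call(-1), degeneracy = frame$degeneracy)))
  }
  cdet(if (parity == "even") frame$S_even else frame$S_odd)
}

# determinant with columns matched to a reference root ordering; returns NA
# on degenerate frames instead of erroring (used inside Newton loops)
char_det_matched <- function(model, z, parity, ref_rho) {
  fr <- tryCatch(char_frame(model, z, ref_rho = ref_rho),
                 error = function(e) NULL)
  if (is.null(fr) || fr$degenerate) return(NA_complex_)
  cdet(if (parity == "even") fr$S_even else fr$S_odd)
}

# one Newton solve for a root of det S^{z,parity} starting from z0;
# derivative by central differences with locally matched root ordering
newton_det <- function(model, z0, parity, tol = 1e-11, max_iter = 40L) {
  z <- as.complex(z0)
  for (it in seq_len(max_iter)) {
    fr <- tryCatch(char_frame(model, z), error = function(e) NULL)
    if (is.null(fr) || fr$degenerate) return(NULL)
    f <- cdet(if (parity == "even") fr$S_even else fr$S_odd)
    h <- 1e-6 * max(1, Mod(z))
    fp <- (char_det_matched(model, z + h, parity, fr$rho) -
             char_det_matched(model, z - h, parity, fr$rho)) / (2 * h)
    if (is.na(fp) || Mod(fp) == 0) return(NULL)
    step <- f / fp
    if (!is.finite(Re(step)) || !is.finite(Im(step))) return(NULL)
    # guard against wild steps from distant seeds
    if (Mod(step) > 1) step <- step / Mod(step)
    z <- z - step
    if (Mod(step) <= tol * max(1, Mod(z))) {
      return(list(z = z, iterations = it))
    }
  }
  NULL
}

#' Essential spectrum of the linearisation
#'
#' The delayed coupling is a compact perturbation, so the essential spectrum
#' is that of the diffusion-decay operator alone: empty for `d > 0` and the
#' single point `-alpha` for `d = 0`.
#'
#' @param model an `nf_model`.
#' @return numeric vector: `numeric(0)` when `d > 0`, `-alpha` when `d = 0`.
#' @export
essential_spectrum <- function(model) {
  stopifnot(inherits(model, "nf_model"))
  if (model$d > 0) numeric(0) else -model$alpha
}

#' Eigenvector of the linearisation at a located eigenvalue
#'
#' Takes the right-singular vector of the smallest singular value of the
#' parity matrix as the nullspace direction, normalises it to unit Euclidean
#' norm, rotates the phase so the largest-modulus component is real and
#' positive (flipping the overall sign if the leading significant component
#' would otherwise be negative), and assembles the spatial profile
#' `q(x) = sum_m coeff_m cosh(rho_m x)` (even) or `sinh` (odd).
#'
#' @param model an `nf_model`.
#' @param lam complex eigenvalue (must satisfy the determinant condition).
#' @param parity `"even"` or `"odd"`.
#' @param det_tol relative determinant tolerance for accepting `lam`.
#' @return object of class `nf_eigenpair`: `lambda`, `parity`, `coeff`,
#'   `rho`, callable `q`, `dq`, `d2q`, and `residual` (relative determinant).
#' @export
eigenvector <- function(model, lam, parity = c("even", "odd"),
                        det_tol = 1e-8) {
  parity <- match.arg(parity)
  fr <- char_frame(model, lam)
  S <- if (parity == "even") fr$S_even else fr$S_odd
  resid <- Mod(cdet(S)) / frame_scale(S)
  if (resid > det_tol) {
    stop("lam is not an eigenvalue of the requested parity (relative |det| = ",
         format(resid), ")")
  }
  sv <- svd(S)
  M <- length(fr$rho)
  if (M >= 2L && sv$d[M - 1L] <= det_tol * max(sv$d)) {
    stop("nullspace dimension >= 2: non-simple eigenvalue, not supported")
  }
  coeff <- sv$v[, M]
  lead <- which.max(Mod(coeff))
  coeff <- coeff * Mod(coeff[lead]) / coeff[lead]
  first <- which(Mod(coeff) > 1e-8)[1]
  if (!is.na(first) && Re(coeff[first]) < 0) coeff <- -coeff
  coeff <- coeff / sqrt(sum(Mod(coeff)^2))
  rho <- fr$rho
  even <- parity == "even"
  q <- function(x) {
    xr <- outer(rho, x)
    as.vector(coeff %*% (if (even) cosh(xr) else sinh(xr)))
  }
  dq <- function(x) {
    xr <- outer(rho, x)
    as.vector((coeff * rho) %*% (if (even) sinh(xr) else cosh(xr)))
  }
  d2q <- function(x) {
    xr <- outer(rho, x)
    as.vector((coeff * rho^2) %*% (if (even) cosh(xr) else sinh(xr)))
  }
  structure(list(lambda = as.complex(lam), parity = parity, coeff = coeff,
                 rho = rho, q = q, dq = dq, d2q = d2q, residual = resid),
            class = "nf_eigenpair")
}

#' @export
print.nf_eigenpair <- function(x, ...) {
  cat(sprintf("Eigenpair: lambda = %s (%s parity)\n", format(x$lambda),
              x$parity))
  cat("  rho:  ", paste(format(x$rho, digits = 5), collapse = ", "), "\n")
  cat("  coeff:", paste(format(x$coeff, digits = 5), collapse = ", "), "\n")
  invisible(x)
}

#' Eigenvalue search over a rectangle in the complex plane
#'
#' Evaluates the scaled even and odd characteristic determinants on a
#' uniform grid over the rectangle, seeds Newton iterations (derivative by
#' central differences under locally matched root ordering) at every local
#' minimum of `|det|`, and polishes each seed to a root. Converged roots
#' are deduplicated within a clustering radius, roots landing in the
#' degeneracy set or outside the (slightly enlarged) rectangle are
#' discarded, and eigenpairs are returned sorted by real part, descending.
#' For real-parameter models the output is closed under conjugation.
#'
#' @param model an `nf_model`.
#' @param re_lim,im_lim rectangle limits, length-2 numeric.
#' @param grid_density scan points per axis.
#' @param parities which determinants to search.
#' @param det_tol relative determinant tolerance for accepting a root.
#' @param cluster_radius deduplication radius.
#' @return object of class `nf_spectrum`: list with `eigenpairs` (list of
#'   `nf_eigenpair`) and `table` (data.frame re, im, parity, residual).
#' @export
find_eigenvalues <- function(model, re_lim = c(-3, 0.5), im_lim = c(-6, 6),
                             grid_density = 48L,
                             parities = c("even", "odd"),
                             det_tol = 1e-8, cluster_radius = 1e-6) {
  res <- seq(re_lim[1], re_lim[2], length.out = grid_density)
  ims <- seq(im_lim[1], im_lim[2], length.out = grid_density)
  margin <- 1e-6 + 1e-6 * max(abs(c(re_lim, im_lim)))
  found <- list()
  for (parity in parities) {
    # scan |det| (scaled) over the grid; NA on degenerate frames
    dv <- matrix(NA_real_, grid_density, grid_density)
    for (a in seq_len(grid_density)) {
      for (b in seq_len(grid_density)) {
        fr <- tryCatch(char_frame(model, complex(real = res[a],
                                                 imaginary = ims[b])),
                       error = function(e) NULL)
        if (is.null(fr) || fr$degenerate) next
        S <- if (parity == "even") fr$S_even else fr$S_odd
        dv[a, b] <- Mod(cdet(S)) / frame_scale(S)
      }
    }
    seeds <- complex(0)
    for (a in seq_len(grid_density)) {
      for (b in seq_len(grid_density)) {
        v <- dv[a, b]
        if (is.na(v)) next
        nb <- dv[max(1, a - 1):min(grid_density, a + 1),
                 max(1, b - 1):min(grid_density, b + 1)]
        if (v <= min(nb, na.rm = TRUE)) {
          seeds <- c(seeds, complex(real = res[a], imaginary = ims[b]))
        }
      }
    }
    # roots on the real axis produce only shallow dips in the 2-D scan (the
    # nearest grid row passes a finite distance above them), so they get a
    # dedicated dense 1-D scan whenever the rectangle touches the axis
    if (im_lim[1] <= 0 && im_lim[2] >= 0) {
      res1 <- seq(re_lim[1], re_lim[2], length.out = 8L * grid_density)
      dv1 <- vapply(res1, function(zr) {
        fr <- tryCatch(char_frame(model, complex(real = zr)),
                       error = function(e) NULL)
        if (is.null(fr) || fr$degenerate) return(NA_real_)
        S <- if (parity == "even") fr$S_even else fr$S_odd
        Mod(cdet(S)) / frame_scale(S)
      }, numeric(1))
      for (a in seq_along(res1)) {
        v <- dv1[a]
        if (is.na(v)) next
        nb <- dv1[max(1, a - 1):min(length(res1), a + 1)]
        if (v <= min(nb, na.rm = TRUE)) {
          seeds <- c(seeds, complex(real = res1[a]))
        }
      }
    }
    roots <- complex(0)
    for (seed in seeds) {
      sol <- newton_det(model, seed, parity)
      if (is.null(sol)) next
      z <- sol$z
      if (Re(z) < re_lim[1] - margin || Re(z) > re_lim[2] + margin ||
          Im(z) < im_lim[1] - margin || Im(z) > im_lim[2] + margin) next
      if (length(roots) && min(Mod(roots - z)) < cluster_radius) next
      dg <- degeneracy_check(model, z)
      if (!dg$clean) next
      fr <- char_frame(model, z)
      S <- if (parity == "even") fr$S_even else fr$S_odd
      if (Mod(cdet(S)) / frame_scale(S) > det_tol) next
      roots <- c(roots, z)
    }
    for (z in roots) {
      ep <- tryCatch(eigenvector(model, z, parity, det_tol = det_tol),
                     error = function(e) NULL)
      if (!is.null(ep)) found <- c(found, list(ep))
    }
  }
  if (length(found)) {
    found <- found[order(-vapply(found, function(e) Re(e$lambda), numeric(1)),
                         vapply(found, function(e) Im(e$lambda), numeric(1)))]
  }
  tab <- data.frame(
    re = vapply(found, function(e) Re(e$lambda), numeric(1)),
    im = vapply(found, function(e) Im(e$lambda), numeric(1)),
    parity = vapply(found, function(e) e$parity, character(1)),
    residual = vapply(found, function(e) e$residual, numeric(1))
  )
  structure(list(eigenpairs = found, table = tab), class = "nf_spectrum")
}

#' @export
print.nf_spectrum <- function(x, ...) {
  cat(sprintf("Point spectrum: %d eigenvalue(s) found\n", nrow(x$table)))
  if (nrow(x$table)) print(x$table, ...)
  invisible(x)
}
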