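# Complex dense linear algebra helpers and quadrature utilities.
#
# Base R (4.x) `det()` does not accept complex matrices, so the determinant and
# adjugate of the small (N+1)x(N+1) characteristic matrices are computed by an
# LU factorisation with partial pivoting written out below. `solve()`, `svd()`
# and `polyroot()` do handle complex input and are used directly elsewhere.

#' Determinant of a complex matrix
#'
#' LU factorisation with partial pivoting. Intended for the small dense
#' complex matrices that arise throughout the package (typically 2x2 to 4x4);
#' it is exact up to rounding for any size but makes no effort to avoid
#' overflow for very large matrices.
#'
#' @param m square complex (or numeric) matrix.
#' @return complex scalar.
#' @keywords internal
cdet <- function(m) {
  m <- as.matrix(m) + 0i
  n <- nrow(m)
  if (n != ncol(m)) stop("cdet: matrix must be square")
  if (n == 1L) return(m[1L, 1L])
  d <- 1 + 0i
  for (i in seq_len(n - 1L)) {
    p <- which.max(Mod(m[i:n, i])) + i - 1L
    if (Mod(m[p, i]) == 0) return(0 + 0i)
    if (p != i) {
      m[c(i, p), ] <- m[c(p, i), ]
      d <- -d
    }
    d <- d * m[i, i]
    r <- (i + 1L):n
    m[r, ] <- m[r, ] - outer(m[r, i] / m[i, i], m[i, ])
  }
  d * m[n, n]
}

#' Adjugate of a complex matrix
#'
#' Cofactor transpose, computed minor-by-minor with [cdet()]. Satisfies
#' `m %*% cadj(m) = cdet(m) * I` even when `m` is singular, which is exactly
#' the property the residue formula for spectral projections relies on.
#'
#' @param m square complex matrix.
#' @return complex matrix of the same dimension.
#' @keywords internal
cadj <- function(m) {
  m <- as.matrix(m) + 0i
  n <- nrow(m)
  if (n == 1L) return(matrix(1 + 0i, 1L, 1L))
  a <- matrix(0 + 0i, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a[j, i] <- (-1)^(i + j) * cdet(m[-i, -j, drop = FALSE])
    }
  }
  a
}

# cached Gauss-Legendre nodes/weights on [-1, 1]
.gl_cache <- new.env(parent = emptyenv())

gl_rule <- function(n) {
  key <- as.character(n)
  r <- .gl_cache[[key]]
  if (is.null(r)) {
    r <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- r
  }
  r
}

# Gauss-Legendre nodes and weights on [a, b]
gl_nodes <- function(n, a, b) {
  r <- gl_rule(n)
  list(x = (a + b) / 2 + (b - a) / 2 * r$x, w = (b - a) / 2 * r$w)
}

#' Quadrature of an integrand with a kink at an interior point
#'
#' Integrates `f` over `[-1, 1]` by Gauss-Legendre after splitting the
#' interval at `x0`, where integrands of the form `e^{-k|x0 - x'|} g(x')`
#' lose smoothness. `f` must be vectorised in its argument.
#'
#' @param f vectorised integrand.
#' @param x0 kink location in `[-1, 1]`.
#' @param n nodes per smooth piece.
#' @return complex or numeric scalar.
#' @keywords internal
quad_split <- function(f, x0, n = 48L) {
  s <- 0
  if (x0 > -1) {
    g <- gl_nodes(n, -1, x0)
    s <- s + sum(g$w * f(g$x))
  }
  if (x0 < 1) {
    g <- gl_nodes(n, x0, 1)
    s <- s + sum(g$w * f(g$x))
  }
  s
}

# lexicographic (Re, Im) ordering used for canonical root sorting
lex_order <- function(z) order(Re(z), Im(z))

# match each element of z to the nearest element of ref, returning the
# permutation p with z[p] aligned to ref (greedy, adequate for well-separated
# roots under small perturbations of the base point)
match_nearest <- function(z, ref) {
  n <- length(ref)
  p <- integer(n)
  avail <- rep(TRUE, n)
  for (i in seq_len(n)) {
    d <- Mod(z - ref[i])
    d[!avail] <- Inf
    j <- which.min(d)
    p[i] <- j
    avail[j] <- FALSE
  }
  p
}
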