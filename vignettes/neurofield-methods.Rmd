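---
title: "Methods: spectra, Hopf normal forms and simulation for delayed neural fields with diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectra, Hopf normal forms and simulation for delayed neural fields with diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurofield)
```

# The model

`neurofield` analyses the scalar neural field on the interval
$\Omega = [-1, 1]$,

$$
\frac{\partial u}{\partial t}(t,x)
 = d\,\frac{\partial^2 u}{\partial x^2}(t,x) - \alpha\,u(t,x)
 + \alpha \int_{-1}^{1} J(x,x')\,
   S\bigl(u(t - \tau(x,x'),\,x')\bigr)\,dx',
$$

with no-flux boundary conditions $u_x(t,\pm 1) = 0$ when $d > 0$. Here
$u(t,x)$ is the deviation of the averaged membrane potential of a neural
population from its resting state, $\alpha > 0$ [1/time] is the intrinsic
decay rate, and $d \ge 0$ [space$^2$/time] models direct electrical
(gap-junction) coupling as diffusion. The connectivity kernel is a sum of
exponentials, $J(x,x') = \sum_{j=1}^N \eta_j e^{-\mu_j |x - x'|}$, with
amplitudes $\eta_j \neq 0$ and spatial decay rates $\mu_j$ [1/space]; the
bundled two-term "wizard hat" (local excitation, broader inhibition) is
$\tfrac{25}{2}e^{-2|x-x'|} - 10\,e^{-|x-x'|}$. Signals propagate at finite
(normalised) speed, so the delay is distance-dependent:
$\tau(x,x') = \tau^0 + |x - x'|$ with baseline delay $\tau^0 \ge 0$; the
total delay horizon is $h = \tau^0 + 2$. The activation
$S(u) = 1/(1 + e^{-\gamma u}) - 1/2$ is an odd sigmoid with gain
$\gamma > 0$; the toolkit also accepts any smooth activation supplied as a
callable plus its derivative values at 0 (`activation_table()`), in which
case the quadratic centre-manifold terms below are nonzero.

The trivial state $u \equiv 0$ is always an equilibrium ($S(0)=0$); all
spectral statements refer to the linearisation about it.

# Eigenvalues from determinant conditions

Exponential solutions $e^{\lambda t} q(x)$ reduce the linearisation to the
characteristic equation $\bigl(\lambda + \alpha - d\,\partial_x^2 -
K^\lambda\bigr) q = 0$, where $K^z$ acts as
$K^z y(x) = \sum_j c_j(z) \int e^{-k_j(z)|x-x'|} y(x')dx'$ with
$k_j(z) = \mu_j + z$ and $c_j(z) = S'(0)\,\alpha\,\eta_j\,e^{-\tau^0 z}$
(`kz_cz()`). Because each kernel term is annihilated by
$k_j^2 - \partial_x^2$, applying the product of these operators converts the
characteristic equation into a linear ODE whose exponential ansatz
$e^{\rho x}$ has the even characteristic polynomial

$$
P^z(\rho) = (\alpha + z - d\rho^2)\prod_p (k_p^2 - \rho^2)
 - 2\sum_j c_j k_j \prod_{p \ne j}(k_p^2 - \rho^2),
$$

of degree $2(N+1)$ in $\rho$, i.e. degree $N+1$ in $s = \rho^2$
(`char_poly_coeffs()`, exact coefficient convolution). Solutions are
hyperbolic combinations $q(x) = \sum_m a_m \cosh(\rho_m x) + b_m
\sinh(\rho_m x)$. Substituting back and imposing the boundary conditions
yields two square matrices $S^{z,\mathrm{even}}$, $S^{z,\mathrm{odd}}$
(`char_frame()`): rows $1..N$ carry the kernel compatibility conditions
$(k_j\cosh\rho_m + \rho_m\sinh\rho_m)/(k_j^2-\rho_m^2)$ (cosh family) and
$(\rho_m\cosh\rho_m + k_j\sinh\rho_m)/(k_j^2-\rho_m^2)$ (sinh family), and,
for $d>0$, a final row $\rho_m \sinh\rho_m$ / $\rho_m\cosh\rho_m$ encodes
$q'(\pm 1)=0$. A point $\lambda$ is an eigenvalue iff
$\det S^{\lambda,\mathrm{even}} \cdot \det S^{\lambda,\mathrm{odd}} = 0$;
the vanishing parity names the eigenvalue even (cosh-sum eigenfunction) or
odd (sinh-sum). The essential spectrum is $\emptyset$ for $d>0$ and
$\{-\alpha\}$ for $d=0$ (`essential_spectrum()`).

Design choices made here, where the underlying theory fixes none:

* **Canonical branch and ordering.** Only $\pm\rho_m$ pairs are determined;
  we fix the representative with $\operatorname{Re}\rho > 0$ (tie:
  $\operatorname{Im}\rho \ge 0$) and sort lexicographically by (Re, Im), so
  matrices are reproducible across calls. Along paths in $z$ (Newton steps,
  determinant derivatives) roots are re-matched to a reference frame by
  nearest neighbour, which keeps determinants continuous even when the
  lexicographic order would swap columns.
* **$d = 0$ as a first-class reduced case.** Without diffusion the
  polynomial degree drops to $N$, the boundary row disappears (the domain of
  the decay operator has no Neumann condition) and all matrices are
  $N \times N$. Treating this exactly avoids the artificial stiff root
  $\rho \sim 1/\sqrt d$ of a small-$d$ limit.
* **Degeneracy set.** Frames are refused (error, never silent) when branch
  roots collide, when $k_j^2 = k_p^2$ or $k_j^2 = \rho_m^2$ (the hyperbolic
  basis degenerates), or when a $k_j$ or $\rho_m$ vanishes, all within a
  relative tolerance of $10^{-8}$ (`degeneracy_check()`). These are isolated
  points in $z$; for the wizard-hat model, $z = -3/2$ (where
  $k_1^2 = k_2^2$) and $z = -\mu_j$ are examples.
* **Root search.** `find_eigenvalues()` scans the scaled $|\det|$ on a grid
  over the requested rectangle and Newton-polishes every local minimum
  (derivative by central differences, step $10^{-6}\max(1,|z|)$).
  Simple zeros on the real axis produce only shallow dips in a 2-D scan —
  the nearest grid row passes a finite distance above them — so real-axis
  roots get a dedicated dense 1-D scan. Completeness is still heuristic, as
  for any damped-Newton search; raising `grid_density` tightens it, and the
  discretised oracle (below) provides an independent cross-check.
* **Determinant tolerance.** A root is accepted when the determinant is
  below $10^{-8}$ relative to the product of row norms (a Hadamard bound,
  which makes the tolerance scale-free).
* **Eigenvectors.** The nullspace direction is the right-singular vector of
  the smallest singular value — robust to near-singularity — normalised to
  unit Euclidean coefficient norm with the largest-modulus component rotated
  real-positive (and a sign flip if the leading significant component would
  otherwise be negative). This normalisation matches the reference
  eigenvectors, whose coefficient norms are 1.000 to four decimals, and it
  is the scale on which $c_1$ and $\ell_1$ are reported.

Base R cannot take determinants of complex matrices, so a small LU
factorisation with partial pivoting (`cdet()`, with the adjugate `cadj()`
by cofactors) is included; `solve()`, `svd()` and `polyroot()` handle
complex input natively and are used everywhere else.

# The explicit resolvent

For $z$ in the resolvent set and outside the degeneracy set, the resolvent
$q = \Delta^{-1}(z) y$ of the characteristic operator is constructed in
closed form by variation of constants (`delta_inverse()`):

$$
q(x) = R(z,B)y(x) + \sum_m \bigl[a_m(x)\cosh(\rho_m x)
 + b_m(x)\sinh(\rho_m x)\bigr],
$$

where $R(z,B)$ is the diffusion-decay resolvent and the coefficient
functions are sign-split integrals

$$
\mathbf a(x) = \tfrac12\int_{-1}^{1}\Bigl[\operatorname{sgn}(x-x')\hat S(x')
 + (S^{z,\mathrm{even}})^{-1} S^{z,\mathrm{odd}} \hat C(x')\Bigr]
 \hat K^{-1} \hat R y(x')\,dx',
$$

and the mirrored expression for $\mathbf b(x)$. The hat workspace
(`hat_matrices()`) consists of the Cauchy-like matrix
$\hat Q_{jm} = 1/(k_j^2 - \rho_m^2)$ (last row of ones when $d>0$, with
$k_{N+1} := 1$), its scalings $\hat K = \hat Q\,\mathrm{diag}(\rho)$ and
$\hat M = \mathrm{diag}(k)\,\hat Q$, and the diagonal hyperbolic matrices
$\hat C(x)$, $\hat S(x)$. The identities $\det\hat M = \det\hat Q\prod k_j$
and $\det\hat K = \det\hat Q \prod\rho_m$ are asserted in the tests. Because
the lifted forcing $\hat R y(x)$ is $R(z,B)y(x)$ in every kernel component
and 0 in the boundary component, its $x$-dependence factorises and the
workspace reduces to one constant vector $u = \hat K^{-1} w_0$ scaling the
scalar function $R(z,B)y$.

Numerical choices:

* $R(z,B)$ for $d>0$ is the Neumann Green's function with
  $\beta = \sqrt{(z+\alpha)/d}$ (principal branch; the kernel is even in
  $\beta$ so the branch is immaterial),
  $G(x,x') = \cosh(\beta(1+x_<))\cosh(\beta(1-x_>))/(d\beta\sinh 2\beta)$,
  applied by Gauss–Legendre quadrature split at the kink. The appendix
  material the original derivation defers to is not reproduced anywhere in
  accessible form, so this Green's function was derived independently and is
  validated against a dense finite-difference solve in the tests.
* All integrands with an $e^{-k|x-x'|}$ kink are integrated by
  Gauss–Legendre split at the kink (64 nodes per smooth piece by default);
  smooth integrands get a single 64-node rule, which is already at machine
  precision for these analytic integrands.
* $R(z,B)y$ and its first derivative are tabulated on a 401-point grid and
  splined, so that the nested quadratures cost $O(1)$ per evaluation; the
  second derivative is recovered *exactly* from the defining ODE
  $R''=((z+\alpha)R - y)/d$ rather than by differentiating the spline. The
  same identities collapse the derivatives of the hyperbolic expansion, so
  `delta_inverse()` returns analytic `dq` and `d2q` — the residual checks
  $\| \Delta(z)q - y\|_\infty \le 10^{-6}\|y\|_\infty$ in the tests are
  limited by quadrature, not by numerical differentiation.
* The antiderivative convention that makes the two boundary relations hold
  is implemented directly as the symmetric sgn form above; no separate
  constant-fixing step exists.

# Hopf points and the first Lyapunov coefficient

`hopf_find()` locates a Hopf point in any scalar model parameter (gain
$\gamma$ by default) by damped Newton on the two real equations
$\operatorname{Re}\det S^{i\omega,p} = \operatorname{Im}\det S^{i\omega,p}
= 0$ in (parameter, $\omega$), with central-difference Jacobians and step
halving (at most 8 halvings); parity $p$ is user-declared because the even
and odd determinants can vanish at nearby parameters. Convergence is
declared at a scaled determinant below $10^{-10}$. Transversality is
reported as the numerically continued $d\operatorname{Re}\lambda/dp$ across
the critical value.

At a simple critical pair $\pm i\omega$ the normal form
$\dot z = i\omega z + c_1 z|z|^2 + \dots$ has first Lyapunov coefficient
$\ell_1 = \operatorname{Re}(c_1)/\omega$; $\ell_1 < 0$ means the
bifurcation is supercritical (a stable limit cycle branch). The package
computes $c_1$ entirely in closed form:

1. **Fréchet derivatives** (`frechet_k()`): on eigen-type arguments
   $e^{\lambda_m\theta} f_m(x)$ the $k$-th derivative of the delayed
   nonlinearity collapses to
   $\alpha S^{(k)}(0)\int J(x,x') e^{-(\sum_m \lambda_m)\tau(x,x')}
   \prod_m f_m(x')\,dx'$.
2. **Quadratic centre terms** (`centre_coefficients()`): for odd
   activations $S''(0)=0$ and both quadratic profiles vanish identically;
   otherwise the two quadratic homological systems are solved with
   `delta_inverse()` at $2i\omega$ and $0$. The source derivation labels
   these two systems in the opposite way to the standard Hopf homological
   equations; since the reference worked example has a vanishing quadratic
   term, its results cannot discriminate. The standard labelling
   ($\Delta(2i\omega)$ for the profile paired with $\bar\psi$) is the
   default; `convention = "alternative"` switches the labelling for audit.
3. **Residue projection** (`residue_projection()`): the spectral projection
   of the cubic forcing $y$ onto the critical eigenspace is
   $\nu = $ coefficient in
   $\mathrm{adj}(S^{\lambda,p})\,S^{\lambda,\bar p}
   \int \hat C(x')\hat K^{-1}\hat R y(x')dx' \,/\,
   \bigl(2\,\tfrac{d}{dz}\det S^{z,p}|_\lambda\bigr) = \nu\,\mathbf a$,
   a closed form with no numerical contour integration. The determinant
   derivative uses central differences with one Richardson refinement
   (step $10^{-6}\max(1,|\lambda|)$) along a root-matched branch. $\nu$ is
   extracted by complex least squares over the whole coefficient vector —
   robust when one component is near zero — and a relative mismatch above
   $10^{-3}$ between the residue vector and the eigen-direction raises an
   error (it signals a degenerate or non-simple point). The tests verify
   the closed form against a 16-point trapezoid Dunford integral on a
   radius-$10^{-2}$ circle to $10^{-4}$ relative.
4. $c_1 = \nu/2$ (the normal-form contour carries $1/(4\pi i)$ where the
   projection carries $1/(2\pi i)$), and $\ell_1 =
   \operatorname{Re}(c_1)/\omega$ by definition — the identity is exact in
   the code, and is reported on the unit-coefficient-norm eigenvector scale;
   rescaling the eigenvector by $r e^{i\varphi}$ multiplies $c_1$ by $r^2$
   and leaves $\ell_1$'s sign invariant (tested).

# Discretisation, simulation and the brute-force oracle

`discretize()` places $n^x$ equidistant nodes on $[-1,1]$
($\delta = 2/(n^x-1)$), discretises the coupling integral with trapezoid
weights ($\xi_m = 1$ inside, $\tfrac12$ at the ends) and the Laplacian with
the central stencil plus ghost-point reflection at the boundaries
(boundary rows $2(u_{\text{neighbour}} - u_{\text{self}})$), a second-order
discretisation throughout. The same assembly backs both the simulator and
the spectral oracle, so time-domain and frequency-domain validations test
the identical discrete operator.

**The Laplacian prefactor.** The reference discrete system for this model
carries $d/(2\delta^2)$ on the second-difference stencil, which is half the
standard $d/\delta^2$ that the continuum operator implies; the convergence
test against Neumann eigenfunctions discriminates cleanly in favour of the
standard factor, which is therefore the default. The halved variant is
kept as `laplacian = "halved"`. This is not a cosmetic issue: the
reference space–time scenarios are reproducible *only* under the
halved-diffusion stencil. At $\gamma = 4$ the nominal continuum model with
$d = 0.2$ has its largest real (odd-parity) eigenvalue at $-0.014$ —
analytic machinery and discrete oracle agree — so an odd perturbation
decays; at the effective $d = 0.1$ of the halved stencil that eigenvalue is
$+0.060$ and the odd initial condition converges to a nontrivial
equilibrium, exactly as the reference scenarios have it. The
scenario-reproduction tests therefore run with `laplacian = "halved"`,
while every spectral/analytic statement uses the standard stencil.

**Integration.** The $n^x$ delay equations are integrated by the method of
steps with a fixed-step 4-stage Lawson (integrating-factor) Runge–Kutta
scheme: the stiff linear part $L - \alpha I$ is propagated exactly through
precomputed matrix exponentials (`Matrix::expm`; at $n^x = 50$, $d = 0.2$
an explicit scheme would be CFL-limited to $dt \lesssim 0.006$, an order of
magnitude below the accuracy-motivated step), while the smooth delayed
coupling enters through the classical tableau. Because every delay is at
least $\tau^0$, all delayed lookups with $dt \le \tau^0/2$ fall strictly
behind the current step and are served by a cubic-Hermite dense interpolant
of the stored trajectory (value and derivative at every knot), matching the
integrator's $O(dt^4)$ accuracy; within one step the coupling is then a
known smooth function of time and the scheme reduces to an exponential
Simpson rule, which is fourth order (verified by Richardson
self-convergence on a horizon inside the first delay interval). Past the
first delay horizon the usual delay-equation breakpoints — derivative
discontinuities propagating from the history/solution junction at $t=0$ —
limit the *observable* order on short horizons; the tests assert full
fourth order on the smooth regime and order $\ge 2$ beyond it. Defaults:
$dt = \min(0.05, \tau^0/4)$, reproducible bit-for-bit re-runs.

**Attractor classification** (`classify_attractor()`): over the final 20
time units of a $t_{\mathrm{end}} = 200$ run, sup-norm below $10^{-3}$ is
the trivial equilibrium; per-node oscillation amplitude below $10^{-3}$
with a larger sup-norm is a nontrivial equilibrium; anything else is an
oscillation, with amplitude and dominant period (interpolated upward zero
crossings at the most active node) reported. These tolerances separate all
reference scenarios robustly at $n^x = 50$, and the classification is
stable from $n^x = 50$ to 100.

**The oracle** (`discrete_eigenvalues()`, `discrete_resolve()`): the
discretised characteristic matrix
$\Delta_N(z) = (z+\alpha)I - L - M(z)$ with
$M(z)_{nm} = \alpha\,\delta\,\xi_m S'(0) J(x_n,x_m) e^{-z\tau_{nm}}$ is the
linearisation of the simulator's vector field on exponential solutions. Its
roots are found by Newton on the log-determinant,
$z \leftarrow z - 1/\operatorname{tr}(\Delta_N^{-1}\Delta_N')$ — one dense
complex solve per iteration, no determinant ever formed (which also avoids
overflow at $n^x = 400$) — and its linear solves validate
`delta_inverse()`. Observed convergence to the analytic quantities is
second order in $n^x$, consistent with the spatial discretisation, with
$|\Delta\lambda| \le 10^{-3}$ at $n^x = 400$ across the bundled and random
fixtures. (The reference discrete system's coupling row omits the factor
$\alpha$, invisible in the reference example where $\alpha = 1$; the
implementation keeps $\alpha$, consistent with the continuum model.)

# What the synthetic fixtures do and do not show

`random_fixture()` draws parameter sets from the regime the reference
analysis inhabits: $\alpha \in [0.5, 2]$, $d = 0$ (one draw in three) or
$d \in [0.05, 0.5]$, $\tau^0 \in [0.25, 1]$, $|\eta_j| \in [0.5, 15]$ with
either sign, $\mu_j \in [0.5, 4]$ pairwise separated by at least $0.2$
(which keeps the $k_j^2 = k_p^2$ degeneracy uniformly away), gains in
$[2, 4]$. Property tests over these fixtures exercise the machinery on
kernels with mixed excitation/inhibition and both with and without
diffusion. They do *not* emulate heterogeneous or asymmetric connectivity,
space-dependent diffusion, multiple populations, two-dimensional domains,
or physiologically calibrated parameter magnitudes — passing tests say the
*mathematics* is implemented correctly on this model class, not that the
model describes any particular tissue.

# Problem sizes and reproducibility

The test-suite and the acceptance script use the sizes at which the
reference quantities are themselves defined: $n^x = 50$ and
$t_{\mathrm{end}} = 200$ (600 near onset, where critical slowing down makes
the limit cycle take $O(1/(\gamma - \gamma^*))$ time units to establish)
for simulations, $n^x \in \{100, 200, 400\}$ for oracle convergence
studies, 64-node quadrature (doubled in robustness checks) for all
integrals. All randomness flows through explicit seeds; the numerical
pipelines themselves are deterministic.

# Known limitations

* Non-simple eigenvalues (Jordan blocks) and resonant Hopf points are
  detected and refused, not handled.
* The resolvent and residue formulas are undefined on the degeneracy set
  $\mathcal S$ (isolated points); callers get an error, not a limit.
* Eigenvalue sweeps are heuristic-complete (grid-seeded Newton); the
  oracle cross-check catches misses in practice but carries no proof.
* For $d = 0$ the discretised operator approximates the essential spectrum
  $\{-\alpha\}$ by an eigenvalue cluster; point eigenvalues lying close to
  $-\alpha$ (within about $0.1$ for the bundled model) are trapped by that
  cluster at moderate $n^x$ and only resolve at much finer grids, so the
  second-order oracle-agreement contract is asserted away from the
  essential spectrum.
* Kernels must be finite sums of exponentials and the delay affine in
  distance; Gaussian kernels or state-dependent delays need different
  machinery.
* Very large $|z|$ (far beyond the spectral region of interest) can
  overflow the hyperbolic functions in the Green's kernel; the analysis
  region of interest is unaffected.
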