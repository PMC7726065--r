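# neurofield

Spectral analysis, Hopf normal forms and delay simulation for
one-dimensional neural field models with transmission delays and
gap-junction diffusion.

## The problem

Neural fields describe the averaged membrane potential $u(t,x)$ of a
cortical population coupled nonlocally through a connectivity kernel, with
distance-dependent transmission delays from finite axonal propagation
speed. Adding direct electrical coupling (gap junctions) contributes a
diffusion term, giving, on $\Omega = [-1,1]$ with no-flux boundaries,

$$
u_t = d\,u_{xx} - \alpha u
 + \alpha\!\int_{-1}^{1} J(x,x')\,S\bigl(u(t-\tau(x,x'),x')\bigr)\,dx',
\qquad
\begin{aligned}
J(x,x') &= \textstyle\sum_{j=1}^{N}\eta_j e^{-\mu_j|x-x'|},\\
\tau(x,x') &= \tau^0 + |x-x'|,
\end{aligned}
$$

with a sigmoid activation $S(u) = 1/(1+e^{-\gamma u}) - 1/2$. The package
is for dynamicists and computational neuroscientists who want the
*analytic* route to this model's linear and weakly nonlinear behaviour —
not just brute-force simulation:

* **Eigenvalues and eigenvectors** of the linearisation from an explicit
  characteristic polynomial $P^z(\rho)$ and determinant conditions on small
  complex matrices $S^{z,\mathrm{even}}$, $S^{z,\mathrm{odd}}$
  (`char_frame()`, `char_det()`, `find_eigenvalues()`, `eigenvector()`);
  essential spectrum $\emptyset$ ($d>0$) or $\{-\alpha\}$ ($d=0$).
* **The explicit resolvent** $\Delta^{-1}(z)y$ of the characteristic
  operator by a variation-of-constants formula (`delta_inverse()`).
* **Hopf points** located in any parameter by Newton on
  $\det S^{i\omega,\mathrm{parity}} = 0$ (`hopf_find()`), with the first
  Lyapunov coefficient $\ell_1 = \operatorname{Re}(c_1)/\omega$ computed
  through a closed-form residue of the spectral projection
  (`residue_projection()`, `lyapunov_coefficient()`) — no numerical contour
  integration.
* **A method-of-steps delay simulator** on the trapezoid/ghost-point
  spatial discretisation (`discretize()`, `integrate_dde()`,
  `classify_attractor()`), which doubles as a brute-force oracle for the
  analytic spectrum and resolvent (`discrete_eigenvalues()`,
  `discrete_resolve()`).

## Worked example

The bundled reference model is the "wizard-hat" kernel
$J = \tfrac{25}{2}e^{-2|x-x'|} - 10\,e^{-|x-x'|}$ with $\alpha = 1$,
$\tau^0 = 3/4$. Locate the Hopf point in the gain $\gamma$ with diffusion
$d = 0.2$:

```r
library(neurofield)
m <- nf_model(alpha = 1, d = 0.2, tau0 = 0.75,
              eta = c(12.5, -10), mu = c(2, 1), gamma = 3)
h <- hopf_find(m, "gamma", guess = c(3, 1), parity = "even")
h
#> Hopf point: gamma = 3.309427, omega = 1.237929 (lambda = 1.23793i)
#>   c1 = -1.1528-0.2583i, l1 = -0.931269 (supercritical)
#>   transversality d Re(lambda)/d gamma = 0.1335
h$eigenpair
#> Eigenpair: lambda = 0+1.237929i (even parity)
#>   rho:   0.25354-0.84904i, 1.73147+3.24747i, 3.90746+0.35854i
#>   coeff:  0.9971714+0.0000000i, -0.0727306-0.0177389i,  0.0028805-0.0060338i
```

Read: the trivial state loses stability at gain $\gamma^* = 3.3094$
through a conjugate eigenvalue pair $\pm 1.2379\,i$ crossing the imaginary
axis (oscillation period $2\pi/\omega \approx 5.08$ time units). The
critical eigenfunction is the even cosh-sum
$\sum_m c_m \cosh(\rho_m x)$ with the roots and coefficients shown —
dominated by the nearly flat mode $\cosh((0.254 - 0.849i)x)$. The first
Lyapunov coefficient $\ell_1 = -0.931 < 0$: the bifurcation is
supercritical, so a stable limit cycle branches off. Without diffusion
(`d = 0`) the same call gives $\gamma^* = 3.3482$, $\omega = 1.2403$,
$\ell_1 = -0.9123$.

Simulating the discretised field near onset confirms the analytic picture:

```r
sys <- discretize(h$model, nx = 50)
tr  <- integrate_dde(sys, set_param(h$model, "gamma", h$value + 0.1),
                     ic_phi2, t_end = 400, dt = 0.05)
classify_attractor(tr)$period
#> [1] 5.078163       # 2*pi/omega = 5.0757
```

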