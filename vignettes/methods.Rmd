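---
title: "Methods: exact solutions of coupled reaction-diffusion equations on a growing domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact solutions of coupled reaction-diffusion equations on a growing domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growdom)
```

## Model and assumptions

`growdom` solves the coupled linear system

$$
\frac{\partial C_1}{\partial t} = D \frac{\partial^2 C_1}{\partial x^2}
  - \frac{\partial (v C_1)}{\partial x} - k_1 C_1, \qquad
\frac{\partial C_i}{\partial t} = D \frac{\partial^2 C_i}{\partial x^2}
  - \frac{\partial (v C_i)}{\partial x} + m\,k_{i-1} C_{i-1} - k_i C_i,
$$

for generations $i = 2, \dots, G$ on a growing interval $0 < x < L(t)$ with
zero diffusive flux at both ends. $C_i(x,t)$ is the density of the $i$-th
generation of a cell lineage; each generation converts into the next at rate
$k_i$ with amplification $m$ ($m = 2$ for proliferation, $m = 1$ for
differentiation). The assumptions that make the exact solution possible are:

* **Linearity.** Reaction terms are first order; there is no crowding or
  density dependence. Linear models approximate nonlinear (logistic-type)
  models well at the low-density leading edge of a spreading front, which is
  exactly the regime that decides colonization.
* **Uniform growth.** The local stretch rate
  $\partial v/\partial x = \sigma(t) = L'(t)/L(t)$ is independent of
  position, so $v(x,t) = x\,\sigma(t)$ with the origin fixed. Apical or
  otherwise position-biased growth is out of scope.
* **Chain topology.** Generation $i$ feeds only generation $i+1$; branching
  lineage trees and time-dependent rates are not supported.
* **Growth only.** Shrinking domains ($L' < 0$) are rejected at
  construction. Negative $k_i$ are accepted with a warning because the
  uncoupled solutions can then grow without bound.

Truncating the lineage at $G$ generations means the last generation acts as
an absorbing compartment unless $k_G = 0$; the worked examples set $k_4 = 0$
so the fourth generation does not proliferate further.

## Solution strategy

Three coordinate/algebra steps reduce the system to textbook form.

1. **Boundary fixing.** $\xi = x / L(t)$ maps the moving interval to
   $(0, 1)$; under uniform growth the advection term cancels exactly,
   leaving a diffusion coefficient $D/L^2(t)$ and an extra dilution sink
   $-\sigma(t) C_i$ (a fixed number of cells occupies a lengthening
   domain).
2. **Time rescaling.** $T(t) = \int_0^t D / L^2(s)\,ds$ makes the diffusion
   coefficient constant. Closed forms are used for exponential growth,
   $T = D(1 - e^{-2\alpha t})/(2\alpha L_0^2)$, and linear growth,
   $T = (D/\beta)(1/L_0 - 1/(L_0 + \beta t))$; custom laws use adaptive
   quadrature (absolute tolerance $10^{-12}$), with $\sigma$ obtained by
   central differencing of $\log L$ with step $10^{-6}\max(1, t)$, since a
   custom law supplies only the experimentally observed primitive $L(t)$.
3. **Uncoupling.** The Sun–Clement transform $a = W C$, with unit
   lower-triangular $W[i,j] = \prod_{l=j}^{i-1} m k_l / (k_l - k_i)$,
   satisfies $W K W^{-1} = \mathrm{diag}(-k_i)$ for the reaction matrix $K$
   and so turns the chain into $G$ independent single-species equations.
   It exists only for pairwise distinct rates.

Each uncoupled field then has the separated cosine-series solution

$$
a_i(x,t) = \sum_{n=0}^{N} \Psi_{i,n} \cos\!\Big(\frac{n\pi x}{L(t)}\Big)
  e^{-(n\pi)^2 T(t)}\, e^{-k_i t}\, \frac{L(0)}{L(t)},
$$

and $C = W^{-1} a$ by forward substitution. The combined reaction–dilution
factor is evaluated through the identity
$\int_0^t (k_i + \sigma)\,ds = k_i t + \ln(L(t)/L_0)$, i.e. as
$e^{-k_i t} L_0/L(t)$, which holds for *any* uniform growth law; for
exponential growth it reduces to the familiar $e^{-(\alpha + k_i)t}$. Since
only the exponential-growth specialisation has a printed closed form, the
general factor is asserted in the test suite by agreement with the
finite-difference solver on a linearly growing domain.

Fourier coefficients come from the initial condition. For the Heaviside
block (generation 1 at density $\mathcal{C}$ on $0 < x < \gamma$, all later
generations empty),
$\Psi_{1,0} = \mathcal{C}\gamma/L_0$ and
$\Psi_{1,n} = (2\mathcal{C}/n\pi)\sin(n\pi\gamma/L_0)$; the uncoupled
coefficients are then $\Psi_{i,n} = W[i,1]\,\Psi_{1,n}$. General initial
conditions are projected by adaptive quadrature and transformed with the
full matrix $W$. The value assigned to the jump point itself is irrelevant
(measure zero).

## Repeated rates

When rates coincide the transform is singular, but the solution is the
smooth limit of the distinct-rate solution. Two rates are declared equal
when $|k_i - k_j| \le 10^{-8}\max(1, |k_i|, |k_j|)$; beyond that threshold
the rate-ratio products in $W$ amplify rounding error faster than the limit
formulas lose accuracy. `solve_series()` dispatches:

* **All rates equal** (generation-1-only start): the L'Hôpital limit
  $C_i = \dfrac{(m k_1 t)^{i-1}}{(i-1)!}\, C_1$.
* **Four generations with $k_1 = k_2 = k_3 \ne k_4$**: the corresponding
  explicit closed form, implemented directly and cross-checked against the
  modal solver.
* **Any other repeated pattern**: delegation to `solve_modal()`. Deriving
  symbolic limits for every multiplicity pattern would add code paths that
  are hard to validate, while the modal route is exact for all of them; the
  two printed patterns are kept as independent closed forms precisely so
  that the delegation target can be cross-checked.

The limit behaviour is itself tested: evaluating the distinct-rate path at
$k_2 = k_1 + \varepsilon$ converges linearly in $\varepsilon$ to the
equal-rates form, with the Richardson-extrapolated limit agreeing to
$10^{-6}$.

## The modal solver

`solve_modal()` is a second, independent derivation used both as a
user-facing solver and as an internal oracle. Expanding every generation in
the same cosine basis, mode $n$ carries a generation-amplitude vector
$b_n(t)$ obeying $\dot b_n = K b_n$ — the spatial operators contribute only
the shared scalar decay $g_n(t) = e^{-(n\pi)^2 T(t)} L_0/L(t)$, because
diffusion, dilution and the reaction chain all commute mode by mode. Hence
$b_n(t) = e^{K t} b_n(0)$ with the matrix exponential computed densely
(scaling and squaring; $G$ is at most tens, so structure exploitation is
pointless) and shared across modes. This route never forms $W$, so it has
no distinct-rates restriction, and it agrees with the series route to
$10^{-10}$ sup-norm wherever both apply.

## The finite-difference solver

`solve_fd()` discretises the boundary-fixed form
$\partial C_i/\partial t = (D/L^2)\,\partial^2 C_i/\partial\xi^2 -
(\sigma + k_i) C_i + m k_{i-1} C_{i-1}$ with central second differences in
$\xi$, a ghost-point closure for the zero-flux boundaries, and backward
Euler in time with diffusion and reaction implicit at the new time level;
the coupling source uses the already-updated previous generation, so each
step is one tridiagonal (Thomas) solve per generation, marched in compiled
code. The time-dependent coefficient $D/L^2$ is evaluated at the new time
level. Backward Euler was chosen over Crank–Nicolson for unconditional
stability and monotone handling of the discontinuous initial profile; at
the default steps $\delta\xi = \delta t = 10^{-3}$ its first-order-in-time
error is far below the visual-agreement tolerance used for validation, and
the scheme's accuracy is accepted against the exact series solution rather
than against any particular reference discretisation. Block initial data
are discretised by cell averages (the node whose cell straddles
$x = \gamma$ receives the occupied fraction), which reduces the grid
sensitivity of the jump.

## Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `L0` | initial domain length | length | — (worked examples: 1) |
| `alpha` / `beta` | exponential / linear growth rate | 1/time, length/time | — |
| `D` | cell diffusivity | length²/time | — (examples: $10^{-5}$–$10^{-2}$) |
| `k` | per-generation conversion rates | 1/time | — |
| `m` | amplification per conversion | — | 2 |
| `C0`, `gamma` | block density and width | cells/length, length | — |
| `N` | retained cosine modes beyond $n=0$ | — | 1000 |
| `dxi`, `dt` | finite-difference steps | —, time | $10^{-3}$, $10^{-3}$ |

$N = 1000$ is deliberately conservative: for the worked examples the
truncation error at $(x,t) = (0,20)$ is below machine precision from about
10 modes, because the modal decay $e^{-(n\pi)^2 T(t)}$ is already
$\sim 10^{-21}$ at $n = 10$. Rather than prescribing a universal $N$,
`choose_truncation()` implements iterative doubling — evaluate, double $N$,
compare successive values — with default tolerance $10^{-12}$, which is
also exposed on the command line. Series evaluation at $t = 0$ exhibits the
usual Gibbs oscillation at the jump; comparisons against the discontinuous
profile exclude a window of width $0.02\,L_0$ around $\gamma$ and require
several thousand modes for a $10^{-3}$ sup-norm away from it. Headline
boundary densities are reported rounded half-to-even to four decimal
places. Output grids are fixed-$\xi$ by default (matching scaled density
profiles); fixed-$x$ grids are available and must lie inside the domain at
every requested time.

## What the worked examples do and do not show

The bundled configurations emulate the canonical colonization scenario: a
block of founder cells confined near the fixed end of an exponentially
growing domain, with graded (or equal) proliferation rates across four
generations. They exercise every analytical path in the package. They do
not emulate features of real developmental data — crowding effects,
position-dependent growth, stochastic small-population effects, branching
fates — so passing tests demonstrate correctness of the stated linear
model, not fidelity of that model to any particular tissue.

Verification is layered: closed-form growth quantities against adaptive
quadrature; the uncoupling matrix against its defining similarity property
(50 random well-separated rate ladders, $G \le 8$); the series against an
independently coded heat-kernel series in the static single-species limit;
series vs modal to $10^{-10}$ on distinct-rate problems and series vs
finite differences to 1% of the solution maximum on the worked examples;
and mass balance — with zero-flux boundaries, diffusion and dilution leave
the per-generation totals $M_i(t) = \int_0^{L(t)} C_i\,dx$ obeying the pure
reaction kinetics $\dot M = K M$, so quadrature totals of the spatial
solution are matched to the matrix-exponential kinetics to $10^{-6}$
relative over 20 random parameter draws. Test problem sizes (grids of
101–501 points, $N$ up to 8000 for the Gibbs check, 20 random draws per
property) were chosen so that each layer probes a different failure mode at
comfortable numerical margins.

## Known limitations

* Homogeneous Neumann boundaries only; Dirichlet or non-zero-flux
  conditions require different eigenfunctions and extra care, and raise a
  not-implemented error.
* One spatial dimension; for 2-D/3-D growing domains numerical methods are
  the practical choice.
* Linear kinetics with constant, chain-structured rates; no density
  dependence, branching, or $k_i(t)$.
* The closed-form dispatch for repeated rates covers the two patterns with
  explicit formulas; all other patterns take the modal route, which is
  exact but ties evaluation cost to the matrix exponential per output time.
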