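---
title: "Methods: a mean field game of diel vertical migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mean field game of diel vertical migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A continuum of identical small organisms (think copepods) lives in a water
column $x \in [0, H]$, $x$ increasing downward. Each agent steers its vertical
velocity $V$ against random displacement:
$dX_t = V\,dt + \sigma\,dB_t$, reflected at surface and bottom, with
independent noise across agents. An agent harvests energy at rate
$g(x) = g_0/(1+e^{k_2(x - x_{\mathrm{clin}})})$, pays a quadratic locomotion
cost $\tfrac{\nu}{2}V^2$, and dies at rate
$\mu(x,t) = \mu_0(x,t) + \mu_1 N(x,t)$. The density-independent part is
visual predation risk: surface light
$I_s(t) = I_0/(1+e^{A\cos(2\pi t/T)})$ (time zero is midnight; the logistic
is evaluated via `plogis` so arbitrary amplitudes $A$ cannot overflow) decays
as $I = I_s e^{-k_1 x}$, a predator's detection radius solves the saturating
visual-range equation $r^2 e^{k_1 r} = \gamma^2 I/(K+I)$, and
$\mu_0 = m\,r^2 + \mu_{\text{base}}$ is proportional to the detection
cross-section. The crowding term $\mu_1 N$ is the mean-field coupling.

A Nash equilibrium is a time-periodic pair $(N, U)$: the density solves the
forward Kolmogorov (Fokker-Planck) equation under $V = U_x/\nu$, while the
value function $U$ — expected remaining lifetime energy gain — solves the
Hamilton-Jacobi-Bellman equation
$U_t + U_x^2/2\nu + \tfrac{\sigma^2}{2}U_{xx} + g - U(\mu_0+\mu_1 N) = 0$
with homogeneous Neumann walls. If both PDEs hold simultaneously, the
verification theorem gives a Nash equilibrium; the solver therefore treats
the simultaneous residual as the object of interest, and "solved" means both
residuals vanish to tolerance at once.

An equivalent route (valid in the quasi-static regime, where lifetime spans
many days and fluctuations of $U$ are negligible) is PDE-constrained
optimization: maximize
$\iint (g - F(\mu_0 + \mu_1 N/2) - \tfrac{\nu}{2}V^2)\,N\,dx\,dt$ over
velocity fields, the density being the periodic Fokker-Planck response to
$V$. The crowding term enters with $\mu_1/2$ because its functional
derivative then restores the full $\mu_1 N$ — the familiar wedge between
selfish equilibrium and common good. The fitness constant
$F = \langle N, g - \tfrac{\nu}{2}V^2\rangle / \langle N, \mu_0+\mu_1
N\rangle$ is the unique value for which the periodic adjoint equation is
solvable; the package treats that solvability as a computable diagnostic (the
per-period drift $\langle N, g - F(\mu_0{+}\mu_1 N) - \tfrac{\nu}{2}V^2\rangle$).

## Parameters

Defaults of `env_params()` (SI-ish units as stated):

| symbol | meaning | default | units |
|---|---|---|---|
| H | column depth | 500 | m |
| T | light period | 24 | h |
| I0 | max irradiance | 1 | W m^-2 nm^-1 |
| K | light saturation | 1 | W m^-2 nm^-1 |
| gamma | max detection distance | 0.02 | m |
| k1 | light absorption | 0.02 | m^-1 |
| A | light-cycle contrast | 13 | – |
| nu | drag (cost of motion) | 1e-6 | J h m^-2 |
| sigma2 | diffusivity | 20 | m^2 h^-1 |
| mu1 | crowding mortality | 1 | h^-1 |
| m | predation scaling | 100 | m^-2 h^-1 |
| mu_base | baseline mortality | 1e-5 | h^-1 |
| k2 | food profile decay | 0.02 | m^-1 |
| g0 | max harvest | 0.01 | J h^-1 |
| x_clin | mixed-layer depth | 100 | m |

The drag is deliberately small: velocity responds sharply to value gradients,
which is what makes the coupled system numerically stiff (see below).
`I` and `K` are taken in identical units, so only the ratio $I/(K+I)$ enters
the optics.

## Discretization

Cell-centred finite volumes in depth ($n_x$ cells of width $dx = H/n_x$,
velocities on faces) crossed with a periodic time grid ($n_t$ slices,
implicit Euler, slice $n_t{+}1 \equiv$ slice 1 structurally — periodicity is
not a boundary condition but an identification, so $N(\cdot,0)=N(\cdot,T)$
holds by storage). The advective-diffusive flux uses Scharfetter-Gummel
exponential fitting
$J_f = \tfrac{D}{dx}[B(-w)N_{\text{up}} - B(w)N_{\text{down}}]$,
$w = V_f\,dx/D$, $B(w) = w/(e^w - 1)$, $D = \sigma^2/2$, with $J = 0$ imposed
on both boundary faces. This choice buys three exact discrete properties that
the test suite leans on:

* every operator column sums to zero — mass is conserved per step to
  round-off;
* implicit Euler steps are positivity-preserving (M-matrix);
* constant-coefficient steady states $N^* \propto e^{2Vx/\sigma^2}$ are
  reproduced to machine precision, and smooth variable-coefficient steady
  states converge at second order.

The backward (HJB) transport operator is defined as the *exact transpose* of
the Fokker-Planck operator, so the forward/backward duality that justifies
the Neumann condition holds identically at the discrete level (constants are
in its kernel because the FP columns sum to zero). Time indexing is
backward-looking for the density and forward-looking for the value function,
which keeps the duality pairing consistent across the periodic wrap. The
Bernoulli function and its derivative are evaluated in overflow-safe branches
with series near zero, so transient Newton iterates with extreme face Peclet
numbers cannot produce NaNs.

## The monolithic Newton solver

All $2 n_x n_t$ unknowns (density, then value) are solved at once. The
stacked residual replaces one redundant Fokker-Planck row (cell 1, slice 1)
with the mass constraint $dx\sum_j N_{j,1} = 1$ — the periodic FP block has a
one-dimensional mass kernel, and since the dropped row is a linear
combination of the others, the pinned solution still satisfies it exactly.
The Jacobian is analytic and sparse (~115k nonzeros at 100×96), including
the velocity coupling $\partial(A(V)N)/\partial U$ through the flux
sensitivities $B'(\pm w)$; a finite-difference check of every entry is part
of development lore, and the directional-derivative tests in the suite would
catch regressions.

Damping is Armijo backtracking on the residual 2-norm; convergence is
declared on the max-norm at `newton_tol = 1e-8`. The interesting difficulty
is the $1/\nu$ Hamiltonian: at the default drag, Newton from any generic
initialization stalls, because the quadratic convergence basin in $U$ has
radius of order $\nu\,dx$. The solver therefore ramps the drag down a ladder
($\nu \times 10^4, 10^3, 10^2, 30, 10, 5, 3, 2, 1.5, 1.2, 1$ by default),
warm-starting each stage — with inflated drag the game is nearly linear, and
each subsequent stage converges in a handful of iterations. A continuation in
the crowding parameter was tried first and discarded: crowding is not where
the stiffness lives. Initialization is a uniform density plus one linear
periodic HJB pass (quadratic term dropped, density frozen uniform), which is
exact for homogeneous environments — so the analytic closed-form cases
converge at iteration zero.

Local uniqueness is probed by restarting from a perturbed solution (10%
multiplicative noise on the density; on the value field the noise is applied
to its depth structure, since $U$ is nearly depth-constant while its
*gradient* carries the strategy — noise on the absolute level of $U$ would
perturb velocities by three orders of magnitude) and checking return to the
same equilibrium within 1e-6 relative.

## The reduced-gradient optimizer

The optimization route is kept independent of the game solver: it starts
from $V \equiv 0$, eliminates the density through the pinned periodic
Fokker-Planck solve, refreshes $F$ from `fitness_F` each outer cycle
(under-relaxed by 0.5 — the undamped fixed point alternates), and ascends the
reduced objective with L-BFGS-B on the exact discrete gradient.

"Exact" is the operative word: the gradient is derived by
differentiate-the-discretization, not by discretizing the continuous
optimality condition. The adjoint of the pinned FP system turns out to be the
clean periodic adjoint equation shifted by a constant (the pinning multiplier
vanishes when $F$ is consistent), and the face gradient is
$q_f\,(\partial_x p)_f - \nu N_f V_f$ where
$q_f = -B'(-w)N_{\text{left}} - B'(w)N_{\text{right}}$ is the
Scharfetter-Gummel flux sensitivity. $q_f$ reduces to the arithmetic face
mean as $w \to 0$; using the arithmetic mean at finite $w$ leaves an $O(w)$
error that a central-difference check at 1e-5 relative exposes immediately.
With $q_f$, the directional derivatives match finite differences to the
accuracy of the differencing itself (~1e-8 observed on a 20×12 grid).

The periodic adjoint system always carries the constants in its kernel (no
killing term acts on $p$), so it is solved in bordered form: the density
direction completes the range, a mean-zero row pins the constant, and the
bordering multiplier reports any incompatibility alongside the per-period
drift. Inflating $F$ by 10% yields a clearly negative drift — that sign is a
test.

Convergence is declared on a density-weighted gradient norm
($\sum dx\,dt\,\mathrm{grad}^2/N_f$)^{1/2} ≤ `grad_tol`, because the
unweighted norm is dominated by void regions where the objective is flat in
$V$. On scenarios with a well-populated column the optimizer matches the
game solver's density to well under 5% relative $L^2$; on the baseline it
plateaus with a small but nonzero weighted gradient — the criterion is
genuinely ill-conditioned where nobody lives, and the solver reports
`converged = FALSE` honestly in that case rather than pretending
stationarity.

## The stochastic simulator

Euler-Maruyama with folding reflection (exact for the Euler step, preserves
the uniform stationary law), velocity and density fields interpolated
linearly in depth and held piecewise constant per time slice — matching the
implicit-Euler field semantics — and Bernoulli killing at probability
$1-e^{-\mu\,dt_{\text{sim}}}$ per step. The fitness estimator `mc_fitness`
instead keeps all paths alive and weights the energy integrand by the
analytic survival weight $e^{-\int\mu}$ (with a midpoint half-step discount,
second order in $dt_{\text{sim}}$): a variance-reduced estimator of the
discounted value. Everything is driven by a single `set.seed` call, so a
seed reproduces an ensemble bit for bit.

## Verification strategy and problem sizes

The suite checks each layer against an independent oracle: closed forms
(homogeneous environment $N \equiv 1/H$, $U \equiv g/(\mu_0+\mu_1/H) = 10/3$;
constant-advection exponential profiles), transpose/duality identities,
manufactured variable-coefficient steady states for convergence order,
central finite differences for the adjoint gradient, and the stochastic
simulator against the grid transport. Monte-Carlo comparisons use a
parametric bootstrap null band: the Wasserstein-1 distance between a
20,000-agent ensemble and the propagated grid density is required to sit
below the mean + 3 sd of the same statistic computed on samples drawn from
the grid density itself. The comparison is meaningful only where
discretization bias is below that band, which sets the test design: fields
with moderate face Peclet numbers, $dt = 0.25$ h, $dt_{\text{sim}} = dt/8$.
Feynman-Kac probes compare discounted path integrals against the value
function at five depths with a 3-SE bracket plus a 1e-3 J allowance; the
allowance covers the $O(dx^2) + O(dt_{\text{sim}})$ discretization bias,
which at the default resolution is about 2e-4 J and dominates the tiny
standard error of the weighted estimator. Path horizons (1200 h baseline,
3000 h homogeneous) are several expected lifetimes, and the estimator
reports a worst-case truncation bound alongside.

Default production resolution is $n_x = 100$, $n_t = 96$ (5 m × 15 min),
which resolves the dawn/dusk transitions; solver-equivalence and uniqueness
probes run at 40×24 and 50×48, where the solutions are already within 2% of
the refined ones (the refinement test quantifies exactly that).

## Diagnostics conventions

Quantile trajectories interpolate the per-slice CDF keeping both endpoints
of every increasing run, so quantiles land inside occupied cells rather than
being smeared across voids. The temporal symmetry axis minimizes the
periodic reflection mismatch over grid axes with quadratic refinement; since
reflecting about $t^*$ and $t^* + T/2$ induces the same slice pairing, the
axis is defined only modulo half a period, and the reported representative
is the one with the deeper population median — the daytime axis. For the
baseline this is noon: the model is symmetric under time reversal about both
midnight and noon, and the axis lands at 12 h up to one time step. Solution
comparisons use a symmetrized relative $L^2$ for densities and a
density-weighted metric for velocities (void regions say nothing about the
strategy).

## What the synthetic scenarios do and do not capture

The built-in scenarios (baseline; drag ×10; crowding ×0.1; predation ×0.1;
low-mortality; homogeneous and constant-advection analytic cases; a
diffusivity sweep σ² ∈ {5, 20, 80}) probe the model's response surface and
its analytic limits. They are still the model's own world: time-invariant
logistic food, wavelength-free optics, one homogeneous population,
independent noise. Passing tests demonstrates internal consistency of the
equilibrium computation — not that real zooplankton follow a quadratic cost
of motion, and not anything about correlated turbulence, predator dynamics,
or seasonal forcing, all of which are outside the model class.

## Known limitations

* The optimizer can stall before true stationarity in void regions (reported
  honestly via `converged`/`gradient_norm`); the game solver is the
  authoritative route there.
* No velocity bound is imposed anywhere; extreme parameter sets could in
  principle produce face Peclet numbers where the flux saturates and the
  Jacobian becomes nearly singular — the drag ladder mitigates, but does not
  eliminate, this.
* Fitness values other than `fitness_F` make the periodic adjoint
  inconsistent; the drift is reported but the non-equilibrium extension (a
  multiplier on the normalization constraint) is not implemented.
* The symmetry axis is intrinsically half-period ambiguous; the median-depth
  tie-break assumes a migrating (depth-structured) density.
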