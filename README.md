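# dvmgame

Diel vertical migration (DVM) — the daily descent of zooplankton and other
small aquatic organisms to dark, safe depths by day and their return to
food-rich surface waters by night — is a collective phenomenon: the risk any
individual faces depends on where everyone else is. `dvmgame` models DVM as a
*mean field game* with a continuum of identical players in a water column
`[0, H]`, solves for its Nash equilibrium, and cross-validates the solution by
three independent routes. It is aimed at theoretical/behavioural ecologists
and applied mathematicians studying habitat selection under density
dependence.

## The model

Each agent controls its vertical velocity `V` but is also jostled by
uncontrolled fluctuations,

    dX = V dt + sigma dB,     X in [0, H], reflected at both walls,

and accumulates fitness at rate `g(x) - (nu/2) V^2` (logistic food profile
minus a quadratic cost of motion) while being killed at rate

    mu(x, t) = mu0(x, t) + mu1 N(x, t),

where `mu0 = m r^2 + mu_base` is visual predation risk — `r` solves the
saturating visual-range equation `r^2 exp(k1 r) = gamma^2 I/(K + I)` with
`I(x, t)` the periodically varying, exponentially attenuated light — and
`mu1 N` penalizes crowding. A Nash equilibrium of the game is a time-periodic
pair: a density `N` solving the Fokker-Planck equation under the optimal
velocity, and a value function `U` solving the Hamilton-Jacobi-Bellman
equation

    U_t + (U_x)^2 / (2 nu) + (sigma^2/2) U_xx + g - U (mu0 + mu1 N) = 0,

with `V = U_x / nu`, no-flux and homogeneous Neumann boundary conditions, and
unit mass. `dvmgame` solves this coupled system monolithically (damped Newton
on a Scharfetter-Gummel finite-volume discretization with a drag
continuation), and independently solves the equivalent PDE-constrained
optimization problem — maximize the population energy gain
`∬ (g - F(mu0 + mu1 N / 2) - nu V^2/2) N dx dt` over velocity fields, with an
adjoint state `p` and the quasi-static fitness constant
`F = <N, g - nu V^2/2> / <N, mu0 + mu1 N>` — by exact-adjoint reduced-gradient
ascent. A reflected, killed Euler-Maruyama simulator provides Monte-Carlo
checks of both the density (Wasserstein distance) and the value function
(Feynman-Kac discounted path integrals).

## Worked example

```r
library(dvmgame)

p   <- env_params()                 # defaults: H = 500 m, T = 24 h, nu = 1e-6, ...
g   <- build_grid(100, 96, p)       # 5 m cells, 15 min slices
sol <- solve_mfg(p, g, solver_options())
print(sol)
#> <mfg_solution> 100x96 grid; converged: TRUE (|r|_inf = 1.95e-13, 58 iterations)
#>   fitness F = 0.671638 J; mass range 1.000e+00..1.000e+00

med <- quantile_trajectories(sol$N, g, c(0.25, 0.5, 0.75))
med[2, c(1, 49)]      # median depth at midnight and at noon
#> 52.9 157.1
symmetry_axis(sol$N, g)
#> 12.04
range(sol$V)
#> -43.8  63.8
```

The population sits at ~53 m at midnight, descends to ~157 m at noon (a
104 m migration of the median), and the density field is mirror-symmetric
about 12.04 h — noon, as the symmetric light cycle dictates. The fitness
`F = 0.67 J` is the expected remaining lifetime energy gain of an agent.
Velocities peak near 64 m/h downward at dawn: descending faster than
ascending, because being caught near the bright surface is expensive. The
optimization route is run with `solve_opt(p, g)` and compared with
`compare_solutions()`; the stochastic simulator with `simulate_agents()` and
`mc_fitness()`.

A command-line front end wraps these functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "dvmgame.R", package = "dvmgame"))') \
    solve-mfg --config cfg.json --out run
```

with subcommands `env`, `solve-mfg`, `solve-opt`, `simulate`, `compare`,
`scenarios` and `convergence`.

## Scope

One spatial dimension, one population, periodic days, independent noise
across agents. Common-noise games, trophic coupling, population dynamics,
seasonal or horizontal movement and heterogeneous agents are out of scope.
See the methods vignette (`vignettes/methods.Rmd`) for the discretization,
solver design, and verification strategy.
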