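test_that("the periodic FP solve reproduces closed forms and stays normalized", {
  p <- homog_params()
  g <- build_grid(30, 12, p)
  # no advection: uniform
  N <- solve_periodic_fp(matrix(0, 31, 12), g, p)
  expect_lt(max(abs(N - 1 / p$H)) * p$H, 1e-12)
  # constant velocity: exponential profile, machine precision
  for (c0 in c(-6, 2, 9)) {
    V <- matrix(0, 31, 12); V[2:30, ] <- c0
    N <- solve_periodic_fp(V, g, p)
    ex <- exp(2 * c0 * g$x / p$sigma2); ex <- ex / (g$dx * sum(ex))
    expect_lt(max(abs(N - ex)) / max(ex), 1e-12)
  }
  # arbitrary velocity: unit mass at every slice, nonnegative
  V <- test_velocity(g, amp = 12, seed = 8)
  N <- solve_periodic_fp(V, g, p)
  expect_lt(max(abs(cell_integral(N, g) - 1)), 1e-12)
  expect_true(min(N) >= 0)
})

test_that("objective and fitness agree with the homogeneous closed forms", {
  p <- homog_params()
  g <- build_grid(20, 8, p)
  N <- matrix(1 / p$H, 20, 8)
  V0 <- matrix(0, 21, 8)
  Fstar <- 10 / 3
  # integrand constant: T (g - F(mu0 + mu1/(2H)))
  expect_equal(objective(N, V0, Fstar, g, p),
               p$T * (0.01 - Fstar * (0.001 + 1 / (2 * p$H))), tolerance = 1e-12)
  pg0 <- env_params(g0 = 0)
  expect_identical(objective(N, V0, 0, build_grid(20, 8, pg0), pg0), 0)
  expect_equal(fitness_F(N, V0, g, p), Fstar, tolerance = 1e-14)
  # doubling nu doubles the kinetic part of the objective
  V <- test_velocity(g, amp = 5, seed = 2)
  p2 <- p; p2$nu <- 2 * p$nu
  kin1 <- objective(N, V0, 0, g, p) - objective(N, V, 0, g, p)
  kin2 <- objective(N, V0, 0, g, p2) - objective(N, V, 0, g, p2)
  expect_equal(kin2, 2 * kin1, tolerance = 1e-12)
  # inflating V strictly decreases F
  expect_lt(fitness_F(N, V, g, p), Fstar)
  # mu1 = 0 with constant g/mu0 ratio returns that ratio for any density
  pr <- env_params(m = 0, mu_base = 0.002, mu1 = 0, k2 = 0, g0 = 0.02)
  set.seed(4)
  Nr <- matrix(runif(160), 20, 8); Nr <- sweep(Nr, 2, g$dx * colSums(Nr), "/")
  expect_equal(fitness_F(Nr, V0, g, pr), 0.01 / 0.002, tolerance = 1e-12)
  expect_error(fitness_F(Nr, V0, g, env_params(m = 0, mu_base = 0, mu1 = 0)), "fitness")
})

test_that("the adjoint is periodic for the consistent fitness and flags drift otherwise", {
  p <- env_params(m = 10)  # milder surface risk, still structured
  g <- build_grid(24, 12, p)
  V <- test_velocity(g, amp = 3, seed = 13)
  N <- solve_periodic_fp(V, g, p)
  Fc <- fitness_F(N, V, g, p)
  ad <- adjoint_solve(N, V, Fc, g, p)
  # compatible: drift machine-small, bordering multiplier negligible
  expect_lt(abs(attr(ad, "period_drift")), 1e-12)
  expect_lt(abs(attr(ad, "border_lambda")), 1e-8)
  # the adjoint equation itself is satisfied: residual of Eqs. transport form
  src <- with(env_fields(g, p), g - Fc * (mu0 + p$mu1 * N)) -
    (p$nu / 2) * dvmgame:::face_sq_to_cell(V)
  adn <- ad[, c(2:12, 1)]
  sg <- dvmgame:::sg_all(V, g, p)
  resid <- (adn - ad) / g$dt + dvmgame:::at_apply(ad, sg, g) + src
  expect_lt(max(abs(resid)), 1e-9)
  # inflated fitness: negative per-period drift, detected
  ad2 <- adjoint_solve(N, V, 1.1 * Fc, g, p)
  expect_lt(attr(ad2, "period_drift"), 0)
  # homogeneous case: adjoint constant, gradient zero
  ph <- homog_params()
  gh <- build_grid(20, 8, ph)
  Nh <- matrix(1 / ph$H, 20, 8); Vh <- matrix(0, 21, 8)
  adh <- adjoint_solve(Nh, Vh, 10 / 3, gh, ph)
  expect_lt(max(abs(adh - mean(adh))), 1e-12)
  expect_lt(max(abs(reduced_gradient(Nh, Vh, adh, gh, ph))), 1e-15)
})

test_that("reduced gradient matches central finite differences of the reduced objective", {
  p <- env_params()
  g <- build_grid(20, 12, p)
  env <- env_fields(g, p)
  set.seed(21)
  V <- matrix(0, 21, 12)
  V[2:20, ] <- matrix(rnorm(19 * 12, 0, 5), 19, 12)
  N <- solve_periodic_fp(V, g, p)
  Fc <- fitness_F(N, V, g, p, env)
  ad <- adjoint_solve(N, V, Fc, g, p, env)
  gr <- reduced_gradient(N, V, ad, g, p)
  Jred <- function(Vm) objective(solve_periodic_fp(Vm, g, p), Vm, Fc, g, p, env)
  eps <- 1e-5
  for (trial in 1:5) {
    dV <- matrix(0, 21, 12)
    dV[2:20, ] <- matrix(rnorm(19 * 12), 19, 12)
    fd <- (Jred(V + eps * dV) - Jred(V - eps * dV)) / (2 * eps)
    an <- g$dx * g$dt * sum(gr * dV)
    expect_lt(abs(fd - an) / abs(fd), 1e-5)
  }
  # gradient vanishes where the population does: zero out a region's density
  Nz <- N; Nz[15:20, ] <- 0
  gz <- reduced_gradient(Nz, V, ad, g, p)
  expect_identical(gz[17:20, ], matrix(0, 4, 12))
})

test_that("the crowding term differentiates to the full mu1 (factor-1/2 bookkeeping)", {
  p <- env_params()
  g <- build_grid(12, 6, p)
  env <- env_fields(g, p)
  set.seed(31)
  N <- matrix(runif(72), 12, 6); N <- sweep(N, 2, g$dx * colSums(N), "/")
  V <- test_velocity(g, amp = 2, seed = 32)
  Fc <- 1.3
  # dJ/dN_jk of the discrete objective must carry F*mu1*N (not mu1*N/2)
  h <- 1e-6
  jk <- c(5, 3)
  Np <- N; Np[jk[1], jk[2]] <- N[jk[1], jk[2]] + h
  Nm <- N; Nm[jk[1], jk[2]] <- N[jk[1], jk[2]] - h
  fd <- (objective(Np, V, Fc, g, p, env) - objective(Nm, V, Fc, g, p, env)) / (2 * h)
  expected <- g$dx * g$dt *
    (env$g[jk[1]] - Fc * (env$mu0[jk[1], jk[2]] + p$mu1 * N[jk[1], jk[2]]) -
       (p$nu / 2) * dvmgame:::face_sq_to_cell(V)[jk[1], jk[2]])
  expect_equal(fd, expected, tolerance = 1e-6)
})

test_that("the Lagrangian collapses to the objective on feasible densities", {
  p <- env_params(m = 10)
  g <- build_grid(16, 8, p)
  V <- test_velocity(g, amp = 4, seed = 41)
  N <- solve_periodic_fp(V, g, p)
  Fc <- fitness_F(N, V, g, p)
  ad <- adjoint_solve(N, V, Fc, g, p)
  expect_equal(lagrangian_value(N, V, ad, Fc, g, p),
               objective(N, V, Fc, g, p), tolerance = 1e-10)
  # p = 0 also collapses it, feasible or not
  set.seed(42)
  Nbad <- N * matrix(runif(length(N), 0.5, 1.5), nrow(N))
  expect_equal(lagrangian_value(Nbad, V, 0 * ad, Fc, g, p),
               objective(Nbad, V, Fc, g, p))
  # generic infeasible density: difference equals <fp_residual, p>
  diffv <- objective(Nbad, V, Fc, g, p) - lagrangian_value(Nbad, V, ad, Fc, g, p)
  expect_equal(diffv, g$dx * g$dt * sum(fp_residual(Nbad, V, g, p) * ad),
               tolerance = 1e-12)
})

test_that("the optimizer is stationary at the homogeneous start and ascends otherwise", {
  ph <- homog_params()
  gh <- build_grid(20, 8, ph)
  sol <- solve_opt(ph, gh)
  expect_true(sol$converged)
  expect_identical(sol$iterations, 0L)
  expect_identical(sol$V, matrix(0, 21, 8))
  expect_lt(max(abs(sol$N - 1 / ph$H)), 1e-14)
  expect_equal(sol$F, 10 / 3, tolerance = 1e-12)
})

test_that("game and optimization densities agree in the quasi-static regime", {
  # low-mortality limit: value-function fluctuations are negligible and the
  # two formulations coincide within 1 percent
  mfg <- mfg_on("low_mortality", 40, 24)
  opt <- opt_on("low_mortality", 40, 24)
  expect_true(mfg$converged)
  rel <- sqrt(sum((mfg$N - opt$N)^2) / sum(mfg$N^2))
  expect_lt(rel, 0.01)
})
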