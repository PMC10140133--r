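# memoized fixtures shared across test files (computed on first use)
.dvm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.dvm_cache[[key]])) .dvm_cache[[key]] <- force(expr)
  .dvm_cache[[key]]
}

# the analytic homogeneous environment: g = 0.01, mu0 = 0.001 everywhere
homog_params <- function() scenario_params("homogeneous")

baseline_solution <- function() cached("baseline_100x96", {
  p <- env_params()
  solve_mfg(p, build_grid(100, 96, p), solver_options())
})

baseline_small <- function() cached("baseline_50x48", {
  p <- env_params()
  solve_mfg(p, build_grid(50, 48, p), solver_options())
})

high_drag_solution <- function() cached("high_drag_100x96", {
  p <- scenario_params("high_drag")
  solve_mfg(p, build_grid(100, 96, p), solver_options())
})

mfg_on <- function(scenario, nx, nt) cached(sprintf("mfg_%s_%dx%d", scenario, nx, nt), {
  p <- scenario_params(scenario)
  solve_mfg(p, build_grid(nx, nt, p), solver_options())
})

opt_on <- function(scenario, nx, nt) cached(sprintf("opt_%s_%dx%d", scenario, nx, nt), {
  p <- scenario_params(scenario)
  suppressWarnings(solve_opt(p, build_grid(nx, nt, p), opt_options()))
})

# a fixed non-trivial face velocity field for operator tests
test_velocity <- function(grid, amp = 5, seed = 42) {
  set.seed(seed)
  V <- matrix(0, grid$nx + 1L, grid$nt)
  V[2:grid$nx, ] <- matrix(stats::rnorm((grid$nx - 1L) * grid$nt, 0, amp),
                           grid$nx - 1L, grid$nt)
  V
}
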