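# linear interpolation of a face field at arbitrary depths (faces at j*dx)
interp_faces <- function(vals, x, grid) {
  s <- x / grid$dx
  i <- pmin(pmax(floor(s), 0), grid$nx - 1L)
  fr <- s - i
  vals[i + 1L] * (1 - fr) + vals[i + 2L] * fr
}

# linear interpolation of a cell field at arbitrary depths (centres at
# (j-1/2)dx), constant extrapolation beyond the outermost centres
interp_cells <- function(vals, x, grid) {
  s <- x / grid$dx - 0.5
  i <- pmin(pmax(floor(s), 0), grid$nx - 2L)
  fr <- pmin(pmax(s - i, 0), 1)
  vals[i + 1L] * (1 - fr) + vals[i + 2L] * fr
}

# fold positions back into [0, H] (exact reflection for the Euler step)
reflect_fold <- function(x, H) {
  for (rep in 1:50) {
    out <- x < 0 | x > H
    if (!any(out)) break
    x <- ifelse(x < 0, -x, x)
    x <- ifelse(x > H, 2 * H - x, x)
  }
  pmin(pmax(x, 0), H)
}

time_slice <- function(t, grid) (floor((t %% grid$T) / grid$dt) %% grid$nt) + 1L

#' Simulate an ensemble of migrating agents
#'
#' Euler-Maruyama integration of the controlled diffusion
#' \code{dX = V dt + sigma dB} with reflection at the surface and bottom
#' (folding, exact for the Euler step) and, optionally, killing at the local
#' risk rate: each step an agent dies with probability
#' \code{1 - exp(-mu(X,t) dt_sim)} and enters an absorbing coffin state.
#' The velocity and density fields are interpolated linearly in depth and
#' held piecewise constant on the solver time slices, matching the
#' implicit-Euler field semantics. Each agent has an independent Brownian
#' path; a fixed seed reproduces the ensemble bit for bit.
#'
#' @param V Face velocity field ((nx+1) x nt) or NULL for no advection.
#' @param N Density field (nx x nt) feeding the crowding term of the risk
#'   rate, or NULL to drop it.
#' @param params A \code{dvm_params}.
#' @param grid A \code{dvm_grid} giving the field layout.
#' @param n Number of agents.
#' @param dt_sim Simulation step (h); default a quarter of the grid step.
#' @param horizon Simulated time span (h).
#' @param seed RNG seed (integer).
#' @param x0 Initial depths: a vector of length n, a single depth, or NULL to
#'   start uniform on [0, H].
#' @param t0 Start time (h), default 0.
#' @param kill Logical: apply Bernoulli killing (TRUE) or keep all agents
#'   alive (FALSE).
#' @param record_dt Spacing of recorded snapshots (h); must be a multiple of
#'   \code{dt_sim}.
#' @return A \code{trajectory_ensemble}: list with \code{times} (recorded
#'   stamps), \code{positions} (n x length(times)), \code{alive} (logical,
#'   same shape), \code{death_time} (h; Inf for survivors), \code{seed},
#'   \code{step}, \code{params}, \code{grid}.
#' @export
simulate_agents <- function(V, N, params, grid, n, dt_sim = grid$dt / 4,
                            horizon = params$T, seed = 1L, x0 = NULL, t0 = 0,
                            kill = TRUE, record_dt = grid$dt) {
  if (dt_sim <= 0) stop("dt_sim must be positive", call. = FALSE)
  if (n < 1) stop("need at least one agent", call. = FALSE)
  nrec_step <- record_dt / dt_sim
  if (abs(nrec_step - round(nrec_step)) > 1e-9)
    stop("record_dt must be a multiple of dt_sim", call. = FALSE)
  nrec_step <- round(nrec_step)
  nsteps <- ceiling(horizon / dt_sim - 1e-9)
  env <- env_fields(grid, params)
  sig <- sqrt(params$sigma2 * dt_sim)

  set.seed(seed)
  X <- if (is.null(x0)) stats::runif(n, 0, params$H) else rep_len(x0, n)
  alive <- rep(TRUE, n)
  death <- rep(Inf, n)

  times <- t0 + seq(0, by = record_dt, length.out = floor(nsteps / nrec_step) + 1L)
  pos <- matrix(NA_real_, n, length(times))
  alv <- matrix(FALSE, n, length(times))
  pos[, 1L] <- X; alv[, 1L] <- alive
  rec <- 1L

  t <- t0
  for (s in seq_len(nsteps)) {
    k <- time_slice(t, grid)
    drift <- if (is.null(V)) 0 else interp_faces(V[, k], X, grid)
    Xn <- X + drift * dt_sim + sig * stats::rnorm(n)
    Xn <- reflect_fold(Xn, params$H)
    if (kill) {
      mu <- interp_cells(env$mu0[, k], X, grid)
      if (!is.null(N)) mu <- mu + params$mu1 * interp_cells(N[, k], X, grid)
      die <- alive & (stats::runif(n) < -expm1(-mu * dt_sim))
      death[die] <- t + dt_sim
      alive <- alive & !die
    }
    X <- ifelse(alive, Xn, X)
    t <- t0 + s * dt_sim
    if (s %% nrec_step == 0L && rec < length(times)) {
      rec <- rec + 1L
      pos[, rec] <- X
      alv[, rec] <- alive
    }
  }
  structure(list(times = times, positions = pos, alive = alv,
                 death_time = death, seed = seed, step = dt_sim,
                 params = params, grid = grid),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d agents, %d snapshots over %.3g h (dt_sim = %g h, seed %d)\n",
              nrow(x$positions), length(x$times), diff(range(x$times)), x$step, x$seed))
  cat(sprintf("  survivors at end: %.1f%%\n", 100 * mean(x$alive[, ncol(x$alive)])))
  invisible(x)
}

#' Histogram density of the living agents at a time stamp
#'
#' @param ens A \code{trajectory_ensemble}.
#' @param t Time stamp (h); snapped to the nearest recorded snapshot.
#' @param bins Number of depth bins; with \code{bins = nx} the bin edges
#'   align with the grid faces.
#' @return List with \code{density} (length bins, integrates to 1),
#'   \code{mids}, \code{breaks} and \code{n_alive}.
#' @export
empirical_density <- function(ens, t, bins = ens$grid$nx) {
  j <- which.min(abs(ens$times - t))
  if (abs(ens$times[j] - t) > ens$step * 0.51 + 1e-9)
    stop("requested time outside the simulated horizon", call. = FALSE)
  x <- ens$positions[ens$alive[, j], j]
  if (length(x) == 0L) stop("no alive agents at the requested time", call. = FALSE)
  H <- ens$params$H
  breaks <- seq(0, H, length.out = bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(density = h$counts / (length(x) * (H / bins)), mids = h$mids,
       breaks = breaks, n_alive = length(x))
}

#' Monte-Carlo estimate of expected lifetime fitness
#'
#' Simulates unkilled paths from \code{(x0, t0)} under the velocity field and
#' accumulates the discounted energy integral
#' \eqn{\int (g - \nu V^2/2)\, e^{-\int \mu}\, dt}: survival enters through
#' the analytic exponential weight rather than Bernoulli killing, a
#' variance-reduced estimator of the value function. The horizon truncates
#' the integral; the reported bound is the worst-case remaining tail
#' \code{mean(w_end) * max(g) / min(mu)} computed from the realized terminal
#' weights.
#'
#' @param x0 Start depth (m).
#' @param t0 Start time (h).
#' @param V Face velocity field or NULL.
#' @param N Density field for the crowding mortality or NULL.
#' @param params A \code{dvm_params}.
#' @param grid A \code{dvm_grid}.
#' @param n Number of paths.
#' @param seed RNG seed.
#' @param horizon Path length (h); should be several expected lifetimes.
#' @param dt_sim Simulation step (h).
#' @return List with \code{estimate} (J), \code{se} (J), \code{truncation_bound}
#'   (J), \code{n}, \code{seed}, \code{horizon}.
#' @export
mc_fitness <- function(x0, t0, V, N, params, grid, n = 2000L, seed = 1L,
                       horizon = 100 * params$T, dt_sim = grid$dt) {
  if (dt_sim <= 0) stop("dt_sim must be positive", call. = FALSE)
  env <- env_fields(grid, params)
  sig <- sqrt(params$sigma2 * dt_sim)
  nsteps <- ceiling(horizon / dt_sim - 1e-9)

  set.seed(seed)
  X <- rep(x0, n)
  acc <- numeric(n)       # discounted energy integral per path
  logw <- numeric(n)      # log survival weight
  t <- t0
  for (s in seq_len(nsteps)) {
    k <- time_slice(t, grid)
    drift <- if (is.null(V)) 0 else interp_faces(V[, k], X, grid)
    mu <- interp_cells(env$mu0[, k], X, grid)
    if (!is.null(N)) mu <- mu + params$mu1 * interp_cells(N[, k], X, grid)
    gain <- harvest(X, params) - (params$nu / 2) * drift^2
    # midpoint discount within the step: second-order accurate in dt_sim
    acc <- acc + gain * exp(logw - mu * dt_sim / 2) * dt_sim
    logw <- logw - mu * dt_sim
    X <- reflect_fold(X + drift * dt_sim + sig * stats::rnorm(n), params$H)
    t <- t0 + s * dt_sim
  }
  mu_min <- max(min(env$mu0) + if (!is.null(N)) params$mu1 * min(N) else 0, 1e-12)
  list(estimate = mean(acc), se = stats::sd(acc) / sqrt(n),
       truncation_bound = mean(exp(logw)) * max(env$g) / mu_min,
       n = n, seed = seed, horizon = horizon)
}
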