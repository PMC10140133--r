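#' Built-in scenario presets
#'
#' Named parameter variations used throughout: the baseline parameter set,
#' single-parameter multipliers probing the cost of motion, crowding
#' mortality, predation pressure and diffusivity, and two analytic
#' configurations with closed-form solutions used for verification.
#'
#' @return A named list of \code{scenario_spec} objects, each with fields
#'   \code{name}, \code{multipliers} (factors applied to baseline parameter
#'   fields), \code{overrides} (absolute replacements) and
#'   \code{description}; analytic scenarios carry extra reference data.
#' @export
builtin_scenarios <- function() {
  sc <- function(name, description, multipliers = list(), overrides = list(), ...) {
    structure(list(name = name, multipliers = multipliers,
                   overrides = overrides, description = description, ...),
              class = "scenario_spec")
  }
  list(
    baseline = sc("baseline", "default parameterization"),
    high_drag = sc("high_drag", "increased cost of motion (nu x 10)",
                   multipliers = list(nu = 10)),
    low_mu1 = sc("low_mu1", "reduced density-dependent mortality (mu1 x 0.1)",
                 multipliers = list(mu1 = 0.1)),
    attractive_surface = sc("attractive_surface",
                            "reduced visual predation (m x 0.1): no void surface region",
                            multipliers = list(m = 0.1)),
    low_mortality = sc("low_mortality",
                       "quasi-static regime (m and mu_base x 0.01)",
                       multipliers = list(m = 0.01, mu_base = 0.01)),
    homogeneous = sc("homogeneous",
                     "depth- and time-invariant environment: g = 0.01, mu0 = 0.001; uniform N, constant U = g/(mu0 + mu1/H) = 10/3",
                     overrides = list(m = 0, mu_base = 1e-3, k2 = 0, g0 = 0.02)),
    constant_advection = sc("constant_advection",
                            "homogeneous environment probed with a fixed downward velocity; steady density ~ exp(2Vx/sigma^2)",
                            overrides = list(m = 0, mu_base = 1e-3, k2 = 0, g0 = 0.02),
                            const_velocity = 10),
    sigma_low = sc("sigma_low", "reduced diffusivity (sigma^2 = 5)",
                   overrides = list(sigma2 = 5)),
    sigma_mid = sc("sigma_mid", "baseline diffusivity (sigma^2 = 20)",
                   overrides = list(sigma2 = 20)),
    sigma_high = sc("sigma_high", "increased diffusivity (sigma^2 = 80)",
                    overrides = list(sigma2 = 80))
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> %s: %s\n", x$name, x$description))
  invisible(x)
}

#' Resolve a scenario into a parameter set
#'
#' @param scenario A scenario name (see \code{\link{builtin_scenarios}}) or a
#'   \code{scenario_spec}.
#' @param base Baseline parameters the multipliers/overrides act on.
#' @return A \code{dvm_params} object.
#' @export
scenario_params <- function(scenario, base = env_params()) {
  if (is.character(scenario)) {
    all <- builtin_scenarios()
    if (!scenario %in% names(all))
      stop("unknown scenario '", scenario, "'; available: ",
           paste(names(all), collapse = ", "), call. = FALSE)
    scenario <- all[[scenario]]
  }
  stopifnot(inherits(scenario, "scenario_spec"))
  p <- unclass(base)
  for (nm in names(scenario$multipliers)) {
    if (!nm %in% names(p)) stop("multiplier on unknown parameter '", nm, "'", call. = FALSE)
    p[[nm]] <- p[[nm]] * scenario$multipliers[[nm]]
  }
  for (nm in names(scenario$overrides)) {
    if (!nm %in% names(p)) stop("override on unknown parameter '", nm, "'", call. = FALSE)
    p[[nm]] <- scenario$overrides[[nm]]
  }
  class(p) <- "dvm_params"
  validate_params(p)
  p
}

#' Quantile depth trajectories
#'
#' For each time slice, the depth at which the cumulative vertical
#' distribution first reaches each probability (linear interpolation within
#' cells). These curves stand in for typical individual migration paths.
#'
#' @param N Density field, nx x nt.
#' @param grid A \code{dvm_grid}.
#' @param probs Probabilities in (0,1).
#' @return A length(probs) x nt matrix of depths (m), rows named by
#'   probability; non-crossing in the probability order.
#' @export
quantile_trajectories <- function(N, grid, probs = c(0.25, 0.5, 0.75)) {
  if (any(probs <= 0 | probs >= 1)) stop("probs must lie strictly in (0,1)", call. = FALSE)
  check_shapes(grid, N = N)
  out <- matrix(NA_real_, length(probs), grid$nt,
                dimnames = list(format(probs), NULL))
  for (k in seq_len(grid$nt)) {
    cdf <- c(0, cumsum(N[, k]) * grid$dx)
    cdf <- cdf / cdf[length(cdf)]
    # keep both endpoints of every increasing run so that quantiles land
    # inside occupied cells, not smeared across empty ones
    up <- diff(cdf) > 0
    keep <- c(FALSE, up) | c(up, FALSE)
    out[, k] <- stats::approx(cdf[keep], grid$xf[keep], xout = probs,
                              ties = "ordered", rule = 2)$y
  }
  out
}

#' Temporal mirror-symmetry axis of a periodic field
#'
#' Finds the time about which the field is most nearly mirror symmetric:
#' minimizes over candidate axes on the time grid the summed squared
#' difference between slices at \code{t* + s} and \code{t* - s} (periodic
#' indexing), then refines the minimizer by quadratic interpolation through
#' its grid neighbours. Reflections about \code{t*} and \code{t* + T/2}
#' produce the same set of slice pairings, so the mismatch determines the
#' axis only modulo half a period; of the two representatives the one where
#' the population median depth is larger (the daytime axis, for a migrating
#' density) is returned. For the baseline game this is noon.
#'
#' @param N Field, nx x nt (any role).
#' @param grid A \code{dvm_grid}.
#' @return Axis time in [0, T) (h). If the field is constant in time the
#'   smallest grid time is returned with attribute \code{degenerate = TRUE}.
#' @export
symmetry_axis <- function(N, grid) {
  check_shapes(grid, N = N)
  nt <- grid$nt
  mism <- vapply(seq_len(nt), function(a) {
    s <- seq_len(nt - 1L)
    ip <- ((a - 1L + s) %% nt) + 1L
    im <- ((a - 1L - s) %% nt) + 1L
    sum((N[, ip, drop = FALSE] - N[, im, drop = FALSE])^2)
  }, numeric(1))
  if (max(mism) - min(mism) <= 1e-14 * max(mism, 1e-300))
    return(structure(grid$t[1L], degenerate = TRUE))
  a <- which.min(mism)
  # quadratic refinement from the three neighbouring grid values
  m0 <- mism[((a - 2L) %% nt) + 1L]; m1 <- mism[a]; m2 <- mism[(a %% nt) + 1L]
  denom <- m0 - 2 * m1 + m2
  delta <- if (denom > 0) 0.5 * (m0 - m2) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  axis <- (grid$t[a] + delta * grid$dt) %% grid$T
  # half-period ambiguity: pick the representative with the deeper median
  alt <- (axis + grid$T / 2) %% grid$T
  med_at <- function(tt) {
    k <- (round(tt / grid$dt) %% nt) + 1L
    quantile_trajectories(N[, k, drop = FALSE],
                          grid_slice(grid), probs = 0.5)[1, 1]
  }
  if (med_at(alt) > med_at(axis)) alt else axis
}

# single-slice view of a grid (helper for per-slice quantile evaluation)
grid_slice <- function(grid) {
  g <- grid
  g$nt <- 1L
  g$t <- 0
  g
}

#' Compare the two solution routes
#'
#' Space-time relative L2 distance of the densities (symmetric in the two
#' arguments) and a density-weighted relative L2 distance of the velocities:
#' the objective is insensitive to velocities where nobody lives, so the
#' velocity metric weights squared differences by the mean density of the
#' adjacent cells, averaged over both solutions.
#'
#' @param a,b Solutions (\code{mfg_solution} / \code{opt_solution}) on the
#'   same grid.
#' @return A list of class \code{comparison_report}: \code{rel_L2_N},
#'   \code{rel_L2_V_weighted}, \code{F_a}, \code{F_b}, \code{notes}.
#' @export
compare_solutions <- function(a, b) {
  ga <- a$grid; gb <- b$grid
  if (ga$nx != gb$nx || ga$nt != gb$nt || ga$H != gb$H || ga$T != gb$T)
    stop("solutions live on different grids", call. = FALSE)
  dN <- sqrt(sum((a$N - b$N)^2))
  rel_N <- dN / ((sqrt(sum(a$N^2)) + sqrt(sum(b$N^2))) / 2)
  nx <- ga$nx
  wface <- function(N) rbind(0, (N[-nx, , drop = FALSE] + N[-1, , drop = FALSE]) / 2, 0)
  w <- (wface(a$N) + wface(b$N)) / 2
  num <- sum(w * (a$V - b$V)^2)
  den <- (sum(w * a$V^2) + sum(w * b$V^2)) / 2
  rel_V <- if (den > 0) sqrt(num / den) else 0
  structure(list(rel_L2_N = rel_N, rel_L2_V_weighted = rel_V,
                 F_a = a$F, F_b = b$F,
                 notes = sprintf("grids %dx%d", ga$nx, ga$nt)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> rel_L2_N = %.4g; weighted rel_L2_V = %.4g; F = %.6g vs %.6g\n",
              x$rel_L2_N, x$rel_L2_V_weighted, x$F_a, x$F_b))
  invisible(x)
}

#' Grid refinement study
#'
#' Solves a scenario on a sequence of nested grids and reports errors against
#' the analytic solution (where the scenario has one) or against the finest
#' grid, together with observed convergence orders.
#'
#' @param scenario Scenario name or \code{scenario_spec}.
#' @param grids A list of \code{c(nx, nt)} pairs, coarse to fine (at least
#'   3 when no analytic reference exists).
#' @param opts Solver options.
#' @param base Baseline parameters.
#' @return A data.frame with columns nx, nt, err_N (relative L2) and
#'   observed order (log2 ratio of successive errors).
#' @export
convergence_study <- function(scenario, grids, opts = solver_options(),
                              base = env_params()) {
  spec <- if (is.character(scenario)) builtin_scenarios()[[scenario]] else scenario
  if (is.null(spec)) stop("unknown scenario", call. = FALSE)
  params <- scenario_params(spec, base)
  analytic <- spec$name %in% c("homogeneous", "constant_advection")
  if (!analytic && length(grids) < 3L)
    stop("need at least 3 nested grids without an analytic reference", call. = FALSE)

  sols <- lapply(grids, function(gz) {
    grid <- build_grid(gz[1], gz[2], params)
    if (identical(spec$name, "constant_advection")) {
      V <- matrix(0, grid$nx + 1L, grid$nt)
      V[2:grid$nx, ] <- spec$const_velocity
      list(N = solve_periodic_fp(V, grid, params), grid = grid)
    } else {
      s <- solve_mfg(params, grid, opts)
      list(N = s$N, grid = s$grid)
    }
  })
  ref_density <- function(grid) {
    if (identical(spec$name, "constant_advection")) {
      prof <- exp(2 * spec$const_velocity * grid$x / params$sigma2)
      matrix(prof / (grid$dx * sum(prof)), grid$nx, grid$nt)
    } else {
      matrix(1 / params$H, grid$nx, grid$nt)
    }
  }
  errs <- vapply(seq_along(sols), function(i) {
    s <- sols[[i]]
    if (analytic) {
      R <- ref_density(s$grid)
      sqrt(sum((s$N - R)^2)) / sqrt(sum(R^2))
    } else {
      fine <- sols[[length(sols)]]
      rx <- fine$grid$nx / s$grid$nx; rt <- fine$grid$nt / s$grid$nt
      if (rx != round(rx) || rt != round(rt)) stop("grids must be nested", call. = FALSE)
      # average the fine solution onto the coarse cells/slices
      Nc <- fine$N
      Nc <- apply(Nc, 2, function(col) colMeans(matrix(col, nrow = rx)))
      Nc <- t(apply(Nc, 1, function(row) row[seq(1, length(row), by = rt)]))
      sqrt(sum((s$N - Nc)^2)) / sqrt(sum(Nc^2))
    }
  }, numeric(1))
  ord <- c(NA, log2(errs[-length(errs)] / errs[-1]))
  if (!analytic) { errs[length(errs)] <- NA; ord[length(ord)] <- NA }
  data.frame(nx = vapply(grids, `[`, numeric(1), 1),
             nt = vapply(grids, `[`, numeric(1), 2),
             err_N = errs, order = ord)
}

#' Propagate a density one step at a time under a periodic velocity field
#'
#' Non-periodic initial-value integration of the discrete Fokker-Planck
#' system (implicit Euler, same operator as the periodic solver): used to
#' cross-check the stochastic simulator against the grid transport.
#'
#' @param N0 Initial cell density (length nx, mass 1).
#' @param V Face velocity field, (nx+1) x nt, indexed periodically.
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params}.
#' @param nsteps Number of dt-steps to take.
#' @param k0 Time-slice index of the first step (default 1).
#' @return An nx x (nsteps+1) matrix of densities, first column \code{N0}.
#' @export
fp_propagate <- function(N0, V, grid, params, nsteps, k0 = 1L) {
  out <- matrix(NA_real_, grid$nx, nsteps + 1L)
  out[, 1L] <- N0
  I <- Matrix::Diagonal(grid$nx)
  for (s in seq_len(nsteps)) {
    k <- ((k0 - 1L + s - 1L) %% grid$nt) + 1L
    ksl <- (k %% grid$nt) + 1L  # slice whose operator advances t_k -> t_{k+1}
    A <- fp_operator(V[, ksl], grid, params)
    out[, s + 1L] <- as.numeric(Matrix::solve(I / grid$dt - A, out[, s] / grid$dt))
  }
  out
}

#' Wasserstein-1 distance between a sample and a grid density
#'
#' Integral of the absolute difference between the empirical CDF of the
#' sample and the piecewise-linear CDF of the cell density, evaluated on a
#' fine uniform abscissa.
#'
#' @param x Sample of depths.
#' @param N_slice Cell density (length nx, integrating to 1).
#' @param grid A \code{dvm_grid}.
#' @param M Number of evaluation points.
#' @return Distance in metres.
#' @export
wasserstein1_density <- function(x, N_slice, grid, M = 2000L) {
  xs <- seq(0, grid$H, length.out = M)
  Fe <- stats::ecdf(x)(xs)
  cdf <- c(0, cumsum(N_slice) * grid$dx)
  cdf <- cdf / cdf[length(cdf)]
  Fn <- stats::approx(grid$xf, cdf, xout = xs)$y
  mean(abs(Fe - Fn)) * grid$H
}
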