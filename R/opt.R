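# Monolithic periodic Fokker-Planck system matrix M over all slices
# (implicit Euler, backward-looking, periodic wrap). If pinned, the FP row of
# cell 1 at slice 1 is replaced by the mass constraint row.
fp_system <- function(V, grid, params, pinned = TRUE) {
  nx <- grid$nx; nt <- grid$nt; NN <- nx * nt
  sg <- sg_all(V, grid, params)
  kk <- rep(seq_len(nt), each = nx - 1L)
  fF <- rep(2:nx, times = nt)
  iL <- idx_n(fF - 1L, kk, nx)
  iR <- idx_n(fF, kk, nx)
  aL <- as.vector(sg$aL); aR <- as.vector(sg$aR)
  jd <- seq_len(NN)
  kprev <- rep(c(nt, seq_len(nt - 1L)), each = nx)
  jprev <- idx_n(rep(seq_len(nx), nt), kprev, nx)
  dx <- grid$dx
  i <- c(jd, jd, iL, iL, iR, iR)
  j <- c(jd, jprev, iL, iR, iL, iR)
  x <- c(rep(1 / grid$dt, 2L * NN) * c(rep(1, NN), rep(-1, NN)),
         aL / dx, aR / dx, -aL / dx, -aR / dx)
  if (pinned) {
    keep <- i != 1L
    i <- c(i[keep], rep(1L, nx))
    j <- c(j[keep], idx_n(seq_len(nx), 1L, nx))
    x <- c(x[keep], rep(dx, nx))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(NN, NN))
}

#' Periodic Fokker-Planck solve for a given velocity field
#'
#' Computes the unique time-periodic, mass-one density that solves the
#' implicit-Euler discretization of the forward Kolmogorov equation driven by
#' \code{V}. The one-dimensional mass kernel of the cyclic system is pinned by
#' replacing one redundant residual row with the normalization constraint;
#' conservation then propagates unit mass to every slice.
#'
#' @param V Face velocity field, (nx+1) x nt.
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params}.
#' @return An nx x nt density matrix (m^-1), nonnegative with unit mass at
#'   every slice.
#' @export
solve_periodic_fp <- function(V, grid, params) {
  check_shapes(grid, V = V)
  if (!all(is.finite(V))) stop("non-finite velocity entries", call. = FALSE)
  M <- fp_system(V, grid, params, pinned = TRUE)
  rhs <- c(1, rep(0, grid$nx * grid$nt - 1L))
  N <- tryCatch(as.numeric(Matrix::solve(M, rhs)),
                error = function(e) stop("periodic FP system is singular beyond the mass kernel: ",
                                         conditionMessage(e), call. = FALSE))
  matrix(N, grid$nx, grid$nt)
}

#' Population-level objective of the constrained formulation
#'
#' Discrete total energy gain of the population over one period,
#' \deqn{\int\!\!\int (g - F(\mu_0 + \mu_1 N/2) - \nu V^2/2)\, N \,dx\,dt,}
#' evaluated as the exact cell/slice sum with \code{V^2} averaged from the two
#' adjacent faces. The factor 1/2 on the crowding term makes the functional
#' derivative reproduce the full \eqn{\mu_1 N} of the game.
#'
#' @param N Density field, nx x nt.
#' @param V Face velocity field, (nx+1) x nt.
#' @param fitness The fitness constant F (J) converting mortality into energy
#'   loss.
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params}.
#' @param env Optional precomputed \code{\link{env_fields}}.
#' @return Scalar objective (J).
#' @export
objective <- function(N, V, fitness, grid, params, env = NULL) {
  check_shapes(grid, N = N, V = V)
  if (is.null(env)) env <- env_fields(grid, params)
  integrand <- env$g - fitness * (env$mu0 + params$mu1 * N / 2) -
    (params$nu / 2) * face_sq_to_cell(V)
  grid$dx * grid$dt * sum(integrand * N)
}

#' Fitness constant admitting a periodic adjoint
#'
#' \deqn{F = \langle N, g - \nu V^2/2 \rangle / \langle N, \mu_0 + \mu_1 N
#' \rangle:} the expected lifetime energy gain of an organism under the
#' quasi-static approximation, and the unique value of F for which the
#' periodic adjoint equation is solvable.
#'
#' @inheritParams objective
#' @return Scalar fitness (J).
#' @export
fitness_F <- function(N, V, grid, params, env = NULL) {
  check_shapes(grid, N = N, V = V)
  if (is.null(env)) env <- env_fields(grid, params)
  num <- sum(N * (env$g - (params$nu / 2) * face_sq_to_cell(V)))
  den <- sum(N * (env$mu0 + params$mu1 * N))
  if (den <= 0) stop("mortality vanishes identically: fitness undefined", call. = FALSE)
  num / den
}

#' Periodic adjoint state of the constrained problem
#'
#' Solves the time-periodic adjoint equation
#' \deqn{\partial p/\partial t + V \partial p/\partial x + (\sigma^2/2)
#' \partial^2 p/\partial x^2 + g - F(\mu_0+\mu_1 N) - \nu V^2/2 = 0}
#' with homogeneous Neumann walls, transport discretized as the exact
#' transpose of the Fokker-Planck operator. The periodic system always has
#' the constants in its kernel (no killing acts on p), so a bordered system
#' pins \code{mean(p) = 0}; the bordering multiplier absorbs any
#' incompatibility. When \code{fitness} differs from \code{fitness_F(N, V)}
#' the system is inconsistent and the per-period drift
#' \eqn{\langle N, g - F(\mu_0+\mu_1 N) - \nu V^2/2 \rangle} (attached as
#' attribute \code{period_drift}, units J per period) is nonzero: a fitness
#' set too high shows up as a negative drift.
#'
#' @inheritParams objective
#' @return An nx x nt adjoint matrix (J) with attributes \code{period_drift}
#'   and \code{border_lambda}.
#' @export
adjoint_solve <- function(N, V, fitness, grid, params, env = NULL) {
  check_shapes(grid, N = N, V = V)
  if (is.null(env)) env <- env_fields(grid, params)
  if (!is.finite(fitness)) stop("fitness must be finite", call. = FALSE)
  nx <- grid$nx; nt <- grid$nt; NN <- nx * nt
  S <- -Matrix::t(fp_system(V, grid, params, pinned = FALSE))
  src <- env$g - fitness * (env$mu0 + params$mu1 * N) -
    (params$nu / 2) * face_sq_to_cell(V)
  drift <- grid$dx * grid$dt * sum(N * src)
  # bordered system: [S, a; b', 0] [p; lambda] = [-src; 0]
  # a = vec(N) spans the complement of range(S); b pins the mean of p.
  Striplet <- methods::as(S, "TsparseMatrix")
  i <- c(Striplet@i + 1L, seq_len(NN), rep(NN + 1L, NN))
  j <- c(Striplet@j + 1L, rep(NN + 1L, NN), seq_len(NN))
  x <- c(Striplet@x, as.vector(N), rep(1 / NN, NN))
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(NN + 1L, NN + 1L))
  sol <- as.numeric(Matrix::solve(M, c(-as.vector(src), 0)))
  structure(matrix(sol[seq_len(NN)], nx, nt),
            period_drift = drift, border_lambda = sol[NN + 1L])
}

# Scharfetter-Gummel face density weight: the exact discrete sensitivity of
# the face flux to the face velocity. Reduces to the arithmetic mean of the
# adjacent cell densities as the face Peclet number tends to zero.
sg_face_density <- function(N, V, grid, params) {
  sg <- sg_all(V, grid, params)
  nx <- grid$nx
  sg$c1 * N[-nx, , drop = FALSE] + sg$c2 * N[-1, , drop = FALSE]
}

#' Reduced gradient of the objective over the velocity field
#'
#' The exact gradient (per unit of the space-time measure dx*dt) of the
#' reduced objective \code{J(V)} -- the objective with the density eliminated
#' through the periodic Fokker-Planck solve and the fitness held fixed --
#' evaluated from the adjoint state:
#' \code{grad_f = q_f * face_gradient(p)_f - nu * N_face_f * V_f}, where
#' \code{q_f} is the Scharfetter-Gummel face density weight (the discrete
#' flux sensitivity; the arithmetic face mean in the vanishing-Peclet limit)
#' and \code{N_face} the arithmetic face mean. The gradient vanishes wherever
#' the density does: the objective is insensitive to velocities in void
#' regions.
#'
#' @param N Density field, nx x nt (solving the periodic FP equation for V).
#' @param V Face velocity field, (nx+1) x nt.
#' @param ad Adjoint field from \code{\link{adjoint_solve}}.
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params}.
#' @return An (nx+1) x nt face field; boundary faces zero.
#' @export
reduced_gradient <- function(N, V, ad, grid, params) {
  check_shapes(grid, N = N, V = V, ad = ad)
  nx <- grid$nx
  q <- sg_face_density(N, V, grid, params)
  Gp <- face_gradient(ad, grid)
  Nface <- (N[-nx, , drop = FALSE] + N[-1, , drop = FALSE]) / 2
  g <- q * Gp[2:nx, , drop = FALSE] - params$nu * Nface * V[2:nx, , drop = FALSE]
  rbind(0, g, 0)
}

#' Lagrange-relaxed objective value
#'
#' The objective minus the space-time inner product of the Fokker-Planck
#' residual with the adjoint; equal to the objective whenever the density is
#' feasible.
#'
#' @inheritParams reduced_gradient
#' @param fitness The fitness constant F (J).
#' @return Scalar (J).
#' @export
lagrangian_value <- function(N, V, ad, fitness, grid, params) {
  check_shapes(grid, N = N, V = V, ad = ad)
  objective(N, V, fitness, grid, params) -
    grid$dx * grid$dt * sum(fp_residual(N, V, grid, params) * ad)
}

#' Options for the reduced-gradient optimizer
#'
#' @param grad_tol Threshold on the density-weighted norm of the reduced
#'   gradient.
#' @param max_outer Maximum outer iterations (fitness refresh cycles).
#' @param inner_maxit L-BFGS-B iterations per outer cycle.
#' @param obj_tol Outer loop also stops when the objective improves by less
#'   than this between cycles (reported unconverged unless the gradient test
#'   passes).
#' @param f_damping Under-relaxation factor for the fitness refresh,
#'   \code{F <- F + f_damping*(fitness_F - F)}; 1 is a full refresh, smaller
#'   values stabilize the outer fixed-point cycle.
#' @param quiet Suppress progress messages.
#' @return A list of class \code{dvm_opt_options}.
#' @export
opt_options <- function(grad_tol = 1e-6, max_outer = 15L, inner_maxit = 40L,
                        obj_tol = 1e-14, f_damping = 0.5, quiet = TRUE) {
  list(grad_tol = grad_tol, max_outer = as.integer(max_outer),
       inner_maxit = as.integer(inner_maxit), obj_tol = obj_tol,
       f_damping = f_damping, quiet = quiet)
}

# density-weighted gradient norm: ||grad||^2 = sum dx dt grad_f^2 / N_face
weighted_grad_norm <- function(gr, N, grid) {
  nx <- grid$nx
  Nface <- (N[-nx, , drop = FALSE] + N[-1, , drop = FALSE]) / 2
  g <- gr[2:nx, , drop = FALSE]
  w <- ifelse(Nface > 0, g^2 / Nface, 0)
  sqrt(grid$dx * grid$dt * sum(w))
}

#' Solve the PDE-constrained optimization problem
#'
#' Maximizes the population energy-gain objective over velocity fields, with
#' the density eliminated through the periodic Fokker-Planck solve (reduced
#' formulation) and the fitness constant refreshed from \code{fitness_F} at
#' every outer cycle (quasi-static closure). Inner ascent uses L-BFGS-B on
#' the exact discrete adjoint gradient. Starts from \code{V = 0} so the
#' optimizer is independent of the mean-field solver.
#'
#' @param params A \code{dvm_params}.
#' @param grid A \code{dvm_grid}.
#' @param opts An \code{\link{opt_options}} list.
#' @param V0 Optional initial velocity field (default zero).
#' @return An object of class \code{opt_solution}: fields \code{N}, \code{V},
#'   \code{p} (adjoint), \code{F}, \code{objective}, \code{gradient_norm},
#'   \code{iterations}, \code{converged}, \code{grid}, \code{params}.
#' @export
solve_opt <- function(params, grid, opts = opt_options(), V0 = NULL) {
  env <- env_fields(grid, params)
  nxp <- grid$nx + 1L
  V <- if (is.null(V0)) matrix(0, nxp, grid$nt) else V0
  check_shapes(grid, V = V)

  memo <- new.env(parent = emptyenv())
  fp_of <- function(v) {
    if (!is.null(memo$v) && identical(memo$v, v)) return(memo$N)
    Vm <- matrix(v, nxp, grid$nt)
    N <- solve_periodic_fp(Vm, grid, params)
    memo$v <- v; memo$N <- N
    N
  }

  obj <- -Inf; obj_prev <- -Inf; it_total <- 0L; converged <- FALSE
  wn <- NA_real_; ad <- NULL
  N <- solve_periodic_fp(V, grid, params)
  Fv <- fitness_F(N, V, grid, params, env)
  Freport <- Fv
  ad <- adjoint_solve(N, V, Fv, grid, params, env)
  wn <- weighted_grad_norm(reduced_gradient(N, V, ad, grid, params), N, grid)
  if (wn <= opts$grad_tol) {
    # already stationary (e.g. a homogeneous environment from V = 0)
    return(structure(list(N = N, V = V, p = ad, F = Fv,
                          objective = objective(N, V, Fv, grid, params, env),
                          gradient_norm = wn, iterations = 0L, converged = TRUE,
                          grid = grid, params = params),
                     class = "opt_solution"))
  }
  for (outer in seq_len(opts$max_outer)) {
    fn <- function(v) {
      N <- fp_of(v)
      objective(N, matrix(v, nxp, grid$nt), Fv, grid, params, env)
    }
    gr <- function(v) {
      N <- fp_of(v)
      Vm <- matrix(v, nxp, grid$nt)
      ad <- adjoint_solve(N, Vm, Fv, grid, params, env)
      grid$dx * grid$dt * as.vector(reduced_gradient(N, Vm, ad, grid, params))
    }
    res <- stats::optim(as.vector(V), fn, gr, method = "L-BFGS-B",
                        control = list(fnscale = -1, maxit = opts$inner_maxit,
                                       factr = 10, pgtol = 0))
    it_total <- it_total + res$counts[["function"]]
    V <- matrix(res$par, nxp, grid$nt)
    N <- solve_periodic_fp(V, grid, params)
    Fnew <- fitness_F(N, V, grid, params, env)
    ad <- adjoint_solve(N, V, Fnew, grid, params, env)
    grad <- reduced_gradient(N, V, ad, grid, params)
    wn <- weighted_grad_norm(grad, N, grid)
    objnew <- objective(N, V, Fnew, grid, params, env)
    if (!opts$quiet)
      message(sprintf("  outer %d: objective %.8g, F %.6g, |grad|_N %.3e", outer, objnew, Fnew, wn))
    Freport <- Fnew; obj <- objnew
    if (wn <= opts$grad_tol) { converged <- TRUE; break }
    progressed <- objnew > obj_prev + opts$obj_tol || abs(Fnew - Fv) > 1e-12 * max(1, abs(Fv))
    obj_prev <- objnew
    Fv <- Fv + opts$f_damping * (Fnew - Fv)
    if (!progressed) break
  }
  if (!converged)
    warning(sprintf("solve_opt stopped with |grad|_N = %.3e > grad_tol after %d evaluations (last iterate returned)",
                    wn, it_total))
  structure(list(N = N, V = V, p = ad, F = Freport, objective = obj,
                 gradient_norm = wn, iterations = it_total,
                 converged = converged, grid = grid, params = params),
            class = "opt_solution")
}

#' @export
print.opt_solution <- function(x, ...) {
  cat(sprintf("<opt_solution> %dx%d grid; converged: %s (|grad|_N = %.2e, %d evaluations)\n",
              x$grid$nx, x$grid$nt, x$converged, x$gradient_norm, x$iterations))
  cat(sprintf("  objective = %.6g J, fitness F = %.6g J\n", x$objective, x$F))
  invisible(x)
}
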