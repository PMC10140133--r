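#' Options for the coupled mean-field solver
#'
#' @param newton_tol Convergence threshold on the max-norm of the stacked
#'   space-time residual.
#' @param max_iter Maximum Newton iterations (per continuation stage).
#' @param armijo_c,armijo_min Backtracking line-search parameters: a step
#'   \code{alpha} is accepted when the residual 2-norm drops below
#'   \code{(1 - armijo_c*alpha)} times its current value; \code{alpha} is
#'   halved until \code{armijo_min}.
#' @param continuation Decreasing multiplier schedule on the drag \code{nu}
#'   (ending at 1): each stage solves the game with inflated cost of motion
#'   and warm-starts the next, taming the stiff \code{1/nu} Hamiltonian.
#'   \code{NULL} runs a single direct Newton solve.
#' @param init Either \code{"warm"} (uniform density, value field from one
#'   linear Hamilton-Jacobi-Bellman pass with the quadratic term dropped) or
#'   \code{"uniform"} (uniform density, zero value field).
#' @param quiet Suppress per-iteration messages.
#' @return A list of class \code{dvm_solver_options}.
#' @export
solver_options <- function(newton_tol = 1e-8, max_iter = 50L,
                           armijo_c = 1e-4, armijo_min = 1e-4,
                           continuation = c(1e4, 1e3, 1e2, 30, 10, 5, 3, 2, 1.5, 1.2, 1),
                           init = c("warm", "uniform"), quiet = TRUE) {
  stopifnot(newton_tol > 0, max_iter >= 1)
  if (!is.null(continuation)) {
    stopifnot(all(diff(continuation) < 0), continuation[length(continuation)] == 1)
  }
  list(newton_tol = newton_tol, max_iter = as.integer(max_iter),
       armijo_c = armijo_c, armijo_min = armijo_min,
       continuation = continuation, init = match.arg(init), quiet = quiet)
}

# Scharfetter-Gummel data for all interior faces and slices.
# V is (nx+1) x nt; returns (nx-1) x nt matrices.
sg_all <- function(V, grid, params) {
  D <- params$sigma2 / 2
  Vf <- V[2:grid$nx, , drop = FALSE]
  w <- Vf * grid$dx / D
  list(w = w, Vf = Vf,
       aL = (D / grid$dx) * bernoulli_fun(-w),
       aR = -(D / grid$dx) * bernoulli_fun(w),
       c1 = -dbernoulli_fun(-w),
       c2 = -dbernoulli_fun(w))
}

# (A(V) N) for all slices at once (divergence of SG fluxes, no-flux walls)
fp_apply <- function(N, sg, grid) {
  nx <- grid$nx
  J <- sg$aL * N[-nx, , drop = FALSE] + sg$aR * N[-1, , drop = FALSE]
  (rbind(0, J) - rbind(J, 0)) / grid$dx
}

# (t(A(V)) U) for all slices at once
at_apply <- function(U, sg, grid) {
  S <- apply(U, 2, diff) / grid$dx
  if (!is.matrix(S)) S <- matrix(S, nrow = grid$nx - 1L)
  rbind(sg$aL * S, 0) + rbind(0, sg$aR * S)
}

#' Fokker-Planck residual of a periodic space-time field pair
#'
#' Implicit-Euler, backward-looking in time with periodic wrap:
#' \code{R_k = (N_k - N_{k-1})/dt - A(V_k) N_k}, where \code{A} is the
#' conservative Scharfetter-Gummel operator. Column sums of every slice
#' residual vanish (discrete mass conservation).
#'
#' @param N Density field, nx x nt.
#' @param V Velocity field, (nx+1) x nt (boundary faces zero).
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params}.
#' @return An nx x nt residual matrix (units m^-1 h^-1).
#' @export
fp_residual <- function(N, V, grid, params) {
  check_shapes(grid, N = N, V = V)
  sg <- sg_all(V, grid, params)
  Nprev <- N[, c(grid$nt, seq_len(grid$nt - 1L)), drop = FALSE]
  (N - Nprev) / grid$dt - fp_apply(N, sg, grid)
}

#' Hamilton-Jacobi-Bellman residual
#'
#' Forward-looking implicit Euler with periodic wrap. With
#' \code{V_k = face_gradient(U_k)/nu}, the residual is
#' \deqn{R_k = (U_{k+1}-U_k)/dt + A(V_k)^T U_k - (\nu/2)\overline{V_k^2}
#'   + g - U_k(\mu_0 + \mu_1 N_k),}
#' so the transport + kinetic pairing evaluates the optimized Hamiltonian
#' \eqn{(\partial U/\partial x)^2 / 2\nu} at the discrete level.
#'
#' @param U Value field, nx x nt (J).
#' @param N Density field, nx x nt.
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params}.
#' @param env Optional precomputed \code{\link{env_fields}} tabulation.
#' @return An nx x nt residual matrix (units J h^-1).
#' @export
hjb_residual <- function(U, N, grid, params, env = NULL) {
  check_shapes(grid, N = N, U = U)
  if (is.null(env)) env <- env_fields(grid, params)
  V <- face_gradient(U, grid) / params$nu
  sg <- sg_all(V, grid, params)
  Unext <- U[, c(seq_len(grid$nt)[-1], 1L), drop = FALSE]
  (Unext - U) / grid$dt + at_apply(U, sg, grid) -
    (params$nu / 2) * face_sq_to_cell(V) +
    env$g - U * (env$mu0 + params$mu1 * N)
}

#' Optimal velocity from the value function
#'
#' The optimizer of the concave Hamiltonian: \code{V = face_gradient(U)/nu},
#' zero at the boundary faces. Positive values point downward.
#'
#' @inheritParams hjb_residual
#' @return An (nx+1) x nt face velocity field (m h^-1).
#' @export
velocity_from_value <- function(U, grid, params) {
  face_gradient(U, grid) / params$nu
}

check_shapes <- function(grid, N = NULL, U = NULL, V = NULL, ad = NULL) {
  bad <- function(M, nr) !is.matrix(M) || nrow(M) != nr || ncol(M) != grid$nt
  if (!is.null(N) && bad(N, grid$nx)) stop("density field has wrong shape for grid", call. = FALSE)
  if (!is.null(U) && bad(U, grid$nx)) stop("value field has wrong shape for grid", call. = FALSE)
  if (!is.null(ad) && bad(ad, grid$nx)) stop("adjoint field has wrong shape for grid", call. = FALSE)
  if (!is.null(V) && bad(V, grid$nx + 1L)) stop("velocity field has wrong shape for grid", call. = FALSE)
  invisible(TRUE)
}

# index helpers: column-major stacking, N block first then U block
idx_n <- function(j, k, nx) (k - 1L) * nx + j

# stacked residual with the mass-constraint row replacing the Fokker-Planck
# row of cell 1 at slice 1 (pins the one-dimensional mass kernel)
mfg_residual_vec <- function(N, U, grid, params, env) {
  Rfp <- fp_residual(N, U_velocity(U, grid, params), grid, params)
  Rhjb <- hjb_residual(U, N, grid, params, env)
  r <- c(Rfp, Rhjb)
  r[1L] <- grid$dx * sum(N[, 1L]) - 1
  r
}

U_velocity <- function(U, grid, params) face_gradient(U, grid) / params$nu

# analytic sparse Jacobian of the stacked residual
mfg_jacobian <- function(N, U, grid, params, env) {
  nx <- grid$nx; nt <- grid$nt; NN <- nx * nt
  dt <- grid$dt; dx <- grid$dx; nu <- params$nu
  V <- U_velocity(U, grid, params)
  sg <- sg_all(V, grid, params)

  kk <- rep(seq_len(nt), each = nx - 1L)          # slice of each interior face
  fF <- rep(2:nx, times = nt)                     # face index f (2..nx)
  iL <- idx_n(fF - 1L, kk, nx)                    # cell left of face
  iR <- idx_n(fF, kk, nx)                         # cell right of face
  aL <- as.vector(sg$aL); aR <- as.vector(sg$aR)
  c1 <- as.vector(sg$c1); c2 <- as.vector(sg$c2)
  NL <- as.vector(N[-nx, , drop = FALSE]); NR <- as.vector(N[-1, , drop = FALSE])
  S <- as.vector(apply(U, 2, diff)) / dx          # face gradient of U
  Vf <- as.vector(sg$Vf)
  q <- c1 * NL + c2 * NR                          # d(flux)/d(face velocity)

  jd <- seq_len(NN)                               # all (j,k) cells, stacked
  kprev <- rep(c(nt, seq_len(nt - 1L)), each = nx)
  jprev <- idx_n(rep(seq_len(nx), nt), kprev, nx)
  knext <- rep(c(seq_len(nt)[-1], 1L), each = nx)
  jnext <- idx_n(rep(seq_len(nx), nt), knext, nx)

  ii <- jj <- xx <- vector("list", 12L)
  put <- local({ n <- 0L; function(i, j, x) { n <<- n + 1L; ii[[n]] <<- i; jj[[n]] <<- j; xx[[n]] <<- x } })

  ## Fokker-Planck rows (row indices = N block)
  put(jd, jd, rep(1 / dt, NN))                    # dR/dN_k diagonal
  put(jd, jprev, rep(-1 / dt, NN))                # dR/dN_{k-1}
  # -A entries
  put(iL, iL, aL / dx); put(iL, iR, aR / dx)
  put(iR, iL, -aL / dx); put(iR, iR, -aR / dx)
  # coupling to U through V = grad(U)/nu
  qv <- q / (nu * dx * dx)
  put(iL, NN + iR, qv); put(iL, NN + iL, -qv)
  put(iR, NN + iR, -qv); put(iR, NN + iL, qv)

  ## HJB rows (row indices = U block)
  mu <- as.vector(env$mu0 + params$mu1 * N)
  put(NN + jd, NN + jnext, rep(1 / dt, NN))
  put(NN + jd, NN + jd, -1 / dt - mu)
  # t(A) entries
  put(NN + iL, NN + iL, -aL / dx); put(NN + iL, NN + iR, aL / dx)
  put(NN + iR, NN + iL, -aR / dx); put(NN + iR, NN + iR, aR / dx)
  # V-dependence of transport + kinetic terms, chained through dV/dU
  h1 <- (c1 * S - (nu / 2) * Vf) / (nu * dx)
  h2 <- (c2 * S - (nu / 2) * Vf) / (nu * dx)
  put(NN + iL, NN + iR, h1); put(NN + iL, NN + iL, -h1)
  put(NN + iR, NN + iR, h2); put(NN + iR, NN + iL, -h2)
  # coupling to N through the mortality term
  put(NN + jd, jd, -params$mu1 * as.vector(U))

  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)
  # replace FP row 1 (cell 1, slice 1) by the mass constraint
  keep <- i != 1L
  i <- c(i[keep], rep(1L, nx))
  j <- c(j[keep], idx_n(seq_len(nx), 1L, nx))
  x <- c(x[keep], rep(dx, nx))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(2L * NN, 2L * NN))
}

# one linear periodic HJB pass with N frozen uniform and the quadratic
# Hamiltonian dropped: used as the deterministic warm start
hjb_linear_init <- function(grid, params, env) {
  nx <- grid$nx; nt <- grid$nt; NN <- nx * nt
  A0 <- fp_operator(rep(0, nx + 1L), grid, params)
  At <- Matrix::t(A0)
  mu <- env$mu0 + params$mu1 / params$H
  blocks_i <- blocks_j <- blocks_x <- vector("list", 2L * nt + 1L)
  trip <- methods::as(At, "TsparseMatrix")
  n <- 0L
  for (k in seq_len(nt)) {
    off <- (k - 1L) * nx
    offn <- (k %% nt) * nx
    n <- n + 1L
    blocks_i[[n]] <- off + trip@i + 1L; blocks_j[[n]] <- off + trip@j + 1L; blocks_x[[n]] <- trip@x
    n <- n + 1L
    blocks_i[[n]] <- c(off + seq_len(nx), off + seq_len(nx))
    blocks_j[[n]] <- c(off + seq_len(nx), offn + seq_len(nx))
    blocks_x[[n]] <- c(-1 / grid$dt - mu[, k], rep(1 / grid$dt, nx))
  }
  M <- Matrix::sparseMatrix(i = unlist(blocks_i), j = unlist(blocks_j),
                            x = unlist(blocks_x), dims = c(NN, NN))
  rhs <- rep(-env$g, nt)
  matrix(as.numeric(Matrix::solve(M, rhs)), nx, nt)
}

#' Solve the coupled mean-field system
#'
#' Finds the time-periodic Nash-equilibrium pair (N, U) of the vertical game:
#' the density solves the periodic Fokker-Planck equation under the optimal
#' velocity \code{V = face_gradient(U)/nu}, and the value function solves the
#' periodic Hamilton-Jacobi-Bellman equation with the density-dependent
#' killing rate. The discretized space-time system (2*nx*nt unknowns, one
#' Fokker-Planck row replaced by the mass constraint) is solved monolithically
#' by damped Newton iteration with an analytic sparse Jacobian; if the direct
#' solve stalls, a continuation over \code{mu1} restarts it from progressively
#' easier problems.
#'
#' @param params A \code{dvm_params}.
#' @param grid A \code{dvm_grid}.
#' @param opts A \code{\link{solver_options}} list.
#' @param N0,U0 Optional initial fields (nx x nt) overriding the default
#'   initialization, e.g. to restart from a perturbed known solution.
#' @return An object of class \code{mfg_solution}: fields \code{N} (m^-1),
#'   \code{U} (J), \code{V} (m h^-1, faces), scalar fitness \code{F} (J),
#'   \code{residual_norm}, \code{iterations}, \code{converged},
#'   \code{history} (per-iteration residual norms), \code{grid},
#'   \code{params}.
#' @export
solve_mfg <- function(params, grid, opts = solver_options(), N0 = NULL, U0 = NULL) {
  env <- env_fields(grid, params)
  if (is.null(N0)) N0 <- matrix(1 / params$H, grid$nx, grid$nt)
  first_par <- params
  if (!is.null(opts$continuation)) first_par$nu <- params$nu * opts$continuation[1]
  if (is.null(U0))
    U0 <- if (opts$init == "warm") hjb_linear_init(grid, first_par, env) else matrix(0, grid$nx, grid$nt)

  if (is.null(opts$continuation)) {
    sol <- mfg_newton(params, grid, opts, env, N0, U0)
  } else {
    its <- 0L; hist <- numeric(0)
    for (fac in opts$continuation) {
      par_c <- params; par_c$nu <- params$nu * fac
      if (!opts$quiet) message(sprintf("continuation stage nu x%g", fac))
      sol <- mfg_newton(par_c, grid, opts, env, N0, U0)
      its <- its + sol$iterations; hist <- c(hist, sol$history)
      N0 <- sol$N; U0 <- sol$U
    }
    sol$iterations <- its
    sol$history <- hist
  }
  if (!sol$converged)
    warning(sprintf("solve_mfg did not converge: residual %.3e after %d iterations (history attached)",
                    sol$residual_norm, sol$iterations))
  sol
}

mfg_newton <- function(params, grid, opts, env, N0, U0) {
  nx <- grid$nx; nt <- grid$nt; NN <- nx * nt
  N <- N0; U <- U0
  hist <- numeric(0)
  conv <- FALSE
  it <- 0L
  r <- mfg_residual_vec(N, U, grid, params, env)
  while (it < opts$max_iter) {
    rn <- max(abs(r))
    hist <- c(hist, rn)
    if (rn <= opts$newton_tol) { conv <- TRUE; break }
    it <- it + 1L
    J <- mfg_jacobian(N, U, grid, params, env)
    step <- as.numeric(Matrix::solve(J, -r))
    dN <- matrix(step[seq_len(NN)], nx, nt)
    dU <- matrix(step[NN + seq_len(NN)], nx, nt)
    r2 <- sqrt(sum(r^2))
    alpha <- 1
    repeat {
      rtry <- tryCatch(mfg_residual_vec(N + alpha * dN, U + alpha * dU, grid, params, env),
                       error = function(e) NULL)
      ok <- !is.null(rtry) && all(is.finite(rtry)) &&
        sqrt(sum(rtry^2)) <= (1 - opts$armijo_c * alpha) * r2
      if (ok || alpha <= opts$armijo_min) break
      alpha <- alpha / 2
    }
    if (is.null(rtry) || !all(is.finite(rtry))) break
    N <- N + alpha * dN; U <- U + alpha * dU
    r <- rtry
    if (!opts$quiet) message(sprintf("  newton it %d: |r|_inf = %.3e (alpha = %g)", it, max(abs(r)), alpha))
  }
  rn <- max(abs(r))
  if (rn <= opts$newton_tol) conv <- TRUE
  V <- U_velocity(U, grid, params)
  fit <- tryCatch(fitness_F(N, V, grid, params, env), error = function(e) NA_real_)
  structure(list(N = N, U = U, V = V, F = fit, residual_norm = rn,
                 iterations = it, converged = conv, history = hist,
                 grid = grid, params = params),
            class = "mfg_solution")
}

#' @export
print.mfg_solution <- function(x, ...) {
  cat(sprintf("<mfg_solution> %dx%d grid; converged: %s (|r|_inf = %.2e, %d iterations)\n",
              x$grid$nx, x$grid$nt, x$converged, x$residual_norm, x$iterations))
  cat(sprintf("  fitness F = %.6g J; mass range %.3e..%.3e\n", x$F,
              min(cell_integral(x$N, x$grid)), max(cell_integral(x$N, x$grid))))
  invisible(x)
}
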