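#' Space-time grid for the water column
#'
#' Cell-centred finite-volume grid in depth crossed with a periodic time grid.
#' Cells are \code{[ (j-1)dx, j dx )} with centres \code{x_j = (j-1/2)dx},
#' faces sit at \code{(j-1)dx}, and time slices at \code{t_k = (k-1)dt} with
#' index arithmetic modulo \code{nt} (slice \code{nt+1} is slice 1; the
#' periodic identification is structural, no duplicated storage).
#'
#' @param nx Number of depth cells (>= 4).
#' @param nt Number of time slices per period (>= 4).
#' @param params A \code{dvm_params} object supplying \code{H} and \code{T}.
#' @return An object of class \code{dvm_grid} with fields \code{nx, nt, dx,
#'   dt, H, T, x} (cell centres), \code{xf} (faces) and \code{t} (slice
#'   times).
#' @export
build_grid <- function(nx, nt, params) {
  nx <- as.integer(nx); nt <- as.integer(nt)
  if (is.na(nx) || is.na(nt) || nx < 4L || nt < 4L)
    stop("grid sizes nx and nt must be integers >= 4", call. = FALSE)
  dx <- params$H / nx
  dt <- params$T / nt
  g <- list(nx = nx, nt = nt, dx = dx, dt = dt, H = params$H, T = params$T,
            x = (seq_len(nx) - 0.5) * dx,
            xf = (0:nx) * dx,
            t = (seq_len(nt) - 1) * dt)
  class(g) <- "dvm_grid"
  g
}

#' @export
print.dvm_grid <- function(x, ...) {
  cat(sprintf("<dvm_grid> nx=%d (dx=%g m), nt=%d (dt=%g h), H=%g m, T=%g h\n",
              x$nx, x$dx, x$nt, x$dt, x$H, x$T))
  invisible(x)
}

#' Grid-valued field with a role tag
#'
#' Thin validated container: density, value and adjoint fields live on cells
#' (nx x nt matrices); velocity fields live on faces ((nx+1) x nt matrices,
#' boundary rows structurally zero, carrying the no-flux condition).
#'
#' @param values Numeric matrix of the shape required by \code{role}.
#' @param grid A \code{dvm_grid}.
#' @param role One of \code{"density"}, \code{"value"}, \code{"velocity"},
#'   \code{"adjoint"}.
#' @param positivity_tol,mass_tol Tolerances for the density-role checks.
#' @return The values matrix with class \code{dvm_field} and attributes
#'   \code{role}.
#' @export
scalar_field <- function(values, grid, role = c("density", "value", "velocity", "adjoint"),
                         positivity_tol = 1e-10, mass_tol = 1e-8) {
  role <- match.arg(role)
  values <- as.matrix(values)
  nr <- if (role == "velocity") grid$nx + 1L else grid$nx
  if (nrow(values) != nr || ncol(values) != grid$nt)
    stop(sprintf("field of role '%s' must be %d x %d", role, nr, grid$nt), call. = FALSE)
  if (!all(is.finite(values))) stop("field contains non-finite values", call. = FALSE)
  if (role == "density") {
    if (min(values) < -positivity_tol)
      stop("density field has entries below -positivity_tol", call. = FALSE)
    mass <- grid$dx * colSums(values)
    if (max(abs(mass - 1)) > mass_tol)
      stop("density field mass deviates from 1 beyond mass_tol", call. = FALSE)
  }
  if (role == "velocity" && any(values[c(1L, nr), ] != 0))
    stop("velocity boundary faces must be zero (no-flux)", call. = FALSE)
  structure(values, class = "dvm_field", role = role)
}

# Bernoulli function B(w) = w / (e^w - 1), evaluated stably:
# series for small |w|, exp(-|w|)-based forms for large |w|.
bernoulli_fun <- function(w) {
  out <- numeric(length(w))
  aw <- abs(w)
  small <- aw < 1e-8
  out[small] <- 1 - w[small] / 2 + w[small]^2 / 12
  ws <- w[!small]
  # w>0: B(w) = w e^{-w}/(1-e^{-w}) avoids overflow; w<0: w/expm1(w) is stable
  out[!small] <- ifelse(ws > 0,
                        ws * exp(-ws) / (-expm1(-ws)),
                        ws / expm1(ws))
  out
}

# Derivative B'(w) = (e^w - 1 - w e^w) / (e^w - 1)^2, stable form:
# B'(w) = [ (1 - e^{-w}) - w ] e^{-w} ... use e^{-|w|} factoring.
dbernoulli_fun <- function(w) {
  out <- numeric(length(w))
  aw <- abs(w)
  small <- aw < 1e-6
  out[small] <- -0.5 + w[small] / 6 - w[small]^3 / 180
  ws <- w[!small]
  # for w>0: B'(w) = e^{-w} (1 - e^{-w} - w) / (1-e^{-w})^2
  # for w<0: B'(w) = (e^{w} - 1 - w e^{w}) / (e^{w}-1)^2 directly (e^w < 1)
  pos <- ws > 0
  res <- numeric(length(ws))
  ew <- exp(-abs(ws))
  d <- (1 - ew)^2
  res[pos] <- ew[pos] * (1 - ew[pos] - ws[pos]) / d[pos]
  res[!pos] <- (ew[!pos] - 1 - ws[!pos] * ew[!pos]) / d[!pos]
  out[!small] <- res
  out
}

# Scharfetter-Gummel face coefficients for flux
#   J_f = (D/dx) [ B(-w_f) N_left - B(w_f) N_right ],  w_f = V_f dx / D,
# D = sigma^2/2. Returns per-interior-face coefficient lists.
sg_coeffs <- function(V, grid, params) {
  D <- params$sigma2 / 2
  f <- 2:grid$nx                      # interior faces
  w <- V[f] * grid$dx / D
  list(f = f, w = w,
       aL = (D / grid$dx) * bernoulli_fun(-w),   # multiplies N_{f-1}
       aR = -(D / grid$dx) * bernoulli_fun(w))   # multiplies N_f
}

#' Discrete Fokker-Planck operator for one time slice
#'
#' Divergence of the Scharfetter-Gummel (exponential-fitting) advection-
#' diffusion flux with zero flux imposed at both boundary faces, as a sparse
#' nx x nx matrix \code{A} such that \code{dN/dt = A \%*\% N}. Every column of
#' \code{A} sums to zero (discrete mass conservation), nonnegative densities
#' stay nonnegative under implicit Euler stepping (M-matrix), and the scheme
#' is exact for constant coefficients: \code{N* ~ exp(2 V x / sigma^2)} is a
#' null vector when \code{V} is constant.
#'
#' @param V Face velocity values, length \code{nx+1} (boundary entries
#'   ignored: the boundary flux is identically zero).
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params} object (supplies sigma2).
#' @return A \code{dgCMatrix} of dimension nx x nx.
#' @export
fp_operator <- function(V, grid, params) {
  if (!all(is.finite(V[2:grid$nx]))) stop("non-finite velocity entries", call. = FALSE)
  sg <- sg_coeffs(V, grid, params)
  nx <- grid$nx
  # (A N)_j = (J_j - J_{j+1})/dx ; face f couples cells f-1 (left) and f.
  i <- c(sg$f - 1L, sg$f - 1L, sg$f, sg$f)
  j <- c(sg$f - 1L, sg$f,      sg$f - 1L, sg$f)
  x <- c(-sg$aL, -sg$aR, sg$aL, sg$aR) / grid$dx
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nx, nx))
}

#' Discrete backward transport operator (HJB side)
#'
#' The exact transpose of \code{\link{fp_operator}} for the same face
#' velocities. Its row sums are zero, so constants lie in its kernel -- the
#' discrete form of the homogeneous Neumann boundary condition on the value
#' function -- and the forward/backward duality
#' \code{<A N, U> == <N, t(A) U>} holds to machine precision by construction.
#'
#' @inheritParams fp_operator
#' @return A \code{dgCMatrix} of dimension nx x nx.
#' @export
hjb_transport_operator <- function(V, grid, params) {
  Matrix::t(fp_operator(V, grid, params))
}

#' Face gradient of a cell field
#'
#' Interior faces carry \code{(U_{j} - U_{j-1})/dx}; the two boundary faces
#' carry zero, encoding the Neumann condition \code{dU/dx = 0} at the surface
#' and the bottom.
#'
#' @param U Cell values: a length-nx vector or an nx x nt matrix.
#' @param grid A \code{dvm_grid}.
#' @return Face values of the same time-extent as \code{U} (length nx+1 or
#'   (nx+1) x nt).
#' @export
face_gradient <- function(U, grid) {
  if (is.matrix(U)) {
    G <- rbind(0, diff(U) / grid$dx, 0)
    dimnames(G) <- NULL
    G
  } else {
    c(0, diff(U) / grid$dx, 0)
  }
}

#' Integral of a cell field over depth
#'
#' Exact discrete integral \code{dx * sum} (per time slice for matrices);
#' the discrete form of the normalization constraint on the density.
#'
#' @param v Cell values: a length-nx vector or an nx x nt matrix.
#' @param grid A \code{dvm_grid}.
#' @return A scalar, or one value per time slice.
#' @export
cell_integral <- function(v, grid) {
  if (is.matrix(v)) grid$dx * colSums(v) else grid$dx * sum(v)
}

# cell average of squared face velocities: (V_f(j)^2 + V_f(j+1)^2)/2 per cell
face_sq_to_cell <- function(V) {
  n <- nrow(as.matrix(V))
  if (is.matrix(V)) (V[-n, , drop = FALSE]^2 + V[-1, , drop = FALSE]^2) / 2
  else (V[-n]^2 + V[-1]^2) / 2
}
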