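#' Model parameters for the vertical migration game
#'
#' Constructs the full parameter set of the water-column model. The defaults
#' are the baseline parameterization of the game: a 500 m column with a 24 h
#' light cycle, a saturating visual-range model for the predation risk, a
#' logistic depth profile for the food, and quadratic cost of motion.
#'
#' @param H Maximum depth of the water column (m).
#' @param T Period of the light cycle (h).
#' @param I0 Maximum surface irradiance (W m^-2 nm^-1).
#' @param K Saturating light level of the visual range model (W m^-2 nm^-1).
#' @param gamma Maximum detection distance of the predator in clear water at
#'   saturating light (m).
#' @param k1 Light absorption coefficient of the water (m^-1).
#' @param A Amplitude of the diel light fluctuation (dimensionless; larger
#'   values give a sharper day/night contrast).
#' @param nu Drag coefficient: the cost of motion is nu*V^2/2 (J h m^-2).
#' @param sigma2 Diffusivity sigma^2 of the uncontrolled vertical displacement
#'   (m^2 h^-1).
#' @param mu1 Density-dependent mortality coefficient (h^-1 per unit density).
#' @param m Mortality scaling: predation risk is m*r^2 with r the detection
#'   radius (m^-2 h^-1).
#' @param mu_base Baseline density- and light-independent mortality (h^-1).
#' @param k2 Decay rate of the logistic food profile (m^-1).
#' @param g0 Maximum energy harvest rate (J h^-1).
#' @param x_clin Mixed layer depth: midpoint of the food profile (m).
#'
#' @return An object of class \code{dvm_params} (a validated named list).
#' @examples
#' p <- env_params()
#' surface_irradiance(12, p)
#' @export
env_params <- function(H = 500, T = 24, I0 = 1, K = 1, gamma = 0.02,
                       k1 = 0.02, A = 13, nu = 1e-6, sigma2 = 20,
                       mu1 = 1, m = 100, mu_base = 1e-5, k2 = 0.02,
                       g0 = 0.01, x_clin = 100) {
  p <- list(H = H, T = T, I0 = I0, K = K, gamma = gamma, k1 = k1, A = A,
            nu = nu, sigma2 = sigma2, mu1 = mu1, m = m, mu_base = mu_base,
            k2 = k2, g0 = g0, x_clin = x_clin)
  p <- lapply(p, as.numeric)
  class(p) <- "dvm_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "dvm_params"))
  chk <- function(cond, msg) if (!cond) stop("invalid parameters: ", msg, call. = FALSE)
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))
  chk(all(num), paste("non-finite or non-scalar:", paste(names(p)[!num], collapse = ", ")))
  chk(p$H > 0, "H must be > 0")
  chk(p$T > 0, "T must be > 0")
  chk(p$nu > 0, "nu must be > 0")
  chk(p$sigma2 > 0, "sigma2 must be > 0")
  chk(p$I0 >= 0, "I0 must be >= 0")
  chk(p$K > 0, "K must be > 0")
  chk(p$gamma >= 0, "gamma must be >= 0")
  chk(p$k1 >= 0, "k1 must be >= 0")
  chk(p$m >= 0, "m must be >= 0")
  chk(p$mu_base >= 0, "mu_base must be >= 0")
  chk(p$mu1 >= 0, "mu1 must be >= 0")
  chk(p$g0 >= 0, "g0 must be >= 0")
  chk(p$k2 >= 0, "k2 must be >= 0")
  chk(p$x_clin >= 0 && p$x_clin <= p$H, "x_clin must lie in [0, H]")
  invisible(p)
}

#' @export
print.dvm_params <- function(x, ...) {
  cat("<dvm_params>\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Surface irradiance over the diel cycle
#'
#' Periodic surface light \eqn{I_s(t) = I_0 / (1 + \exp(A \cos(2\pi t/T)))}.
#' Time zero is midnight (light minimal); noon is at \code{t = T/2}. The
#' logistic is evaluated in a numerically stable form, and \code{t} is reduced
#' modulo \code{T} first so that periodicity holds exactly in floating point.
#'
#' @param t Time (h); any real, vectorized.
#' @param params A \code{dvm_params} object.
#' @return Irradiance (W m^-2 nm^-1), in (0, I0].
#' @export
surface_irradiance <- function(t, params) {
  tm <- t %% params$T
  params$I0 * stats::plogis(-params$A * cos(2 * pi * tm / params$T))
}

#' Irradiance at depth
#'
#' Exponential light attenuation, \eqn{I(x,t) = I_s(t) e^{-k_1 x}}. Depth is
#' measured downward from the surface at \code{x = 0}.
#'
#' @param x Depth (m), in \code{[0, H]}; vectorized (recycled against
#'   \code{t}).
#' @param t Time (h).
#' @param params A \code{dvm_params} object.
#' @return Irradiance (W m^-2 nm^-1).
#' @export
irradiance_at_depth <- function(x, t, params) {
  if (any(x < 0 | x > params$H)) stop("depth x outside [0, H]", call. = FALSE)
  surface_irradiance(t, params) * exp(-params$k1 * x)
}

#' Visual detection radius
#'
#' Solves the saturating visual-range equation
#' \eqn{r^2 e^{k_1 r} = \gamma^2 I/(K+I)} for the unique root
#' \eqn{r \in [0, \gamma]}. The left side is strictly increasing, and since
#' \eqn{e^{k_1 r} \ge 1} the root is bracketed by
#' \eqn{[0, \gamma \sqrt{I/(K+I)}]}; a vectorized bisection drives the bracket
#' to an absolute width below \code{1e-14 * gamma}.
#'
#' @param I Irradiance (W m^-2 nm^-1); nonnegative, vectorized. \code{Inf} is
#'   allowed and means saturating light, \eqn{I/(K+I) = 1}.
#' @param params A \code{dvm_params} object.
#' @return Detection radius (m), same length as \code{I}.
#' @export
detection_radius <- function(I, params) {
  if (any(I < 0)) stop("irradiance I must be nonnegative", call. = FALSE)
  gam <- params$gamma
  k1 <- params$k1
  if (gam == 0) return(rep(0, length(I)))
  ratio <- ifelse(is.infinite(I), 1, I / (params$K + I))
  rhs <- gam^2 * ratio
  lo <- rep(0, length(I))
  hi <- gam * sqrt(ratio)
  if (k1 == 0) return(hi)  # closed form: r = gamma*sqrt(I/(K+I))
  # f(r) = r^2 exp(k1 r) - rhs; f(lo) <= 0 <= f(hi)
  for (it in seq_len(60L)) {
    mid <- 0.5 * (lo + hi)
    pos <- mid^2 * exp(k1 * mid) - rhs > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
    if (max(hi - lo) < 1e-15 * gam) break
  }
  r <- 0.5 * (lo + hi)
  r[rhs == 0] <- 0
  r
}

#' Density-independent mortality rate
#'
#' Visual predation risk proportional to the cross-section of the detection
#' sphere plus a baseline: \eqn{\mu_0(x,t) = m\, r(I(x,t))^2 + \mu_{base}}.
#'
#' @param x Depth (m), in \code{[0, H]}.
#' @param t Time (h).
#' @param params A \code{dvm_params} object.
#' @return Mortality rate (h^-1).
#' @export
mu0 <- function(x, t, params) {
  I <- irradiance_at_depth(x, t, params)
  r <- detection_radius(I, params)
  params$m * r^2 + params$mu_base
}

#' Energy harvest rate
#'
#' Logistic depth profile of food availability,
#' \eqn{g(x) = g_0/(1 + \exp(k_2 (x - x_{clin})))}; time invariant.
#'
#' @param x Depth (m), in \code{[0, H]}.
#' @param params A \code{dvm_params} object.
#' @return Energy harvest rate (J h^-1).
#' @export
harvest <- function(x, params) {
  if (any(x < 0 | x > params$H)) stop("depth x outside [0, H]", call. = FALSE)
  params$g0 * stats::plogis(-params$k2 * (x - params$x_clin))
}

#' Total risk rate
#'
#' \eqn{\mu(x,t) = \mu_0(x,t) + \mu_1 N(x,t)}: density-independent visual
#' predation plus the mean-field crowding term.
#'
#' @param x Depth (m).
#' @param t Time (h).
#' @param N_at_xt Local population density (m^-1), nonnegative.
#' @param params A \code{dvm_params} object.
#' @return Mortality rate (h^-1).
#' @export
total_mortality <- function(x, t, N_at_xt, params) {
  if (any(N_at_xt < 0)) stop("density must be nonnegative", call. = FALSE)
  mu0(x, t, params) + params$mu1 * N_at_xt
}

#' Exogenous fields tabulated on a grid
#'
#' Evaluates mu0 and the harvest rate at all cell centres and time slices of a
#' grid. Used internally by the solvers; exported because the tabulation is
#' also the natural input for plotting and for the CLI `env` dump.
#'
#' @param grid A \code{dvm_grid}.
#' @param params A \code{dvm_params} object.
#' @return A list with \code{mu0} (nx x nt matrix, h^-1), \code{g}
#'   (length-nx vector, J h^-1) and \code{I} (nx x nt matrix).
#' @export
env_fields <- function(grid, params) {
  Is <- surface_irradiance(grid$t, params)
  I <- exp(-params$k1 * grid$x) %o% Is
  r <- detection_radius(as.vector(I), params)
  mu0m <- matrix(params$m * r^2 + params$mu_base, grid$nx, grid$nt)
  list(mu0 = mu0m, g = harvest(grid$x, params), I = I)
}
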