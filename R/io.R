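#' Load and validate a run configuration
#'
#' Reads a flat JSON object (or an R list) and fills defaults: the baseline
#' model parameters, grid sizes \code{nx = 100, nt = 96}, a \code{seed}, an
#' optional \code{scenario} name (multipliers applied on top of any explicit
#' parameter values), and optional nested \code{solver}, \code{optimizer}
#' and \code{simulator} option objects. Unknown keys are rejected by name.
#'
#' @param path Path to a JSON file, or a named list.
#' @return A list of class \code{run_config} with elements \code{params}
#'   (\code{dvm_params}), \code{nx}, \code{nt}, \code{seed}, \code{scenario},
#'   \code{solver}, \code{optimizer}, \code{simulator} and \code{echo} (the
#'   raw input).
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) path else stop("config must be a path or a list", call. = FALSE)
  if (length(raw) && is.null(names(raw))) stop("config must be a named object", call. = FALSE)

  par_keys <- names(formals(env_params))
  top_keys <- c("nx", "nt", "seed", "scenario", "solver", "optimizer", "simulator", "out")
  unknown <- setdiff(names(raw), c(par_keys, top_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)

  for (k in intersect(names(raw), c(par_keys, "nx", "nt", "seed"))) {
    v <- raw[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("config key '", k, "' must be a finite number", call. = FALSE)
  }

  base <- do.call(env_params, raw[intersect(names(raw), par_keys)])
  params <- if (!is.null(raw$scenario)) scenario_params(raw$scenario, base) else base

  for (nm in c("solver", "optimizer", "simulator")) {
    if (!is.null(raw[[nm]]) && !is.list(raw[[nm]]))
      stop("config key '", nm, "' must be an object", call. = FALSE)
  }
  ok_sub <- list(solver = names(formals(solver_options)),
                 optimizer = names(formals(opt_options)),
                 simulator = c("n", "dt_sim", "horizon", "kill", "record_dt"))
  for (nm in names(ok_sub)) {
    bad <- setdiff(names(raw[[nm]]), ok_sub[[nm]])
    if (length(bad))
      stop("unknown key(s) in '", nm, "': ", paste(bad, collapse = ", "), call. = FALSE)
  }

  structure(list(params = params,
                 nx = as.integer(raw$nx %||% 100L),
                 nt = as.integer(raw$nt %||% 96L),
                 seed = as.integer(raw$seed %||% 1L),
                 scenario = raw$scenario,
                 solver = raw$solver %||% list(),
                 optimizer = raw$optimizer %||% list(),
                 simulator = raw$simulator %||% list(),
                 echo = raw),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write solution fields to CSV / read them back
#'
#' Long format, one row per cell and time slice with columns
#' \code{depth_m} (cell centre), \code{time_h}, \code{N}, \code{U_or_p} and
#' \code{V}. The velocity lives on cell faces; row \code{j} carries the
#' interior face below cell \code{j} (at depth \code{j*dx}), and the two
#' boundary faces are structurally zero. Values are written with 17
#' significant digits, so the round trip reproduces every double exactly.
#'
#' @param sol An \code{mfg_solution} or \code{opt_solution}.
#' @param path Output CSV path.
#' @return \code{write_fields} returns \code{path} invisibly;
#'   \code{read_fields} returns a list with \code{N}, \code{U} (value or
#'   adjoint), \code{V}, \code{x}, \code{t}.
#' @export
write_fields <- function(sol, path) {
  grid <- sol$grid
  Ucol <- if (!is.null(sol$U)) sol$U else sol$p
  nx <- grid$nx
  Vint <- sol$V[2:(nx + 1L), , drop = FALSE]  # face below cell j; row nx is bottom face = 0
  num <- function(v) sub("e([+-])0(\\d\\d)", "e\\1\\2", sprintf("%.17g", v))
  dt <- data.table::data.table(
    depth_m = num(rep(grid$x, grid$nt)),
    time_h = num(rep(grid$t, each = nx)),
    N = num(as.vector(sol$N)),
    U_or_p = num(as.vector(Ucol)),
    V = num(as.vector(Vint)))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_fields
#' @param grid Grid the file was written on (shape check).
#' @export
read_fields <- function(path, grid) {
  dt <- data.table::fread(path)
  need <- c("depth_m", "time_h", "N", "U_or_p", "V")
  if (!identical(names(dt), need))
    stop("malformed fields CSV: expected header ", paste(need, collapse = ","),
         " in ", path, call. = FALSE)
  nx <- grid$nx; nt <- grid$nt
  if (nrow(dt) != nx * nt) stop("fields CSV size does not match grid", call. = FALSE)
  V <- rbind(0, matrix(dt$V, nx, nt)[-nx, , drop = FALSE], 0)
  list(N = matrix(dt$N, nx, nt), U = matrix(dt$U_or_p, nx, nt), V = V,
       x = grid$x, t = grid$t)
}

#' Write a run summary as JSON
#'
#' Captures the scalar outcome of a solve together with everything needed to
#' reproduce it: fitness, residual or gradient norm, iteration count,
#' convergence flag, grid, seed, the fully resolved configuration echo and
#' the package version.
#'
#' @param sol An \code{mfg_solution} or \code{opt_solution}.
#' @param cfg A \code{run_config} (or NULL).
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_summary <- function(sol, cfg, path) {
  s <- list(F = sol$F,
            converged = sol$converged,
            iterations = sol$iterations,
            grid = list(nx = sol$grid$nx, nt = sol$grid$nt),
            package_version = as.character(utils::packageVersion("dvmgame")))
  if (!is.null(sol$residual_norm)) s$residual_norm <- sol$residual_norm
  if (!is.null(sol$gradient_norm)) {
    s$gradient_norm <- sol$gradient_norm
    s$objective <- sol$objective
  }
  if (!is.null(cfg)) {
    s$seed <- cfg$seed
    s$config <- cfg$echo
  }
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
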