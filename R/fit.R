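#' Configuration for fitting the unintuitive circuit
#'
#' Bundles the optimiser settings and the fixed parameter bounds (the 18
#' weights in `[0, 2]`, the balance parameter in `[0, 1]`).
#'
#' @param n_pop Differential-evolution population size.
#' @param n_gen Number of generations.
#' @param grid_n Steering-surface grid resolution used by the objective.
#' @param seed Integer seed; the fit is deterministic given the seed.
#' @param cr Crossover rate.
#' @param tol Convergence tolerance passed to [de_optimize()].
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_pop = 60, n_gen = 900, grid_n = 36, seed = 1L,
                       cr = 0.9, tol = 1e-8) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    abort("`seed` must be a single integer.")
  }
  if (grid_n < 8) {
    abort("`grid_n` must be at least 8.")
  }
  structure(
    list(
      n_pop = as.integer(n_pop),
      n_gen = as.integer(n_gen),
      grid_n = as.integer(grid_n),
      seed = as.integer(seed),
      cr = cr,
      tol = tol,
      bounds = unintuitive_bounds()
    ),
    class = "fit_config"
  )
}

# Internal: objective factory.  Returns a function of the 19-parameter
# vector giving the raw RMSE between the candidate unintuitive surface and
# the reference command matrix.  Degenerate parameter vectors (zero-norm
# steering or goal-component directions) receive a large penalty so the
# optimiser moves away from them.
unintuitive_objective <- function(ref_matrix, headings, goals, k, act) {
  theta <- unintuitive_pfds()
  rc <- sigmoid_rate(
    cos(deg2rad(outer(headings, theta, "-"))), act$slope, act$bias
  )
  n_h <- length(headings)
  n_g <- length(goals)
  function(x) {
    m <- unintuitive_matrices(x)
    eta <- infer_eta_core(theta, m$w_cs_l, m$w_cs_r, m$w_gs_l, m$w_gs_r, x[19])
    if (is.null(eta)) {
      return(1e6)
    }
    rg <- sigmoid_rate(
      cos(deg2rad(outer(goals, eta$eta_deg, "-"))), act$slope, act$bias
    )
    side_sum <- function(w_cs, w_gs) {
      a <- rc %*% t(w_cs)
      b <- rg %*% t(w_gs)
      total <- matrix(0, n_h, n_g)
      for (s in seq_len(ncol(a))) {
        total <- total +
          sigmoid_rate(outer(a[, s], b[, s], "+"), act$slope, act$bias)
      }
      total
    }
    cmd <- k * ((1 - x[19]) * side_sum(m$w_cs_l, m$w_gs_l) -
      x[19] * side_sum(m$w_cs_r, m$w_gs_r))
    sqrt(mean((cmd - ref_matrix)^2))
  }
}

#' Fit the unintuitive circuit to a reference steering surface
#'
#' Searches the 19 free parameters of the unintuitive circuit (see
#' [build_unintuitive()]) by differential evolution so that its steering
#' surface matches the reference surface in raw root-mean-square error.  By
#' default the reference is the fly model's surface, each model evaluated
#' with its own output gain.
#'
#' @param reference A [steering_surface()] to match; defaults to
#'   `steering_surface(build_fly(), config$grid_n)`.  Must be square and,
#'   if supplied, on a `config$grid_n` grid.
#' @param config A [fit_config()].
#' @return An object of class `steering_fit`: list with `x` (best
#'   parameters), `rmse`, `spec` (the fitted [circuit_spec()], goal
#'   directions inferred), `inference`, `converged`, `trace`, `config`.
#' @examples
#' \donttest{
#' fit <- fit_unintuitive(config = fit_config(n_pop = 30, n_gen = 100, seed = 1))
#' rule_check(fit$spec)$passes
#' }
#' @export
fit_unintuitive <- function(reference = NULL, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  if (is.null(reference)) {
    reference <- steering_surface(build_fly(), grid_n = config$grid_n)
  }
  stopifnot(inherits(reference, "steering_surface"))
  headings <- attr(reference, "headings")
  goals <- attr(reference, "goals")
  if (length(headings) != config$grid_n) {
    abort("`reference` grid does not match `config$grid_n`.")
  }
  ref_matrix <- matrix(reference$command, length(headings), length(goals))
  # candidate surfaces use the default unintuitive gain k = -1, matching
  # steering_surface(build_unintuitive(x))
  objective <- unintuitive_objective(
    ref_matrix, headings, goals,
    k = -1, act = list(slope = 2, bias = 0.6)
  )
  b <- config$bounds
  res <- de_optimize(
    objective, b$lower, b$upper,
    n_pop = config$n_pop, n_gen = config$n_gen,
    cr = config$cr, tol = config$tol, seed = config$seed
  )
  spec <- build_unintuitive(res$par)
  fit <- list(
    x = res$par,
    rmse = res$value,
    spec = spec,
    inference = infer_goal_directions(spec),
    converged = res$converged,
    trace = res$trace,
    config = config,
    reference_builder = attr(reference, "builder")
  )
  class(fit) <- "steering_fit"
  fit
}

#' @export
print.steering_fit <- function(x, ...) {
  cat("<steering_fit> unintuitive circuit vs", x$reference_builder, "surface\n")
  cat(
    "  rmse:", signif(x$rmse, 5),
    " converged:", x$converged,
    " (", x$config$n_pop, "x", x$config$n_gen, "DE, seed",
    x$config$seed, ")\n"
  )
  cat(
    "  inferred goal dirs:",
    paste(round(x$inference$eta_deg, 1), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @describeIn fit_unintuitive Tidy the fitted parameters: one row per
#'   parameter with its estimate and bounds.
#' @param x A `steering_fit`.
#' @param ... Unused.
#' @method tidy steering_fit
#' @export
tidy.steering_fit <- function(x, ...) {
  b <- x$config$bounds
  tibble(
    term = c(paste0("x", 0:17), "balance"),
    estimate = x$x,
    lower = b$lower,
    upper = b$upper
  )
}

#' @describeIn fit_unintuitive One-row fit summary.
#' @method glance steering_fit
#' @export
glance.steering_fit <- function(x, ...) {
  tibble(
    rmse = x$rmse,
    converged = x$converged,
    n_pop = x$config$n_pop,
    n_gen = x$config$n_gen,
    grid_n = x$config$grid_n,
    seed = x$config$seed
  )
}
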