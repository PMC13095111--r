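#' Differential-evolution optimiser (best/1/bin)
#'
#' Minimises `fn` over a box-bounded parameter space using the classic
#' differential-evolution strategy: each trial vector is the current best
#' member plus a scaled difference of two random members (scale factor
#' dithered uniformly in `f_range` each generation), binomially crossed with
#' the target member at rate `cr`, clipped to the bounds, and accepted on
#' improvement.
#'
#' @param fn Objective function taking a numeric vector, returning a scalar.
#' @param lower,upper Numeric bound vectors of equal length.
#' @param n_pop Population size (default `10 * length(lower)`).
#' @param n_gen Number of generations.
#' @param cr Crossover rate in (0, 1].
#' @param f_range Range for the per-generation dithered scale factor.
#' @param tol Convergence tolerance: converged when the population's
#'   objective spread falls below `tol * max(1, |best|)`.
#' @param seed Optional integer seed (set before initialisation, making the
#'   run reproducible).
#' @return List with `par` (best parameters), `value` (best objective),
#'   `converged` (logical), `trace` (best objective per generation), `n_gen`,
#'   `n_pop`.  When the generation limit is reached without convergence the
#'   best-so-far is returned with a warning (never silently).
#' @examples
#' sphere <- function(x) sum(x^2)
#' de_optimize(sphere, c(-1, -1), c(1, 1), n_pop = 20, n_gen = 50, seed = 1)$value
#' @export
de_optimize <- function(fn, lower, upper,
                        n_pop = 10 * length(lower), n_gen = 200,
                        cr = 0.9, f_range = c(0.5, 1),
                        tol = 1e-8, seed = NULL) {
  if (length(lower) != length(upper) || any(lower > upper)) {
    abort("`lower` and `upper` must be equal-length with lower <= upper.")
  }
  if (n_pop < 4) {
    abort("`n_pop` must be at least 4.")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- length(lower)
  pop <- matrix(
    runif(n_pop * d, rep(lower, each = n_pop), rep(upper, each = n_pop)),
    nrow = n_pop
  )
  fit <- apply(pop, 1, fn)
  trace <- numeric(n_gen)
  for (g in seq_len(n_gen)) {
    best_i <- which.min(fit)
    f_g <- runif(1, f_range[1], f_range[2])
    for (i in seq_len(n_pop)) {
      idx <- sample.int(n_pop, 2)
      mutant <- pmin(
        pmax(pop[best_i, ] + f_g * (pop[idx[1], ] - pop[idx[2], ]), lower),
        upper
      )
      cross <- runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      f_trial <- fn(trial)
      if (f_trial <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
      }
    }
    trace[g] <- min(fit)
  }
  best_i <- which.min(fit)
  converged <- (max(fit) - min(fit)) <= tol * max(1, abs(min(fit)))
  if (!converged) {
    warning(
      "differential evolution reached the generation limit without ",
      "population convergence; returning best-so-far (objective ",
      signif(min(fit), 6), ")."
    )
  }
  list(
    par = pop[best_i, ],
    value = fit[best_i],
    converged = converged,
    trace = trace,
    n_gen = n_gen,
    n_pop = n_pop
  )
}
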