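# Internal: identity with columns cyclically shifted by one, so right
# steering neuron i samples compass neuron i + 1 (its left partner samples
# compass neuron i; each pair reads neighbouring compass neurons with the
# left neuron at the lower preferred direction).
roll_columns <- function(m) {
  n <- ncol(m)
  m[, c(n, seq_len(n - 1)), drop = FALSE]
}

#' Build a uniform steering circuit
#'
#' A uniform circuit has `n` compass neurons with evenly spaced preferred
#' directions `360 * j / n`, `n` goal neurons, and `2 n` steering neurons.
#' Compass input to the left steering population is `d * I`; to the right
#' population it is `d * I` with columns cyclically shifted by one, so each
#' left/right steering pair samples neighbouring compass neurons.  Goal
#' wiring is the identity on both sides.  Goal directions are inferred from
#' the wiring (they are the midpoints of adjacent compass directions).
#'
#' @param n Number of compass neurons (at least 3, so the compass can form a
#'   positive basis).
#' @param d Compass-to-steering scale (default 0.2).
#' @param k Steering gain (default 1; positive gives negative feedback for
#'   this wiring).  Tune with [tune_gain()].
#' @return A [circuit_spec()].
#' @examples
#' build_uniform(3)$compass_pfds # 0, 120, 240
#' @export
build_uniform <- function(n, d = 0.2, k = 1) {
  if (!is.numeric(n) || length(n) != 1 || n < 3 || n != round(n)) {
    abort("`n` must be an integer >= 3 (fewer cannot form a positive basis).")
  }
  if (!is.numeric(d) || d <= 0) {
    abort("`d` must be positive.")
  }
  n <- as.integer(n)
  eye <- diag(n)
  spec <- circuit_spec(
    compass_pfds = 360 * (0:(n - 1)) / n,
    w_cs_l = d * eye,
    w_cs_r = d * roll_columns(eye),
    w_gs_l = eye,
    w_gs_r = eye,
    k = k,
    balance = 0.5,
    builder = "uniform",
    builder_params = list(n = n, d = d)
  )
  set_inferred_goal_dirs(spec)
}

#' Build the fly steering circuit
#'
#' Embeds the twelve FC2 goal-neuron directions (30-degree spacing) and the
#' twelve left and twelve right PFL3 steering-neuron heading tunings (eight
#' distinct values, 45-degree spacing) of the fly steering model, together
#' with its softplus activation and output gain (see [fly_model_params()]).
#' Rates are evaluated directly from heading and goal; for wiring-based
#' analyses (rule checking, goal-direction inference) the circuit is also
#' represented generically, with the eight distinct PFL3 tunings as compass
#' directions, 0/1 selector matrices routing them to the steering neurons,
#' and identity FC2-to-PFL3 goal wiring.
#'
#' The gain is `k = 2 * output_gain`, so that with the symmetric balance 0.5
#' the command equals `output_gain * (sum(S_L) - sum(S_R))`; left/right are
#' assigned so that positive command = counter-clockwise and the closed loop
#' tracks the goal.
#'
#' @return A [circuit_spec()] of flavor `"fly-softplus"`, with `goal_dirs`
#'   declared as the FC2 tunings (the wiring-inferred directions fall within
#'   15 degrees of these labels).
#' @examples
#' sort(unique(build_fly()$fly$fc2_dirs))
#' @export
build_fly <- function() {
  p <- fly_model_params()
  compass <- sort(unique(c(p$pfl3_left_dirs, p$pfl3_right_dirs)))
  selector <- function(dirs) {
    m <- matrix(0, length(dirs), length(compass))
    for (j in seq_along(dirs)) {
      m[j, which.min(abs(wrap_diff(compass, dirs[j])))] <- 1
    }
    m
  }
  eye12 <- diag(12)
  circuit_spec(
    compass_pfds = compass,
    w_cs_l = selector(p$pfl3_left_dirs),
    w_cs_r = selector(p$pfl3_right_dirs),
    w_gs_l = eye12,
    w_gs_r = eye12,
    k = 2 * p$output_gain,
    balance = 0.5,
    goal_dirs = p$fc2_dirs,
    goal_dirs_source = "declared",
    flavor = "fly-softplus",
    fly = p,
    builder = "fly"
  )
}

# Internal: sparsity template of the unintuitive circuit.  Four compass
# neurons at {350, 10, 90, 200} degrees; two left and three right steering
# neurons; three goal neurons.  x holds the 18 free weights followed by the
# balance parameter.
unintuitive_matrices <- function(x) {
  list(
    w_cs_l = rbind(
      c(x[1], 0, 0, x[2]),
      c(0, 0, x[3], x[4])
    ),
    w_cs_r = rbind(
      c(x[5], x[6], 0, 0),
      c(0, 0, x[7], x[8]),
      c(x[9], 0, 0, x[10])
    ),
    w_gs_l = rbind(
      c(x[11], x[12], 0),
      c(x[13], 0, x[14])
    ),
    w_gs_r = rbind(
      c(x[15], 0, 0),
      c(0, x[16], 0),
      c(0, x[17], x[18])
    )
  )
}

unintuitive_pfds <- function() c(350, 10, 90, 200)

#' Bounds of the unintuitive circuit's free parameters
#'
#' The 18 connection weights vary in `[0, 2]` and the final balance
#' parameter in `[0, 1]`.
#'
#' @return List with numeric vectors `lower` and `upper` (length 19).
#' @export
unintuitive_bounds <- function() {
  list(lower = c(rep(0, 18), 0), upper = c(rep(2, 18), 1))
}

#' Build the unintuitive circuit from its 19 free parameters
#'
#' The unintuitive circuit has four compass neurons with unevenly spaced
#' preferred directions (350, 10, 90, 200 degrees; a positive basis), two
#' left and three right steering neurons, and three goal neurons.  The four
#' weight matrices have a fixed sparsity pattern; `x` supplies the 18 free
#' weights (row-major over the allowed entries of the compass-to-left,
#' compass-to-right, goal-to-left, then goal-to-right matrices) followed by
#' the left/right balance parameter.  Goal directions are inferred from the
#' wiring.
#'
#' This wiring orientation drives the agent clockwise, so the default gain is
#' negative to keep the package-wide convention (positive command =
#' counter-clockwise, closed loop = negative feedback).
#'
#' @param x Numeric vector of 19 parameters within [unintuitive_bounds()].
#' @param k Steering gain (default -1); tune with [tune_gain()].
#' @return A [circuit_spec()].
#' @export
build_unintuitive <- function(x, k = -1) {
  b <- unintuitive_bounds()
  if (!is.numeric(x) || length(x) != 19 || any(!is.finite(x))) {
    abort("`x` must be a finite numeric vector of length 19.")
  }
  if (any(x < b$lower) || any(x > b$upper)) {
    abort(paste0(
      "parameters out of bounds: the 18 weights must lie in [0, 2] ",
      "and the balance parameter in [0, 1]."
    ))
  }
  m <- unintuitive_matrices(x)
  spec <- circuit_spec(
    compass_pfds = unintuitive_pfds(),
    w_cs_l = m$w_cs_l, w_cs_r = m$w_cs_r,
    w_gs_l = m$w_gs_l, w_gs_r = m$w_gs_r,
    k = k,
    balance = x[19],
    builder = "unintuitive",
    builder_params = list(x = x)
  )
  # rejects degenerate (e.g. all-zero) parameter vectors
  set_inferred_goal_dirs(spec)
}

#' Build a deliberately rule-breaking circuit
#'
#' Constructs minimal circuits that each violate exactly the intended
#' prescriptive rule(s):
#' \describe{
#'   \item{`rule1`}{Compass preferred directions \{0, 60, 120\} (not a
#'     positive basis) on otherwise-minimal uniform wiring.}
#'   \item{`rule4`}{The minimal uniform circuit with declared goal
#'     directions displaced 180 degrees from their wiring-implied values
#'     (wiring untouched).}
#'   \item{`rule5`}{The minimal uniform circuit with goal-to-steering wiring
#'     rerouted so all inferred goal directions fall inside one half-plane
#'     (every goal neuron drives steering pairs whose midpoints lie within a
#'     narrow arc).}
#'   \item{`rule1and5`}{Both the `rule1` compass and the `rule5` goal
#'     wiring.}
#' }
#'
#' @param which One of `"rule1"`, `"rule4"`, `"rule5"`, `"rule1and5"`.
#' @param d,k Passed to the underlying minimal wiring (see
#'   [build_uniform()]).
#' @return A [circuit_spec()].
#' @examples
#' rule_check(build_rule_breaker("rule1"))$passes
#' @export
build_rule_breaker <- function(which = c("rule1", "rule4", "rule5", "rule1and5"),
                               d = 0.2, k = 1) {
  which <- match.arg(which)
  base <- build_uniform(3, d = d, k = k)
  # goal wiring concentrating all inferred directions in one narrow arc:
  # every goal neuron routes through the first left/right steering pair
  rule5_goal_wiring <- function(spec) {
    spec$w_gs_l <- rbind(
      c(1, 1, 1),
      c(0, 1, 0),
      c(0, 0, 0)
    )
    spec$w_gs_r <- rbind(
      c(1, 1, 1),
      c(0, 0, 2),
      c(0, 0, 0)
    )
    spec
  }
  spec <- switch(which,
    rule1 = {
      s <- base
      s$compass_pfds <- wrap_angle(c(0, 60, 120))
      set_inferred_goal_dirs(s)
    },
    rule4 = {
      s <- base
      s$goal_dirs <- wrap_angle(s$goal_dirs + 180)
      s$goal_dirs_source <- "declared"
      s
    },
    rule5 = set_inferred_goal_dirs(rule5_goal_wiring(base)),
    rule1and5 = {
      s <- rule5_goal_wiring(base)
      s$compass_pfds <- wrap_angle(c(0, 60, 120))
      set_inferred_goal_dirs(s)
    }
  )
  spec$builder <- paste0("rule_breaker_", which)
  spec$builder_params <- list(which = which, d = d)
  spec
}
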