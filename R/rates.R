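#' Compass population rates for a heading
#'
#' Each compass neuron receives input `cos(heading - pfd)` passed through the
#' sigmoid activation, so every heading produces some activity in every
#' neuron (rates are strictly positive).
#'
#' @param heading_deg Heading in degrees (single value).
#' @param spec A sigmoid-rate [circuit_spec()].
#' @return Numeric vector of rates, one per compass neuron.
#' @export
compass_rates <- function(heading_deg, spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (spec$flavor != "sigmoid-rate") {
    abort(paste0(
      "compass_rates() applies to sigmoid-rate circuits; the fly-softplus ",
      "model computes steering rates directly from heading and goal."
    ))
  }
  sigmoid_rate(
    cos(deg2rad(heading_deg - spec$compass_pfds)),
    spec$activation$slope, spec$activation$bias
  )
}

#' Goal population rates for a goal direction
#'
#' Mirror of [compass_rates()]: each goal neuron receives `cos(goal -
#' goal_dir)` through the sigmoid activation.
#'
#' @param goal_deg Goal direction in degrees (single value).
#' @param spec A sigmoid-rate [circuit_spec()] with `goal_dirs` set.
#' @return Numeric vector of rates, one per goal neuron.
#' @export
goal_rates <- function(goal_deg, spec) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (spec$flavor != "sigmoid-rate") {
    abort("goal_rates() applies to sigmoid-rate circuits.")
  }
  if (is.null(spec$goal_dirs)) {
    abort(paste0(
      "`spec$goal_dirs` is unset; infer directions first ",
      "(see infer_goal_directions())."
    ))
  }
  sigmoid_rate(
    cos(deg2rad(goal_deg - spec$goal_dirs)),
    spec$activation$slope, spec$activation$bias
  )
}

# Internal: evaluate left/right steering rates of a sigmoid-rate circuit.
sigmoid_steering_rates <- function(spec, rc, rg) {
  act <- spec$activation
  list(
    left = sigmoid_rate(
      as.numeric(spec$w_cs_l %*% rc + spec$w_gs_l %*% rg),
      act$slope, act$bias
    ),
    right = sigmoid_rate(
      as.numeric(spec$w_cs_r %*% rc + spec$w_gs_r %*% rg),
      act$slope, act$bias
    )
  )
}

# Internal: fly steering rates from heading and goal.
fly_steering_rates <- function(heading_deg, goal_deg, fly) {
  drive <- function(pfl3) {
    cos(deg2rad(heading_deg - pfl3)) +
      fly$goal_input_weight * cos(deg2rad(goal_deg - fly$fc2_dirs))
  }
  sp <- function(x) {
    fly_softplus(x, fly$softplus_scale, fly$softplus_slope, fly$softplus_shift)
  }
  list(
    left = sp(drive(fly$pfl3_left_dirs)),
    right = sp(drive(fly$pfl3_right_dirs))
  )
}

#' Steering command of a circuit at a given heading and goal
#'
#' Evaluates the full forward pass: compass and goal rates, steering inputs
#' as weighted sums, steering rates through the activation, and the scalar
#' turn command `k * ((1 - balance) * sum(r_SL) - balance * sum(r_SR))`.
#' Positive command = counter-clockwise (heading increases).
#'
#' For the fly-softplus flavor, steering rates are computed directly from
#' heading and goal (there is no explicit compass rate layer); compass and
#' goal rate slots are `NULL` in that case.
#'
#' @param heading_deg,goal_deg Heading and goal in degrees (single values).
#' @param spec A [circuit_spec()].
#' @param goal_rate_override Optional numeric vector replacing the goal
#'   population rates (sigmoid flavor only), e.g. a one-hot pattern
#'   activating a single goal neuron for equilibrium probing.
#' @return A list with `command` (degrees/s) and `rates` (list with
#'   `compass`, `goal`, `steer_l`, `steer_r`).
#' @examples
#' u <- build_uniform(3)
#' steering_command(0, 60, u)$command > 0 # drives counter-clockwise toward 60
#' @export
steering_command <- function(heading_deg, goal_deg, spec,
                             goal_rate_override = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (spec$flavor == "fly-softplus") {
    if (!is.null(goal_rate_override)) {
      abort("`goal_rate_override` is not available for the fly-softplus model.")
    }
    sr <- fly_steering_rates(heading_deg, goal_deg, spec$fly)
    rc <- NULL
    rg <- NULL
  } else {
    rc <- compass_rates(heading_deg, spec)
    rg <- goal_rate_override %||% goal_rates(goal_deg, spec)
    if (length(rg) != n_goal(spec)) {
      abort("`goal_rate_override` must hold one rate per goal neuron.")
    }
    sr <- sigmoid_steering_rates(spec, rc, rg)
  }
  command <- spec$k *
    ((1 - spec$balance) * sum(sr$left) - spec$balance * sum(sr$right))
  list(
    command = command,
    rates = list(
      compass = rc, goal = rg,
      steer_l = sr$left, steer_r = sr$right
    )
  )
}

#' Fly steering command from heading and goal
#'
#' Standalone evaluation of the fly steering model: per-neuron softplus
#' responses to `cos(heading - pfl3_dir) + 0.3 * cos(goal - fc2_dir)` over
#' the twelve left and twelve right steering neurons, combined as
#' `output_gain * (sum(S_L) - sum(S_R))` with the left/right assignment of
#' [fly_model_params()], so the sign convention matches [steering_command()]
#' (positive = counter-clockwise).
#'
#' @param heading_deg,goal_deg Heading and goal in degrees (single values).
#' @param params Fly-model constants, see [fly_model_params()].
#' @return Scalar command.
#' @examples
#' fly_steering(30, 30) # ~0 at the goal
#' @export
fly_steering <- function(heading_deg, goal_deg, params = fly_model_params()) {
  sr <- fly_steering_rates(heading_deg, goal_deg, params)
  params$output_gain * (sum(sr$left) - sum(sr$right))
}
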