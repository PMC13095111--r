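#' Canonical fly steering-model parameters
#'
#' Returns the constants of the fly (PFL3/FC2) steering model: the goal-input
#' weight (0.3), the softplus parameters (scale 29.23, slope 2.17, shift
#' 0.7), the output gain (0.00018), and the three 12-element direction lists
#' (goal/FC2 tunings 30 degrees apart; left and right steering/PFL3 heading
#' tunings, each drawn from eight distinct values 45 degrees apart).
#'
#' The model's published left/right summation order drives the agent
#' clockwise under this package's sign convention (positive command =
#' counter-clockwise heading change), so the list serving as the *left*
#' population here is the one whose excess must turn the agent
#' counter-clockwise; with that assignment the closed loop is negative
#' feedback toward the goal and the inferred goal-neuron directions fall
#' within 15 degrees of the corresponding FC2 tunings.
#'
#' @return A named list of fly-model constants.
#' @examples
#' p <- fly_model_params()
#' diff(sort(p$fc2_dirs))[1] # 30-degree spacing
#' @export
fly_model_params <- function() {
  fc2 <- c(-15, -45, -75, -105, -135, -165, 165, 135, 105, 75, 45, 15)
  pfl3_a <- c(
    67.5, 22.5, -22.5, -22.5, -67.5, -112.5,
    -112.5, -157.5, 157.5, 157.5, 112.5, 67.5
  )
  pfl3_b <- c(
    -67.5, -112.5, -157.5, -157.5, 157.5, 112.5,
    112.5, 67.5, 22.5, 22.5, -22.5, -67.5
  )
  list(
    goal_input_weight = 0.3,
    softplus_scale = 29.23,
    softplus_slope = 2.17,
    softplus_shift = 0.7,
    output_gain = 0.00018,
    fc2_dirs = wrap_angle(fc2),
    # left population = the list whose excess drives counter-clockwise turns
    pfl3_left_dirs = wrap_angle(pfl3_b),
    pfl3_right_dirs = wrap_angle(pfl3_a)
  )
}

validate_weight_matrix <- function(w, name, n_row, n_col) {
  if (!is.matrix(w) || !is.numeric(w)) {
    abort(paste0("`", name, "` must be a numeric matrix."))
  }
  if (nrow(w) != n_row || ncol(w) != n_col) {
    abort(paste0(
      "`", name, "` must be ", n_row, "x", n_col,
      " (got ", nrow(w), "x", ncol(w), ")."
    ))
  }
  if (any(!is.finite(w))) {
    abort(paste0("`", name, "` contains non-finite entries."))
  }
  if (any(w < 0)) {
    abort(paste0(
      "`", name, "` contains negative weights; ",
      "all connections must be excitatory (weights >= 0)."
    ))
  }
  invisible(w)
}

#' Construct a steering-circuit specification
#'
#' A `circuit_spec` fully parameterises one steering circuit: compass
#' preferred firing directions, the four weight matrices routing compass and
#' goal activity to the left and right steering populations, the output gain
#' and left/right balance, the activation parameters, and (for the fly
#' flavor) the fly-model constants.
#'
#' The scalar steering command is `k * ((1 - balance) * sum(r_SL) - balance *
#' sum(r_SR))`, positive = counter-clockwise.  Builders choose the sign of
#' `k` so that the closed loop is negative feedback toward the goal; `k` may
#' therefore be negative for circuits whose printed wiring orientation drives
#' clockwise.
#'
#' @param compass_pfds Compass preferred directions in degrees.
#' @param w_cs_l,w_cs_r Compass-to-steering weight matrices (rows =
#'   postsynaptic left/right steering neurons, columns = compass neurons).
#'   All weights non-negative (connections are excitatory); prohibited
#'   connections are explicit zeros.
#' @param w_gs_l,w_gs_r Goal-to-steering weight matrices (rows = steering
#'   neurons, columns = goal neurons).
#' @param k Steering gain (degrees/s per unit summed-rate difference); sign
#'   sets the wiring orientation, see Details.
#' @param balance Left/right balance weight in `[0, 1]` (0.5 = symmetric).
#' @param activation List with positive `slope` and `bias` for the sigmoid
#'   rate function.
#' @param goal_dirs Declared goal-neuron associated directions in degrees
#'   (one per goal neuron), or `NULL` if they are to be inferred from wiring.
#' @param goal_dirs_source `"inferred"` (directions derived from wiring) or
#'   `"declared"` (labels supplied independently of wiring, as in the
#'   rule-4-breaking circuit).
#' @param flavor `"sigmoid-rate"` (generic circuits) or `"fly-softplus"`
#'   (fly model, evaluated directly from heading and goal).
#' @param fly Fly-model constants (see [fly_model_params()]); required when
#'   `flavor = "fly-softplus"`.
#' @param builder Name of the constructor that produced this spec
#'   (provenance).
#' @param builder_params Named list of constructor parameters (provenance).
#' @return An object of class `circuit_spec`.
#' @seealso [build_uniform()], [build_fly()], [build_unintuitive()],
#'   [build_rule_breaker()]
#' @export
circuit_spec <- function(compass_pfds,
                         w_cs_l, w_cs_r, w_gs_l, w_gs_r,
                         k = 1,
                         balance = 0.5,
                         activation = list(slope = 2, bias = 0.6),
                         goal_dirs = NULL,
                         goal_dirs_source = c("inferred", "declared"),
                         flavor = c("sigmoid-rate", "fly-softplus"),
                         fly = NULL,
                         builder = "custom",
                         builder_params = list()) {
  flavor <- match.arg(flavor)
  goal_dirs_source <- match.arg(goal_dirs_source)
  if (!is.numeric(compass_pfds) || length(compass_pfds) < 1 ||
    any(!is.finite(compass_pfds))) {
    abort("`compass_pfds` must be a non-empty finite numeric vector.")
  }
  compass_pfds <- wrap_angle(compass_pfds)
  n_c <- length(compass_pfds)
  if (!is.matrix(w_cs_l) || !is.matrix(w_gs_l)) {
    abort("weight matrices must be matrices.")
  }
  n_l <- nrow(w_cs_l)
  n_r <- nrow(w_cs_r)
  n_g <- ncol(w_gs_l)
  validate_weight_matrix(w_cs_l, "w_cs_l", n_l, n_c)
  validate_weight_matrix(w_cs_r, "w_cs_r", n_r, n_c)
  validate_weight_matrix(w_gs_l, "w_gs_l", n_l, n_g)
  validate_weight_matrix(w_gs_r, "w_gs_r", n_r, n_g)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k == 0) {
    abort("`k` must be a single non-zero finite number.")
  }
  if (!is.numeric(balance) || length(balance) != 1 ||
    balance < 0 || balance > 1) {
    abort("`balance` must be a single number in [0, 1].")
  }
  if (!is.list(activation) || is.null(activation$slope) ||
    is.null(activation$bias) || activation$slope <= 0) {
    abort("`activation` must be a list with positive `slope` and a `bias`.")
  }
  if (!is.null(goal_dirs)) {
    if (length(goal_dirs) != n_g || any(!is.finite(goal_dirs))) {
      abort(paste0("`goal_dirs` must hold ", n_g, " finite angles."))
    }
    goal_dirs <- wrap_angle(goal_dirs)
  }
  if (flavor == "fly-softplus") {
    if (is.null(fly)) {
      abort("`fly` parameters are required for the fly-softplus flavor.")
    }
    needed <- c(
      "goal_input_weight", "softplus_scale", "softplus_slope",
      "softplus_shift", "output_gain", "fc2_dirs",
      "pfl3_left_dirs", "pfl3_right_dirs"
    )
    missing <- setdiff(needed, names(fly))
    if (length(missing) > 0) {
      abort(paste0("`fly` is missing: ", paste(missing, collapse = ", ")))
    }
    for (f in c("fc2_dirs", "pfl3_left_dirs", "pfl3_right_dirs")) {
      if (length(fly[[f]]) != 12) {
        abort(paste0("`fly$", f, "` must have length 12."))
      }
    }
  } else if (!is.null(fly)) {
    abort("`fly` parameters are only valid for the fly-softplus flavor.")
  }
  structure(
    list(
      flavor = flavor,
      compass_pfds = compass_pfds,
      goal_dirs = goal_dirs,
      goal_dirs_source = goal_dirs_source,
      w_cs_l = w_cs_l, w_cs_r = w_cs_r,
      w_gs_l = w_gs_l, w_gs_r = w_gs_r,
      k = k,
      balance = balance,
      activation = activation,
      fly = fly,
      builder = builder,
      builder_params = builder_params
    ),
    class = "circuit_spec"
  )
}

#' Population sizes of a circuit
#'
#' @param spec A [circuit_spec()].
#' @return Integer count.
#' @examples
#' n_steering(build_uniform(3)) # 6
#' @export
n_compass <- function(spec) length(spec$compass_pfds)

#' @rdname n_compass
#' @export
n_goal <- function(spec) ncol(spec$w_gs_l)

#' @rdname n_compass
#' @export
n_steering <- function(spec) nrow(spec$w_cs_l) + nrow(spec$w_cs_r)

#' @export
print.circuit_spec <- function(x, ...) {
  cat("<circuit_spec>", x$flavor, " (builder:", x$builder, ")\n")
  cat(
    " ", n_compass(x), "compass,", n_goal(x), "goal,",
    nrow(x$w_cs_l), "left +", nrow(x$w_cs_r), "right steering neurons\n"
  )
  cat(
    "  compass PFDs:",
    paste(round(x$compass_pfds, 2), collapse = ", "), "\n"
  )
  if (!is.null(x$goal_dirs)) {
    cat(
      "  goal dirs (", x$goal_dirs_source, "):",
      paste(round(x$goal_dirs, 2), collapse = ", "), "\n"
    )
  } else {
    cat("  goal dirs: unset (infer with infer_goal_directions())\n")
  }
  cat("  gain k =", signif(x$k, 6), ", balance =", x$balance, "\n")
  invisible(x)
}
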