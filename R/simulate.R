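# Internal: fast scalar command closure for closed-loop simulation,
# precomputing everything that does not depend on heading or goal.
make_command_fun <- function(spec, goal_rate_override = NULL) {
  k <- spec$k
  w <- spec$balance
  if (spec$flavor == "fly-softplus") {
    if (!is.null(goal_rate_override)) {
      abort("`goal_rate_override` is not available for the fly-softplus model.")
    }
    fly <- spec$fly
    pl <- deg2rad(fly$pfl3_left_dirs)
    pr <- deg2rad(fly$pfl3_right_dirs)
    fc <- deg2rad(fly$fc2_dirs)
    gw <- fly$goal_input_weight
    sc <- fly$softplus_scale
    sl <- fly$softplus_slope
    sh <- fly$softplus_shift
    function(h, g) {
      gterm <- gw * cos(deg2rad(g) - fc)
      s_l <- fly_softplus(cos(deg2rad(h) - pl) + gterm, sc, sl, sh)
      s_r <- fly_softplus(cos(deg2rad(h) - pr) + gterm, sc, sl, sh)
      k * ((1 - w) * sum(s_l) - w * sum(s_r))
    }
  } else {
    if (is.null(spec$goal_dirs) && is.null(goal_rate_override)) {
      abort("`spec$goal_dirs` is unset; infer directions first.")
    }
    theta <- deg2rad(spec$compass_pfds)
    phi <- if (is.null(spec$goal_dirs)) NULL else deg2rad(spec$goal_dirs)
    slope <- spec$activation$slope
    bias <- spec$activation$bias
    w_cs_l <- spec$w_cs_l
    w_cs_r <- spec$w_cs_r
    w_gs_l <- spec$w_gs_l
    w_gs_r <- spec$w_gs_r
    fixed_rg <- goal_rate_override
    if (!is.null(fixed_rg) && length(fixed_rg) != ncol(w_gs_l)) {
      abort("`goal_rate_override` must hold one rate per goal neuron.")
    }
    function(h, g) {
      rc <- 1 / (1 + exp(-slope * (cos(deg2rad(h) - theta) - bias)))
      rg <- fixed_rg %||%
        (1 / (1 + exp(-slope * (cos(deg2rad(g) - phi) - bias))))
      r_l <- 1 / (1 + exp(-slope * (
        as.numeric(w_cs_l %*% rc + w_gs_l %*% rg) - bias)))
      r_r <- 1 / (1 + exp(-slope * (
        as.numeric(w_cs_r %*% rc + w_gs_r %*% rg) - bias)))
      k * ((1 - w) * sum(r_l) - w * sum(r_r))
    }
  }
}

#' Run a closed-loop heading simulation
#'
#' Explicit first-order (Euler) integration of the heading under the
#' circuit's steering command: `heading[t + 1] = wrap(heading[t] +
#' command[t] * dt)`.  Deterministic given the spec and goal trace.
#'
#' @param spec A [circuit_spec()].
#' @param goal A goal protocol tibble (from [random_walk_goal()],
#'   [smooth_turn_goal()], [step_change_goal()]) or a numeric vector of goal
#'   angles, one per timestep.
#' @param dt Timestep in seconds; taken from the protocol attributes when
#'   available.
#' @param init_heading_deg Initial heading; defaults to the first goal value.
#' @param goal_rate_override Optional fixed goal-population rate vector
#'   (sigmoid flavor only); when supplied the goal trace is ignored by the
#'   circuit (used for single-goal-neuron equilibrium probes).
#' @return A tibble of class `steering_trajectory` with columns `t`,
#'   `goal_deg`, `heading_deg`, `command_deg_per_s`.
#' @examples
#' u <- tune_gain(build_uniform(3))
#' traj <- run_closed_loop(u, step_change_goal(90, n_cycles = 1))
#' @export
run_closed_loop <- function(spec, goal, dt = NULL, init_heading_deg = NULL,
                            goal_rate_override = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (is.data.frame(goal)) {
    dt <- dt %||% attr(goal, "dt")
    goal <- goal$goal_deg
  }
  dt <- dt %||% 0.01
  if (dt <= 0) abort("`dt` must be positive.")
  n <- length(goal)
  if (n < 1) abort("`goal` must contain at least one value.")
  goal <- wrap_angle(goal)
  cmd_fun <- make_command_fun(spec, goal_rate_override)
  heading <- numeric(n)
  command <- numeric(n)
  heading[1] <- wrap_angle(init_heading_deg %||% goal[1])
  for (i in seq_len(n)) {
    command[i] <- cmd_fun(heading[i], goal[i])
    if (!is.finite(command[i])) {
      abort(paste0(
        "non-finite steering command at step ", i,
        " (t = ", signif((i - 1) * dt, 6), " s, heading ",
        round(heading[i], 3), ", goal ", round(goal[i], 3), ")."
      ))
    }
    if (i < n) {
      heading[i + 1] <- wrap_angle(heading[i] + command[i] * dt)
    }
  }
  out <- tibble(
    t = (seq_len(n) - 1) * dt,
    goal_deg = goal,
    heading_deg = heading,
    command_deg_per_s = command
  )
  class(out) <- c("steering_trajectory", class(out))
  attr(out, "dt") <- dt
  attr(out, "builder") <- spec$builder
  out
}

#' Tune the steering gain to a target peak turn rate
#'
#' Adjusts the magnitude of the circuit's gain `k` (preserving its sign, i.e.
#' the wiring orientation) by bisection until the peak turn rate during a
#' 90-degree step response falls inside `rate_band`.  All reference circuits
#' are tuned this way so they steer at comparable rates (50-60 deg/s by
#' default).
#'
#' @param spec A [circuit_spec()].
#' @param rate_band Target band for the peak turn rate, degrees/s.
#' @param dt Timestep for the probe simulation.
#' @param duration Probe duration in seconds.
#' @param max_iter Maximum bisection iterations before declaring the band
#'   unreachable.
#' @return The spec with `k` updated (pipe-friendly).
#' @examples
#' u <- tune_gain(build_uniform(3))
#' @export
tune_gain <- function(spec, rate_band = c(50, 60), dt = 0.01, duration = 4,
                      max_iter = 60) {
  stopifnot(inherits(spec, "circuit_spec"))
  if (length(rate_band) != 2 || any(rate_band <= 0) ||
    rate_band[1] >= rate_band[2]) {
    abort("`rate_band` must be two increasing positive numbers.")
  }
  sign_k <- sign(spec$k)
  goal <- rep(90, round(duration / dt))
  peak_rate <- function(k_mag) {
    s <- spec
    s$k <- sign_k * k_mag
    traj <- run_closed_loop(s, goal, dt = dt, init_heading_deg = 0)
    max(abs(traj$command_deg_per_s))
  }
  target <- mean(rate_band)
  p1 <- peak_rate(abs(spec$k))
  if (p1 <= 0) {
    abort("steering command is identically zero; gain band unreachable.")
  }
  # the command is linear in k, so this initial guess usually lands in band
  k_mag <- abs(spec$k) * target / p1
  lo <- k_mag / 64
  hi <- k_mag * 64
  for (i in seq_len(max_iter)) {
    p <- peak_rate(k_mag)
    if (p >= rate_band[1] && p <= rate_band[2]) {
      spec$k <- sign_k * k_mag
      return(spec)
    }
    if (p < rate_band[1]) lo <- k_mag else hi <- k_mag
    k_mag <- sqrt(lo * hi)
  }
  abort("tune_gain: target rate band unreachable within iteration limit.")
}

#' Detect stable-heading plateaus in a trajectory
#'
#' Histograms heading dwell time into `bin_width`-degree bins and finds
#' circularly contiguous runs of bins whose dwell fraction exceeds
#' `baseline_factor` times the uniform baseline (`1 / n_bins`).  Runs whose
#' total dwell fraction reaches `dwell_threshold` are reported as plateaus;
#' each plateau's position is the circular mean of the heading samples inside
#' its bins.  A circuit that tracks a smooth 0-360-0 goal ramp perfectly
#' dwells uniformly and produces no plateau; a circuit with stable headings
#' piles dwell time onto a few adjacent bins.
#'
#' @param traj A [run_closed_loop()] trajectory (heading trace used).
#' @param bin_width Histogram bin width in degrees (default 5).
#' @param dwell_threshold Minimum total dwell fraction for a plateau
#'   (default 0.15).
#' @param baseline_factor Multiple of the uniform dwell fraction a bin must
#'   exceed to count as above baseline (default 2).
#' @return A tibble of class `stable_heading_report` with columns
#'   `plateau_deg`, `dwell_fraction`, `n_bins`, sorted by `plateau_deg`.
#' @export
detect_stable_headings <- function(traj, bin_width = 5,
                                   dwell_threshold = 0.15,
                                   baseline_factor = 2) {
  h <- if (is.data.frame(traj)) traj$heading_deg else traj
  if (360 %% bin_width != 0) {
    abort("`bin_width` must divide 360.")
  }
  n_bins <- 360 / bin_width
  bin <- floor(wrap_angle(h) / bin_width) + 1
  bin[bin > n_bins] <- n_bins
  frac <- tabulate(bin, n_bins) / length(h)
  above <- frac > baseline_factor / n_bins

  runs <- list()
  if (all(above)) {
    runs[[1]] <- seq_len(n_bins)
  } else if (any(above)) {
    # rotate so position 1 is below baseline, then take maximal runs
    start <- which(!above)[1]
    order_idx <- ((seq_len(n_bins) + start - 2) %% n_bins) + 1
    r <- rle(above[order_idx])
    ends <- cumsum(r$lengths)
    begins <- ends - r$lengths + 1
    for (j in which(r$values)) {
      runs[[length(runs) + 1]] <- order_idx[begins[j]:ends[j]]
    }
  }

  plateaus <- list()
  for (run in runs) {
    dwell <- sum(frac[run])
    if (dwell >= dwell_threshold) {
      samples <- h[bin %in% run]
      centre <- wrap_angle(rad2deg(Arg(sum(unit_complex(samples)))))
      plateaus[[length(plateaus) + 1]] <- tibble(
        plateau_deg = centre,
        dwell_fraction = dwell,
        n_bins = length(run)
      )
    }
  }
  out <- if (length(plateaus) > 0) {
    arrange(bind_rows(plateaus), .data$plateau_deg)
  } else {
    tibble(
      plateau_deg = numeric(0),
      dwell_fraction = numeric(0),
      n_bins = integer(0)
    )
  }
  class(out) <- c("stable_heading_report", class(out))
  attr(out, "bin_width") <- bin_width
  attr(out, "dwell_threshold") <- dwell_threshold
  attr(out, "baseline_factor") <- baseline_factor
  out
}

#' Closed-loop equilibrium probe for a fixed goal
#'
#' Commands a fixed goal (either a goal angle, or a one-hot activation of a
#' single goal neuron for sigmoid circuits) and runs the closed loop from
#' several initial headings, reporting where each run settles and the wrapped
#' error relative to the commanded direction.
#'
#' @param spec A [circuit_spec()].
#' @param goal_deg Fixed goal direction in degrees (the settling target).
#' @param goal_neuron Optional index of a single goal neuron to activate
#'   one-hot (rate 1, all others 0; sigmoid circuits only).  The settling
#'   target is then that neuron's inferred direction unless `goal_deg` is
#'   also given.
#' @param init_heading_deg Initial headings; default
#'   `goal + c(-120, -45, 0, 45, 120)`.
#' @param duration,dt Simulation length and timestep.
#' @return A tibble with columns `init_heading_deg`, `settled_deg`,
#'   `abs_err_deg` (wrapped distance from the target), and
#'   `final_command_deg_per_s`.
#' @examples
#' u <- tune_gain(build_uniform(3))
#' goal_equilibrium(u, goal_deg = 120)$abs_err_deg # ~0
#' @export
goal_equilibrium <- function(spec, goal_deg = NULL, goal_neuron = NULL,
                             init_heading_deg = NULL, duration = 40,
                             dt = 0.01) {
  stopifnot(inherits(spec, "circuit_spec"))
  override <- NULL
  if (!is.null(goal_neuron)) {
    n_g <- n_goal(spec)
    if (goal_neuron < 1 || goal_neuron > n_g) {
      abort("`goal_neuron` out of range.")
    }
    override <- replace(rep(0, n_g), goal_neuron, 1)
    if (is.null(goal_deg)) {
      goal_deg <- infer_goal_directions(spec)$eta_deg[goal_neuron]
    }
  }
  if (is.null(goal_deg)) {
    abort("supply `goal_deg` and/or `goal_neuron`.")
  }
  goal_deg <- wrap_angle(goal_deg)
  inits <- wrap_angle(init_heading_deg %||%
    (goal_deg + c(-120, -45, 0, 45, 120)))
  goal <- rep(goal_deg, round(duration / dt))
  rows <- map(inits, function(h0) {
    traj <- run_closed_loop(
      spec, goal,
      dt = dt, init_heading_deg = h0,
      goal_rate_override = override
    )
    last <- nrow(traj)
    tibble(
      init_heading_deg = h0,
      settled_deg = traj$heading_deg[last],
      abs_err_deg = abs(wrap_diff(traj$heading_deg[last], goal_deg)),
      final_command_deg_per_s = traj$command_deg_per_s[last]
    )
  })
  bind_rows(rows)
}

#' @describeIn run_closed_loop Goal and heading traces over time.
#' @param object A `steering_trajectory`.
#' @param ... Unused.
#' @method autoplot steering_trajectory
#' @export
autoplot.steering_trajectory <- function(object, ...) {
  ggplot(object, aes(.data$t)) +
    geom_line(aes(y = .data$goal_deg), colour = "#2166ac") +
    geom_line(aes(y = .data$heading_deg), colour = "#b2182b") +
    labs(
      x = "time (s)", y = "angle (deg)",
      title = paste0(
        "Closed loop (", attr(object, "builder"),
        "): goal (blue) vs heading (red)"
      )
    ) +
    theme_minimal()
}

#' @describeIn run_closed_loop Print the trace plot.
#' @param traj A `steering_trajectory`.
#' @export
plot_trajectory <- function(traj, ...) print(autoplot(traj, ...))

#' @describeIn run_closed_loop One-row tracking summary: angular RMSE between
#'   heading and goal, final wrapped error, peak turn rate.
#' @param x A `steering_trajectory`.
#' @method glance steering_trajectory
#' @export
glance.steering_trajectory <- function(x, ...) {
  tibble(
    n = nrow(x),
    duration_s = x$t[nrow(x)],
    angular_rmse_deg = angular_rmse(x$heading_deg, x$goal_deg),
    final_abs_err_deg = abs(wrap_diff(
      x$heading_deg[nrow(x)], x$goal_deg[nrow(x)]
    )),
    peak_rate_deg_per_s = max(abs(x$command_deg_per_s))
  )
}
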