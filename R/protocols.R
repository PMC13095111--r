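#' Sample from a von Mises distribution
#'
#' Rejection sampler (Best-Fisher wrapped-Cauchy envelope) for the circular
#' analogue of the Gaussian.  Uses the current R random-number stream; seed
#' with `set.seed()` (or via the protocol functions) for reproducibility.
#'
#' @param n Number of samples.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0; 0 gives the uniform distribution, large
#'   values concentrate at `mu`).
#' @return Numeric vector of `n` angles in degrees, each within
#'   `mu + [-180, 180)`.
#' @examples
#' set.seed(1)
#' mean(sample_von_mises(1e4, 0, 10.3)) # ~0
#' @export
sample_von_mises <- function(n, mu = 0, kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa < 0) {
    abort("`kappa` must be a single non-negative number.")
  }
  if (n == 0) {
    return(numeric(0))
  }
  if (kappa < 1e-8) {
    return(mu + runif(n, -180, 180))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  filled <- 0
  while (filled < n) {
    m <- n - filled
    u1 <- runif(m)
    u2 <- runif(m)
    u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    n_ok <- sum(ok)
    if (n_ok > 0) {
      theta <- sign(u3[ok] - 0.5) * acos(pmin(pmax(f[ok], -1), 1))
      out[(filled + 1):(filled + n_ok)] <- rad2deg(theta)
      filled <- filled + n_ok
    }
  }
  mu + out
}

protocol_tibble <- function(goal, dt, kind, params) {
  out <- tibble(
    t = (seq_along(goal) - 1) * dt,
    goal_deg = wrap_angle(goal)
  )
  attr(out, "dt") <- dt
  attr(out, "kind") <- kind
  attr(out, "params") <- params
  class(out) <- c("goal_protocol", class(out))
  out
}

#' Random-walk goal protocol
#'
#' The goal direction accumulates von Mises increments (`mu = 0`, default
#' `kappa = 10.3`), one increment per `step_every` seconds of simulated time
#' (default 0.1 s) so the walk does not change faster than a circuit tuned to
#' 50-60 deg/s can follow; between increments the goal is held constant at
#' the simulation timestep `dt`.
#'
#' @param duration Total duration in seconds.
#' @param dt Simulation timestep in seconds.
#' @param kappa Concentration of the increment distribution.
#' @param mu Mean increment in degrees (default 0).
#' @param seed Optional integer seed (applied with `set.seed()`).
#' @param step_every Seconds between increments.
#' @param start_deg Initial goal direction.
#' @return A tibble with columns `t` and `goal_deg`.
#' @export
random_walk_goal <- function(duration = 60, dt = 0.01, kappa = 10.3, mu = 0,
                             seed = NULL, step_every = 0.1, start_deg = 0) {
  if (dt <= 0 || duration <= 0 || step_every < dt) {
    abort("need `duration` > 0, `dt` > 0 and `step_every` >= `dt`.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration / dt)
  n_inc <- ceiling(duration / step_every)
  per <- round(step_every / dt)
  increments <- sample_von_mises(n_inc - 1, mu, kappa)
  levels <- wrap_angle(start_deg + cumsum(c(0, increments)))
  goal <- rep(levels, each = per)[seq_len(n)]
  protocol_tibble(
    goal, dt, "random_walk",
    list(
      duration = duration, kappa = kappa, mu = mu, seed = seed,
      step_every = step_every, start_deg = start_deg
    )
  )
}

#' Smooth-turn goal protocol
#'
#' The goal ramps linearly from 0 to 360 degrees over the first half of the
#' protocol and back to 0 over the second half.  With the default 80 s
#' duration the ramp rate is 9 deg/s, well below the 50-60 deg/s steering
#' rate circuits are tuned to.
#'
#' @param duration Total duration in seconds.
#' @param dt Simulation timestep in seconds.
#' @return A tibble with columns `t` and `goal_deg`.
#' @export
smooth_turn_goal <- function(duration = 80, dt = 0.01) {
  if (dt <= 0 || duration <= 0) {
    abort("need `duration` > 0 and `dt` > 0.")
  }
  n <- round(duration / dt)
  half <- floor(n / 2)
  ramp <- c(
    seq(0, 360, length.out = half),
    seq(360, 0, length.out = n - half)
  )
  protocol_tibble(ramp, dt, "smooth_turn", list(duration = duration))
}

#' Step-change goal protocol
#'
#' Piecewise-constant goal alternating between 0 and `step_deg` degrees,
#' holding each level for `hold` seconds.
#'
#' @param step_deg Step size: 30, 60 or 90 degrees.
#' @param dt Simulation timestep in seconds.
#' @param hold Seconds per level.
#' @param n_cycles Number of 0/`step_deg` cycles.
#' @return A tibble with columns `t` and `goal_deg`.
#' @export
step_change_goal <- function(step_deg = 30, dt = 0.01, hold = 5,
                             n_cycles = 3) {
  if (!step_deg %in% c(30, 60, 90)) {
    abort("`step_deg` must be 30, 60 or 90.")
  }
  if (dt <= 0 || hold <= 0 || n_cycles < 1) {
    abort("need `dt` > 0, `hold` > 0 and `n_cycles` >= 1.")
  }
  goal <- rep(rep(c(0, step_deg), n_cycles), each = round(hold / dt))
  protocol_tibble(
    goal, dt, "step_change",
    list(step_deg = step_deg, hold = hold, n_cycles = n_cycles)
  )
}
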