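test_that("von Mises sampler matches the Bessel-function oracle", {
  set.seed(101)
  kappa <- 10.3
  x <- sample_von_mises(2e4, mu = 40, kappa = kappa)
  z <- mean(exp(1i * pi * x / 180))
  mean_dir <- wrap_angle(180 * Arg(z) / pi)
  expect_equal(mean_dir, 40, tolerance = 1.5)
  # circular sd from the mean resultant length vs the analytic value
  sd_emp <- sqrt(-2 * log(Mod(z)))
  r_theory <- besselI(kappa, 1) / besselI(kappa, 0)
  sd_theory <- sqrt(-2 * log(r_theory))
  expect_equal(sd_emp, sd_theory, tolerance = 0.02)
  expect_true(all(x >= 40 - 180 & x < 40 + 180))
})

test_that("von Mises sampler handles edge cases", {
  set.seed(7)
  u <- sample_von_mises(5e3, 0, 0) # uniform
  expect_gt(sqrt(-2 * log(max(Mod(mean(exp(1i * pi * u / 180))), 1e-12))), 2)
  expect_equal(sample_von_mises(0, 0, 5), numeric(0))
  expect_error(sample_von_mises(10, 0, -1), "non-negative")
})

test_that("goal protocols have the declared shape and timing", {
  rw <- random_walk_goal(duration = 10, dt = 0.01, seed = 3)
  expect_equal(nrow(rw), 1000)
  expect_equal(attr(rw, "dt"), 0.01)
  expect_true(all(rw$goal_deg >= 0 & rw$goal_deg < 360))
  # goal level changes only at 0.1 s boundaries
  ch <- which(diff(rw$goal_deg) != 0)
  expect_true(all(ch %% 10 == 0))
  # seeded reproducibility
  rw2 <- random_walk_goal(duration = 10, dt = 0.01, seed = 3)
  expect_identical(rw$goal_deg, rw2$goal_deg)

  st <- smooth_turn_goal(duration = 80, dt = 0.01)
  expect_equal(nrow(st), 8000)
  expect_equal(max(st$goal_deg), 360, tolerance = 0.1)
  expect_equal(st$goal_deg[1], 0)
  # ramp rate ~9 deg/s
  expect_equal(
    abs(diff(st$goal_deg[2:100])) / 0.01,
    rep(9, 98),
    tolerance = 0.02
  )

  sc <- step_change_goal(step_deg = 60, hold = 2, n_cycles = 2)
  expect_equal(nrow(sc), 800)
  expect_equal(sort(unique(sc$goal_deg)), c(0, 60))
  expect_error(step_change_goal(step_deg = 45), "30, 60 or 90")
})

test_that("run_closed_loop integrates and tracks deterministically", {
  u <- tune_gain(build_uniform(3))
  traj <- run_closed_loop(u, step_change_goal(90, hold = 5, n_cycles = 1))
  expect_s3_class(traj, "steering_trajectory")
  expect_equal(names(traj), c("t", "goal_deg", "heading_deg", "command_deg_per_s"))
  # settles on both levels of the step (final approach is an asymptotic
  # crawl, so allow a few degrees after 5 s per level)
  expect_lt(abs(wrap_diff(traj$heading_deg[500], 0)), 1)
  expect_lt(abs(wrap_diff(traj$heading_deg[1000], 90)), 5)
  traj2 <- run_closed_loop(u, step_change_goal(90, hold = 5, n_cycles = 1))
  expect_identical(traj$heading_deg, traj2$heading_deg)
  # numeric goal vectors are accepted
  traj3 <- run_closed_loop(u, rep(45, 100), dt = 0.01, init_heading_deg = 45)
  expect_equal(nrow(traj3), 100)
  expect_error(run_closed_loop(u, numeric(0)), "at least one")
  expect_error(run_closed_loop(u, rep(0, 10), dt = -1), "positive")
})

test_that("tune_gain lands the peak turn rate in band, preserving sign", {
  for (builder in list(build_uniform(3), build_uniform(8), build_fly())) {
    tuned_spec <- tune_gain(builder)
    probe <- run_closed_loop(
      tuned_spec, rep(90, 400),
      dt = 0.01, init_heading_deg = 0
    )
    peak <- max(abs(probe$command_deg_per_s))
    expect_gte(peak, 50)
    expect_lte(peak, 60)
    expect_equal(sign(tuned_spec$k), sign(builder$k))
  }
  un <- build_unintuitive(c(seq(0.2, 1.7, length.out = 18), 0.5))
  expect_lt(tune_gain(un)$k, 0)
  expect_error(tune_gain(build_uniform(3), rate_band = c(60, 50)), "increasing")
})

test_that("detect_stable_headings separates dwell modes from sweeps", {
  # constant heading: one plateau exactly at the constant
  const <- tibble::tibble(heading_deg = rep(100, 1000))
  r <- detect_stable_headings(const)
  expect_equal(nrow(r), 1)
  expect_equal(r$plateau_deg, 100, tolerance = 1e-9)
  expect_equal(r$dwell_fraction, 1)
  # uniform sweep: no plateau
  sweep <- tibble::tibble(heading_deg = seq(0, 359.9, length.out = 3600))
  expect_equal(nrow(detect_stable_headings(sweep)), 0)
  # two modes with noise
  set.seed(5)
  two <- tibble::tibble(heading_deg = wrap_angle(c(
    rnorm(500, 60, 2), rnorm(500, 240, 2), runif(200, 0, 360)
  )))
  r2 <- detect_stable_headings(two)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$plateau_deg, c(60, 240), tolerance = 3)
  expect_error(detect_stable_headings(const, bin_width = 7), "divide 360")
})

test_that("goal_equilibrium settles at the commanded direction", {
  u <- tune_gain(build_uniform(3))
  eq <- goal_equilibrium(u, goal_deg = 120)
  expect_equal(nrow(eq), 5)
  expect_true(all(eq$abs_err_deg < 1))
  expect_true(all(abs(eq$final_command_deg_per_s) < 0.5))
  # one-hot activation of goal neuron 2 settles at its inferred direction
  eq2 <- goal_equilibrium(u, goal_neuron = 2)
  expect_true(all(eq2$abs_err_deg < 1))
  expect_error(goal_equilibrium(u, goal_neuron = 7), "out of range")
  expect_error(goal_equilibrium(u), "supply")
})

test_that("trajectory glance and autoplot summarise a run", {
  u <- tune_gain(build_uniform(3))
  traj <- run_closed_loop(u, rep(30, 500), dt = 0.01, init_heading_deg = 0)
  gl <- generics::glance(traj)
  expect_equal(gl$n, 500)
  expect_lt(gl$final_abs_err_deg, 3)
  expect_lte(gl$peak_rate_deg_per_s, 60)
  expect_s3_class(ggplot2::autoplot(traj), "ggplot")
})
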