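test_that("compass_rates and goal_rates follow the cosine-sigmoid form", {
  u <- build_uniform(3)
  rc <- compass_rates(90, u)
  expect_equal(rc, sigmoid_rate(cos(pi * (90 - c(0, 120, 240)) / 180)))
  expect_true(all(rc > 0 & rc < 1))
  # rate is maximal for the neuron whose preferred direction matches
  expect_equal(which.max(compass_rates(120, u)), 2)
  rg <- goal_rates(60, u)
  expect_equal(rg, sigmoid_rate(cos(pi * (60 - c(60, 180, 300)) / 180)))
  expect_equal(which.max(rg), 1)
})

test_that("rate helpers reject the fly flavor with informative errors", {
  fl <- build_fly()
  expect_error(compass_rates(0, fl), "sigmoid-rate")
  expect_error(goal_rates(0, fl), "sigmoid-rate")
  expect_error(
    steering_command(0, 0, fl, goal_rate_override = rep(1, 12)),
    "not available"
  )
})

test_that("steering_command matches a hand-computed forward pass", {
  u <- build_uniform(3, d = 0.2, k = 1)
  h <- 25
  g <- 200
  rc <- sigmoid_rate(cos(pi * (h - c(0, 120, 240)) / 180))
  rg <- sigmoid_rate(cos(pi * (g - c(60, 180, 300)) / 180))
  r_l <- sigmoid_rate(0.2 * rc + rg)
  r_r <- sigmoid_rate(0.2 * rc[c(2, 3, 1)] + rg)
  manual <- 1 * (0.5 * sum(r_l) - 0.5 * sum(r_r))
  got <- steering_command(h, g, u)
  expect_equal(got$command, manual, tolerance = 1e-12)
  expect_equal(got$rates$steer_l, r_l, tolerance = 1e-12)
  expect_equal(got$rates$steer_r, r_r, tolerance = 1e-12)
})

test_that("steering_command drives the heading toward the goal", {
  u <- build_uniform(3)
  expect_gt(steering_command(0, 60, u)$command, 0) # goal CCW -> turn CCW
  expect_lt(steering_command(120, 60, u)$command, 0) # goal CW -> turn CW
  fl <- build_fly()
  expect_gt(steering_command(-10, 0, fl)$command, 0)
  expect_lt(steering_command(10, 0, fl)$command, 0)
})

test_that("one-hot goal_rate_override replaces the goal population", {
  u <- build_uniform(3)
  got <- steering_command(10, 999, u, goal_rate_override = c(1, 0, 0))
  expect_equal(got$rates$goal, c(1, 0, 0))
  # with neuron 1 clamped the command is independent of the goal angle
  got2 <- steering_command(10, 123, u, goal_rate_override = c(1, 0, 0))
  expect_equal(got$command, got2$command)
  expect_error(
    steering_command(0, 0, u, goal_rate_override = c(1, 0)),
    "one rate per goal neuron"
  )
})

test_that("fly_steering agrees with steering_command on the fly circuit", {
  fl <- build_fly()
  for (hg in list(c(30, 30), c(-10, 0), c(200, 45), c(0, 180))) {
    expect_equal(
      fly_steering(hg[1], hg[2]),
      steering_command(hg[1], hg[2], fl)$command,
      tolerance = 1e-12
    )
  }
  # near-zero command when heading is at the goal (small residual from the
  # discrete tuning lattice), tiny relative to the peak command
  peak <- max(abs(vapply(
    seq(0, 350, by = 10),
    function(h) fly_steering(h, 30), numeric(1)
  )))
  expect_lt(abs(fly_steering(30, 30)), 0.01 * peak)
})
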