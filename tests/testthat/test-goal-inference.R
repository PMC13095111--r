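# Minimal two-compass circuit with one steering neuron per side and one goal
# neuron, used to exercise the directed-midpoint construction directly.
two_vector_spec <- function(left_dir, right_dir, balance = 0.5) {
  circuit_spec(
    compass_pfds = wrap_angle(c(left_dir, right_dir)),
    w_cs_l = matrix(c(1, 0), 1, 2),
    w_cs_r = matrix(c(0, 1), 1, 2),
    w_gs_l = matrix(1, 1, 1),
    w_gs_r = matrix(1, 1, 1),
    k = 1,
    balance = balance,
    builder = "test"
  )
}

test_that("inference reproduces the worked directed-midpoint examples", {
  # components at 0 and +90: counter-clockwise separation, midpoint at 45
  expect_equal(
    infer_goal_directions(two_vector_spec(0, 90))$eta_deg, 45,
    tolerance = 1e-9
  )
  # components at 0 and -90: clockwise separation, outer midpoint at 135
  expect_equal(
    infer_goal_directions(two_vector_spec(0, -90))$eta_deg, 135,
    tolerance = 1e-9
  )
  # balance weights the midpoint toward the more influential side
  expect_equal(
    infer_goal_directions(two_vector_spec(0, 90, balance = 0.25))$eta_deg,
    22.5,
    tolerance = 1e-9
  )
})

test_that("inference matches the closed form on uniform circuits", {
  for (n in c(3, 5, 8, 21)) {
    u <- build_uniform(n)
    gi <- infer_goal_directions(u)
    closed_form <- wrap_angle(u$compass_pfds + 180 / n)
    expect_equal(gi$eta_deg, closed_form, tolerance = 1e-9)
  }
})

test_that("fly inferred directions sit near their declared labels", {
  fl <- build_fly()
  gi <- infer_goal_directions(fl)
  expect_equal(nrow(gi), 12)
  diffs <- abs(wrap_diff(gi$eta_deg, fl$goal_dirs))
  expect_true(all(diffs <= 15 + 1e-9))
})

test_that("inference reports its intermediate geometry", {
  gi <- infer_goal_directions(two_vector_spec(0, 90))
  expect_equal(gi$gl_deg, 0, tolerance = 1e-9)
  expect_equal(gi$gr_deg, 90, tolerance = 1e-9)
  expect_equal(gi$signed_angle_deg, 90, tolerance = 1e-9)
  expect_equal(gi$u, 0, tolerance = 1e-9)
  expect_equal(gi$v, 1, tolerance = 1e-9)
})

test_that("degenerate wiring is rejected with informative errors", {
  bad <- build_uniform(3)
  bad$w_gs_l[, 2] <- 0 # goal neuron 2 loses its left innervation
  expect_error(infer_goal_directions(bad), "goal neuron")
  # steering neuron whose compass inputs cancel exactly
  s <- circuit_spec(
    compass_pfds = c(0, 120, 180),
    w_cs_l = matrix(c(1, 0, 1, 0, 1, 0), 2, 3, byrow = TRUE),
    w_cs_r = matrix(c(0, 1, 0), 1, 3),
    w_gs_l = matrix(1, 2, 1),
    w_gs_r = matrix(1, 1, 1),
    k = 1, balance = 0.5, builder = "test"
  )
  expect_error(infer_goal_directions(s), "zero-norm")
})

test_that("set_inferred_goal_dirs stamps the inferred source", {
  u <- build_uniform(5)
  u$goal_dirs <- NULL
  u$goal_dirs_source <- NULL
  u2 <- set_inferred_goal_dirs(u)
  expect_equal(u2$goal_dirs, infer_goal_directions(u)$eta_deg)
  expect_equal(u2$goal_dirs_source, "inferred")
})

test_that("steering_directions returns the weighted compass sums", {
  u <- build_uniform(3)
  d <- steering_directions(u)
  expect_equal(d$direction_deg[d$side == "L"], c(0, 120, 240))
  expect_equal(d$direction_deg[d$side == "R"], c(120, 240, 0))
  # a two-compass blend lands between the two directions
  s <- two_vector_spec(0, 90)
  s$w_cs_l <- matrix(c(1, 1), 1, 2)
  expect_equal(
    steering_directions(s)$direction_deg[1], 45,
    tolerance = 1e-9
  )
})
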