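test_that("build_uniform lays out compass, wiring and goal directions", {
  u <- build_uniform(3)
  expect_equal(u$compass_pfds, c(0, 120, 240))
  expect_equal(u$w_cs_l, 0.2 * diag(3))
  # right steering neuron i samples compass neuron i + 1
  expect_equal(u$w_cs_r[1, ], c(0, 0.2, 0))
  expect_equal(u$w_cs_r[3, ], c(0.2, 0, 0))
  expect_equal(u$w_gs_l, diag(3))
  expect_equal(u$goal_dirs, c(60, 180, 300), tolerance = 1e-9)
  expect_equal(u$goal_dirs_source, "inferred")
  expect_equal(n_steering(u), 6)
  u8 <- build_uniform(8)
  expect_equal(n_compass(u8), 8)
  expect_true(is_positive_basis(u8$compass_pfds)$is_positive_basis)
  expect_error(build_uniform(2), "positive basis")
  expect_error(build_uniform(3, d = -1), "positive")
})

test_that("build_fly embeds the published population structure", {
  fl <- build_fly()
  expect_equal(fl$flavor, "fly-softplus")
  expect_equal(length(fl$fly$fc2_dirs), 12)
  expect_equal(length(fl$fly$pfl3_left_dirs), 12)
  expect_equal(length(fl$fly$pfl3_right_dirs), 12)
  # FC2 goal tunings are 30 degrees apart
  fc2 <- sort(wrap_angle(fl$fly$fc2_dirs))
  expect_equal(diff(fc2), rep(30, 11), tolerance = 1e-9)
  # eight distinct steering tunings, 45 degrees apart
  pl <- sort(unique(wrap_angle(fl$fly$pfl3_left_dirs)))
  expect_equal(length(pl), 8)
  expect_equal(diff(pl), rep(45, 7), tolerance = 1e-9)
  expect_equal(sort(unique(wrap_angle(fl$fly$pfl3_right_dirs))), pl)
  expect_equal(fl$k, 2 * fl$fly$output_gain)
  expect_equal(n_steering(fl), 24)
  # selector wiring routes each steering neuron to its tuning
  dirs <- steering_directions(fl)
  expect_equal(
    sort(wrap_angle(dirs$direction_deg[dirs$side == "L"])),
    sort(wrap_angle(fl$fly$pfl3_left_dirs)),
    tolerance = 1e-9
  )
})

test_that("build_unintuitive enforces the template and bounds", {
  b <- unintuitive_bounds()
  expect_equal(b$lower, rep(0, 19))
  expect_equal(b$upper, c(rep(2, 18), 1))
  x <- c(seq(0.1, 1.8, length.out = 18), 0.4)
  s <- build_unintuitive(x)
  expect_equal(s$compass_pfds, c(350, 10, 90, 200))
  expect_equal(dim(s$w_cs_l), c(2, 4))
  expect_equal(dim(s$w_cs_r), c(3, 4))
  expect_equal(dim(s$w_gs_l), c(2, 3))
  expect_equal(dim(s$w_gs_r), c(3, 3))
  expect_equal(n_steering(s), 5)
  expect_equal(s$balance, 0.4)
  expect_lt(s$k, 0) # printed orientation needs a negative gain
  # free parameters land in their template slots
  expect_equal(s$w_cs_l[1, 1], x[1])
  expect_equal(s$w_cs_l[2, 3], x[3])
  expect_equal(s$w_cs_r[3, 4], x[10])
  expect_equal(s$w_gs_l[2, 3], x[14])
  expect_equal(s$w_gs_r[3, 3], x[18])
  # masked entries stay zero
  expect_equal(s$w_cs_l[1, 2], 0)
  expect_equal(s$w_gs_r[1, 2], 0)
  expect_error(build_unintuitive(rep(3, 19)), "out of bounds")
  expect_error(build_unintuitive(rep(0.5, 18)), "length 19")
})

test_that("rule breakers violate exactly the intended rules", {
  p1 <- rule_check(build_rule_breaker("rule1"))$passes
  expect_equal(p1, c(rule1 = FALSE, rule4 = TRUE, rule5 = TRUE))
  p4 <- rule_check(build_rule_breaker("rule4"))$passes
  expect_equal(p4, c(rule1 = TRUE, rule4 = FALSE, rule5 = TRUE))
  p5 <- rule_check(build_rule_breaker("rule5"))$passes
  expect_equal(p5, c(rule1 = TRUE, rule4 = TRUE, rule5 = FALSE))
  p15 <- rule_check(build_rule_breaker("rule1and5"))$passes
  expect_equal(p15, c(rule1 = FALSE, rule4 = TRUE, rule5 = FALSE))
  expect_error(build_rule_breaker("rule9"))
})
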