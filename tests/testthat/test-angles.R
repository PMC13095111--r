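test_that("wrap_angle maps to [0, 360) and preserves congruence", {
  expect_equal(wrap_angle(0), 0)
  expect_equal(wrap_angle(360), 0)
  expect_equal(wrap_angle(-90), 270)
  expect_equal(wrap_angle(725), 5)
  a <- c(-1000, -360.5, 0, 359.999, 1234.5)
  w <- wrap_angle(a)
  expect_true(all(w >= 0 & w < 360))
  expect_equal(sin(pi * w / 180), sin(pi * a / 180), tolerance = 1e-12)
  expect_error(wrap_angle(NA_real_), "finite")
  expect_error(wrap_angle(Inf), "finite")
})

test_that("wrap_diff is the signed shortest rotation in [-180, 180)", {
  expect_equal(wrap_diff(350, 10), -20)
  expect_equal(wrap_diff(10, 350), 20)
  expect_equal(wrap_diff(180), -180) # half-open: 180 maps to -180
  expect_equal(wrap_diff(90, 90), 0)
  a <- runif(50, -720, 720)
  b <- runif(50, -720, 720)
  d <- wrap_diff(a, b)
  expect_true(all(d >= -180 & d < 180))
  # adding the wrapped difference back recovers the first angle
  expect_equal(wrap_angle(b + d), wrap_angle(a), tolerance = 1e-9)
})

test_that("signed_angle follows the counter-clockwise-positive convention", {
  expect_equal(signed_angle(0, 90), 90)
  expect_equal(signed_angle(0, 270), -90)
  expect_equal(signed_angle(45, 45), 0)
  expect_equal(abs(signed_angle(0, 180)), 180)
  # agrees with wrap_diff away from the 180 branch point
  u <- runif(50, 0, 360)
  v <- u + runif(50, -179, 179)
  expect_equal(signed_angle(u, v), wrap_diff(v, u), tolerance = 1e-9)
})

test_that("angular_rmse wraps differences before squaring", {
  expect_equal(angular_rmse(c(0, 10), c(0, 10)), 0)
  expect_equal(angular_rmse(c(0, 90), c(180, 270)), 180)
  expect_equal(angular_rmse(359, 1), 2)
  expect_equal(angular_rmse(c(0, 0), c(10, -10)), 10)
  expect_error(angular_rmse(1:3, 1:2), "equal length")
  expect_error(angular_rmse(numeric(0), numeric(0)), "at least one")
})

test_that("pva_decode recovers directions from population activity", {
  expect_equal(pva_decode(c(1, 1, 0), c(0, 120, 240)), 60)
  expect_equal(pva_decode(c(0, 1, 0), c(0, 120, 240)), 120)
  # cosine-tuned population decodes the encoded angle
  dirs <- seq(0, 330, by = 30)
  rates <- 1 + cos(pi * (dirs - 77) / 180)
  expect_equal(pva_decode(rates, dirs), 77, tolerance = 1e-9)
  expect_error(pva_decode(c(0, 0), c(0, 90)), "zero")
  expect_error(pva_decode(c(1, 1), c(0, 180)), "zero norm")
  expect_error(pva_decode(c(-1, 2), c(0, 90)), "non-negative")
})

test_that("is_positive_basis classifies the canonical example sets", {
  expect_true(is_positive_basis(c(0, 120, 240))$is_positive_basis)
  expect_true(is_positive_basis(c(350, 10, 90, 200))$is_positive_basis)
  expect_false(is_positive_basis(c(0, 60, 120))$is_positive_basis)
})

test_that("is_positive_basis applies the strict 180-degree boundary", {
  # one gap of exactly 180 degrees: NOT a positive basis
  r <- is_positive_basis(c(0, 90, 180))
  expect_false(r$is_positive_basis)
  expect_equal(max(r$adjacent_gaps), 180)
  # nudging the middle vector across the diameter makes it one
  expect_true(is_positive_basis(c(0, 90, 180.001))$is_positive_basis)
})

test_that("is_positive_basis handles duplicates and degenerate input", {
  r <- is_positive_basis(c(0, 0, 120, 240))
  expect_true(r$is_positive_basis)
  expect_equal(length(r$directions), 3)
  expect_equal(r$multiplicity, c(2, 1, 1), ignore_attr = TRUE)
  d <- is_positive_basis(c(45, 45, 45))
  expect_true(d$degenerate)
  expect_false(d$is_positive_basis)
  # two distinct directions can never span the plane positively
  expect_false(is_positive_basis(c(0, 180))$is_positive_basis)
  expect_error(is_positive_basis(90), "at least 2")
})

test_that("positive-basis report tidies into one row per direction", {
  r <- is_positive_basis(c(10, 130, 250))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$gap_to_next_deg), 360)
})
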