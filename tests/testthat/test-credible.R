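test_that("credible bands are central quantile intervals", {
  set.seed(4)
  draws <- matrix(rnorm(200000), ncol = 4)  # 4 "time points"
  b <- credible_band(draws, level = 0.95)
  expect_true(all(abs(b$lower + 1.96) < 0.05))
  expect_true(all(abs(b$upper - 1.96) < 0.05))
  const <- matrix(2.5, nrow = 100, ncol = 3)
  bc <- credible_band(const, level = 0.9)
  expect_equal(bc$lower, bc$upper)
  expect_equal(unname(bc$lower), rep(2.5, 3))
  expect_error(credible_band(draws, level = 1.2), "level")
  expect_error(credible_band(draws, level = 0), "level")
})

test_that("narrower bands nest inside wider ones from the same draws", {
  set.seed(5)
  draws <- matrix(rt(5000, df = 3), ncol = 5)
  b50 <- credible_band(draws, level = 0.5)
  b95 <- credible_band(draws, level = 0.95)
  expect_true(all(b50$lower >= b95$lower))
  expect_true(all(b50$upper <= b95$upper))
})

test_that("condition comparison follows the closed-interval overlap rule", {
  mk <- function(lo, hi) {
    structure(list(level = 0.95, t = 1L, lower = lo, upper = hi,
                   mean = (lo + hi) / 2, component = "load",
                   condition = NA), class = "credible_band")
  }
  expect_equal(compare_conditions(mk(0, 1), mk(2, 3), at = 1), "separated")
  expect_equal(compare_conditions(mk(0, 2), mk(1, 3), at = 1), "overlapping")
  # touching endpoints count as overlap
  expect_equal(compare_conditions(mk(0, 1), mk(1, 2), at = 1), "overlapping")
  # symmetry
  expect_equal(compare_conditions(mk(2, 3), mk(0, 1), at = 1), "separated")
  b2 <- mk(0, 1); b2$level <- 0.5
  expect_error(compare_conditions(mk(0, 1), b2, at = 1), "levels")
  expect_error(compare_conditions(mk(0, 1), mk(0, 1), at = 9), "range")
})

test_that("fit-based bands expose components per condition", {
  truth <- quick_truth(seed = 21)
  fit <- quick_fit(truth$y, seed = 3)
  b <- credible_band(fit, "load", "c", level = 0.5)
  expect_s3_class(b, "credible_band")
  expect_length(b$lower, 23)
  expect_true(all(b$lower <= b$upper))
  expect_equal(b$condition, "T_26-36")
  expect_error(credible_band(fit, "load", "T_26-26"), "control")
  df <- as.data.frame(b)
  expect_named(df, c("component", "condition", "t", "mean", "lower",
                     "upper", "level"))
})
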