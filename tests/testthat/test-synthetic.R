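test_that("scenarios realise their defining Load orderings", {
  g <- hf_grid()
  TT <- nrow(g$points)
  tn <- generate_dataset("null", g, seed = 1)
  expect_equal(max(abs(tn$states$load)), 0)
  expect_equal(max(abs(tn$states$env)), 0)
  ts <- generate_dataset("step_load", g, seed = 1)
  lT <- ts$states$load[TT, ]
  expect_lt(lT[[1]], lT[[2]])
  expect_lte(lT[[2]], lT[[3]])
  expect_gt(max(abs(ts$states$env)), 0)
  tc <- generate_dataset("cooling", g, seed = 1)
  lc <- tc$states$load[TT, ]
  expect_lt(lc[[3]], lc[[2]])
  expect_error(generate_dataset("boom", g, seed = 1), "arg")
})

test_that("datasets and fixtures are byte-identical under a fixed seed", {
  g <- hf_grid()
  t1 <- generate_dataset("step_load", g, seed = 12)
  t2 <- generate_dataset("step_load", g, seed = 12)
  expect_identical(t1$y$y, t2$y$y)
  expect_identical(t1$states, t2$states)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  fx1 <- generate_raw_fixtures(t1, seed = 3)
  fx2 <- generate_raw_fixtures(t2, seed = 3)
  f1 <- write_fixtures(fx1, d1); f2 <- write_fixtures(fx2, d2)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
})

test_that("the truth sidecar stores everything needed to regenerate", {
  g <- hf_grid()
  tr <- generate_dataset("cooling", g, seed = 9)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth(tr, f)
  obj <- yaml::read_yaml(f)
  expect_equal(obj$scenario, "cooling")
  expect_equal(obj$seed, 9)
  expect_equal(obj$params$h, tr$params$h)
  expect_equal(unlist(obj$states$base), tr$states$base, tolerance = 1e-9)
  expect_equal(matrix(unlist(obj$y), ncol = 4), unname(tr$y$y),
               tolerance = 1e-9)
})

test_that("skin fixtures reproduce a constant truth within 0.01 degC", {
  gs <- build_grid(default_protocol(), "skin")
  p <- hyperparams(sigma_obs = 0, sigma_base = 0, sigma_load = 0,
                   sigma_env = 0, h = 0.8, period = 8)
  tr <- generate_dataset("null", gs, params = p, seed = 2,
                         base_start = 33, base_slope = 0)
  expect_equal(max(abs(tr$y$y - 33)), 0)
  fx <- generate_raw_fixtures(tr, seed = 4)
  pp <- preprocess_fixtures(fx)
  expect_lt(max(abs(pp$y - 33)), 0.01)
})

test_that("raw fixtures preprocess and fit to the generated Load ordering", {
  g <- hf_grid()
  tr <- generate_dataset("step_load", g, seed = 77)
  fx <- generate_raw_fixtures(tr, seed = 78)
  pp <- preprocess_fixtures(fx)
  fit <- quick_fit(pp, seed = 79, warmup = 250, sampling = 250)
  bb <- credible_band(fit, "load", "b", level = 0.5)
  bc <- credible_band(fit, "load", "c", level = 0.5)
  TT <- nrow(g$points)
  expect_equal(compare_conditions(bb, bc, at = TT), "separated")
  expect_gt(bc$lower[TT], bb$upper[TT])  # larger step carries more Load
})

test_that("an HF-only RRI fixture yields strongly negative log LF/HF", {
  r <- synth_rri(0, 300, mean_rri = 1000, lf_power = 1e-8, hf_power = 900)
  f <- hrv_features(r)
  expect_lt(f$log_lf_hf, -2)
})

test_that("HRV fixtures reproduce the truth series through preprocessing", {
  g <- hf_grid()
  tr <- generate_dataset("step_load", g, seed = 6)
  fx <- generate_raw_fixtures(tr, seed = 7)
  pp <- preprocess_fixtures(fx)
  err <- abs(pp$y - tr$y$y)
  expect_lt(mean(err), 0.1)
  expect_lt(max(err), 1)
  expect_lt(stats::quantile(err, 0.9), 0.3)
})
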