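test_that("R-hat is near 1 for independent chains and flags split chains", {
  set.seed(1)
  iid <- matrix(rnorm(8000), nrow = 2000, ncol = 4)
  expect_lt(abs(rhat(iid) - 1), 0.01)
  shifted <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(rhat(shifted), 1.1)
  # within-chain drift is caught by splitting
  drift <- matrix(rep(1:1000, 2) + rnorm(2000, 0, 0.1), ncol = 2)
  expect_gt(rhat(drift), 1.1)
})

test_that("ESS matches closed-form expectations for iid and AR(1) draws", {
  set.seed(2)
  iid <- matrix(rnorm(8000), nrow = 2000, ncol = 4)
  expect_lt(abs(ess_bulk(iid) - 8000) / 8000, 0.15)
  rho <- 0.9
  ar <- vapply(1:4, function(j)
    as.numeric(arima.sim(list(ar = rho), n = 2000)), numeric(2000))
  e <- ess_bulk(ar)
  expect_lt(e, 0.2 * 8000)
  # closed form n (1-rho)/(1+rho) ~ 421; allow a broad stochastic factor
  expect_gt(e, 100); expect_lt(e, 1600)
})

test_that("degenerate draws are flagged rather than scored", {
  const <- matrix(5, nrow = 100, ncol = 4)
  expect_true(is.nan(rhat(const)))
  expect_true(is.nan(ess_bulk(const)))
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(ess_bulk(matrix(rnorm(100), ncol = 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(4), nrow = 2)), "4 draws")
})

test_that("diagnostics() tabulates every sampled hyperparameter", {
  truth <- quick_truth(seed = 8)
  fit <- quick_fit(truth$y, seed = 2)
  d <- diagnostics(fit)
  expect_setequal(d$parameter, fit$par_names)
  expect_true(all(is.finite(d$rhat)))
  expect_true(all(d$ess > 0))
  expect_type(d$ok, "logical")
})
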