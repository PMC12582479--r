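test_that("fitting returns a complete, reproducible posterior object", {
  truth <- quick_truth(seed = 1)
  fit <- quick_fit(truth$y, seed = 5)
  expect_s3_class(fit, "thermoload")
  expect_equal(dim(fit$draws$hyper), c(150, 2, 8))
  expect_equal(dim(fit$draws$states), c(150, 2, 7 * 23))
  expect_true(all(is.finite(fit$draws$hyper)))
  expect_named(coef(fit), fit$par_names)
  expect_output(print(fit), "decomposition")
  # determinism under the seed
  fit2 <- quick_fit(truth$y, seed = 5)
  expect_identical(fit$draws, fit2$draws)
  fit3 <- quick_fit(truth$y, seed = 6)
  expect_false(identical(fit$draws$hyper, fit3$draws$hyper))
})

test_that("fitted values, residuals and predictions are coherent", {
  truth <- quick_truth(seed = 2)
  fit <- quick_fit(truth$y, seed = 7)
  fv <- fitted(fit)
  expect_equal(dim(fv), c(23, 4))
  expect_equal(colnames(fv), CONDITIONS)
  expect_equal(residuals(fit), truth$y$y - fv)
  pr <- predict(fit, level = 0.9)
  expect_true(all(pr$lower <= pr$mean & pr$mean <= pr$upper))
  # response intervals include observation noise, hence are wider
  prr <- predict(fit, type = "response", level = 0.9)
  expect_gt(mean(prr$upper - prr$lower), mean(pr$upper - pr$lower))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_s3_class(sims[[1]], "measurement_series")
  expect_identical(simulate(fit, nsim = 2, seed = 9)[[1]]$y,
                   simulate(fit, nsim = 2, seed = 9)[[1]]$y)
})

test_that("missing observations are imputed as latent quantities", {
  truth <- quick_truth(seed = 3)
  yv <- truth$y$y
  yv[1, 2] <- NA  # first time point of a step condition
  ym <- measurement_series(yv, period = 6)
  fit <- quick_fit(ym, seed = 8)
  expect_false(is.null(fit$missing_draws))
  expect_equal(colnames(fit$missing_draws), "y_mis[T_26-31,1]")
  est <- mean(fit$missing_draws)
  expect_lt(abs(est - truth$y$y[1, 2]), 1)
  expect_true(all(is.finite(fit$draws$hyper)))
})

test_that("posterior Base tracks the control series when noise is small", {
  g <- hf_grid()
  p <- hyperparams(sigma_obs = 0.02, sigma_base = 0.05, sigma_load = 0.002,
                   sigma_env = 0.02, h = 0.8, period = 6)
  truth <- generate_dataset("null", g, params = p, seed = 17)
  fit <- quick_fit(truth$y, seed = 9, warmup = 200, sampling = 200)
  base_mean <- colMeans(thermoload:::component_draws(fit, "base", "T_26-26"))
  base_sd <- apply(thermoload:::component_draws(fit, "base", "T_26-26"), 2, sd)
  expect_true(all(abs(base_mean - truth$y$y[, 1]) < 2 * base_sd + 0.05))
})

test_that("Base inference is unaffected by Load-free step-condition data", {
  g <- hf_grid()
  truth <- generate_dataset("null", g, seed = 31)
  yv_only <- truth$y$y; yv_only[, 2:4] <- NA   # control data alone
  yv_b <- truth$y$y; yv_b[, 3:4] <- NA         # control + one null condition
  f1 <- quick_fit(measurement_series(yv_only, period = 6), seed = 1,
                  warmup = 200, sampling = 200)
  f2 <- quick_fit(measurement_series(yv_b, period = 6), seed = 1,
                  warmup = 200, sampling = 200)
  b1 <- colMeans(thermoload:::component_draws(f1, "base", "T_26-26"))
  b2 <- colMeans(thermoload:::component_draws(f2, "base", "T_26-26"))
  s1 <- apply(thermoload:::component_draws(f1, "base", "T_26-26"), 2, sd)
  expect_lt(max(abs(b1 - b2) / s1), 1)  # well within Monte-Carlo error
})

test_that("per-condition scale options expand the parameter vector", {
  truth <- quick_truth(seed = 4)
  fit <- quick_fit(truth$y, seed = 10, warmup = 50, sampling = 50,
                   share_load_scale = FALSE, share_env_scale = FALSE,
                   estimate_h = FALSE, h = 0.9)
  expect_true(all(paste0("sigma_load[", CONDITIONS[-1], "]") %in%
                    fit$par_names))
  expect_true(all(paste0("sigma_env[", CONDITIONS[-1], "]") %in%
                    fit$par_names))
  expect_false("h" %in% fit$par_names)
  expect_equal(fit$meta$h_fixed, 0.9)
})

test_that("input validation rejects impossible settings", {
  truth <- quick_truth(seed = 5)
  expect_error(thermoload(truth$y, period = 1), "period")
  expect_error(thermoload(truth$y, period = 99), "period")
  expect_error(thermoload("not a series"), "measurement_series")
})
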