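test_that("log_joint matches the term-by-term oracle on toy instances", {
  for (s in 1:5) {
    toy <- random_toy(TT = 5, N = 3, seed = s,
                      family = if (s %% 2) "cauchy" else "normal",
                      miss = s %% 3)
    expect_equal(log_joint(toy$y, toy$st, toy$params, toy$priors),
                 oracle_log_joint(toy$y, toy$st, toy$params, toy$priors),
                 tolerance = 1e-10)
  }
  toy6 <- random_toy(TT = 6, N = 4, seed = 99)
  expect_equal(log_joint(toy6$y, toy6$st, toy6$params, toy6$priors),
               oracle_log_joint(toy6$y, toy6$st, toy6$params, toy6$priors),
               tolerance = 1e-10)
})

test_that("masking one observation removes exactly its density term", {
  toy <- random_toy(TT = 5, N = 3, seed = 7)
  lj_full <- log_joint(toy$y, toy$st, toy$params, toy$priors)
  yv <- toy$y$y
  t0 <- 3L; j0 <- 2L
  mu <- toy$st$base[t0] + toy$st$load[t0, j0 - 1] + toy$st$env[t0, j0 - 1]
  term <- unname(dnorm(yv[t0, j0], mu, toy$params$sigma_obs[j0], log = TRUE))
  yv[t0, j0] <- NA
  ym <- measurement_series(yv, period = 3)
  lj_masked <- log_joint(ym, toy$st, toy$params, toy$priors)
  expect_equal(lj_full - lj_masked, term, tolerance = 1e-10)
})

test_that("switching the Load family changes only the Load state terms", {
  toy <- random_toy(TT = 6, N = 3, seed = 11, family = "cauchy")
  pn <- toy$params; pn$load_noise_family <- "normal"
  diff_lj <- log_joint(toy$y, toy$st, toy$params, toy$priors) -
    log_joint(toy$y, toy$st, pn, toy$priors)
  d2 <- function(v) v[3:6] - 2 * v[2:5] + v[1:4]
  expected <- 0
  for (k in 1:3) {
    r <- d2(toy$st$load[, k])
    expected <- expected + sum(dcauchy(r, 0, toy$params$sigma_load[k],
                                       log = TRUE)) -
      sum(dnorm(r, 0, toy$params$sigma_load[k], log = TRUE))
  }
  expect_equal(diff_lj, expected, tolerance = 1e-10)
})

test_that("log_joint rejects degenerate inputs", {
  toy <- random_toy(TT = 5, N = 3, seed = 2)
  bad <- toy$params; bad$sigma_base <- 0
  expect_error(log_joint(toy$y, toy$st, bad, toy$priors), "positive")
  stbad <- toy$st; stbad$base[2] <- NaN
  expect_error(log_joint(toy$y, stbad, toy$params, toy$priors), "finite")
})

test_that("noise-free simulation continues linear initialisations exactly", {
  p <- hyperparams(sigma_obs = 0, sigma_base = 0, sigma_load = 0,
                   sigma_env = 0, h = 1, period = 4)
  sim <- ssm_simulate(p, list(base = c(1, 2),
                              load = rbind(rep(0, 3), rep(0.5, 3)),
                              env_window = matrix(0, 3, 3)),
                      T = 12, seed = 1)
  expect_equal(sim$states$base, seq(1, by = 1, length.out = 12))
  expect_equal(sim$states$load[, 2], seq(0, by = 0.5, length.out = 12))
  expect_equal(max(abs(diff(sim$states$base, differences = 2))), 0)
  expect_equal(sim$y$y[, 1], sim$states$base)
})

test_that("undamped noiseless Env keeps every period window at zero sum", {
  p <- hyperparams(sigma_obs = 0, sigma_base = 0, sigma_load = 0,
                   sigma_env = 0, h = 1, period = 4)
  ew <- matrix(c(1, -0.5, -0.5), 3, 3)  # zero-sum once Env_4 is appended
  sim <- ssm_simulate(p, list(base = c(0, 0), load = matrix(0, 2, 3),
                              env_window = ew), T = 16, seed = 1)
  for (k in 1:3) {
    e <- sim$states$env[, k]
    sums <- vapply(1:13, function(i) sum(e[i:(i + 3)]), numeric(1))
    expect_equal(max(abs(sums)), 0, tolerance = 1e-12)
  }
})

test_that("simulation is reproducible under a fixed seed", {
  p <- hyperparams(period = 4)
  init <- list(base = c(0, 0), load = matrix(0, 2, 3),
               env_window = matrix(0.1, 3, 3))
  s1 <- ssm_simulate(p, init, T = 20, seed = 33)
  s2 <- ssm_simulate(p, init, T = 20, seed = 33)
  expect_identical(s1, s2)
  expect_error(ssm_simulate(p, init, T = 1), "at least 2")
})

test_that("predicted means add the components that exist per condition", {
  set.seed(3)
  st <- state_components(rnorm(8), matrix(rnorm(24), 8), matrix(rnorm(24), 8))
  expect_equal(predicted_mean(st, "T_26-26"), st$base)
  expect_equal(predicted_mean(st, "a"), st$base)
  expect_equal(predicted_mean(st, "T_26-36"),
               st$base + st$load[, 2] + st$env[, 2])
  for (j in 2:4)
    expect_equal(predicted_mean(st, CONDITIONS[j]),
                 st$base + st$load[, j - 1] + st$env[, j - 1])
  z <- state_components(st$base, matrix(0, 8, 3), matrix(0, 8, 3))
  for (cc in CONDITIONS) expect_equal(predicted_mean(z, cc), st$base)
  expect_error(predicted_mean(st, "T_99"), "unknown condition")
})
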