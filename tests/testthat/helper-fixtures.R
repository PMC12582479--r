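# shared fixtures: small synthetic datasets and light MCMC settings used
# across the unit tests (acceptance tests set their own sizes)

hf_grid <- function() build_grid(default_protocol(), "hf")

quick_truth <- function(scenario = "step_load", seed = 42, ...) {
  generate_dataset(scenario, hf_grid(), seed = seed, ...)
}

quick_fit <- function(y, seed = 1, chains = 2, warmup = 150, sampling = 150,
                      ...) {
  thermoload(y, chains = chains, warmup = warmup, sampling = sampling,
             seed = seed, ...)
}

# ideal tachogram fixture: interval values laid on a regular 2 Hz beat
# grid, isolating the spectral estimator from beat-sampling effects
regular_tachogram <- function(duration = 300, mean_rri = 1000,
                              lf_amp = 0, hf_amp = 0, lf_freq = 0.10,
                              hf_freq = 0.30, noise_sd = 0) {
  tt <- seq(0, duration, by = 0.5)
  vals <- mean_rri + lf_amp * sin(2 * pi * lf_freq * tt) +
    hf_amp * sin(2 * pi * hf_freq * tt + 1)
  if (noise_sd > 0) vals <- vals + rnorm(length(vals), 0, noise_sd)
  rri_series(tt, vals)
}

# independent band-power oracle: raw periodogram of the evenly resampled,
# mean-removed tachogram (no AR model involved)
periodogram_band_powers <- function(rri, fs = 4) {
  tt <- seq(rri$onsets[1], rri$onsets[length(rri$onsets)], by = 1 / fs)
  x <- stats::spline(rri$onsets, rri$intervals, xout = tt)$y
  x <- x - mean(x)
  sp <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0,
                          detrend = FALSE, plot = FALSE)
  lf <- sp$freq >= 0.04 & sp$freq < 0.15
  hf <- sp$freq >= 0.15 & sp$freq <= 0.40
  c(lf = sum(sp$spec[lf]), hf = sum(sp$spec[hf]))
}

# brute-force scalar-density oracle for the joint model density
oracle_log_joint <- function(y, st, params, pr) {
  TT <- nrow(y$y); N <- params$period
  lp <- 0
  for (t in 1:TT) for (j in 1:4) {
    if (is.na(y$y[t, j])) next
    mu <- st$base[t] + if (j > 1) st$load[t, j - 1] + st$env[t, j - 1] else 0
    lp <- lp + dnorm(y$y[t, j], mu, params$sigma_obs[j], log = TRUE)
  }
  for (t in 3:TT) {
    lp <- lp + dnorm(st$base[t] - 2 * st$base[t - 1] + st$base[t - 2], 0,
                     params$sigma_base, log = TRUE)
    for (k in 1:3) {
      r <- st$load[t, k] - 2 * st$load[t - 1, k] + st$load[t - 2, k]
      lp <- lp + if (params$load_noise_family == "cauchy")
        dcauchy(r, 0, params$sigma_load[k], log = TRUE)
      else dnorm(r, 0, params$sigma_load[k], log = TRUE)
    }
  }
  for (t in N:TT) for (k in 1:3)
    lp <- lp + dnorm(st$env[t, k] + params$h * sum(st$env[(t - N + 1):(t - 1), k]),
                     0, params$sigma_env[k], log = TRUE)
  lp <- lp + sum(dnorm(st$base[1:2], pr$mu0, pr$s_init, log = TRUE)) +
    sum(dnorm(st$load[1:2, ], 0, pr$s_init, log = TRUE)) +
    sum(dnorm(st$env[1:(N - 1), ], 0, pr$s_init, log = TRUE)) +
    sum(dnorm(c(params$sigma_obs, params$sigma_base, params$sigma_load,
                params$sigma_env), 0, pr$s_sigma, log = TRUE) + log(2))
  unname(lp)
}

random_toy <- function(TT = 5, N = 3, seed = 1,
                       family = c("cauchy", "normal"), miss = 0L) {
  family <- match.arg(family)
  set.seed(seed)
  params <- hyperparams(sigma_obs = runif(4, 0.1, 0.5),
                        sigma_base = runif(1, 0.1, 1),
                        sigma_load = runif(1, 0.1, 1),
                        sigma_env = runif(1, 0.1, 1),
                        h = runif(1, 0.2, 1), period = N,
                        load_noise_family = family)
  st <- state_components(rnorm(TT), matrix(rnorm(3 * TT), TT),
                         matrix(rnorm(3 * TT), TT))
  yv <- matrix(rnorm(4 * TT, 1, 1), TT, 4, dimnames = list(NULL, CONDITIONS))
  if (miss > 0L) yv[sample.int(4 * TT, miss)] <- NA
  y <- measurement_series(yv, period = N)
  list(y = y, st = st, params = params, priors = default_priors(y))
}
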