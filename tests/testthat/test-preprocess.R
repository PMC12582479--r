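test_that("mean skin temperature reproduces the weighted sum", {
  expect_equal(mean_skin_temperature(30, 30, 30, 30), 30)
  expect_equal(mean_skin_temperature(30, 30, 40, 40), 34)
  expect_equal(mean_skin_temperature(0, 0, 0, 0), 0)
  expect_error(mean_skin_temperature(NA, 30, 30, 30), "finite")
  expect_error(skin_weights(0.5, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("mean skin temperature is monotone and shift-equivariant", {
  set.seed(1)
  for (i in 1:20) {
    x <- runif(4, 25, 38)
    base <- mean_skin_temperature(x[1], x[2], x[3], x[4])
    expect_gte(base, min(x)); expect_lte(base, max(x))
    # raising any one site raises the mean
    for (j in 1:4) {
      x2 <- x; x2[j] <- x2[j] + 1
      expect_gt(mean_skin_temperature(x2[1], x2[2], x2[3], x2[4]), base)
    }
    shifted <- mean_skin_temperature(x[1] + 2, x[2] + 2, x[3] + 2, x[4] + 2)
    expect_equal(shifted, base + 2)
  }
})

test_that("rest windows exclude the contaminated start", {
  r <- rri_series(seq(0, 320, by = 0.8))
  w <- rest_window(r, 0, 300, exclusion = 30)
  expect_gte(min(w$onsets), 30)
  expect_lte(max(w$onsets), 300)
  expect_equal(diff(range(w$onsets)), 270, tolerance = 0.01)
  w0 <- rest_window(r, 0, 300, exclusion = 0)
  expect_equal(length(w0$onsets), sum(r$onsets <= 300))
  expect_error(rest_window(r, 0, 20, exclusion = 30), "shorter")
})

test_that("heart rate is the reciprocal mean interval", {
  expect_equal(heart_rate(rri_series(seq(0, 10))), 60)
  expect_equal(heart_rate(rri_series(seq(0, 10, by = 0.5))), 120)
  on <- cumsum(c(0, rep(c(0.8, 1.0), 10)))
  r <- rri_series(on, c(rep(c(800, 1000), 10), 800))
  expect_equal(heart_rate(r), 60000 / mean(r$intervals))
})

test_that("MEM band powers agree with the periodogram oracle on sinusoids", {
  hf_only <- synth_rri(0, 300, mean_rri = 1000, lf_power = 1e-10,
                       hf_power = 1250)
  p <- mem_band_powers(hf_only)
  expect_gt(p[["hf_power"]] / sum(p), 0.9)
  o <- periodogram_band_powers(hf_only)
  expect_gt(o[["hf"]] / sum(o), 0.9)  # same dominant band

  lf_only <- synth_rri(0, 300, mean_rri = 1000, lf_power = 1250,
                       hf_power = 1e-10)
  p <- mem_band_powers(lf_only)
  o <- periodogram_band_powers(lf_only)
  expect_gt(p[["lf_power"]] / sum(p), 0.9)
  expect_gt(o[["lf"]] / sum(o), 0.9)

  # equal-amplitude superposition on an ideal tachogram: ratio near 1
  both <- regular_tachogram(lf_amp = 40, hf_amp = 40)
  p <- mem_band_powers(both)
  o <- periodogram_band_powers(both)
  expect_lt(abs(log(p[["lf_power"]] / p[["hf_power"]])), log(1.2))
  expect_lt(abs(log(o[["lf"]] / o[["hf"]])), log(1.2))
})

test_that("band dominance is robust across AR orders 8-30", {
  hf_only <- synth_rri(0, 300, mean_rri = 1000, lf_power = 1e-10,
                       hf_power = 900, noise_sd = 2)
  for (ord in c(8, 12, 16, 24, 30)) {
    p <- mem_band_powers(hf_only, order = ord)
    expect_gt(p[["hf_power"]] / sum(p), 0.8)
  }
})

test_that("band powers ignore the mean level and scale with amplitude^2", {
  base <- regular_tachogram(lf_amp = 30, hf_amp = 30)
  up <- base
  up$intervals <- up$intervals + 300  # shift mean level only
  p1 <- mem_band_powers(base); p2 <- mem_band_powers(up)
  expect_equal(unname(p2), unname(p1), tolerance = 0.05)
  # doubling the modulation amplitude quadruples the band power
  big <- regular_tachogram(lf_amp = 60, hf_amp = 60)
  p4 <- mem_band_powers(big)
  expect_equal(p4[["lf_power"]] / p1[["lf_power"]], 4, tolerance = 0.1)
  expect_equal(p4[["hf_power"]] / p1[["hf_power"]], 4, tolerance = 0.1)
  expect_error(mem_band_powers(rri_series(seq(0, 100))), "degenerate")
})

test_that("HRV features are consistent log transforms of band powers", {
  r <- synth_rri(0, 300, mean_rri = 1000, lf_power = 600, hf_power = 300,
                 noise_sd = 1)
  f <- hrv_features(r)
  expect_equal(f$log_hf, log(f$hf_power))
  expect_equal(f$log_lf_hf, log(f$lf_power) - log(f$hf_power))
  expect_equal(f$hr, heart_rate(r))
  # a 2:1 power ratio on an ideal tachogram gives log LF/HF near log 2
  ideal <- regular_tachogram(lf_amp = sqrt(2 * 600), hf_amp = sqrt(2 * 300))
  expect_equal(hrv_features(ideal)$log_lf_hf, log(2), tolerance = 0.2)
})

test_that("grid averaging reproduces closed-form means", {
  g <- build_grid(default_protocol(), "skin")
  secs <- 0:(183 * 60)
  const <- average_onto_grid(secs, rep(3.7, length(secs)), g)
  expect_equal(const, rep(3.7, 34))
  # linear ramp: each sub-range mean equals the value at its midpoint
  ramp <- average_onto_grid(secs, secs / 60, g)
  expect_equal(ramp, g$points$minutes, tolerance = 0.01)
  expect_length(ramp, 34)
  expect_error(average_onto_grid(c(0, 1), c(1, 1), g), "empty")
})
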