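#' Weights for the four-site mean skin temperature
#'
#' Chest and upper arm carry weight 0.3 each, thigh and leg 0.2 each.
#'
#' @param chest,upperarm,thigh,leg site weights; must be in (0, 1) and
#'   sum to 1.
#' @return An object of class `"skin_weights"`.
#' @export
skin_weights <- function(chest = 0.3, upperarm = 0.3, thigh = 0.2, leg = 0.2) {
  w <- c(chest = chest, upperarm = upperarm, thigh = thigh, leg = leg)
  if (any(!is.finite(w)) || any(w <= 0) || any(w >= 1))
    stop("weights must lie strictly in (0, 1)")
  if (abs(sum(w) - 1) > 1e-8) stop("weights must sum to 1")
  structure(as.list(w), class = "skin_weights")
}

#' Weighted mean skin temperature
#'
#' `0.3 * chest + 0.3 * upperarm + 0.2 * thigh + 0.2 * leg` with the
#' default weights.  Vectorised over the four inputs.
#'
#' @param chest,upperarm,thigh,leg site temperatures, degC.
#' @param weights a [skin_weights()] object.
#' @return Weighted mean temperature, degC.
#' @examples
#' mean_skin_temperature(30, 30, 40, 40)  # 34
#' @export
mean_skin_temperature <- function(chest, upperarm, thigh, leg,
                                  weights = skin_weights()) {
  stopifnot(inherits(weights, "skin_weights"))
  vals <- cbind(chest, upperarm, thigh, leg)
  if (any(!is.finite(vals))) stop("skin temperatures must be finite")
  weights$chest * chest + weights$upperarm * upperarm +
    weights$thigh * thigh + weights$leg * leg
}

#' A sequence of heartbeats as R-R intervals
#'
#' @param onsets strictly increasing beat times, seconds.
#' @param intervals R-R intervals in ms, one per beat; when omitted they
#'   are taken as the successive differences of `onsets`.
#' @return Object of class `"rri_series"`: list `onsets`, `intervals`.
#' @export
rri_series <- function(onsets, intervals = NULL) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 2L) stop("need at least 2 beats")
  if (any(diff(onsets) <= 0)) stop("beat onsets must be strictly increasing")
  if (is.null(intervals))
    intervals <- c(diff(onsets) * 1000, diff(onsets)[length(onsets) - 1] * 1000)
  intervals <- as.numeric(intervals)
  if (length(intervals) != length(onsets))
    stop("intervals must have one entry per beat")
  if (any(!is.finite(intervals)) || any(intervals <= 0))
    stop("intervals must be positive and finite")
  structure(list(onsets = onsets, intervals = intervals), class = "rri_series")
}

#' Restrict beats to a rest window, excluding its contaminated start
#'
#' Rest blocks are 5 min; the first 30 s may still reflect the preceding
#' section and are excluded, leaving a 4.5-min analysis window.
#'
#' @param rri an [rri_series()].
#' @param rest_start,rest_end window bounds, seconds.
#' @param exclusion seconds dropped from the start (default 30).
#' @return An [rri_series()] with beats in
#'   `[rest_start + exclusion, rest_end]`.
#' @export
rest_window <- function(rri, rest_start, rest_end, exclusion = 30) {
  stopifnot(inherits(rri, "rri_series"))
  if (rest_end - rest_start <= exclusion)
    stop("rest window shorter than the exclusion period")
  keep <- rri$onsets >= rest_start + exclusion & rri$onsets <= rest_end
  if (sum(keep) < 2L) stop("no beats left in the rest window")
  rri_series(rri$onsets[keep], rri$intervals[keep])
}

#' Mean heart rate of an R-R interval series
#'
#' @param rri an [rri_series()].
#' @return Beats per minute: `60000 / mean(interval in ms)`.
#' @examples
#' heart_rate(rri_series(0:10))  # constant 1000 ms -> 60 bpm
#' @export
heart_rate <- function(rri) {
  stopifnot(inherits(rri, "rri_series"))
  60000 / mean(rri$intervals)
}

# evenly resample the RRI tachogram (cubic spline) and remove its mean
resample_tachogram <- function(rri, fs = 4) {
  t0 <- rri$onsets[1]; t1 <- rri$onsets[length(rri$onsets)]
  tt <- seq(t0, t1, by = 1 / fs)
  x <- stats::spline(rri$onsets, rri$intervals, xout = tt, method = "fmm")$y
  list(t = tt, x = x - mean(x), fs = fs)
}

# one-sided AR (Burg) spectral density on a frequency grid
ar_density <- function(a, var_pred, fs, freq) {
  # S(f) = 2 * sigma2 / fs / |1 - sum_k a_k exp(-2 pi i f k / fs)|^2
  k <- seq_along(a)
  denom <- vapply(freq, function(f) {
    z <- 1 - sum(a * exp(-2i * pi * f * k / fs))
    Mod(z)^2
  }, numeric(1))
  2 * var_pred / fs / denom
}

# integration grid for one band, refined around the AR pole frequencies:
# near-unit-radius poles make the spectrum almost a line and a uniform
# grid misses nearly all of the peak mass
ar_band_grid <- function(a, fs, band) {
  freq <- seq(band[1], band[2], length.out = 513L)
  poles <- polyroot(c(-rev(a), 1))
  fp <- Arg(poles) / (2 * pi) * fs
  hw <- pmax(1 - Mod(poles), 1e-12) * fs / (2 * pi)  # Lorentzian half-width
  keep <- fp > band[1] - 0.05 & fp < band[2] + 0.05
  for (i in which(keep)) {
    offs <- hw[i] * 10^seq(-3, 3, length.out = 61L)
    cand <- fp[i] + c(-rev(offs), 0, offs)
    freq <- c(freq, cand[cand >= band[1] & cand <= band[2]])
  }
  sort(unique(freq))
}

#' Band powers of the RRI spectrum by the maximum entropy method
#'
#' Fits a Burg autoregressive model to the detrended, evenly resampled
#' R-R interval tachogram and integrates the one-sided AR spectral
#' density over the low-frequency (0.04-0.15 Hz) and high-frequency
#' (0.15-0.4 Hz) bands.
#'
#' @param rri an [rri_series()] (typically a [rest_window()] result).
#' @param lf_band,hf_band band edges, Hz.
#' @param order AR model order (default 16).
#' @param fs resampling rate, Hz (default 4).
#' @return Named numeric vector `c(lf_power, hf_power)` in ms^2.
#' @export
mem_band_powers <- function(rri, lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.4), order = 16, fs = 4) {
  stopifnot(inherits(rri, "rri_series"))
  rs <- resample_tachogram(rri, fs)
  if (length(rs$x) < 2L * order + 2L)
    stop("window too short for AR order ", order)
  if (stats::sd(rs$x) < .Machine$double.eps^0.5)
    stop("degenerate (constant) RRI series")
  fit <- stats::ar.burg(rs$x, aic = FALSE, order.max = order, demean = TRUE)
  band_power <- function(band) {
    freq <- ar_band_grid(fit$ar, rs$fs, band)
    s <- ar_density(fit$ar, fit$var.pred, rs$fs, freq)
    df <- diff(freq)
    sum((s[-1] + s[-length(s)]) / 2 * df)  # trapezoid
  }
  c(lf_power = band_power(lf_band), hf_power = band_power(hf_band))
}

#' HRV indices of one rest window
#'
#' Computes the mean heart rate, the log high-frequency power, and the
#' log LF/HF ratio (`log(LF) - log(HF)`, natural log by default) from an
#' R-R interval window.
#'
#' @inheritParams mem_band_powers
#' @param log_base base of the logarithm (default `exp(1)`).
#' @return Object of class `"hrv_features"`: list `hr`, `log_hf`,
#'   `log_lf_hf`, plus the raw band powers.
#' @export
hrv_features <- function(rri, order = 16, fs = 4, log_base = exp(1)) {
  p <- mem_band_powers(rri, order = order, fs = fs)
  if (any(p <= 0)) stop("zero band power; cannot take logs")
  lg <- function(v) log(v, base = log_base)
  structure(list(hr = heart_rate(rri),
                 log_hf = lg(p[["hf_power"]]),
                 log_lf_hf = lg(p[["lf_power"]]) - lg(p[["hf_power"]]),
                 lf_power = p[["lf_power"]], hf_power = p[["hf_power"]]),
            class = "hrv_features")
}

#' @export
print.hrv_features <- function(x, ...) {
  cat(sprintf("HRV features: HR %.1f bpm, log HF %.3f, log LF/HF %.3f\n",
              x$hr, x$log_hf, x$log_lf_hf))
  invisible(x)
}

#' Average a time-stamped stream onto a measurement grid
#'
#' Each grid point carries an averaging window; the stream is averaged
#' within each window.  Windows are treated as half-open
#' `[start, end)` with the final window of each section closed, so the
#' sub-ranges partition each section without double counting.
#'
#' @param seconds,values the stream: time stamps (seconds) and values.
#' @param grid a [build_grid()] result.
#' @return Numeric vector with one mean per grid point.
#' @export
average_onto_grid <- function(seconds, values, grid) {
  stopifnot(inherits(grid, "measurement_grid"), length(seconds) == length(values))
  pts <- grid$points
  minutes <- seconds / 60
  vapply(seq_len(nrow(pts)), function(i) {
    lo <- pts$window_start[i]; hi <- pts$window_end[i]
    # closed upper end for the last window of its section
    same_sec <- pts$section == pts$section[i]
    last_of_sec <- pts$minutes[i] == max(pts$minutes[same_sec])
    inw <- if (last_of_sec) minutes >= lo & minutes <= hi
           else minutes >= lo & minutes < hi
    if (!any(inw)) stop("empty averaging window at grid point ", i)
    mean(values[inw])
  }, numeric(1))
}
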