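#' Fit on early sections and forecast the final set
#'
#' Implements the truncate-and-forecast experiment: observations after
#' `split` are withheld, the prediction variant of the model (Normal
#' Load innovations; undamped Environment recursion, h = 1, unless
#' `estimate_h = TRUE`) is fitted to the remaining data, and the latent
#' states over the forecast window -- which carry no observation terms
#' there -- provide posterior predictive bands for the held-out
#' measurements (observation noise included, so the bands cover future
#' measured values).
#'
#' @param y a [measurement_series()] including the held-out tail.
#' @param split last time index of the fitting window (e.g. the final
#'   point of the third B+A set).
#' @param level credible level of the coverage band (default 0.5).
#' @param chains,warmup,sampling,seed MCMC settings, as in
#'   [thermoload()].
#' @param estimate_h sample the Environment damping instead of fixing
#'   h = 1 (default `FALSE`, the literal prediction-model recursion).
#' @param ... further arguments passed to [thermoload()].
#' @return Object of class `"thermoload_forecast"`: list with the
#'   truncated `fit`, `fit_window`, `forecast_window`, `bands` (per
#'   condition data.frames with predictive mean/lower/upper), `heldout`
#'   (matrix of withheld values), `covered` (logical matrix) and
#'   `coverage` (fraction of held-out values inside the band).
#' @export
forecast_sections <- function(y, split, level = 0.5, chains = 4,
                              warmup = 2000, sampling = 2000, seed = NULL,
                              estimate_h = FALSE, ...) {
  stopifnot(inherits(y, "measurement_series"))
  TT <- n_time(y)
  split <- as.integer(split)
  if (split < 4L || split > TT - 2L)
    stop("split must leave at least 4 points to fit and 2 to forecast")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  ytrunc <- y$y
  ytrunc[(split + 1L):TT, ] <- NA_real_
  yfit <- measurement_series(ytrunc, modality = y$modality, grid = y$grid,
                             period = y$period)
  fit <- thermoload(yfit, chains = chains, warmup = warmup,
                    sampling = sampling, seed = seed,
                    load_noise_family = "normal",
                    estimate_h = estimate_h, h = 1, ...)
  fw <- (split + 1L):TT
  a <- (1 - level) / 2
  bands <- lapply(CONDITIONS, function(cc) {
    dm <- component_draws(fit, "fitted", cc)
    s <- as.vector(hyper_draw_matrix(fit, paste0("sigma_obs[", cc, "]")))
    pp <- dm + matrix(stats::rnorm(length(dm), 0, s), nrow = nrow(dm))
    data.frame(condition = cc, t = seq_len(TT), mean = colMeans(pp),
               lower = apply(pp, 2, stats::quantile, a),
               upper = apply(pp, 2, stats::quantile, 1 - a),
               stringsAsFactors = FALSE)
  })
  names(bands) <- CONDITIONS
  heldout <- y$y[fw, , drop = FALSE]
  covered <- matrix(NA, nrow = length(fw), ncol = 4L,
                    dimnames = list(NULL, CONDITIONS))
  for (j in 1:4) {
    b <- bands[[j]]
    covered[, j] <- heldout[, j] >= b$lower[fw] & heldout[, j] <= b$upper[fw]
  }
  coverage <- mean(covered, na.rm = TRUE)
  structure(list(fit = fit, split = split, level = level,
                 fit_window = seq_len(split), forecast_window = fw,
                 bands = bands, heldout = heldout, covered = covered,
                 coverage = coverage),
            class = "thermoload_forecast")
}

#' @export
print.thermoload_forecast <- function(x, ...) {
  cat(sprintf("Section-wise forecast: fit on t = 1..%d, forecast t = %d..%d\n",
              x$split, x$forecast_window[1],
              x$forecast_window[length(x$forecast_window)]))
  cat(sprintf("  %.0f%% predictive band held-out coverage: %.3f\n",
              100 * x$level, x$coverage))
  invisible(x)
}
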