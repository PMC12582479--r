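#' Fit the Base/Load/Environment decomposition by MCMC
#'
#' Decomposes per-condition psychophysiological series into a shared
#' Base trend (second-order random walk), condition-specific accumulated
#' Load components (second-order random walks with heavy-tailed Cauchy
#' innovations in the analysis model, Normal innovations in the
#' prediction variant), and a damped periodic Environment component
#' synchronized with the room alternation.  Sampling uses a blocked
#' Gibbs sampler: all latent states are drawn jointly from their
#' Gaussian full conditional, Cauchy innovations are handled by normal
#' scale-mixture augmentation, scale hyperparameters by slice sampling
#' under half-Normal priors, and the damping coefficient by an exact
#' truncated-normal draw.
#'
#' Missing observations (NA entries of `y`) contribute no likelihood
#' term; their posterior predictive draws are returned in
#' `$missing_draws`.
#'
#' @param y a [measurement_series()].
#' @param priors prior configuration, see [default_priors()].
#' @param chains number of independent chains (default 4).
#' @param warmup,sampling iterations discarded / kept per chain
#'   (defaults 2000 and 2000).
#' @param seed integer seed; all chains and initial values derive from it.
#' @param load_noise_family `"cauchy"` (analysis model, default) or
#'   `"normal"` (prediction variant).
#' @param period Environment summation length N; defaults to the
#'   series' period.
#' @param estimate_h sample the damping coefficient (default `TRUE`);
#'   when `FALSE`, `h` is held fixed.
#' @param h fixed damping value used when `estimate_h = FALSE`.
#' @param share_load_scale,share_env_scale share one `sigma_load`
#'   (`sigma_env`) across the three step conditions (default `TRUE`).
#'
#' @return An object of class `"thermoload"` with components `draws`
#'   (hyperparameter and state draws as `iterations x chains x quantity`
#'   arrays), `y`, `priors`, `meta`, and `missing_draws`.  Methods:
#'   [print()], [summary()], [coef()], [fitted()], [residuals()],
#'   [predict()], [simulate()], [plot()]; see also [credible_band()],
#'   [diagnostics()].
#' @examples
#' \donttest{
#' g <- build_grid(default_protocol(), "hf")
#' truth <- generate_dataset("step_load", g, seed = 1)
#' fit <- thermoload(truth$y, chains = 2, warmup = 200, sampling = 200,
#'                   seed = 1)
#' summary(fit)
#' }
#' @export
thermoload <- function(y, priors = NULL, chains = 4, warmup = 2000,
                       sampling = 2000, seed = NULL,
                       load_noise_family = c("cauchy", "normal"),
                       period = NULL, estimate_h = TRUE, h = 1,
                       share_load_scale = TRUE, share_env_scale = TRUE) {
  cl <- match.call()
  stopifnot(inherits(y, "measurement_series"))
  load_noise_family <- match.arg(load_noise_family)
  if (any(!is.finite(y$y) & !y$mask)) stop("non-finite data")
  if (is.null(period)) period <- y$period
  period <- as.integer(period)
  TT <- n_time(y)
  if (period < 2L || period > TT)
    stop("period must lie in [2, T]")
  if (chains < 1L) stop("need at least one chain")
  if (is.null(priors)) priors <- default_priors(y)
  if (!is.null(seed)) set.seed(seed)

  sdy <- stats::sd(y$y, na.rm = TRUE); if (!is.finite(sdy) || sdy <= 0) sdy <- 1
  fill <- function(v) {
    if (!any(is.na(v))) return(v)
    if (all(is.na(v))) return(rep(mean(y$y, na.rm = TRUE), length(v)))
    stats::approx(seq_along(v), v, xout = seq_along(v), rule = 2)$y
  }
  ya <- fill(y$y[, 1L])

  n_state <- 7L * TT
  hyper_runs <- vector("list", chains)
  state_runs <- vector("list", chains)
  for (ch in seq_len(chains)) {
    x0 <- numeric(n_state)
    x0[1:TT] <- ya + stats::rnorm(TT, 0, 0.05 * sdy)
    for (n in 1:3) {
      ln <- fill(y$y[, n + 1L]) - ya
      x0[TT + (n - 1L) * TT + 1:TT] <- ln + stats::rnorm(TT, 0, 0.05 * sdy)
      x0[4L * TT + (n - 1L) * TT + 1:TT] <- stats::rnorm(TT, 0, 0.02 * sdy)
    }
    jit <- function(v) v * exp(stats::rnorm(length(v), 0, 0.3))
    d2a <- diff(ya, differences = 2)
    s_obs0 <- jit(rep(max(sdy / 4, 1e-3), 4))
    s_base0 <- jit(max(stats::sd(d2a) / 2, 1e-3))
    s_load0 <- jit(rep(max(stats::sd(d2a), 1e-3), 3))
    s_env0 <- jit(rep(max(sdy / 4, 1e-3), 3))
    h0 <- if (estimate_h) stats::runif(1, 0.2, 1) else h
    res <- .gibbs_chain(y$y, period,
                        ifelse(load_noise_family == "cauchy", 0L, 1L),
                        estimate_h, share_load_scale, share_env_scale,
                        priors$mu0, priors$s_init, priors$s_sigma,
                        s_obs0, s_base0, s_load0, s_env0, h0,
                        x0, as.integer(warmup), as.integer(sampling))
    hyper_runs[[ch]] <- res$hyper
    state_runs[[ch]] <- res$states
  }

  # collapse the 12 raw hyperparameter columns to the sampled ones
  keep <- c(1:5,
            if (share_load_scale) 6L else 6:8,
            if (share_env_scale) 9L else 9:11,
            if (estimate_h) 12L else integer(0))
  par_names <- c(
    paste0("sigma_obs[", CONDITIONS, "]"), "sigma_base",
    if (share_load_scale) "sigma_load"
    else paste0("sigma_load[", CONDITIONS[-1], "]"),
    if (share_env_scale) "sigma_env"
    else paste0("sigma_env[", CONDITIONS[-1], "]"),
    if (estimate_h) "h")

  hyper <- array(NA_real_, dim = c(sampling, chains, length(keep)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(chains)) hyper[, ch, ] <- hyper_runs[[ch]][, keep]
  ckey <- c("b", "c", "d")
  state_names <- c(paste0("base[", 1:TT, "]"),
                   as.vector(vapply(ckey, function(k)
                     paste0("load[", k, ",", 1:TT, "]"), character(TT))),
                   as.vector(vapply(ckey, function(k)
                     paste0("env[", k, ",", 1:TT, "]"), character(TT))))
  states <- array(NA_real_, dim = c(sampling, chains, n_state),
                  dimnames = list(NULL, NULL, state_names))
  for (ch in seq_len(chains)) states[, ch, ] <- state_runs[[ch]]

  fit <- structure(
    list(call = cl, y = y, priors = priors,
         draws = list(hyper = hyper, states = states),
         par_names = par_names, state_names = state_names,
         meta = list(chains = chains, warmup = warmup, sampling = sampling,
                     seed = seed, load_noise_family = load_noise_family,
                     period = period, estimate_h = estimate_h,
                     h_fixed = if (estimate_h) NA_real_ else h,
                     share_load_scale = share_load_scale,
                     share_env_scale = share_env_scale,
                     package_version = as.character(utils::packageVersion("thermoload")))),
    class = "thermoload")
  fit$missing_draws <- posterior_missing(fit)
  fit
}

# draws of one scalar state quantity: matrix [iterations, chains]
state_draw_matrix <- function(fit, name) {
  i <- match(name, fit$state_names)
  if (is.na(i)) stop("unknown state quantity: ", name)
  m <- fit$draws$states[, , i, drop = FALSE]
  dim(m) <- dim(fit$draws$states)[1:2]
  m
}

# pooled draws [ndraw_total x T] of one component/condition trajectory
component_draws <- function(fit, component = c("base", "load", "env",
                                               "fitted"),
                            condition = "T_26-26") {
  component <- match.arg(component)
  keys <- condition_keys()
  if (condition %in% names(keys)) condition <- keys[[condition]]
  j <- match(condition, CONDITIONS)
  if (is.na(j)) stop("unknown condition: ", condition)
  TT <- n_time(fit$y)
  st <- fit$draws$states
  flat <- matrix(st, nrow = dim(st)[1] * dim(st)[2], ncol = dim(st)[3])
  colnames(flat) <- fit$state_names
  base <- flat[, paste0("base[", 1:TT, "]"), drop = FALSE]
  if (component == "base") return(base)
  if (j == 1L) {
    if (component == "fitted") return(base)
    stop("the control condition has no ", component, " component")
  }
  k <- c("b", "c", "d")[j - 1L]
  load <- flat[, paste0("load[", k, ",", 1:TT, "]"), drop = FALSE]
  env <- flat[, paste0("env[", k, ",", 1:TT, "]"), drop = FALSE]
  switch(component, load = load, env = env, fitted = base + load + env)
}

hyper_draw_matrix <- function(fit, par) {
  i <- match(par, fit$par_names)
  if (is.na(i)) stop("unknown parameter: ", par)
  m <- fit$draws$hyper[, , i, drop = FALSE]
  dim(m) <- dim(fit$draws$hyper)[1:2]
  m
}

# pooled posterior predictive draws for masked observations
posterior_missing <- function(fit) {
  mis <- which(fit$y$mask, arr.ind = TRUE)
  if (nrow(mis) == 0L) return(NULL)
  out <- matrix(NA_real_, nrow = dim(fit$draws$states)[1] *
                  dim(fit$draws$states)[2], ncol = nrow(mis))
  colnames(out) <- paste0("y_mis[", CONDITIONS[mis[, 2]], ",", mis[, 1], "]")
  for (i in seq_len(nrow(mis))) {
    t <- mis[i, 1]; j <- mis[i, 2]
    mu <- component_draws(fit, "fitted", CONDITIONS[j])[, t]
    sname <- paste0("sigma_obs[", CONDITIONS[j], "]")
    s <- as.vector(hyper_draw_matrix(fit, sname))
    out[, i] <- mu + stats::rnorm(length(mu), 0, s)
  }
  out
}

#' @export
print.thermoload <- function(x, ...) {
  m <- x$meta
  cat(sprintf("Base/Load/Environment decomposition (%s Load noise)\n",
              m$load_noise_family))
  cat(sprintf("  T = %d, period = %d, %d chains x (%d warmup + %d sampling)\n",
              n_time(x$y), m$period, m$chains, m$warmup, m$sampling))
  d <- diagnostics(x)
  cat(sprintf("  max R-hat %.3f, min bulk ESS %.0f over %d hyperparameters\n",
              max(d$rhat, na.rm = TRUE), min(d$ess, na.rm = TRUE), nrow(d)))
  invisible(x)
}

#' @export
coef.thermoload <- function(object, ...) {
  vapply(object$par_names,
         function(p) mean(hyper_draw_matrix(object, p)), numeric(1))
}

#' @export
summary.thermoload <- function(object, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                               ...) {
  rows <- lapply(object$par_names, function(p) {
    dm <- hyper_draw_matrix(object, p)
    v <- as.vector(dm)
    q <- stats::quantile(v, probs)
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               t(as.matrix(q)), rhat = rhat(dm), ess = ess_bulk(dm),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.thermoload", "data.frame")
  out
}

#' @export
print.summary.thermoload <- function(x, digits = 3, ...) {
  cat("Posterior summary of hyperparameters\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.thermoload <- function(object, ...) {
  TT <- n_time(object$y)
  out <- matrix(NA_real_, TT, 4L, dimnames = list(NULL, CONDITIONS))
  for (j in 1:4)
    out[, j] <- colMeans(component_draws(object, "fitted", CONDITIONS[j]))
  out
}

#' @export
residuals.thermoload <- function(object, ...) {
  object$y$y - fitted(object)
}

#' Posterior trajectories with credible bounds
#'
#' @param object a fitted [thermoload()] model.
#' @param type `"mean"` for the latent predicted mean, `"response"` for
#'   the posterior predictive of new observations (adds observation
#'   noise).
#' @param level credible level of the reported interval.
#' @param ... unused.
#' @return data.frame with columns `condition`, `t`, `mean`, `lower`,
#'   `upper`.
#' @export
predict.thermoload <- function(object, type = c("mean", "response"),
                               level = 0.95, ...) {
  type <- match.arg(type)
  TT <- n_time(object$y)
  a <- (1 - level) / 2
  rows <- lapply(CONDITIONS, function(cc) {
    dm <- component_draws(object, "fitted", cc)
    if (type == "response") {
      s <- as.vector(hyper_draw_matrix(object, paste0("sigma_obs[", cc, "]")))
      dm <- dm + matrix(stats::rnorm(length(dm), 0, s), nrow = nrow(dm))
    }
    data.frame(condition = cc, t = 1:TT, mean = colMeans(dm),
               lower = apply(dm, 2, stats::quantile, a),
               upper = apply(dm, 2, stats::quantile, 1 - a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate posterior predictive datasets
#'
#' Draws whole replicate datasets from the posterior predictive: for each
#' replicate a posterior draw of states and scales is selected and new
#' observations are generated from the observation equations.
#'
#' @param object a fitted [thermoload()] model.
#' @param nsim number of replicate datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return List of `nsim` [measurement_series()] objects.
#' @export
simulate.thermoload <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  TT <- n_time(object$y)
  ntot <- object$meta$sampling * object$meta$chains
  idx <- sample.int(ntot, nsim, replace = nsim > ntot)
  fitted_draws <- lapply(CONDITIONS, function(cc)
    component_draws(object, "fitted", cc))
  sig_draws <- vapply(CONDITIONS, function(cc)
    as.vector(hyper_draw_matrix(object, paste0("sigma_obs[", cc, "]"))),
    numeric(ntot))
  lapply(idx, function(i) {
    yv <- vapply(1:4, function(j)
      fitted_draws[[j]][i, ] + stats::rnorm(TT, 0, sig_draws[i, j]),
      numeric(TT))
    colnames(yv) <- CONDITIONS
    measurement_series(yv, modality = object$y$modality,
                       grid = object$y$grid, period = object$meta$period)
  })
}

#' Plot a fitted decomposition
#'
#' Draws, for each requested condition, the observed series with the
#' posterior mean trajectory and shaded 95% and 50% credible bands of
#' the chosen component.
#'
#' @param x a fitted [thermoload()] model.
#' @param component `"fitted"` (default), `"base"`, `"load"` or `"env"`.
#' @param conditions conditions to show (default: all that have the
#'   component).
#' @param levels credible levels for the shaded bands.
#' @param ... passed to [graphics::plot()].
#' @export
plot.thermoload <- function(x, component = c("fitted", "base", "load", "env"),
                            conditions = NULL, levels = c(0.95, 0.5), ...) {
  component <- match.arg(component)
  if (is.null(conditions))
    conditions <- if (component %in% c("load", "env")) CONDITIONS[-1]
                  else CONDITIONS
  TT <- n_time(x$y)
  op <- graphics::par(mfrow = c(length(conditions), 1),
                      mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  shade <- grDevices::grey(c(0.85, 0.7))
  for (cc in conditions) {
    dm <- component_draws(x, component, cc)
    m <- colMeans(dm)
    ylim <- range(m, x$y$y[, cc], na.rm = TRUE)
    for (lv in levels)
      ylim <- range(ylim, apply(dm, 2, stats::quantile,
                                c((1 - lv) / 2, 1 - (1 - lv) / 2)))
    graphics::plot(1:TT, m, type = "n", ylim = ylim, xlab = "time point",
                   ylab = component, main = cc, ...)
    for (i in seq_along(levels)) {
      a <- (1 - levels[i]) / 2
      lo <- apply(dm, 2, stats::quantile, a)
      hi <- apply(dm, 2, stats::quantile, 1 - a)
      graphics::polygon(c(1:TT, TT:1), c(lo, rev(hi)), border = NA,
                        col = shade[min(i, length(shade))])
    }
    graphics::lines(1:TT, m, lwd = 2)
    if (component == "fitted")
      graphics::points(1:TT, x$y$y[, cc], pch = 16, cex = 0.7)
  }
  invisible(x)
}
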