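#' Hyperparameters of the state-space decomposition model
#'
#' The observation noise scales (one per condition), the state-noise
#' scales of the Base, Load and Environment components, the damping
#' coefficient of the Environment recursion, its summation length
#' (period), and the Load innovation family: heavy-tailed Cauchy for the
#' analysis model, Normal for the prediction (forecasting) variant.
#'
#' @param sigma_obs observation noise SD; length 1 (shared) or 4, one per
#'   condition in [CONDITIONS] order.
#' @param sigma_base Base second-difference innovation SD.
#' @param sigma_load Load innovation scale; length 1 (shared across the
#'   three step conditions) or 3.
#' @param sigma_env Environment innovation SD; length 1 or 3.
#' @param h damping coefficient of the Environment recursion, in (0, 1].
#' @param period summation length N of the Environment recursion
#'   (points per B+A room cycle on the modality's grid).
#' @param load_noise_family `"cauchy"` (analysis model) or `"normal"`
#'   (prediction model).
#' @return Object of class `"hyperparams"`.
#' @export
hyperparams <- function(sigma_obs = 0.1, sigma_base = 0.04,
                        sigma_load = 0.04, sigma_env = 0.05,
                        h = 0.8, period = 6,
                        load_noise_family = c("cauchy", "normal")) {
  load_noise_family <- match.arg(load_noise_family)
  if (length(sigma_obs) == 1L) sigma_obs <- rep(sigma_obs, 4L)
  if (length(sigma_obs) != 4L) stop("sigma_obs must have length 1 or 4")
  names(sigma_obs) <- CONDITIONS
  if (length(sigma_load) == 1L) sigma_load <- rep(sigma_load, 3L)
  if (length(sigma_env) == 1L) sigma_env <- rep(sigma_env, 3L)
  if (length(sigma_load) != 3L || length(sigma_env) != 3L)
    stop("sigma_load and sigma_env must have length 1 or 3")
  names(sigma_load) <- names(sigma_env) <- CONDITIONS[-1]
  scales <- c(sigma_obs, sigma_base, sigma_load, sigma_env)
  if (any(!is.finite(scales)) || any(scales < 0))
    stop("all scales must be finite and non-negative")
  if (!is.finite(h) || h <= 0 || h > 1) stop("h must lie in (0, 1]")
  period <- as.integer(period)
  if (period < 2L) stop("period must be >= 2")
  structure(list(sigma_obs = sigma_obs, sigma_base = sigma_base,
                 sigma_load = sigma_load, sigma_env = sigma_env,
                 h = h, period = period,
                 load_noise_family = load_noise_family),
            class = "hyperparams")
}

#' @export
print.hyperparams <- function(x, ...) {
  cat(sprintf(
    "State-space hyperparameters (%s Load noise, period %d, h = %.3g)\n",
    x$load_noise_family, x$period, x$h))
  cat("  sigma_obs:", paste(sprintf("%.3g", x$sigma_obs), collapse = ", "), "\n")
  cat(sprintf("  sigma_base %.3g; sigma_load %s; sigma_env %s\n",
              x$sigma_base,
              paste(sprintf("%.3g", x$sigma_load), collapse = "/"),
              paste(sprintf("%.3g", x$sigma_env), collapse = "/")))
  invisible(x)
}

#' Latent state components of the decomposition
#'
#' @param base numeric vector, the shared Base trend (length T).
#' @param load,env T x 3 matrices for the three step conditions (columns
#'   `T_26-31`, `T_26-36`, `T_21-36`); the control condition has no Load
#'   or Environment component.
#' @return Object of class `"state_components"`.
#' @export
state_components <- function(base, load, env) {
  base <- as.numeric(base)
  load <- as.matrix(load); env <- as.matrix(env)
  TT <- length(base)
  if (!all(dim(load) == c(TT, 3L)) || !all(dim(env) == c(TT, 3L)))
    stop("load and env must be T x 3 matrices matching length(base)")
  colnames(load) <- colnames(env) <- CONDITIONS[-1]
  structure(list(base = base, load = load, env = env),
            class = "state_components")
}

#' Default prior configuration for the decomposition model
#'
#' Half-Normal(0, `s_sigma`) priors on all scale parameters with
#' `s_sigma` proportional to the overall SD of the observed series;
#' Uniform(0, 1] on the damping coefficient; weakly-informative Normal
#' priors on the initial states (the first two Base and Load values and
#' the first N-1 Environment values), centred on the first control
#' observation for Base and on zero for Load and Environment.
#'
#' @param y a [measurement_series()], used only to set the scales.
#' @param s_sigma half-Normal scale for the sigma priors; default
#'   `2.5 * sd(y)`.
#' @param s_init SD of the initial-state priors; default `10 * sd(y)`.
#' @return List with elements `mu0`, `s_init`, `s_sigma`.
#' @export
default_priors <- function(y, s_sigma = NULL, s_init = NULL) {
  stopifnot(inherits(y, "measurement_series"))
  sdy <- stats::sd(y$y, na.rm = TRUE)
  if (!is.finite(sdy) || sdy <= 0) sdy <- 1
  ya <- y$y[, 1L]
  mu0 <- if (any(!is.na(ya))) ya[which(!is.na(ya))[1]]
         else mean(y$y, na.rm = TRUE)
  list(mu0 = mu0,
       s_init = if (is.null(s_init)) 10 * sdy else s_init,
       s_sigma = if (is.null(s_sigma)) 2.5 * sdy else s_sigma)
}

# half-normal log density
ldhalfnorm <- function(x, s) stats::dnorm(x, 0, s, log = TRUE) + log(2)

#' Log joint density of observations, states and hyperparameters
#'
#' Sums the observation terms (control condition: Normal around Base;
#' step conditions: Normal around Base + Load + Env), the state terms
#' (Normal second-difference density for Base; Cauchy or Normal
#' second-difference density for each condition's Load depending on the
#' model variant; Normal density for the damped periodic Environment
#' recursion), the initial-state priors, and the hyperparameter priors.
#' Missing observations contribute no observation term.
#'
#' @param y a [measurement_series()].
#' @param states a [state_components()].
#' @param params a [hyperparams()].
#' @param priors a prior configuration, see [default_priors()].
#' @return The log joint density (a single finite number, or `-Inf` when
#'   a hard prior constraint is violated).
#' @export
log_joint <- function(y, states, params, priors = default_priors(y)) {
  stopifnot(inherits(y, "measurement_series"),
            inherits(states, "state_components"),
            inherits(params, "hyperparams"))
  TT <- n_time(y)
  if (length(states$base) != TT) stop("state dimensions do not match the grid")
  if (any(!is.finite(states$base)) || any(!is.finite(states$load)) ||
      any(!is.finite(states$env)))
    stop("states contain non-finite values")
  if (any(c(params$sigma_obs, params$sigma_base, params$sigma_load,
            params$sigma_env) <= 0))
    stop("all scales must be positive to evaluate the joint density")
  N <- params$period
  if (TT < N) stop("series shorter than the Environment period")
  lp <- 0
  # observation terms
  for (j in seq_len(4L)) {
    obs <- !y$mask[, j]
    if (!any(obs)) next
    mu <- if (j == 1L) states$base
          else states$base + states$load[, j - 1L] + states$env[, j - 1L]
    lp <- lp + sum(stats::dnorm(y$y[obs, j], mu[obs],
                                params$sigma_obs[j], log = TRUE))
  }
  # Base: second-order random walk
  d2 <- function(v) v[3:TT] - 2 * v[2:(TT - 1)] + v[1:(TT - 2)]
  lp <- lp + sum(stats::dnorm(d2(states$base), 0, params$sigma_base, log = TRUE))
  # Load: second-order random walk, Cauchy or Normal innovations
  for (k in 1:3) {
    r <- d2(states$load[, k])
    lp <- lp + if (params$load_noise_family == "cauchy")
      sum(stats::dcauchy(r, 0, params$sigma_load[k], log = TRUE))
    else
      sum(stats::dnorm(r, 0, params$sigma_load[k], log = TRUE))
  }
  # Environment: damped zero-sum seasonal recursion
  for (k in 1:3) {
    e <- states$env[, k]
    r <- vapply(N:TT, function(t)
      e[t] + params$h * sum(e[(t - N + 1):(t - 1)]), numeric(1))
    lp <- lp + sum(stats::dnorm(r, 0, params$sigma_env[k], log = TRUE))
  }
  # initial-state priors
  lp <- lp + sum(stats::dnorm(states$base[1:2], priors$mu0, priors$s_init,
                              log = TRUE))
  lp <- lp + sum(stats::dnorm(states$load[1:2, ], 0, priors$s_init, log = TRUE))
  lp <- lp + sum(stats::dnorm(states$env[1:(N - 1), ], 0, priors$s_init,
                              log = TRUE))
  # hyperparameter priors
  lp <- lp + sum(ldhalfnorm(params$sigma_obs, priors$s_sigma)) +
    ldhalfnorm(params$sigma_base, priors$s_sigma) +
    sum(ldhalfnorm(params$sigma_load, priors$s_sigma)) +
    sum(ldhalfnorm(params$sigma_env, priors$s_sigma))
  # h ~ Uniform(0, 1]: contributes 0 inside the support
  lp
}

#' Forward-simulate the state-space model
#'
#' Runs the state recursions forward from given initial values and then
#' draws observations from the observation equations.  With all state
#' scales zero the recursions are deterministic: a linear initialisation
#' yields exactly linear Base and Load trajectories.
#'
#' @param params a [hyperparams()].
#' @param init list with `base` (first two Base values), `load` (2 x 3
#'   matrix of first two Load values per step condition) and
#'   `env_window` ((N-1) x 3 matrix of initial Environment values).
#' @param T series length (>= period).
#' @param seed integer seed; the simulation is reproducible under it.
#' @param cauchy_trunc truncation bound, in multiples of `sigma_load`,
#'   applied to Cauchy Load innovations (default `Inf`, the untruncated
#'   model; the synthetic-data generator truncates at 6).
#' @return List with `states` (a [state_components()]) and `y`
#'   (a [measurement_series()]).
#' @export
ssm_simulate <- function(params, init, T, seed = NULL, cauchy_trunc = Inf) {
  stopifnot(inherits(params, "hyperparams"))
  T <- as.integer(T)
  if (T < 2L) stop("T must be at least 2")
  N <- params$period
  if (T < N) stop("T must be at least the period")
  if (!is.null(seed)) set.seed(seed)
  base <- numeric(T); base[1:2] <- init$base
  load <- matrix(0, T, 3L); load[1:2, ] <- init$load
  env <- matrix(0, T, 3L)
  env[seq_len(N - 1L), ] <- init$env_window
  rload <- function(k) {
    s <- params$sigma_load[k]
    if (s == 0) return(0)
    if (params$load_noise_family == "normal") return(stats::rnorm(1, 0, s))
    repeat {
      x <- stats::rcauchy(1, 0, s)
      if (abs(x) <= cauchy_trunc * s) return(x)
    }
  }
  for (t in 3:T) {
    base[t] <- 2 * base[t - 1] - base[t - 2] +
      if (params$sigma_base > 0) stats::rnorm(1, 0, params$sigma_base) else 0
    for (k in 1:3)
      load[t, k] <- 2 * load[t - 1, k] - load[t - 2, k] + rload(k)
  }
  for (t in N:T) for (k in 1:3)
    env[t, k] <- -params$h * sum(env[(t - N + 1):(t - 1), k]) +
      if (params$sigma_env[k] > 0) stats::rnorm(1, 0, params$sigma_env[k]) else 0
  states <- state_components(base, load, env)
  yv <- matrix(NA_real_, T, 4L, dimnames = list(NULL, CONDITIONS))
  for (j in 1:4) {
    mu <- predicted_mean(states, CONDITIONS[j])
    s <- params$sigma_obs[j]
    yv[, j] <- mu + if (s > 0) stats::rnorm(T, 0, s) else 0
  }
  list(states = states,
       y = measurement_series(yv, period = N))
}

#' Predicted mean trajectory of one condition
#'
#' The control condition's mean is the Base component alone; each step
#' condition's mean is Base + Load + Environment.
#'
#' @param states a [state_components()].
#' @param condition one of [CONDITIONS] (or the short keys
#'   `"a"`..`"d"`).
#' @return Numeric vector of length T.
#' @export
predicted_mean <- function(states, condition) {
  stopifnot(inherits(states, "state_components"))
  keys <- condition_keys()
  if (condition %in% names(keys)) condition <- keys[[condition]]
  j <- match(condition, CONDITIONS)
  if (is.na(j)) stop("unknown condition: ", condition)
  if (j == 1L) states$base
  else states$base + states$load[, j - 1L] + states$env[, j - 1L]
}
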