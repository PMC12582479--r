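# MCMC convergence diagnostics: rank-normalized split R-hat and bulk
# effective sample size, following the modern definitions the applied
# Bayesian literature has converged on (split chains, rank
# normalization, Geyer initial-monotone autocorrelation truncation).

as_draw_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

split_chains <- function(x) {
  n <- nrow(x)
  if (n %% 2L == 1L) x <- x[-n, , drop = FALSE]
  half <- nrow(x) / 2L
  cbind(x[seq_len(half), , drop = FALSE],
        x[half + seq_len(half), , drop = FALSE])
}

rank_normalize <- function(x) {
  r <- rank(as.vector(x), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(x), ncol = ncol(x))
}

rhat_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  mu <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(mu)
  varp <- (n - 1) / n * W + B / n
  sqrt(varp / W)
}

#' Rank-normalized split R-hat convergence diagnostic
#'
#' Chains are split in half, the pooled draws are rank-normalized, and
#' the classical potential-scale-reduction statistic is computed; the
#' reported value is the maximum of this bulk statistic and the same
#' statistic on folded draws (absolute deviations from the median),
#' which is sensitive to scale disagreement.  Values near 1 indicate
#' convergence; the packaged default threshold is 1.05.
#'
#' @param x draws of one scalar quantity: an iterations x chains matrix
#'   (at least 2 chains and 4 draws per chain).
#' @return The diagnostic, or `NaN` when the draws are constant.
#' @export
rhat <- function(x) {
  x <- as_draw_matrix(x)
  if (ncol(x) < 2L) stop("rhat needs at least 2 chains")
  if (nrow(x) < 4L) stop("rhat needs at least 4 draws per chain")
  if (any(!is.finite(x))) return(NaN)
  if (stats::sd(x) < .Machine$double.eps^0.5) return(NaN)
  xs <- split_chains(x)
  bulk <- rhat_basic(rank_normalize(xs))
  folded <- rhat_basic(rank_normalize(abs(xs - stats::median(xs))))
  max(bulk, folded)
}

# combined-chain autocorrelation ESS (Geyer initial monotone sequence)
ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = n - 1L, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  W <- mean(apply(x, 2, stats::var))
  varp <- (n - 1) / n * W + stats::var(colMeans(x))
  rho <- 1 - (W - mean_acov) / varp
  rho[1] <- 1
  # Geyer pairwise sums, truncated at first negative, forced monotone
  max_pairs <- floor((n - 1) / 2)
  tau <- 0; prev <- Inf
  for (k in 0:max_pairs) {
    p <- rho[2 * k + 1] + if (2 * k + 2 <= n) rho[2 * k + 2] else 0
    if (k > 0 && p < 0) break
    p <- min(p, prev)
    prev <- p
    tau <- tau + 2 * p
  }
  tau <- max(tau - 1, 1 / log10(n * m + 10))
  n * m / tau
}

#' Bulk effective sample size
#'
#' Effective number of independent draws for estimating central
#' tendency, computed on rank-normalized split chains with chainwise
#' autocorrelations combined across chains and truncated by Geyer's
#' initial monotone sequence.  For independent draws the value is close
#' to the total draw count; strong positive autocorrelation shrinks it.
#'
#' @inheritParams rhat
#' @return The effective sample size, or `NaN` when the draws are
#'   constant.
#' @export
ess_bulk <- function(x) {
  x <- as_draw_matrix(x)
  if (ncol(x) < 2L) stop("ess_bulk needs at least 2 chains")
  if (nrow(x) < 4L) stop("ess_bulk needs at least 4 draws per chain")
  if (any(!is.finite(x))) return(NaN)
  if (stats::sd(x) < .Machine$double.eps^0.5) return(NaN)
  ess_basic(rank_normalize(split_chains(x)))
}

#' Convergence diagnostics table for a fitted decomposition
#'
#' @param fit a fitted [thermoload()] model.
#' @param rhat_threshold,ess_threshold packaged decision thresholds
#'   (defaults 1.05 and 1000).
#' @return data.frame with one row per sampled hyperparameter: `parameter`,
#'   `rhat`, `ess`, `ok` (passes both thresholds).
#' @export
diagnostics <- function(fit, rhat_threshold = 1.05, ess_threshold = 1000) {
  stopifnot(inherits(fit, "thermoload"))
  rows <- lapply(fit$par_names, function(p) {
    dm <- hyper_draw_matrix(fit, p)
    data.frame(parameter = p, rhat = rhat(dm), ess = ess_bulk(dm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$ok <- !is.na(out$rhat) & out$rhat < rhat_threshold &
    !is.na(out$ess) & out$ess > ess_threshold
  out
}
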