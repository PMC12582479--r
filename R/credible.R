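#' Central credible band of a posterior trajectory
#'
#' Computes, at each time point, the central posterior quantile interval
#' of one component x condition trajectory from the pooled MCMC draws:
#' the `(1-level)/2` and `(1+level)/2` quantiles.
#'
#' @param component `"base"`, `"load"`, `"env"` or `"fitted"` (for the
#'   matrix method, a free label).
#' @param condition one of [CONDITIONS] (short keys `"a"`..`"d"` also
#'   accepted).  `"load"` and `"env"` exist only for the step conditions.
#' @param level credible level in (0, 1); both 0.95 and 0.50 are in
#'   routine use.
#' @return Object of class `"credible_band"`: list with `level`, `t`,
#'   `lower`, `upper`, `mean`, `component`, `condition`.
#' @export
credible_band <- function(x, ...) UseMethod("credible_band")

#' @rdname credible_band
#' @param x a fitted [thermoload()] model, or a draws matrix with one
#'   column per time point.
#' @param ... passed between methods.
#' @export
credible_band.thermoload <- function(x, component = "load",
                                     condition = "T_26-31", level = 0.95,
                                     ...) {
  keys <- condition_keys()
  if (condition %in% names(keys)) condition <- keys[[condition]]
  dm <- component_draws(x, component, condition)
  credible_band(dm, level = level, component = component,
                condition = condition)
}

#' @rdname credible_band
#' @export
credible_band.matrix <- function(x, level = 0.95, component = "draws",
                                 condition = NA_character_, ...) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must lie strictly in (0, 1)")
  a <- (1 - level) / 2
  structure(list(level = level, t = seq_len(ncol(x)),
                 lower = apply(x, 2, stats::quantile, a),
                 upper = apply(x, 2, stats::quantile, 1 - a),
                 mean = colMeans(x),
                 component = component, condition = condition),
            class = "credible_band")
}

#' @export
print.credible_band <- function(x, ...) {
  cat(sprintf("%.0f%% credible band of %s (%s), %d time points\n",
              100 * x$level, x$component, x$condition, length(x$t)))
  invisible(x)
}

#' @export
as.data.frame.credible_band <- function(x, ...) {
  data.frame(component = x$component, condition = x$condition, t = x$t,
             mean = x$mean, lower = x$lower, upper = x$upper,
             level = x$level, stringsAsFactors = FALSE)
}

#' Compare two conditions by credible-interval overlap
#'
#' Two conditions are declared `"separated"` at a time point when their
#' credible intervals there are disjoint; intervals that merely touch at
#' an endpoint are `"overlapping"` (closed-interval convention).  The
#' comparison is symmetric in its arguments.
#'
#' @param band1,band2 [credible_band()] objects of the same component,
#'   level and grid.
#' @param at time index at which to compare.
#' @return `"separated"` or `"overlapping"`.
#' @export
compare_conditions <- function(band1, band2, at) {
  stopifnot(inherits(band1, "credible_band"), inherits(band2, "credible_band"))
  if (band1$level != band2$level)
    stop("bands have different credible levels")
  if (length(band1$t) != length(band2$t))
    stop("bands are on different grids")
  if (!at %in% band1$t) stop("time index out of range")
  i <- match(at, band1$t)
  disjoint <- band1$upper[i] < band2$lower[i] || band2$upper[i] < band1$lower[i]
  if (disjoint) "separated" else "overlapping"
}
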