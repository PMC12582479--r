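#' Per-condition observations of one modality on its measurement grid
#'
#' Bundles the observed vectors of a single modality under the four
#' temperature-step conditions, on a shared 1-based time grid.  Missing
#' observations are carried as `NA` and recorded in the `mask`; they
#' contribute no observation term to the model and are imputed as latent
#' quantities when the model is fitted.
#'
#' @param values numeric matrix (or data.frame) with `T` rows and one
#'   column per condition; column names must be the four condition labels
#'   in [CONDITIONS].
#' @param modality one of `"vas"`, `"skin"`, `"hr"`, `"hf"`, `"lfhf"`,
#'   or `NULL` for unlabelled series.
#' @param grid optional [build_grid()] result the rows refer to; its size
#'   must match `nrow(values)`.
#' @param period Environment-recursion summation length; defaults to the
#'   grid's period when a grid is given.
#'
#' @return An object of class `"measurement_series"`: list with elements
#'   `modality`, `y` (T x 4 matrix, `NA` = missing), `mask` (logical
#'   matrix, `TRUE` = missing), `grid`, `period`.
#' @export
measurement_series <- function(values, modality = NULL, grid = NULL,
                               period = NULL) {
  y <- as.matrix(values)
  storage.mode(y) <- "double"
  if (ncol(y) != 4L || !setequal(colnames(y), CONDITIONS))
    stop("values must have exactly the four condition columns: ",
         paste(CONDITIONS, collapse = ", "))
  y <- y[, CONDITIONS, drop = FALSE]
  if (nrow(y) < 2L) stop("a measurement series needs at least 2 time points")
  if (any(!is.finite(y) & !is.na(y)))
    stop("non-missing values must be finite")
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "measurement_grid"))
    if (nrow(grid$points) != nrow(y))
      stop("grid has ", nrow(grid$points), " points but values has ",
           nrow(y), " rows")
    if (is.null(modality)) modality <- grid$modality
    if (is.null(period)) period <- grid$period
  }
  if (is.null(period)) period <- 2L
  rownames(y) <- NULL
  structure(list(modality = modality, y = y, mask = is.na(y),
                 grid = grid, period = as.integer(period)),
            class = "measurement_series")
}

n_time <- function(y) nrow(y$y)

#' @export
print.measurement_series <- function(x, ...) {
  cat(sprintf("Measurement series%s: T = %d, period = %d, %d missing\n",
              if (!is.null(x$modality)) paste0(" '", x$modality, "'") else "",
              n_time(x), x$period, sum(x$mask)))
  print(utils::head(x$y, 3))
  if (n_time(x) > 3) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.measurement_series <- function(x, ...) {
  TT <- n_time(x)
  data.frame(
    modality = if (is.null(x$modality)) NA_character_ else x$modality,
    condition = rep(CONDITIONS, each = TT),
    t = rep(seq_len(TT), times = 4L),
    value = as.vector(x$y),
    stringsAsFactors = FALSE)
}
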