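#' Read tidy measurement tables
#'
#' Reads a long-format table with columns `condition`, `modality`, `t`,
#' `value` (and optionally `participant`) and returns one
#' [measurement_series()] per modality.  Unknown condition labels are
#' rejected; blank or missing value cells become missing-mask entries;
#' duplicate `(condition, modality, t)` rows (within a participant) are
#' an error naming the offending row.  When a `participant` column is
#' present the across-participant mean series is returned (the model is
#' fitted to across-participant means by default); set
#' `aggregate = FALSE` to get a list of per-participant series lists.
#'
#' @param path CSV or XLSX file.
#' @param format `"csv"` (default) or `"xlsx"` (requires the readxl
#'   package).
#' @param aggregate average across participants (default `TRUE`).
#' @return Named list of [measurement_series()] (one per modality), or,
#'   with `aggregate = FALSE` and a participant column, a list of such
#'   lists keyed by participant.
#' @examples
#' f <- system.file("extdata", "synthetic_vas_example.csv",
#'                  package = "thermoload")
#' series <- read_measurements(f)
#' series$vas
#' @export
read_measurements <- function(path, format = c("csv", "xlsx"),
                              aggregate = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading xlsx requires the readxl package")
    as.data.frame(readxl::read_excel(path))
  }
  required <- c("condition", "modality", "t", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(df$condition), CONDITIONS)
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  df$t <- as.integer(df$t)
  df$value <- suppressWarnings(as.numeric(df$value))
  has_part <- "participant" %in% names(df)
  key <- paste(df$condition, df$modality, df$t,
               if (has_part) df$participant else "")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf("duplicate (condition, modality, t) at row %d: %s / %s / %d",
                 i, df$condition[i], df$modality[i], df$t[i]))
  }
  build <- function(d) {
    out <- list()
    for (mod in unique(d$modality)) {
      dm <- d[d$modality == mod, ]
      TT <- max(dm$t)
      yv <- matrix(NA_real_, TT, 4L, dimnames = list(NULL, CONDITIONS))
      for (i in seq_len(nrow(dm)))
        yv[dm$t[i], dm$condition[i]] <- dm$value[i]
      out[[mod]] <- measurement_series(
        yv, modality = if (mod %in% MODALITIES) mod else NULL)
    }
    out
  }
  if (has_part && !aggregate) {
    parts <- split(df, df$participant)
    return(lapply(parts, build))
  }
  if (has_part) {
    agg <- stats::aggregate(value ~ condition + modality + t, data = df,
                            FUN = mean, na.action = stats::na.pass)
    return(build(agg))
  }
  build(df)
}

summary_rows <- function(fit) {
  rows <- list()
  for (cc in CONDITIONS) {
    comps <- if (cc == CONDITIONS[1]) c("base", "fitted")
             else c("load", "env", "fitted")
    for (comp in comps) {
      dm <- component_draws(fit, comp, cc)
      q <- apply(dm, 2, stats::quantile, c(0.025, 0.25, 0.75, 0.975))
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, condition = cc, t = seq_len(ncol(dm)),
        mean = colMeans(dm), q2.5 = q[1, ], q25 = q[2, ], q75 = q[3, ],
        q97.5 = q[4, ], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a posterior or forecast summary to CSV
#'
#' Columns are `component`, `condition`, `t`, `mean`, `q2.5`, `q25`,
#' `q75`, `q97.5` in deterministic order; the header comment lines carry
#' the seed, the MCMC settings and the package version.  For forecast
#' objects the rows describe the posterior predictive trajectory and,
#' where held-out values exist, columns `held_out`, `covered` and the
#' overall `coverage` fraction are added.
#'
#' @param object a fitted [thermoload()] model or a
#'   [forecast_sections()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(object, path) {
  if (inherits(object, "thermoload_forecast")) {
    fit <- object$fit
    tab <- do.call(rbind, object$bands)
    tab <- data.frame(component = "prediction", tab,
                      stringsAsFactors = FALSE)
    names(tab)[names(tab) == "lower"] <- "q_lower"
    names(tab)[names(tab) == "upper"] <- "q_upper"
    tab$held_out <- NA_real_
    tab$covered <- NA
    for (j in seq_along(CONDITIONS)) {
      sel <- tab$condition == CONDITIONS[j] & tab$t %in% object$forecast_window
      tab$held_out[sel] <- object$heldout[, j]
      tab$covered[sel] <- object$covered[, j]
    }
    tab$coverage <- object$coverage
  } else {
    stopifnot(inherits(object, "thermoload"))
    fit <- object
    tab <- summary_rows(object)
  }
  m <- fit$meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# thermoload %s", m$package_version),
    sprintf("# seed=%s chains=%d warmup=%d sampling=%d family=%s period=%d",
            ifelse(is.null(m$seed), "NA", as.character(m$seed)),
            m$chains, m$warmup, m$sampling, m$load_noise_family, m$period)),
    con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Export hyperparameter draws to CSV
#'
#' One row per (chain, iteration), one column per sampled
#' hyperparameter; values round-trip exactly through [read_draws()].
#'
#' @param fit a fitted [thermoload()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "thermoload"))
  h <- fit$draws$hyper
  it <- dim(h)[1]; ch <- dim(h)[2]
  tab <- data.frame(chain = rep(seq_len(ch), each = it),
                    iteration = rep(seq_len(it), times = ch))
  for (k in seq_along(fit$par_names))
    tab[[fit$par_names[k]]] <- as.vector(h[, , k])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thermoload %s draws", fit$meta$package_version), con)
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read hyperparameter draws written by [write_draws()]
#'
#' @param path file written by [write_draws()].
#' @return data.frame with `chain`, `iteration` and one column per
#'   parameter.
#' @export
read_draws <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}
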