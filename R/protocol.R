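#' Condition labels used throughout the package
#'
#' The four temperature-step conditions, in canonical order: the control
#' condition (both rooms at 26 degC), a 5 degC step, a 10 degC step, and a
#' 15 degC step starting from a cool 21 degC room.
#'
#' @format Character vector of length 4.
#' @export
CONDITIONS <- c("T_26-26", "T_26-31", "T_26-36", "T_21-36")

# short keys a..d <-> canonical condition labels
condition_keys <- function() stats::setNames(CONDITIONS, c("a", "b", "c", "d"))

#' Modalities recognised by the measurement grids
#' @keywords internal
MODALITIES <- c("vas", "skin", "hr", "hf", "lfhf")

#' Describe an alternating-room temperature-step session
#'
#' A protocol specification records the ordered sections of one session
#' (preparation, an initial stay in room A, alternating visits to rooms B
#' and A, and a final stay in room A), the room temperatures under each
#' condition, and where the 5-min rest blocks and questionnaire blocks
#' fall within each section.  Measurement grids for every modality are
#' derived from it with [build_grid()].
#'
#' @param sections data.frame with columns `label`, `duration` (minutes)
#'   and `room` (`"A"`, `"B"` or `"none"`).  Labels must start with
#'   `"prep"`, end with `"A_post"`, and any sections between `"A_pre"` and
#'   `"A_post"` must alternate `B, A, B, ..., B` (beginning and ending
#'   with a B visit).
#' @param condition_temperatures named list mapping each of the four
#'   condition labels to `c(room_A, room_B)` temperatures in degC.
#' @param rest_plan integer vector, one entry per section: number of
#'   rest blocks placed in that section.
#' @param questionnaire_plan integer vector, one entry per section:
#'   number of questionnaire blocks in that section.
#' @param rest_duration length of one rest block, minutes.
#' @param questionnaire_duration nominal length of one questionnaire
#'   block, minutes (only used to give grid points a finite window).
#'
#' @return An object of class `"protocol_spec"`.
#' @seealso [default_protocol()], [build_grid()]
#' @export
protocol_spec <- function(sections, condition_temperatures,
                          rest_plan, questionnaire_plan,
                          rest_duration = 5, questionnaire_duration = 1) {
  stopifnot(is.data.frame(sections),
            all(c("label", "duration", "room") %in% names(sections)))
  sections$label <- as.character(sections$label)
  sections$room <- as.character(sections$room)
  if (any(!is.finite(sections$duration)) || any(sections$duration <= 0))
    stop("all section durations must be positive and finite")
  ns <- nrow(sections)
  if (sections$label[1] != "prep" || sections$label[ns] != "A_post")
    stop("sections must begin with 'prep' and end with 'A_post'")
  mid <- sections$label[!(sections$label %in% c("prep", "A_pre", "A_post"))]
  if (length(mid)) {
    expected <- rep(c("B", "A"), length.out = length(mid))
    if (mid[1] != "B" || !all(mid == expected))
      stop("intermediate sections must alternate B, A, B, ... beginning with B")
  }
  if (!setequal(names(condition_temperatures), CONDITIONS))
    stop("condition_temperatures must have exactly the four condition labels")
  if (length(rest_plan) != ns || length(questionnaire_plan) != ns)
    stop("rest_plan and questionnaire_plan need one entry per section")
  structure(
    list(sections = sections,
         condition_temperatures = condition_temperatures,
         n_b_visits = sum(sections$label == "B"),
         rest_plan = as.integer(rest_plan),
         questionnaire_plan = as.integer(questionnaire_plan),
         rest_duration = rest_duration,
         questionnaire_duration = questionnaire_duration),
    class = "protocol_spec")
}

#' The packaged default session protocol
#'
#' Encodes the repeated-temperature-step session: 6 min preparation,
#' 14 min in room A, seven alternating 21-min stays (B, A, B, A, B, A, B
#' -- four visits to room B interleaved with three intermediate stays in
#' room A), and a final 14 min in room A.  Rest blocks (5 min) are placed
#' once in each of A_pre/A_post and three times in every intermediate
#' section, giving 23 heart-rate/HRV points; questionnaire blocks once in
#' prep, A_pre and A_post and four times per intermediate section, giving
#' 31 subjective-fatigue points.  Sub-range averaging of the continuous
#' skin-temperature stream (3 sub-ranges in A_pre/A_post, 4 in each
#' intermediate section) gives 34 points.
#'
#' Room temperatures: `T_26-26` (26, 26), `T_26-31` (26, 31),
#' `T_26-36` (26, 36) and `T_21-36` (21, 36) degC.
#'
#' @return A [protocol_spec()] object.
#' @examples
#' spec <- default_protocol()
#' nrow(build_grid(spec, "skin")$points)  # 34
#' @export
default_protocol <- function() {
  labels <- c("prep", "A_pre", rep(c("B", "A"), length.out = 7), "A_post")
  rooms <- ifelse(labels == "B", "B", "A")
  durations <- c(6, 14, rep(21, 7), 14)
  sections <- data.frame(label = labels, duration = durations, room = rooms,
                         stringsAsFactors = FALSE)
  is_mid <- !(labels %in% c("prep", "A_pre", "A_post"))
  rest_plan <- ifelse(labels %in% c("A_pre", "A_post"), 1L,
                      ifelse(is_mid, 3L, 0L))
  q_plan <- ifelse(is_mid, 4L, 1L)
  protocol_spec(
    sections = sections,
    condition_temperatures = list(
      "T_26-26" = c(26, 26), "T_26-31" = c(26, 31),
      "T_26-36" = c(26, 36), "T_21-36" = c(21, 36)),
    rest_plan = rest_plan,
    questionnaire_plan = q_plan)
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("Temperature-step session protocol\n")
  cat(sprintf("  %d sections, %d room-B visits, total %g min\n",
              nrow(x$sections), x$n_b_visits, sum(x$sections$duration)))
  cat(sprintf("  rest blocks: %d x %g min; questionnaire blocks: %d\n",
              sum(x$rest_plan), x$rest_duration, sum(x$questionnaire_plan)))
  for (cc in CONDITIONS) {
    tt <- x$condition_temperatures[[cc]]
    cat(sprintf("  %-8s rooms (A, B) = (%g, %g) degC\n", cc, tt[1], tt[2]))
  }
  invisible(x)
}

# evenly-spaced block midpoints: k blocks of width wd inside [start, start+D]
block_windows <- function(start, D, k, wd) {
  if (k == 0L) return(NULL)
  centre <- start + D * (2 * seq_len(k) - 1) / (2 * k)
  wd <- min(wd, D / k)
  data.frame(minutes = centre, window_start = centre - wd / 2,
             window_end = centre + wd / 2)
}

#' Build the measurement time grid for one modality
#'
#' The skin-temperature grid splits the first and last room-A sections
#' into 3 equal averaging sub-ranges and every intermediate section into
#' 4; the heart-rate/HRV grids place one point per rest block; the
#' subjective-fatigue (VAS) grid one point per questionnaire block.  Grid
#' midpoints are the arithmetic centres of the averaged sub-ranges or
#' blocks.  The grid `period` is the number of points spanned by one
#' consecutive B+A room cycle; it is the summation length of the damped
#' periodic Environment recursion.
#'
#' @param spec a [protocol_spec()].
#' @param modality one of `"vas"`, `"skin"`, `"hr"`, `"hf"`, `"lfhf"`.
#' @return An object of class `"measurement_grid"`: a list with elements
#'   `modality`, `points` (data.frame `t`, `minutes`, `section`, `room`,
#'   `window_start`, `window_end`) and `period`.
#' @examples
#' g <- build_grid(default_protocol(), "hf")
#' nrow(g$points)  # 23
#' g$period        # 6
#' @export
build_grid <- function(spec, modality) {
  stopifnot(inherits(spec, "protocol_spec"))
  modality <- match.arg(modality, MODALITIES)
  sec <- spec$sections
  starts <- cumsum(c(0, sec$duration[-nrow(sec)]))
  rows <- list()
  per_section <- integer(nrow(sec))
  for (i in seq_len(nrow(sec))) {
    lab <- sec$label[i]; D <- sec$duration[i]; s0 <- starts[i]
    if (modality == "skin") {
      k <- if (lab %in% c("A_pre", "A_post")) 3L
           else if (lab %in% c("A", "B")) 4L else 0L
      if (k > 0L) {
        edges <- s0 + D * (0:k) / k
        w <- data.frame(minutes = (edges[-1] + edges[-(k + 1)]) / 2,
                        window_start = edges[-(k + 1)], window_end = edges[-1])
      } else w <- NULL
    } else if (modality %in% c("hr", "hf", "lfhf")) {
      k <- spec$rest_plan[i]
      w <- block_windows(s0, D, k, spec$rest_duration)
    } else { # vas
      k <- spec$questionnaire_plan[i]
      w <- block_windows(s0, D, k, spec$questionnaire_duration)
    }
    if (!is.null(w)) {
      w$section <- lab; w$room <- sec$room[i]
      rows[[length(rows) + 1L]] <- w
      per_section[i] <- nrow(w)
    }
  }
  pts <- do.call(rbind, rows)
  if (is.null(pts) || nrow(pts) < 2L)
    stop("grid for modality '", modality, "' has fewer than 2 points")
  pts <- pts[order(pts$minutes), c("minutes", "window_start", "window_end",
                                   "section", "room")]
  pts <- data.frame(t = seq_len(nrow(pts)), pts, row.names = NULL)
  # period: points across the first B visit plus the following section
  bpos <- which(sec$label == "B")
  if (length(bpos) >= 1L) {
    period <- per_section[bpos[1]]
    if (bpos[1] + 1L <= nrow(sec) && sec$label[bpos[1] + 1L] == "A")
      period <- period + per_section[bpos[1] + 1L]
    else
      period <- 2L * period
  } else period <- 2L
  period <- max(2L, period)
  structure(list(modality = modality, points = pts, period = as.integer(period)),
            class = "measurement_grid")
}

#' @export
print.measurement_grid <- function(x, ...) {
  cat(sprintf("Measurement grid: modality '%s', %d points, period %d\n",
              x$modality, nrow(x$points), x$period))
  print(utils::head(x$points, 4))
  if (nrow(x$points) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.measurement_grid <- function(x, ...) {
  data.frame(modality = x$modality, x$points[c("t", "minutes", "section", "room")],
             stringsAsFactors = FALSE)
}

#' Serialize a protocol specification to YAML
#'
#' @param spec a [protocol_spec()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(spec, path) {
  stopifnot(inherits(spec, "protocol_spec"))
  obj <- list(sections = as.list(spec$sections),
              condition_temperatures = spec$condition_temperatures,
              rest_plan = spec$rest_plan,
              questionnaire_plan = spec$questionnaire_plan,
              rest_duration = spec$rest_duration,
              questionnaire_duration = spec$questionnaire_duration)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a protocol specification from YAML
#'
#' @param path file written by [write_protocol()].
#' @return A [protocol_spec()].
#' @export
read_protocol <- function(path) {
  obj <- yaml::read_yaml(path)
  protocol_spec(
    sections = data.frame(label = unlist(obj$sections$label),
                          duration = unlist(obj$sections$duration),
                          room = unlist(obj$sections$room),
                          stringsAsFactors = FALSE),
    condition_temperatures = obj$condition_temperatures,
    rest_plan = unlist(obj$rest_plan),
    questionnaire_plan = unlist(obj$questionnaire_plan),
    rest_duration = obj$rest_duration,
    questionnaire_duration = obj$questionnaire_duration)
}
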