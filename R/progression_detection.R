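#' Detection configuration
#'
#' Collects every tunable of the event detector and of the per-second group
#' state it consumes. Defaults implement the conservative progression
#' definition: both the smoothed (5-min running average) polarization and
#' smoothed mean individual speed in the top decile of all data pooled over
#' the study, the group cohesive (at least 10 tracked individuals with a
#' conspecific within 50 m), a line formation (mean elongation over the run
#' above 1), and a minimum duration of 15 s.
#'
#' @param percentile_q pooled quantile defining "top" polarization/speed.
#' @param min_duration minimum event duration in seconds.
#' @param cohesion_radius,cohesion_min_count cohesion rule (metres, count).
#' @param smoothing_window running-average window in seconds.
#' @param elongation_min elongation criterion threshold (length/width ratio).
#' @param elongation_rule `"run_mean"` applies `elongation_min` to the mean
#'   elongation over a candidate run (a progression is elongated on average);
#'   `"per_second"` requires it second by second.
#' @param period_cutoff local clock time splitting daytime from late
#'   afternoon events, as "HH:MM".
#' @param merge_gap candidate runs separated by at most this many seconds are
#'   merged before the duration filter (default 0: no merging).
#' @param travel_window centroid displacement window for the travel
#'   direction, seconds.
#' @param min_displacement centroid displacement floor (m) under which the
#'   travel direction is undefined.
#' @param stationary_floor individual speed (m/s) below which a heading is
#'   undefined.
#' @param elongation_eps floor (m) for the perpendicular extent.
#' @return a `detection_config` list.
#' @export
detection_config <- function(percentile_q = 0.9,
                             min_duration = 15,
                             cohesion_radius = 50,
                             cohesion_min_count = 10,
                             smoothing_window = 300,
                             elongation_min = 1,
                             elongation_rule = c("run_mean", "per_second"),
                             period_cutoff = "16:00",
                             merge_gap = 0,
                             travel_window = 10,
                             min_displacement = 0.1,
                             stationary_floor = 0.05,
                             elongation_eps = 1) {
  stopifnot(percentile_q > 0, percentile_q < 1, min_duration >= 1,
            smoothing_window >= 1, merge_gap >= 0)
  structure(list(
    percentile_q = percentile_q,
    min_duration = min_duration,
    cohesion_radius = cohesion_radius,
    cohesion_min_count = cohesion_min_count,
    smoothing_window = smoothing_window,
    elongation_min = elongation_min,
    elongation_rule = match.arg(elongation_rule),
    period_cutoff = period_cutoff,
    merge_gap = merge_gap,
    travel_window = travel_window,
    min_displacement = min_displacement,
    stationary_floor = stationary_floor,
    elongation_eps = elongation_eps
  ), class = "detection_config")
}

#' Pooled percentile threshold
#'
#' The q-quantile of all finite values, using the linear-interpolation
#' quantile estimator (R type 7). The estimator is fixed and documented
#' because the choice moves detection thresholds.
#'
#' @param values numeric vector (typically a smoothed series pooled over the
#'   whole dataset).
#' @param q quantile in (0, 1).
#' @return threshold in the units of `values`.
#' @export
percentile_threshold <- function(values, q = 0.9) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("no finite values to take a quantile of", call. = FALSE)
  unname(stats::quantile(v, q, type = 7))
}

#' Detect group progression events
#'
#' Extracts maximal runs of seconds on which the smoothed polarization and
#' smoothed mean speed are at or above their pooled `percentile_q` thresholds
#' and the group is cohesive; runs separated by at most `merge_gap` seconds
#' are merged; runs whose mean elongation does not exceed `elongation_min`
#' or that are shorter than `min_duration` are discarded. Runs never span
#' day boundaries. Thresholds are computed from the smoothed series of
#' `state` pooled over all days, or can be supplied (e.g. to apply thresholds
#' calibrated on one dataset to another, or to screen new data against
#' study-derived thresholds).
#'
#' @param state a [group_state()] tibble.
#' @param config a [detection_config()]. Must match the config used for
#'   `state` (the smoothing window in particular).
#' @param thresholds optional `list(polarization =, speed =)` of fixed
#'   thresholds; when `NULL` they are the pooled `percentile_q` quantiles of
#'   the smoothed series.
#' @return tibble of events (`event_id`, `date`, `start_t`, `end_t`,
#'   `duration`, `period`, mean polarization/speed/elongation/length/width),
#'   with the thresholds used stored in attribute `"thresholds"`.
#' @export
detect_progressions <- function(state, config = detection_config(),
                                thresholds = NULL) {
  tz <- attr(state, "tz_offset") %||% 2
  if (is.null(thresholds)) {
    thresholds <- list(
      polarization = percentile_threshold(state$polarization_smooth,
                                          config$percentile_q),
      speed = percentile_threshold(state$speed_smooth, config$percentile_q)
    )
  }
  crit <- !is.na(state$polarization_smooth) &
    state$polarization_smooth >= thresholds$polarization &
    !is.na(state$speed_smooth) &
    state$speed_smooth >= thresholds$speed &
    state$cohesive
  if (config$elongation_rule == "per_second") {
    crit <- crit & !is.na(state$elongation) &
      state$elongation > config$elongation_min
  }

  events <- list()
  for (rows in day_blocks(state$day)) {
    runs <- find_runs(crit[rows])
    if (nrow(runs) == 0) next
    runs <- merge_runs(runs, config$merge_gap)
    for (k in seq_len(nrow(runs))) {
      idx <- rows[runs$start[k]:runs$end[k]]
      if (config$elongation_rule == "run_mean") {
        me <- mean(state$elongation[idx], na.rm = TRUE)
        if (!is.finite(me) || me <= config$elongation_min) next
      }
      if (length(idx) < config$min_duration) next
      events[[length(events) + 1]] <- tibble::tibble(
        date = state$day[idx[1]],
        start_t = state$t[idx[1]],
        end_t = state$t[idx[length(idx)]],
        duration = length(idx),
        mean_polarization = mean(state$polarization[idx], na.rm = TRUE),
        mean_speed = mean(state$mean_speed[idx], na.rm = TRUE),
        mean_elongation = mean(state$elongation[idx], na.rm = TRUE),
        mean_length = mean(state$length[idx], na.rm = TRUE),
        mean_width = mean(state$width[idx], na.rm = TRUE)
      )
    }
  }
  out <- if (length(events) > 0) dplyr::bind_rows(events) else
    tibble::tibble(date = integer(0), start_t = numeric(0), end_t = numeric(0),
                   duration = integer(0), mean_polarization = numeric(0),
                   mean_speed = numeric(0), mean_elongation = numeric(0),
                   mean_length = numeric(0), mean_width = numeric(0))
  out <- dplyr::arrange(out, .data$start_t)
  out$event_id <- if (nrow(out) > 0) sprintf("E%03d", seq_len(nrow(out))) else
    character(0)
  out$period <- label_period(out$start_t, tz_offset = tz,
                             cutoff = config$period_cutoff)
  out <- out[, c("event_id", "date", "start_t", "end_t", "duration", "period",
                 "mean_polarization", "mean_speed", "mean_elongation",
                 "mean_length", "mean_width")]
  attr(out, "thresholds") <- thresholds
  attr(out, "tz_offset") <- tz
  out
}

find_runs <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

merge_runs <- function(runs, merge_gap) {
  if (merge_gap <= 0 || nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (k in seq(2, nrow(runs))) {
    if (runs$start[k] - out$end[nrow(out)] - 1 <= merge_gap) {
      out$end[nrow(out)] <- runs$end[k]
    } else {
      out <- rbind(out, runs[k, , drop = FALSE])
    }
  }
  out
}

#' Label events by day period
#'
#' Daytime if the event *starts* before the cutoff in local clock time
#' (default 16:00), late afternoon otherwise. The start-time rule decides
#' events straddling the cutoff.
#'
#' @param start_t event start, UTC epoch seconds.
#' @param tz_offset display offset from UTC in hours.
#' @param cutoff local clock time "HH:MM".
#' @return character vector: "daytime" or "late_afternoon".
#' @export
label_period <- function(start_t, tz_offset = 2, cutoff = "16:00") {
  hm <- as.numeric(strsplit(cutoff, ":")[[1]])
  cut_s <- hm[1] * 3600 + hm[2] * 60
  ifelse(local_second(start_t, tz_offset) < cut_s, "daytime", "late_afternoon")
}

#' Summaries of detected events
#'
#' @param events tibble from [detect_progressions()].
#' @return list with `per_day` (events and hours per day) and `overall`
#'   (one-row tibble: counts, events/day mean and SD, duration mean and max
#'   in minutes, total hours, geometry means).
#' @export
summarize_events <- function(events) {
  if (nrow(events) == 0) {
    return(list(
      per_day = tibble::tibble(date = integer(0), n_events = integer(0),
                               total_hours = numeric(0)),
      overall = tibble::tibble(n_events = 0L, n_days = 0L,
                               events_per_day_mean = NA_real_,
                               events_per_day_sd = NA_real_,
                               duration_mean_min = NA_real_,
                               duration_max_min = NA_real_,
                               total_hours = 0,
                               mean_length = NA_real_, mean_width = NA_real_,
                               mean_elongation = NA_real_)
    ))
  }
  per_day <- dplyr::summarise(
    dplyr::group_by(events, .data$date),
    n_events = dplyr::n(),
    total_hours = sum(.data$duration) / 3600,
    .groups = "drop"
  )
  overall <- tibble::tibble(
    n_events = nrow(events),
    n_days = nrow(per_day),
    events_per_day_mean = mean(per_day$n_events),
    events_per_day_sd = stats::sd(per_day$n_events),
    duration_mean_min = mean(events$duration) / 60,
    duration_max_min = max(events$duration) / 60,
    total_hours = sum(events$duration) / 3600,
    mean_length = mean(events$mean_length),
    mean_width = mean(events$mean_width),
    mean_elongation = mean(events$mean_elongation)
  )
  list(per_day = per_day, overall = overall)
}
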