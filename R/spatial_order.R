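#' Project positions into the moving group frame
#'
#' The group frame has its origin at the group centroid, its x-axis along
#' the direction of motion (front positive) and its y-axis 90 degrees
#' counter-clockwise from it (left positive). `front_back` is the signed
#' distance of an individual from the centroid along the travel axis — the
#' "spatial position"; its absolute value is the raw spatial interiority
#' (small values = central along the travel axis).
#'
#' @param x,y individual positions (metres).
#' @param cx,cy group centroid.
#' @param direction travel unit vector `c(dx, dy)`.
#' @return tibble with columns front_back, left_right.
#' @export
project_into_group_frame <- function(x, y, cx, cy, direction) {
  if (anyNA(direction)) stop("travel direction undefined", call. = FALSE)
  tibble::tibble(
    front_back = (x - cx) * direction[1] + (y - cy) * direction[2],
    left_right = -(x - cx) * direction[2] + (y - cy) * direction[1]
  )
}

#' Per-second spatial order records inside progressions
#'
#' For every second of every event with a defined travel direction, projects
#' each present individual into the group frame. Seconds with an undefined
#' direction are skipped. Because the centroid is the mean of the same
#' individuals being projected, `front_back` averages to zero across the
#' individuals present at each second.
#'
#' @param traj a `traj_table`.
#' @param state the [group_state()] of `traj`.
#' @param events events from [detect_progressions()].
#' @return tibble: event_id, t, id, front_back, left_right, interiority_raw.
#' @export
order_records <- function(traj, state, events) {
  w <- traj_wide(traj)
  stopifnot(identical(w$t, state$t))
  recs <- vector("list", nrow(events))
  for (k in seq_len(nrow(events))) {
    idx <- which(state$t >= events$start_t[k] & state$t <= events$end_t[k])
    idx <- idx[!is.na(state$dir_x[idx])]
    if (length(idx) == 0) next
    dx <- state$dir_x[idx]; dy <- state$dir_y[idx]
    RX <- w$X[idx, , drop = FALSE] - state$cx[idx]
    RY <- w$Y[idx, , drop = FALSE] - state$cy[idx]
    FB <- RX * dx + RY * dy        # column-wise recycling over time
    LR <- -RX * dy + RY * dx
    present <- which(!is.na(FB), arr.ind = TRUE)
    recs[[k]] <- tibble::tibble(
      event_id = events$event_id[k],
      t = state$t[idx][present[, 1]],
      id = w$ids[present[, 2]],
      front_back = FB[present],
      left_right = LR[present]
    )
  }
  out <- dplyr::bind_rows(recs)
  if (nrow(out) == 0) {
    out <- tibble::tibble(event_id = character(0), t = numeric(0),
                          id = character(0), front_back = numeric(0),
                          left_right = numeric(0))
  }
  out$interiority_raw <- abs(out$front_back)
  dplyr::arrange(out, .data$event_id, .data$t, .data$id)
}

#' Aggregate spatial order to the progression level
#'
#' One row per (event, individual): mean and sample SD of the per-second
#' spatial position, and mean raw interiority. Aggregation to the event
#' level is what breaks the strong second-to-second autocorrelation before
#' any mixed model is fitted.
#'
#' @param records tibble from [order_records()].
#' @param events optional events table; when given, `period` and `date` are
#'   joined on.
#' @return tibble: event_id, id, n_seconds, mean_position, sd_position,
#'   mean_interiority (+ period, date).
#' @export
aggregate_event_positions <- function(records, events = NULL) {
  agg <- dplyr::summarise(
    dplyr::group_by(records, .data$event_id, .data$id),
    n_seconds = dplyr::n(),
    mean_position = mean(.data$front_back),
    sd_position = if (dplyr::n() >= 2) stats::sd(.data$front_back) else NA_real_,
    mean_interiority = mean(.data$interiority_raw),
    .groups = "drop"
  )
  if (!is.null(events)) {
    agg <- dplyr::left_join(agg,
                            events[, c("event_id", "period", "date")],
                            by = "event_id")
  }
  agg
}

#' Mean front-to-rear rank per individual and day period
#'
#' Within each event, individuals are ranked by mean spatial position
#' (rank 1 = most frontal); ties receive average ranks. With
#' `method = "per_event"` (default) the per-event ranks are averaged within
#' each period for each individual; with `method = "period_mean"` the ranks
#' of the per-period mean positions are reported instead.
#'
#' @param aggregates tibble from [aggregate_event_positions()] including a
#'   `period` column.
#' @param method rank aggregation rule.
#' @return tibble: id, one rank column per period present.
#' @export
period_rank_table <- function(aggregates,
                              method = c("per_event", "period_mean")) {
  method <- match.arg(method)
  if (!"period" %in% names(aggregates)) {
    stop("aggregates must carry a 'period' column", call. = FALSE)
  }
  if (method == "per_event") {
    ranked <- dplyr::mutate(
      dplyr::group_by(aggregates, .data$event_id),
      rank = rank(-.data$mean_position, ties.method = "average")
    )
    long <- dplyr::summarise(
      dplyr::group_by(dplyr::ungroup(ranked), .data$id, .data$period),
      mean_rank = mean(.data$rank), .groups = "drop"
    )
  } else {
    bymean <- dplyr::summarise(
      dplyr::group_by(aggregates, .data$id, .data$period),
      mp = mean(.data$mean_position), .groups = "drop"
    )
    long <- dplyr::mutate(
      dplyr::group_by(bymean, .data$period),
      mean_rank = rank(-.data$mp, ties.method = "average")
    )
    long <- dplyr::ungroup(long)[, c("id", "period", "mean_rank")]
  }
  tidyr::pivot_wider(long, names_from = "period", values_from = "mean_rank")
}

#' Within-event positional variability
#'
#' Sample SD of the per-second spatial position for each (event, individual)
#' with at least two seconds of data; the response of the positional
#' variation mixed model.
#'
#' @param records tibble from [order_records()].
#' @return tibble: event_id, id, n_seconds, sd_position.
#' @export
positional_variability <- function(records) {
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$event_id, .data$id),
    n_seconds = dplyr::n(),
    sd_position = if (dplyr::n() >= 2) stats::sd(.data$front_back) else NA_real_,
    .groups = "drop"
  )
  out[!is.na(out$sd_position), ]
}
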