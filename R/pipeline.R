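#' Seconds-level Jaccard overlap of two event lists
#'
#' Treats each event list as the set of seconds covered by its intervals
#' (closed `[start_t, end_t]`) and returns |intersection| / |union|: the
#' natural recovery score of a detector against a planted ground truth.
#'
#' @param a,b event tibbles with `start_t`, `end_t` columns.
#' @return Jaccard index in `[0, 1]` (1 when both lists are empty).
#' @export
event_overlap_jaccard <- function(a, b) {
  sec <- function(ev) {
    if (nrow(ev) == 0) return(numeric(0))
    unlist(Map(seq, ev$start_t, ev$end_t))
  }
  sa <- sec(a)
  sb <- sec(b)
  u <- length(union(sa, sb))
  if (u == 0) return(1)
  length(intersect(sa, sb)) / u
}

#' Run the full progression-analysis pipeline
#'
#' Orchestrates the stages in order: cleaning, per-second group state,
#' event detection, spatial order in the group frame, proximity networks
#' and centrality, nearest-neighbour chains and consistency, and the
#' mixed-model battery. Optionally writes every output table to CSV with a
#' small metadata header. The pipeline contains no randomness: identical
#' inputs and configuration give identical outputs.
#'
#' @param traj a `traj_table` (already cleaned, or set `clean = TRUE`).
#' @param attrs attribute table (id, sex, dominance).
#' @param config a [detection_config()].
#' @param clean run [filter_and_interpolate()] first.
#' @param max_speed,max_gap cleaning parameters when `clean = TRUE`.
#' @param transform distance-to-association transform for centrality.
#' @param thresholds optional fixed detection thresholds.
#' @param out_dir optional output directory for CSV exports.
#' @return a `progression_report`: list with `state`, `events`,
#'   `event_summary`, `records`, `aggregates`, `rank_table`, `networks`,
#'   `centrality`, `centrality_model`, `pair_table`, `chains`,
#'   `consistency`, `battery`, `thresholds`.
#' @export
run_pipeline <- function(traj, attrs, config = detection_config(),
                         clean = FALSE, max_speed = 10, max_gap = 60,
                         transform = "inverse", thresholds = NULL,
                         out_dir = NULL) {
  attrs <- validate_attributes(attrs)
  missing_ids <- setdiff(unique(traj$id), attrs$id)
  if (length(missing_ids) > 0) {
    stop("pipeline stage 'attributes': no attributes for individual(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (clean) {
    traj <- stage("clean", filter_and_interpolate(traj, max_speed, max_gap))
  }
  state <- stage("groupstate", group_state(traj, config))
  events <- stage("detect", detect_progressions(state, config, thresholds))
  event_summary <- summarize_events(events)
  records <- stage("order", order_records(traj, state, events))
  aggregates <- aggregate_event_positions(records, events)
  rank_table <- if (nrow(aggregates) > 0) period_rank_table(aggregates) else NULL
  variability <- positional_variability(records)

  prog_mask <- progression_mask(state, events)
  rest_mask <- rest_of_day_mask(state, events)
  networks <- stage("networks", list(
    progression = pairwise_mean_distances(traj, prog_mask, "progression"),
    rest_of_day = pairwise_mean_distances(traj, rest_mask, "rest_of_day")
  ))
  centrality <- stage("centrality", dplyr::bind_rows(lapply(networks, function(nw) {
    eigenvector_centrality(to_association_weights(nw, transform))
  })))
  centrality_model <- stage("centrality_model",
                            centrality_vs_dominance(centrality, attrs))
  pair_table <- stage("pairs", pairwise_distance_by_date(traj, state, events))

  chains <- stage("neighbours", nearest_neighbour_series(traj, events))
  consistency <- stage("consistency",
                       consistency_model_data(chains, attrs, events))
  battery <- stage("models", model_battery(aggregates, pair_table,
                                           variability, consistency,
                                           attrs, events))
  report <- structure(list(
    state = state, events = events, event_summary = event_summary,
    records = records, aggregates = aggregates, rank_table = rank_table,
    variability = variability, networks = networks, centrality = centrality,
    centrality_model = centrality_model, pair_table = pair_table,
    chains = chains, consistency = consistency, battery = battery,
    thresholds = attr(events, "thresholds"), config = config
  ), class = "progression_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.progression_report <- function(x, ...) {
  ov <- x$event_summary$overall
  cat(sprintf("<progression_report> %d events over %d day(s), %.2f h total\n",
              ov$n_events, ov$n_days, ov$total_hours))
  cat(sprintf("  thresholds: polarization >= %.3f, speed >= %.3f m/s\n",
              x$thresholds$polarization, x$thresholds$speed))
  cat(sprintf("  ICC of spatial position: %.3f\n", x$battery$icc_position))
  invisible(x)
}

#' Write a pipeline report to CSV files
#'
#' Each table is written with a comment header recording the package
#' version, detection thresholds and configuration, so a report directory
#' is self-describing.
#'
#' @param report a `progression_report`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    sprintf("# troopline %s",
            as.character(utils::packageVersion("troopline"))),
    sprintf("# threshold_polarization: %.6f", report$thresholds$polarization),
    sprintf("# threshold_speed: %.6f", report$thresholds$speed),
    sprintf("# percentile_q: %s", report$config$percentile_q),
    sprintf("# smoothing_window: %s", report$config$smoothing_window)
  )
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(as.data.frame(df), con, row.names = FALSE)
    close(con)
  }
  emit(report$state, "group_state")
  emit(report$events, "events")
  emit(report$aggregates, "order_aggregates")
  if (!is.null(report$rank_table)) emit(report$rank_table, "period_ranks")
  emit(report$variability, "positional_variability")
  emit(as_edge_table(report$networks$progression), "network_progression")
  emit(as_edge_table(report$networks$rest_of_day), "network_rest_of_day")
  emit(report$centrality, "centrality")
  emit(report$centrality_model, "centrality_model")
  emit(report$pair_table, "pair_distances")
  emit(report$consistency, "consistency")
  emit(battery_summary(report$battery), "model_battery")
  invisible(dir)
}
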