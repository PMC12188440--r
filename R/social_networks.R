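#' Seconds of cohesive non-progression time
#'
#' The "rest of day" context: seconds on which the group is cohesive and
#' which fall inside no detected event. Together with the progression
#' seconds and the excluded (non-cohesive, non-event) seconds this
#' partitions the time grid.
#'
#' @param state a [group_state()] tibble.
#' @param events events from [detect_progressions()].
#' @return logical vector aligned to the rows of `state`.
#' @export
rest_of_day_mask <- function(state, events) {
  in_event <- rep(FALSE, nrow(state))
  for (k in seq_len(nrow(events))) {
    in_event <- in_event |
      (state$t >= events$start_t[k] & state$t <= events$end_t[k])
  }
  state$cohesive & !in_event
}

#' Seconds inside detected events
#' @inheritParams rest_of_day_mask
#' @return logical vector aligned to the rows of `state`.
#' @export
progression_mask <- function(state, events) {
  in_event <- rep(FALSE, nrow(state))
  for (k in seq_len(nrow(events))) {
    in_event <- in_event |
      (state$t >= events$start_t[k] & state$t <= events$end_t[k])
  }
  in_event
}

#' Mean pairwise-distance network
#'
#' For every pair of individuals, the mean Euclidean distance over the
#' selected seconds on which both were tracked, together with the number of
#' seconds contributing to each edge. Distance edges are the raw spatial
#' associations; see [to_association_weights()] for the monotone-decreasing
#' transform used before centrality.
#'
#' @param traj a `traj_table`.
#' @param seconds either a numeric vector of timestamps to include or a
#'   logical mask aligned to the pooled time grid (as returned by
#'   [rest_of_day_mask()] on the matching [group_state()]).
#' @param context label stored with the network, e.g. "progression" or
#'   "rest_of_day".
#' @return a `distance_network`: list with `context`, `ids`, symmetric
#'   matrices `mean` (m) and `n_seconds`.
#' @export
pairwise_mean_distances <- function(traj, seconds, context = "all") {
  w <- traj_wide(traj)
  keep <- if (is.logical(seconds)) {
    if (length(seconds) != length(w$t)) {
      stop("logical mask not aligned to the time grid", call. = FALSE)
    }
    seconds
  } else {
    w$t %in% seconds
  }
  n <- length(w$ids)
  M <- matrix(NA_real_, n, n, dimnames = list(w$ids, w$ids))
  Ns <- matrix(0L, n, n, dimnames = list(w$ids, w$ids))
  X <- w$X[keep, , drop = FALSE]
  Y <- w$Y[keep, , drop = FALSE]
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- sqrt((X[, i] - X[, j])^2 + (Y[, i] - Y[, j])^2)
      ok <- !is.na(d)
      Ns[i, j] <- Ns[j, i] <- sum(ok)
      if (any(ok)) M[i, j] <- M[j, i] <- mean(d[ok])
    }
  }
  structure(list(context = context, ids = w$ids, mean = M, n_seconds = Ns),
            class = "distance_network")
}

#' @export
print.distance_network <- function(x, ...) {
  cat(sprintf("<distance_network> context=%s, %d nodes, %d defined edges\n",
              x$context, length(x$ids),
              sum(!is.na(x$mean[upper.tri(x$mean)]))))
  invisible(x)
}

#' Per-date pairwise mean distances in two contexts
#'
#' Long-format table of mean pairwise distances per (pair, date), computed
#' separately inside progressions and during cohesive rest-of-day time —
#' the observation unit of the spatial-association mixed model (progression
#' distance against rest-of-day distance with pair and date as random
#' factors).
#'
#' @param traj a `traj_table`.
#' @param state the matching [group_state()].
#' @param events events from [detect_progressions()].
#' @return tibble: date, id_a, id_b, pair, progression_dist, rest_dist,
#'   n_progression, n_rest.
#' @export
pairwise_distance_by_date <- function(traj, state, events) {
  w <- traj_wide(traj)
  stopifnot(identical(w$t, state$t))
  prog <- progression_mask(state, events)
  rest <- rest_of_day_mask(state, events)
  n <- length(w$ids)
  pairs <- utils::combn(n, 2)
  rows <- list()
  for (d in unique(w$day)) {
    in_day <- w$day == d
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      dij <- sqrt((w$X[, i] - w$X[, j])^2 + (w$Y[, i] - w$Y[, j])^2)
      dp <- dij[in_day & prog]
      dr <- dij[in_day & rest]
      rows[[length(rows) + 1]] <- tibble::tibble(
        date = d,
        id_a = w$ids[i], id_b = w$ids[j],
        pair = paste(w$ids[i], w$ids[j], sep = "-"),
        progression_dist = if (any(!is.na(dp))) mean(dp, na.rm = TRUE) else NA_real_,
        rest_dist = if (any(!is.na(dr))) mean(dr, na.rm = TRUE) else NA_real_,
        n_progression = sum(!is.na(dp)),
        n_rest = sum(!is.na(dr))
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Distance-to-association transform
#'
#' Converts distance edges into association weights so that *small*
#' distances mean *strong* association, as eigenvector centrality requires.
#' The transform must be monotone decreasing; its exact form is a
#' configurable modelling choice recorded on the result. Available:
#' `"inverse"` (w = 1/d, default), `"max_minus"` (w = max(d) - d), and
#' `"exp"` (w = exp(-d/sigma), sigma defaulting to the mean distance).
#'
#' @param net a `distance_network`.
#' @param transform transform name.
#' @param sigma length scale for the exponential transform, metres.
#' @return a `distance_network` with a `weight` matrix and the transform
#'   recorded.
#' @export
to_association_weights <- function(net,
                                   transform = c("inverse", "max_minus", "exp"),
                                   sigma = NULL) {
  transform <- match.arg(transform)
  D <- net$mean
  off <- row(D) != col(D)
  defined <- off & !is.na(D)
  if (transform == "inverse" && any(D[defined] == 0)) {
    stop("zero distance edge: 1/d undefined; use the 'exp' or 'max_minus' ",
         "transform or add a distance offset", call. = FALSE)
  }
  W <- matrix(0, nrow(D), ncol(D), dimnames = dimnames(D))
  W[defined] <- switch(transform,
    inverse = 1 / D[defined],
    max_minus = max(D[defined]) - D[defined],
    exp = exp(-D[defined] / (sigma %||% mean(D[defined])))
  )
  net$weight <- W
  net$transform <- transform
  net
}

#' Eigenvector centrality of an association network
#'
#' Entries of the leading eigenvector of the symmetric non-negative weight
#' matrix (Perron-Frobenius guarantees a non-negative vector), scaled so the
#' maximum is 1. A node scores high when it is strongly connected to nodes
#' that are themselves strongly connected. Undefined (never co-tracked)
#' edges are disallowed: a silent zero weight would fabricate social
#' avoidance, so they raise an error instead. Disconnected networks raise an
#' error naming the components.
#'
#' @param net a `distance_network` with weights from
#'   [to_association_weights()].
#' @return tibble: id, centrality (max-normalized), context.
#' @export
eigenvector_centrality <- function(net) {
  if (is.null(net$weight)) {
    stop("network has no association weights; call to_association_weights()",
         call. = FALSE)
  }
  off <- row(net$mean) != col(net$mean)
  if (any(is.na(net$mean[off]))) {
    bad <- which(is.na(net$mean) & off, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("undefined edge(s) (pair never co-tracked): ",
         paste(net$ids[bad[, 1]], net$ids[bad[, 2]],
               sep = "-", collapse = ", "), call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(net$weight, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop("association network is disconnected; components: ",
         paste(tapply(net$ids, comp$membership, paste, collapse = ","),
               collapse = " | "), call. = FALSE)
  }
  ## leading eigenvector via a full symmetric eigendecomposition:
  ## deterministic (unlike restarted iterative solvers), and trivial at
  ## group-tracking scale. Perron-Frobenius makes the leading vector
  ## single-signed; it is flipped positive and max-normalized.
  es <- eigen(net$weight, symmetric = TRUE)
  v <- es$vectors[, which.max(es$values)]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  tibble::tibble(id = net$ids, centrality = v / max(v),
                 context = net$context)
}

#' Linear model of centrality against dominance
#'
#' Ordinary least squares of eigenvector centrality on the standardized
#' dominance rank, one observation per individual, fitted per context.
#'
#' @param centrality tibble from [eigenvector_centrality()].
#' @param attrs attribute table with id and dominance.
#' @return tibble: context, slope, se, p, r_squared, n.
#' @export
centrality_vs_dominance <- function(centrality, attrs) {
  df <- dplyr::inner_join(centrality, attrs, by = "id")
  dplyr::bind_rows(lapply(split(df, df$context), function(d) {
    if (nrow(d) < 3) stop("need at least 3 individuals", call. = FALSE)
    if (stats::var(d$dominance) == 0) {
      stop("dominance is constant; slope undefined", call. = FALSE)
    }
    fit <- stats::lm(centrality ~ dominance, data = d)
    sm <- summary(fit)
    tibble::tibble(context = d$context[1],
                   slope = sm$coefficients["dominance", 1],
                   se = sm$coefficients["dominance", 2],
                   p = sm$coefficients["dominance", 4],
                   r_squared = sm$r.squared,
                   n = nrow(d))
  }))
}

#' Export a distance network as an edge list
#' @param net a `distance_network`.
#' @return tibble: id_a, id_b, mean_dist, n_seconds (+ weight if present).
#' @export
as_edge_table <- function(net) {
  n <- length(net$ids)
  pairs <- utils::combn(n, 2)
  out <- tibble::tibble(
    id_a = net$ids[pairs[1, ]],
    id_b = net$ids[pairs[2, ]],
    mean_dist = net$mean[t(pairs)],
    n_seconds = net$n_seconds[t(pairs)]
  )
  if (!is.null(net$weight)) out$weight <- net$weight[t(pairs)]
  out$context <- net$context
  out
}
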