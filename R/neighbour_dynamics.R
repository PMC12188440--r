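#' Nearest-neighbour identity time series within progressions
#'
#' For each focal individual and each second of each event on which the
#' focal and at least one other individual were tracked, the identity of
#' the nearest tracked conspecific. Exact distance ties are broken towards
#' the lexicographically first id, for reproducibility.
#'
#' @param traj a `traj_table`.
#' @param events events from [detect_progressions()] (or the ground-truth
#'   event list of a synthetic dataset).
#' @param focal optional character vector restricting the focal individuals.
#' @return a `neighbour_chain` tibble: focal, event_id, t, neighbour.
#' @export
nearest_neighbour_series <- function(traj, events, focal = NULL) {
  w <- traj_wide(traj)
  focal <- focal %||% w$ids
  keep <- rep(FALSE, length(w$t))
  ev_id <- rep(NA_character_, length(w$t))
  for (k in seq_len(nrow(events))) {
    sel <- w$t >= events$start_t[k] & w$t <= events$end_t[k]
    keep <- keep | sel
    ev_id[sel] <- events$event_id[k]
  }
  X <- w$X[keep, , drop = FALSE]
  Y <- w$Y[keep, , drop = FALSE]
  tt <- w$t[keep]
  ee <- ev_id[keep]
  out <- list()
  for (f in focal) {
    fi <- match(f, w$ids)
    others <- setdiff(seq_along(w$ids), fi)   # ids sorted => lexicographic
    D <- matrix(Inf, nrow(X), length(others))
    for (k in seq_along(others)) {
      j <- others[k]
      d <- sqrt((X[, fi] - X[, j])^2 + (Y[, fi] - Y[, j])^2)
      D[, k] <- ifelse(is.na(d), Inf, d)
    }
    any_other <- rowSums(is.finite(D)) > 0
    ok <- !is.na(X[, fi]) & any_other
    if (!any(ok)) next
    nn_col <- max.col(-D[ok, , drop = FALSE], ties.method = "first")
    out[[f]] <- tibble::tibble(
      focal = f, event_id = ee[ok], t = tt[ok],
      neighbour = w$ids[others][nn_col]
    )
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(focal = character(0), event_id = character(0),
                          t = numeric(0), neighbour = character(0))
  }
  class(res) <- c("neighbour_chain", class(res))
  res
}

## Consecutive within-event transitions of one focal's chain: a transition
## exists between seconds t and t+1 of the same event only. Gaps (missing
## seconds) and event boundaries never contribute transitions — spanning
## them would fabricate neighbour switches that were never observed.
chain_transitions <- function(chain) {
  chain <- dplyr::arrange(chain, .data$event_id, .data$t)
  same_event <- chain$event_id[-nrow(chain)] == chain$event_id[-1]
  consecutive <- diff(chain$t) == 1
  use <- same_event & consecutive
  tibble::tibble(from = chain$neighbour[-nrow(chain)][use],
                 to = chain$neighbour[-1][use])
}

#' First-order Markov transition matrix of nearest-neighbour identity
#'
#' States are the neighbour identities observed in the focal's chain;
#' transitions are counted between consecutive seconds within one event
#' only. Probabilities are row-normalized counts; rows without outgoing
#' transitions have zero counts and undefined probabilities.
#'
#' @param chain a `neighbour_chain` restricted to (or filtered for) one
#'   focal individual.
#' @return a `transition_matrix`: list with focal, states, counts, probs.
#' @export
transition_matrix <- function(chain) {
  stopifnot(length(unique(chain$focal)) <= 1)
  if (nrow(chain) < 2) {
    return(structure(list(focal = unique(chain$focal), states = character(0),
                          counts = matrix(0, 0, 0), probs = matrix(0, 0, 0)),
                     class = "transition_matrix"))
  }
  tr <- chain_transitions(chain)
  states <- sort(unique(chain$neighbour))
  counts <- matrix(0L, length(states), length(states),
                   dimnames = list(states, states))
  if (nrow(tr) > 0) {
    tab <- table(factor(tr$from, states), factor(tr$to, states))
    counts[] <- as.integer(tab)
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(list(focal = chain$focal[1], states = states,
                 counts = counts, probs = probs),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> focal=%s, %d states, %d transitions\n",
              x$focal %||% "?", length(x$states), sum(x$counts)))
  invisible(x)
}

#' Per-second consistency of one specific nearest neighbour
#'
#' The diagonal entry P(neighbour -> neighbour) of the focal's transition
#' matrix: the per-second probability that the focal keeps that specific
#' individual as its nearest neighbour.
#'
#' @param tm a [transition_matrix()].
#' @param neighbour neighbour id.
#' @return probability, or `NA` if the neighbour state is unseen or has no
#'   outgoing transition.
#' @export
pair_consistency <- function(tm, neighbour) {
  if (!neighbour %in% tm$states) return(NA_real_)
  tm$probs[neighbour, neighbour]
}

#' Overall per-second nearest-neighbour consistency of a focal
#'
#' Fraction of within-event consecutive second pairs on which the focal's
#' nearest-neighbour identity is unchanged. Equals the count-weighted mean
#' of the diagonal of the focal's transition matrix.
#'
#' @param chain a `neighbour_chain` for one focal.
#' @return probability, or `NA` with no within-event transition.
#' @export
focal_consistency <- function(chain) {
  tr <- chain_transitions(chain)
  if (nrow(tr) == 0) return(NA_real_)
  mean(tr$from == tr$to)
}

#' Long-format consistency table for the mixed-model battery
#'
#' Per (focal, neighbour, event): the per-second probability of keeping that
#' neighbour, computed from the transitions of that event alone, joined with
#' the focal's dominance and sex and the event's date. Event-level
#' granularity is what lets date and progression id enter the consistency
#' model as random factors.
#'
#' @param chains a `neighbour_chain` (all focals).
#' @param attrs attribute table (id, sex, dominance).
#' @param events events table supplying the event dates.
#' @return tibble: focal (as `id`), neighbour, event_id, date, consistency,
#'   n_transitions, dominance, sex.
#' @export
consistency_model_data <- function(chains, attrs, events = NULL) {
  groups <- split(chains, list(chains$focal, chains$event_id), drop = TRUE)
  rows <- lapply(groups, function(g) {
    tr <- chain_transitions(g)
    if (nrow(tr) == 0) return(NULL)
    per <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(from = tr$from, stay = tr$from == tr$to),
                      .data$from),
      consistency = mean(.data$stay),
      n_transitions = dplyr::n(), .groups = "drop"
    )
    tibble::tibble(id = g$focal[1], neighbour = per$from,
                   event_id = g$event_id[1],
                   consistency = per$consistency,
                   n_transitions = per$n_transitions)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(id = character(0), neighbour = character(0),
                          event_id = character(0), consistency = numeric(0),
                          n_transitions = integer(0)))
  }
  out <- dplyr::left_join(out, attrs, by = "id")
  if (!is.null(events)) {
    out <- dplyr::left_join(out, events[, c("event_id", "date")],
                            by = "event_id")
  }
  out
}
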