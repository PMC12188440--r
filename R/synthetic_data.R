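#' Simulation configuration
#'
#' Study conditions for the synthetic trajectory generator: 13 individuals
#' tracked at 1 Hz through a 08:00-20:00 local day window, a planted
#' affiliation structure in which higher-ranked individuals have more and
#' stronger ties, episodic line-formation progressions (about 3 per day,
#' duration approximately exponential with mean 640 s) embedded in
#' slow foraging drift, and autocorrelated GPS error of a few metres.
#'
#' Noise model. GPS error is a per-coordinate AR(1) process
#' (`gps_noise_rho`, stationary SD `gps_noise_sd`): satellite error drifts
#' over tens of seconds rather than resampling every fix, which is also what
#' keeps finite-difference velocities usable at 1 Hz. Progressions build up
#' and dissolve over `taper` seconds inside their boundaries — groups string
#' out into a line over minutes, not instantaneously — with a
#' square-root-shaped speed/formation ramp.
#'
#' Order structure. `structure = "affiliation"` plants each individual's
#' habitual slot along the travel axis from the affiliation matrix (see
#' [plant_order()]) and couples affiliation to dominance;
#' `structure = "null"` removes all structure: constant affiliation,
#' freshly shuffled order every event, dominance decoupled from everything —
#' the negative control for the inferential battery.
#'
#' @param n_individuals number of tracked individuals.
#' @param n_days number of tracking days.
#' @param day_start,day_end local clock hours bounding the daily window.
#' @param tz_offset display offset from UTC in hours.
#' @param base_date first tracking day, as Date or "YYYY-MM-DD".
#' @param dominance standardized ranks in `[0, 1]`; default evenly spaced.
#' @param sex character vector; default two males (the top-ranked and one
#'   mid-high-ranked individual), the rest female.
#' @param affiliation_base,affiliation_slope,affiliation_noise_sd affiliation
#'   model: `A_ij = base + slope * min(rank_i, rank_j) + noise`.
#' @param events_per_day_mean Poisson mean of progressions per day.
#' @param duration_mean,duration_min,duration_max progression duration model:
#'   exponential with this mean, truncated to `[min, max]` seconds.
#' @param progression_speed travel speed at full progression, m/s.
#' @param formation_length,formation_width target extent of the line
#'   formation along and across the travel direction, metres.
#' @param order_noise_sd SD of the per-event deviation of an individual from
#'   its habitual slot, metres.
#' @param jitter_sd,jitter_tau within-event positional jitter: OU stationary
#'   SD (m) and relaxation time (s).
#' @param baseline_radius RMS radius of the foraging formation, metres.
#' @param offset_sd,offset_tau baseline individual wander around the anchor:
#'   OU stationary SD (m) and relaxation time (s).
#' @param drift_speed_sd,drift_tau baseline centroid drift velocity: OU
#'   per-component SD (m/s) and relaxation time (s).
#' @param mode_tau,mode_gain latent behavioural mode alternating directional
#'   drift (aligned, slow) with foraging activity (fast positional jitter,
#'   unaligned): OU relaxation time (s) and sigmoid gain.
#' @param forage_sd,forage_tau foraging jitter at full activity: OU
#'   stationary SD (m) and relaxation time (s).
#' @param gps_noise_sd,gps_noise_rho GPS error stationary SD (m; within the
#'   5 m accuracy of the tracking collars emulated) and lag-1
#'   autocorrelation.
#' @param taper progression build-up/dissolution time, seconds.
#' @param structure `"affiliation"` or `"null"` (see Details).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 13,
                       n_days = 2,
                       day_start = 8,
                       day_end = 20,
                       tz_offset = 2,
                       base_date = "2018-08-01",
                       dominance = NULL,
                       sex = NULL,
                       affiliation_base = 0.2,
                       affiliation_slope = 0.6,
                       affiliation_noise_sd = 0.08,
                       events_per_day_mean = 3,
                       duration_mean = 640,
                       duration_min = 60,
                       duration_max = 4200,
                       progression_speed = 1.3,
                       formation_length = 93,
                       formation_width = 38,
                       order_noise_sd = 15,
                       jitter_sd = 3,
                       jitter_tau = 120,
                       baseline_radius = 15,
                       offset_sd = 4,
                       offset_tau = 200,
                       drift_speed_sd = 0.15,
                       drift_tau = 600,
                       mode_tau = 900,
                       mode_gain = 1.5,
                       forage_sd = 4.5,
                       forage_tau = 60,
                       gps_noise_sd = 2,
                       gps_noise_rho = 0.98,
                       taper = 240,
                       structure = c("affiliation", "null"),
                       seed = 1) {
  n <- n_individuals
  if (is.null(dominance)) dominance <- seq(0, 1, length.out = n)
  stopifnot(length(dominance) == n, all(dominance >= 0 & dominance <= 1))
  if (is.null(sex)) {
    sex <- rep("female", n)
    males <- order(dominance, decreasing = TRUE)[c(1, min(4, n))]
    sex[males] <- "male"
  }
  stopifnot(all(c(duration_mean, progression_speed, formation_length,
                  formation_width, baseline_radius) > 0))
  structure(list(
    n_individuals = n, n_days = n_days,
    day_start = day_start, day_end = day_end, tz_offset = tz_offset,
    base_date = as.Date(base_date),
    ids = sprintf("B%02d", seq_len(n)),
    dominance = dominance, sex = sex,
    affiliation_base = affiliation_base,
    affiliation_slope = affiliation_slope,
    affiliation_noise_sd = affiliation_noise_sd,
    events_per_day_mean = events_per_day_mean,
    duration_mean = duration_mean, duration_min = duration_min,
    duration_max = duration_max,
    progression_speed = progression_speed,
    formation_length = formation_length, formation_width = formation_width,
    order_noise_sd = order_noise_sd,
    jitter_sd = jitter_sd, jitter_tau = jitter_tau,
    baseline_radius = baseline_radius,
    offset_sd = offset_sd, offset_tau = offset_tau,
    drift_speed_sd = drift_speed_sd, drift_tau = drift_tau,
    mode_tau = mode_tau, mode_gain = mode_gain,
    forage_sd = forage_sd, forage_tau = forage_tau,
    gps_noise_sd = gps_noise_sd, gps_noise_rho = gps_noise_rho,
    taper = taper,
    structure = match.arg(structure),
    seed = seed
  ), class = "sim_config")
}

## Stationary AR(1)/discretized-OU series of length n.
ar1_series <- function(n, tau, sd_stat) {
  phi <- exp(-1 / tau)
  innov <- rnorm(n, 0, sd_stat * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1, 0, sd_stat)))
}

#' Planted affiliation matrix
#'
#' Symmetric pair affiliations increasing in the *lower* rank of the pair —
#' a minimal monotone coupling that reproduces "higher-ranked individuals
#' have more and stronger ties" (both members must be high-ranked for a
#' strong tie) — plus seeded pair-specific noise, clipped to (0, 1]. The
#' min-rank coupling is a modelling convenience of the generator, not a
#' claim about baboons.
#'
#' @param n number of individuals.
#' @param dominance ranks in `[0, 1]`, length n.
#' @param base,slope,noise_sd model parameters.
#' @param seed optional seed.
#' @return symmetric n x n matrix, diagonal zero.
#' @export
make_affiliation_matrix <- function(n, dominance, base = 0.2, slope = 0.6,
                                    noise_sd = 0.08, seed = NULL) {
  if (n < 2) stop("need at least 2 individuals", call. = FALSE)
  stopifnot(length(dominance) == n)
  if (!is.null(seed)) set.seed(seed)
  A <- base + slope * outer(dominance, dominance, pmin)
  eps <- matrix(rnorm(n * n, 0, noise_sd), n, n)
  A <- A + (eps + t(eps)) / 2
  A <- pmin(pmax(A, 0.01), 1)
  diag(A) <- 0
  A
}

#' Plant habitual order slots from an affiliation matrix
#'
#' One-dimensional centre-out seriation of the individuals: the individual
#' with the highest total affiliation seeds the line, and the line then
#' grows greedily — at each step the remaining individual with the
#' strongest affiliation to either end of the line attaches at that end.
#' Strongly affiliated pairs therefore receive adjacent slots (a chain
#' structure is rebuilt link by link) and well-connected individuals
#' receive central slots, while weakly connected individuals are pushed to
#' *both* peripheral ends — so the signed position carries no systematic
#' gradient in connectedness, only its absolute value does. Adjacent slots
#' are separated by gaps proportional to the squared dissimilarity
#' `(1 - A)^2` of the pair, so weakly bonded neighbours stand farther
#' apart and pairwise slot distances track affiliation; two damped
#' barycentric refinement passes (each slot pulled toward the
#' affiliation-weighted mean of the others) then centre well-connected
#' individuals more precisely without disturbing a chain's order. Slots are
#' finally centred and scaled to span `formation_length`.
#'
#' The arrangement is defined up to reflection: an order and its mirror
#' image are equally valid, and which one is produced depends on the
#' tie-break (rightward on equal affinity).
#'
#' A degenerate (constant off-diagonal) matrix carries no order
#' information; the slots are then an evenly spaced random permutation,
#' seeded.
#'
#' @param A symmetric affiliation matrix in `(0, 1]`.
#' @param formation_length target span of the slots, metres.
#' @param seed seed for the degenerate fallback.
#' @return named numeric vector of slots (metres along the travel axis,
#'   centred on 0), in row order of `A`.
#' @export
plant_order <- function(A, formation_length = 93, seed = NULL) {
  n <- nrow(A)
  off <- A[row(A) != col(A)]
  if (stats::sd(off) < 1e-9) {
    if (!is.null(seed)) set.seed(seed)
    line <- sample(seq_len(n))
  } else {
    s <- rowSums(A)
    line <- which.max(s)
    remaining <- setdiff(seq_len(n), line)
    while (length(remaining) > 0) {
      a_left <- A[remaining, line[1]]
      a_right <- A[remaining, line[length(line)]]
      best <- pmax(a_left, a_right)
      k <- which.max(best)
      i <- remaining[k]
      line <- if (a_left[k] > a_right[k]) c(i, line) else c(line, i)
      remaining <- remaining[-k]
    }
  }
  pos <- numeric(n)
  if (stats::sd(off) >= 1e-9) {
    gaps <- (1 - A[cbind(line[-n], line[-1])])^2
    pos[line] <- cumsum(c(0, gaps))
    W <- A^2
    diag(W) <- 0
    for (k in 1:2) {
      pos <- 0.5 * pos + 0.5 * as.vector(W %*% pos / rowSums(W))
    }
  } else {
    pos[line] <- seq_len(n)
  }
  slots <- rescale_extent(pos, formation_length)
  names(slots) <- rownames(A)
  slots
}

## 2-D baseline anchors: affiliation-structured (2-D MDS of the geodesic
## dissimilarity, so equilibrium pairwise distances decrease with A) or an
## unstructured Gaussian cloud, scaled to RMS radius `radius`.
baseline_anchors <- function(A, radius, structure = "affiliation") {
  n <- nrow(A)
  if (structure == "affiliation" && stats::sd(A[row(A) != col(A)]) >= 1e-9) {
    D <- 1 - A
    diag(D) <- 0
    g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    P <- stats::cmdscale(igraph::distances(g), k = 2)
  } else {
    P <- matrix(rnorm(2 * n), n, 2)
  }
  P <- sweep(P, 2, colMeans(P))
  P * radius / sqrt(mean(rowSums(P^2)))
}

## Taper weight profile for an event of duration D: sqrt-shaped rise over
## R = min(taper, floor(D/2)) seconds, plateau, symmetric fall.
taper_profile <- function(D, taper) {
  R <- max(1L, min(taper, floor(D / 4)))
  tau <- seq_len(D)
  pmin(sqrt(pmin(tau / R, 1)), sqrt(pmin((D - tau + 1) / R, 1)))
}

#' Simulate baseline (non-progression) group movement
#'
#' Slow mean-reverting drift of the group centroid plus per-individual
#' mean-reverting wander around affiliation-structured anchor offsets, so
#' that pairs with higher affiliation keep smaller equilibrium distances.
#' No GPS noise is added here.
#'
#' @param config a [sim_config()].
#' @param A affiliation matrix.
#' @param duration seconds to simulate.
#' @param seed optional seed.
#' @return list with `t` (0-based seconds), `X`, `Y` (duration x n matrices,
#'   metres) and the `anchors` used.
#' @export
simulate_baseline <- function(config, A, duration = 3600, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anchors <- baseline_anchors(A, config$baseline_radius, config$structure)
  sim <- sim_block(config, duration, anchors, events = NULL,
                   lambda = NULL, lateral = NULL)
  list(t = seq_len(duration) - 1, X = sim$X, Y = sim$Y, anchors = anchors)
}

#' Simulate one progression event
#'
#' The group centroid translates at the progression speed along a fixed
#' heading (ramped by the taper profile); each individual holds
#' slot + per-event longitudinal offset along the travel axis and a
#' per-event lateral offset across it, with slow positional jitter.
#' Longitudinal and lateral positions are rescaled per event so the
#' realized formation extents match the configured targets. Without noise
#' the polarization of the core exceeds 0.95 and the elongation equals
#' length/width.
#'
#' @param config a [sim_config()].
#' @param slots habitual slots from [plant_order()].
#' @param duration event duration, seconds.
#' @param heading travel heading, radians.
#' @param order_noise_sd per-event slot deviation SD; defaults to the
#'   config value (0 gives the noiseless formation).
#' @param gps_noise add AR(1) GPS error.
#' @param seed optional seed.
#' @return list with `t`, `X`, `Y` and the per-event longitudinal positions
#'   `lambda`.
#' @export
simulate_progression <- function(config, slots, duration = 600,
                                 heading = 0, order_noise_sd = NULL,
                                 gps_noise = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_individuals
  ons <- order_noise_sd %||% config$order_noise_sd
  lambda <- rescale_extent(slots + rnorm(n, 0, ons), config$formation_length)
  lateral <- rescale_extent(rnorm(n), config$formation_width)
  anchors <- cbind(lambda * cos(heading) - lateral * sin(heading),
                   lambda * sin(heading) + lateral * cos(heading))
  events <- data.frame(start = 1L, duration = as.integer(duration),
                       heading = heading)
  sim <- sim_block(config, duration, anchors,
                   events = events, lambda = cbind(lambda),
                   lateral = cbind(lateral), baseline_free = TRUE)
  X <- sim$X
  Y <- sim$Y
  if (gps_noise) {
    for (j in seq_len(n)) {
      X[, j] <- X[, j] + ar1_series(duration, -1 / log(config$gps_noise_rho),
                                    config$gps_noise_sd)
      Y[, j] <- Y[, j] + ar1_series(duration, -1 / log(config$gps_noise_rho),
                                    config$gps_noise_sd)
    }
  }
  list(t = seq_len(duration) - 1, X = X, Y = Y, lambda = lambda)
}

## centre values and scale so max - min equals `extent`
rescale_extent <- function(v, extent) {
  v <- v - mean(v)
  r <- max(v) - min(v)
  if (r < 1e-12) return(v)
  v / r * extent
}

## Core day engine: continuous centroid path (baseline OU drift blended
## with event translation by the taper weight), individual offsets blended
## between baseline wander and line-formation positions. Returns noiseless
## coordinates.
sim_block <- function(config, T_len, anchors, events, lambda, lateral,
                      baseline_free = FALSE) {
  n <- config$n_individuals
  ## latent behavioural mode: positive = directional drift (aligned, slow),
  ## negative = foraging activity (fast unaligned jitter). The two regimes
  ## are mutually exclusive, as directed group travel and dispersed foraging
  ## are in the field.
  z <- ar1_series(T_len, config$mode_tau, 1)
  g_drift <- stats::plogis(config$mode_gain * z)
  g_forage <- stats::plogis(-config$mode_gain * z)
  ## baseline centroid drift velocity, amplitude-modulated by the mode
  vx <- ar1_series(T_len, config$drift_tau, config$drift_speed_sd) * g_drift
  vy <- ar1_series(T_len, config$drift_tau, config$drift_speed_sd) * g_drift
  ## per-individual baseline wander (smoothed OU), foraging jitter and
  ## event jitter
  OX <- matrix(0, T_len, n); OY <- OX
  JL <- matrix(0, T_len, n); JT <- OX
  for (j in seq_len(n)) {
    OX[, j] <- running_average(ar1_series(T_len, config$offset_tau,
                                          config$offset_sd), 30) +
      ar1_series(T_len, config$forage_tau, config$forage_sd) * g_forage
    OY[, j] <- running_average(ar1_series(T_len, config$offset_tau,
                                          config$offset_sd), 30) +
      ar1_series(T_len, config$forage_tau, config$forage_sd) * g_forage
    JL[, j] <- ar1_series(T_len, config$jitter_tau, config$jitter_sd)
    JT[, j] <- ar1_series(T_len, config$jitter_tau, config$jitter_sd)
  }
  w <- rep(0, T_len)
  ev_idx <- rep(0L, T_len)
  if (!is.null(events)) {
    for (k in seq_len(nrow(events))) {
      span <- events$start[k]:(events$start[k] + events$duration[k] - 1)
      w[span] <- taper_profile(events$duration[k], config$taper)
      ev_idx[span] <- k
    }
  }
  ## centroid velocity: baseline drift outside events, ramped translation
  ## inside (blended so the path is continuous)
  cvx <- (1 - w) * vx
  cvy <- (1 - w) * vy
  if (!is.null(events)) {
    for (k in seq_len(nrow(events))) {
      span <- which(ev_idx == k)
      th <- events$heading[k]
      cvx[span] <- cvx[span] + w[span] * config$progression_speed * cos(th)
      cvy[span] <- cvy[span] + w[span] * config$progression_speed * sin(th)
    }
  }
  Cx <- cumsum(cvx)
  Cy <- cumsum(cvy)
  ## formation offsets; the line formation assembles faster than the
  ## speed builds (groups string out into line before travelling at full
  ## pace), hence the square-root of the speed ramp
  wf <- sqrt(w)
  X <- matrix(0, T_len, n); Y <- X
  base_ox <- if (baseline_free) 0 * OX else
    sweep(OX, 2, anchors[, 1], `+`)
  base_oy <- if (baseline_free) 0 * OY else
    sweep(OY, 2, anchors[, 2], `+`)
  for (j in seq_len(n)) {
    fx <- (1 - wf) * base_ox[, j]
    fy <- (1 - wf) * base_oy[, j]
    if (!is.null(events)) {
      for (k in seq_len(nrow(events))) {
        span <- which(ev_idx == k)
        th <- events$heading[k]
        lam <- lambda[j, k] + JL[span, j]
        lat <- lateral[j, k] + JT[span, j]
        fx[span] <- fx[span] + wf[span] * (lam * cos(th) - lat * sin(th))
        fy[span] <- fy[span] + wf[span] * (lam * sin(th) + lat * cos(th))
      }
    }
    X[, j] <- Cx + fx
    Y[, j] <- Cy + fy
  }
  list(X = X, Y = Y, w = w)
}

## Poisson number of events with truncated-exponential durations, placed
## uniformly with a margin from the day edges and a minimum gap; events
## that cannot be placed after 200 tries are dropped.
schedule_events <- function(config, T_len, margin = 600, gap = 600) {
  k <- rpois(1, config$events_per_day_mean)
  if (k == 0) return(data.frame(start = integer(0), duration = integer(0),
                                heading = numeric(0)))
  durations <- integer(k)
  for (i in seq_len(k)) {
    repeat {
      d <- rexp(1, 1 / config$duration_mean)
      if (d >= config$duration_min && d <= config$duration_max) break
    }
    durations[i] <- as.integer(round(d))
  }
  durations <- sort(durations, decreasing = TRUE)  # place long events first
  placed <- data.frame(start = integer(0), duration = integer(0))
  for (d in durations) {
    hi <- T_len - margin - d
    if (hi <= margin) next
    for (try in seq_len(200)) {
      s <- as.integer(floor(runif(1, margin, hi)))
      ok <- nrow(placed) == 0 ||
        all(s > placed$start + placed$duration + gap |
              s + d + gap < placed$start)
      if (ok) {
        placed <- rbind(placed, data.frame(start = s, duration = d))
        break
      }
    }
  }
  placed <- placed[order(placed$start), , drop = FALSE]
  placed$heading <- runif(nrow(placed), 0, 2 * pi)
  placed
}

#' Generate a full synthetic dataset with ground truth
#'
#' Stitches baseline foraging movement and scheduled progressions into
#' `n_days` days of 1 Hz trajectories for all individuals, adds
#' autocorrelated GPS noise, and attaches the ground truth: the planted
#' event list, the habitual order slots, the affiliation matrix and the
#' attribute table. A single seed drives independent per-component random
#' streams (affiliation, placement, schedule, movement, noise), so the
#' output is reproducible bit for bit.
#'
#' @param config a [sim_config()].
#' @return a `synthetic_dataset`: list with `trajectories` (a `traj_table`),
#'   `attributes`, `events` (ground truth), `slots`, `affiliation`,
#'   `config`.
#' @export
generate <- function(config = sim_config()) {
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1, 4 + config$n_days)
  n <- config$n_individuals
  ids <- config$ids

  set.seed(seeds[1])
  A <- make_affiliation_matrix(n, config$dominance,
                               base = config$affiliation_base,
                               slope = config$affiliation_slope,
                               noise_sd = config$affiliation_noise_sd)
  if (config$structure == "null") {
    A <- matrix(config$affiliation_base + config$affiliation_slope / 2, n, n)
    diag(A) <- 0
  }
  rownames(A) <- colnames(A) <- ids

  set.seed(seeds[2])
  slots <- plant_order(A, config$formation_length, seed = seeds[2])
  anchors <- baseline_anchors(A, config$baseline_radius, config$structure)
  ## persistent lateral preference: affiliates also travel side by side,
  ## so the cross-track coordinate carries the second embedding axis of
  ## the affiliation structure (unit variance; mixed 1:1 with per-event
  ## noise below). Null structure carries no lateral preference.
  lat_base <- if (config$structure == "null") rep(0, n) else {
    lb <- anchors[, 2] - mean(anchors[, 2])
    if (stats::sd(lb) > 1e-9) lb / stats::sd(lb) else rep(0, n)
  }

  day_len <- as.integer((config$day_end - config$day_start) * 3600)
  base_epoch_day <- as.integer(config$base_date)
  trajs <- vector("list", config$n_days)
  truth <- list()
  for (d in seq_len(config$n_days)) {
    set.seed(seeds[4 + d])
    events <- schedule_events(config, day_len)
    ## per-event formation positions
    k <- nrow(events)
    lambda <- matrix(0, n, max(k, 1))
    lateral <- matrix(0, n, max(k, 1))
    for (e in seq_len(k)) {
      base_slots <- if (config$structure == "null") {
        slots[sample(n)]            # fresh order every event: no consistency
      } else slots
      lambda[, e] <- rescale_extent(base_slots + rnorm(n, 0, config$order_noise_sd),
                                    config$formation_length)
      lateral[, e] <- rescale_extent(lat_base + rnorm(n), config$formation_width)
    }
    sim <- sim_block(config, day_len, anchors,
                     events = if (k > 0) events else NULL,
                     lambda = lambda, lateral = lateral)
    ## GPS noise
    tau_gps <- -1 / log(config$gps_noise_rho)
    for (j in seq_len(n)) {
      sim$X[, j] <- sim$X[, j] + ar1_series(day_len, tau_gps, config$gps_noise_sd)
      sim$Y[, j] <- sim$Y[, j] + ar1_series(day_len, tau_gps, config$gps_noise_sd)
    }
    ## UTC epoch seconds for this day's grid
    t0 <- (base_epoch_day + d - 1) * 86400 +
      (config$day_start - config$tz_offset) * 3600
    tt <- t0 + seq_len(day_len) - 1
    trajs[[d]] <- tibble::tibble(
      id = rep(ids, each = day_len),
      t = rep(tt, n),
      x = as.vector(sim$X),
      y = as.vector(sim$Y)
    )
    if (k > 0) {
      truth[[d]] <- tibble::tibble(
        date = base_epoch_day + d - 1,
        start_t = t0 + events$start - 1,
        end_t = t0 + events$start + events$duration - 2,
        duration = events$duration,
        heading = events$heading
      )
    }
  }
  traj <- traj_table(dplyr::bind_rows(trajs), tz_offset = config$tz_offset)
  events <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble::tibble(date = integer(0), start_t = numeric(0),
                   end_t = numeric(0), duration = integer(0),
                   heading = numeric(0))
  if (nrow(events) > 0) {
    events$event_id <- sprintf("T%03d", seq_len(nrow(events)))
    events$period <- label_period(events$start_t, config$tz_offset)
    events <- events[, c("event_id", "date", "start_t", "end_t", "duration",
                         "period", "heading")]
  }
  attributes <- tibble::tibble(id = ids, sex = config$sex,
                               dominance = config$dominance)
  structure(list(trajectories = traj, attributes = attributes,
                 events = events,
                 slots = tibble::tibble(id = ids, slot = unname(slots)),
                 affiliation = A, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d individuals, %d day(s), ",
                     "%d planted events, structure=%s, seed=%d\n"),
              x$config$n_individuals, x$config$n_days, nrow(x$events),
              x$config$structure, x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to CSV files
#'
#' Writes trajectories, attributes, ground-truth events, slots and the
#' affiliation matrix as plain CSV into a directory.
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trajectories(dataset$trajectories, file.path(dir, "trajectories.csv"))
  utils::write.csv(dataset$attributes, file.path(dir, "attributes.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$events, file.path(dir, "events_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$slots, file.path(dir, "slots.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(dataset$affiliation),
                   file.path(dir, "affiliation.csv"), row.names = FALSE)
  invisible(dir)
}
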