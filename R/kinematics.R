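## Wide representation of a trajectory table: one row per second of the
## pooled grid, one column per individual. Days are handled as independent
## blocks (the grid is contiguous within a day, never across days).
traj_wide <- function(traj) {
  tz <- attr(traj, "tz_offset") %||% 2
  ids <- sort(unique(traj$id))
  day <- traj_day(traj$t, tz)
  ts <- sort(unique(traj$t))
  tday <- traj_day(ts, tz)
  ## complete the grid within each day
  full_t <- unlist(lapply(split(ts, tday), function(v) seq(min(v), max(v))),
                   use.names = FALSE)
  full_day <- traj_day(full_t, tz)
  ti <- match(traj$t, full_t)
  ci <- match(traj$id, ids)
  X <- matrix(NA_real_, length(full_t), length(ids),
              dimnames = list(NULL, ids))
  Y <- X
  X[cbind(ti, ci)] <- traj$x
  Y[cbind(ti, ci)] <- traj$y
  list(t = full_t, day = full_day, ids = ids, X = X, Y = Y, tz_offset = tz)
}

## Apply f(block_rows) within contiguous day blocks, rbinding results.
day_blocks <- function(day) {
  r <- rle(day)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  Map(seq, starts, ends)
}

#' Per-second individual velocities
#'
#' Central-difference velocity on the 1 s grid; the first and last second of
#' each individual's day use one-sided differences. Where one neighbour fix
#' is missing, the available one-sided difference is used; where both are
#' missing the velocity is undefined. Heading unit vectors are reported only
#' when speed reaches `stationary_floor` — the heading of an (effectively)
#' stationary animal is noise, and such individuals are excluded from the
#' polarization sum.
#'
#' @param traj a `traj_table`.
#' @param stationary_floor speed (m/s) below which the heading is undefined.
#' @return tibble with columns id, t, vx, vy, speed, hx, hy.
#' @export
individual_velocities <- function(traj, stationary_floor = 0.05) {
  w <- traj_wide(traj)
  V <- velocity_matrices(w)
  speed <- sqrt(V$VX^2 + V$VY^2)
  ok <- !is.na(speed) & speed >= stationary_floor
  HX <- ifelse(ok, V$VX / speed, NA_real_)
  HY <- ifelse(ok, V$VY / speed, NA_real_)
  out <- tibble::tibble(
    id = rep(w$ids, each = length(w$t)),
    t = rep(w$t, length(w$ids)),
    vx = as.vector(V$VX), vy = as.vector(V$VY),
    speed = as.vector(speed),
    hx = as.vector(HX), hy = as.vector(HY)
  )
  out[!is.na(out$vx) | !is.na(out$vy), ]
}

velocity_matrices <- function(w) {
  VX <- matrix(NA_real_, nrow(w$X), ncol(w$X))
  VY <- VX
  for (rows in day_blocks(w$day)) {
    n <- length(rows)
    if (n < 2) next
    X <- w$X[rows, , drop = FALSE]
    Y <- w$Y[rows, , drop = FALSE]
    Xp <- rbind(NA, X[-n, , drop = FALSE])   # position one second earlier
    Xn <- rbind(X[-1, , drop = FALSE], NA)
    Yp <- rbind(NA, Y[-n, , drop = FALSE])
    Yn <- rbind(Y[-1, , drop = FALSE], NA)
    vx <- (Xn - Xp) / 2
    vy <- (Yn - Yp) / 2
    ## one-sided fallback at block edges and next to missing fixes
    fb <- is.na(vx) & !is.na(X)
    use_fwd <- fb & !is.na(Xn)
    vx[use_fwd] <- (Xn - X)[use_fwd]
    vy[use_fwd] <- (Yn - Y)[use_fwd]
    use_bwd <- fb & is.na(Xn) & !is.na(Xp)
    vx[use_bwd] <- (X - Xp)[use_bwd]
    vy[use_bwd] <- (Y - Yp)[use_bwd]
    VX[rows, ] <- vx
    VY[rows, ] <- vy
  }
  list(VX = VX, VY = VY)
}

#' Group polarization
#'
#' Magnitude of the mean heading unit vector over the individuals with a
#' defined heading: `P = || (1/N) sum_i v_i / ||v_i|| ||`, giving 1 for
#' perfect alignment and 0 for full cancellation. `NA` headings are dropped;
#' with no defined heading the value is undefined.
#'
#' @param hx,hy heading unit-vector components for one second.
#' @return polarization in `[0, 1]`, or `NA` if no heading is defined.
#' @export
polarization <- function(hx, hy) {
  ok <- !is.na(hx) & !is.na(hy)
  if (!any(ok)) return(NA_real_)
  sqrt(mean(hx[ok])^2 + mean(hy[ok])^2)
}

#' Centred running average
#'
#' Moving mean over a centred window of `window` seconds (half-width
#' `floor(window/2)` each side). At the edges the window is truncated
#' symmetrically, so the value at position i always averages an interval
#' centred on i. Missing values are ignored; a window with no finite value
#' yields `NA`.
#'
#' @param x numeric series on a regular 1 s grid.
#' @param window window width in seconds (default 300, i.e. a 5-min running
#'   average).
#' @return smoothed series, same length as `x`.
#' @export
running_average <- function(x, window = 300) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  h <- floor(window / 2)
  v <- ifelse(is.na(x), 0, x)
  m <- as.numeric(!is.na(x))
  cs <- c(0, cumsum(v))
  cm <- c(0, cumsum(m))
  i <- seq_len(n)
  hi <- pmin(h, i - 1, n - i)    # symmetric truncation at the edges
  lo <- i - hi
  up <- i + hi
  tot <- cs[up + 1] - cs[lo]
  cnt <- cm[up + 1] - cm[lo]
  ifelse(cnt > 0, tot / cnt, NA_real_)
}

#' Group travel direction
#'
#' Unit vector of the centroid displacement over a centred window (default
#' 10 s): raw second-to-second headings of a noisy centroid are unstable, a
#' short displacement window is not. Undefined (NA) where the displacement
#' is below `min_displacement` or the window collapses at a series edge.
#'
#' @param cx,cy centroid coordinate series on a regular 1 s grid (one day).
#' @param window displacement window in seconds.
#' @param min_displacement stationarity floor in metres.
#' @return two-column matrix of unit-vector components dx, dy.
#' @export
group_travel_direction <- function(cx, cy, window = 10, min_displacement = 0.1) {
  n <- length(cx)
  h <- floor(window / 2)
  i <- seq_len(n)
  hi <- pmin(h, i - 1, n - i)
  dx <- cx[i + hi] - cx[i - hi]
  dy <- cy[i + hi] - cy[i - hi]
  len <- sqrt(dx^2 + dy^2)
  bad <- is.na(len) | len < min_displacement | hi == 0
  cbind(dx = ifelse(bad, NA_real_, dx / len),
        dy = ifelse(bad, NA_real_, dy / len))
}

#' Group elongation at one second
#'
#' Ratio of the group's extent along the travel direction to its extent
#' perpendicular to it. The perpendicular extent is floored at `eps` (1 m)
#' so a perfectly collinear formation yields a large finite ratio rather
#' than dividing by zero.
#'
#' @param x,y positions of the individuals present (metres).
#' @param direction travel unit vector `c(dx, dy)`.
#' @param eps floor for the perpendicular extent in metres.
#' @return elongation ratio, or `NA` with fewer than 2 individuals or an
#'   undefined direction.
#' @export
group_elongation <- function(x, y, direction, eps = 1) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || anyNA(direction)) return(NA_real_)
  fb <- x[ok] * direction[1] + y[ok] * direction[2]
  lr <- -x[ok] * direction[2] + y[ok] * direction[1]
  (max(fb) - min(fb)) / max(eps, max(lr) - min(lr))
}

#' Group cohesion at one second
#'
#' TRUE when at least `min_count` tracked individuals have their nearest
#' tracked conspecific within `radius` metres (default: 10 within 50 m).
#'
#' @param x,y positions of the individuals present (metres).
#' @param radius nearest-neighbour radius in metres.
#' @param min_count minimum number of individuals satisfying the radius rule.
#' @return logical.
#' @export
cohesion_flag <- function(x, y, radius = 50, min_count = 10) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(FALSE)
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  sum(nn <= radius) >= min_count
}

## Nearest-neighbour distance per second per individual, NA when absent or
## alone. Vectorized over the whole grid via per-pair column sweeps.
nn_distance_matrix <- function(w) {
  n <- length(w$ids)
  NN <- matrix(Inf, nrow(w$X), n, dimnames = list(NULL, w$ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dij <- sqrt((w$X[, i] - w$X[, j])^2 + (w$Y[, i] - w$Y[, j])^2)
      dij[is.na(dij)] <- Inf
      NN[, i] <- pmin(NN[, i], dij)
      NN[, j] <- pmin(NN[, j], dij)
    }
  }
  NN[is.na(w$X)] <- Inf
  NN
}

row_range_extent <- function(M) {
  ## max - min per row, NA-safe, without apply() overhead
  mx <- rep(-Inf, nrow(M))
  mn <- rep(Inf, nrow(M))
  cnt <- rep(0L, nrow(M))
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    ok <- !is.na(v)
    mx[ok] <- pmax(mx[ok], v[ok])
    mn[ok] <- pmin(mn[ok], v[ok])
    cnt <- cnt + ok
  }
  ifelse(cnt >= 2, mx - mn, NA_real_)
}

#' Per-second group state
#'
#' Computes, for every second of the pooled grid, the number of individuals
#' present, the group centroid (arithmetic mean of the individuals present),
#' polarization, mean individual speed (over present individuals),
#' travel direction, group length and width in the travel frame, elongation,
#' the cohesion flag, and the smoothed polarization and speed series used by
#' the event detector. Smoothing never crosses day boundaries.
#'
#' @param traj a `traj_table`.
#' @param config a [detection_config()]; supplies the smoothing window,
#'   cohesion rule, travel-direction window and stationarity floors.
#' @return a `group_state` tibble, one row per second.
#' @export
group_state <- function(traj, config = detection_config()) {
  w <- traj_wide(traj)
  V <- velocity_matrices(w)
  speed <- sqrt(V$VX^2 + V$VY^2)
  ok <- !is.na(speed) & speed >= config$stationary_floor
  HX <- ifelse(ok, V$VX / speed, NA_real_)
  HY <- ifelse(ok, V$VY / speed, NA_real_)

  present <- !is.na(w$X)
  n_present <- rowSums(present)
  cx <- rowMeans(w$X, na.rm = TRUE)
  cy <- rowMeans(w$Y, na.rm = TRUE)
  cx[n_present == 0] <- NA_real_
  cy[n_present == 0] <- NA_real_

  n_head <- rowSums(!is.na(HX))
  sx <- rowMeans(HX, na.rm = TRUE)
  sy <- rowMeans(HY, na.rm = TRUE)
  pol <- ifelse(n_head > 0, sqrt(sx^2 + sy^2), NA_real_)
  mean_speed <- ifelse(rowSums(!is.na(speed)) > 0,
                       rowMeans(speed, na.rm = TRUE), NA_real_)

  dir <- matrix(NA_real_, length(w$t), 2)
  for (rows in day_blocks(w$day)) {
    dir[rows, ] <- group_travel_direction(cx[rows], cy[rows],
                                          window = config$travel_window,
                                          min_displacement = config$min_displacement)
  }

  ## extents in the travel frame (per-row direction)
  FB <- (w$X - cx) * dir[, 1] + (w$Y - cy) * dir[, 2]
  LR <- -(w$X - cx) * dir[, 2] + (w$Y - cy) * dir[, 1]
  len <- row_range_extent(FB)
  wid <- row_range_extent(LR)
  elong <- len / pmax(config$elongation_eps, wid)

  NN <- nn_distance_matrix(w)
  cohesive <- rowSums(NN <= config$cohesion_radius) >= config$cohesion_min_count

  pol_s <- rep(NA_real_, length(pol))
  speed_s <- pol_s
  for (rows in day_blocks(w$day)) {
    pol_s[rows] <- running_average(pol[rows], config$smoothing_window)
    speed_s[rows] <- running_average(mean_speed[rows], config$smoothing_window)
  }

  out <- tibble::tibble(
    t = w$t, day = w$day, n_present = n_present,
    cx = cx, cy = cy,
    polarization = pol, mean_speed = mean_speed,
    dir_x = dir[, 1], dir_y = dir[, 2],
    length = len, width = wid, elongation = elong,
    cohesive = cohesive,
    polarization_smooth = pol_s, speed_smooth = speed_s
  )
  attr(out, "tz_offset") <- w$tz_offset
  attr(out, "config") <- config
  class(out) <- c("group_state", class(out))
  out
}
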