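test_that("individual velocities: central and one-sided differences", {
  tr <- traj_table(data.frame(id = "A", t = 1000 + 0:2, x = c(0, 1, 2), y = 0))
  v <- individual_velocities(tr)
  expect_equal(v$vx, c(1, 1, 1))
  expect_equal(v$vy, c(0, 0, 0))
  expect_equal(v$speed, c(1, 1, 1))

  # motion along y at 2 m/s: heading (0, 1)
  tr2 <- traj_table(data.frame(id = "A", t = 1000 + 0:4, x = 0, y = 2 * (0:4)))
  v2 <- individual_velocities(tr2)
  expect_equal(unique(v2$speed), 2)
  expect_equal(unique(v2$hx), 0)
  expect_equal(unique(v2$hy), 1)

  # stationary: zero speed, heading undefined
  tr3 <- traj_table(data.frame(id = "A", t = 1000 + 0:4, x = 5, y = 5))
  v3 <- individual_velocities(tr3)
  expect_equal(unique(v3$speed), 0)
  expect_true(all(is.na(v3$hx)))
})

test_that("polarization follows the mean-heading-magnitude formula", {
  expect_equal(polarization(c(1, 1, 1), c(0, 0, 0)), 1)    # identical
  expect_equal(polarization(c(1, -1), c(0, 0)), 0)         # opposite
  # headings at 0, 90, 180 degrees: |mean| = 1/3
  expect_equal(polarization(c(1, 0, -1), c(0, 1, 0)), 1 / 3)
  expect_true(is.na(polarization(NA_real_, NA_real_)))

  # invariant under global rotation
  set.seed(5)
  for (k in 1:20) {
    ang <- runif(8, 0, 2 * pi)
    rot <- runif(1, 0, 2 * pi)
    p1 <- polarization(cos(ang), sin(ang))
    p2 <- polarization(cos(ang + rot), sin(ang + rot))
    expect_equal(p1, p2)
    expect_equal(p1, oracle_polarization(ang))
  }
})

test_that("running average matches the brute-force windowed mean", {
  expect_equal(running_average(rep(7, 50), 10), rep(7, 50))
  imp <- c(rep(0, 10), 1, rep(0, 10))
  expect_equal(running_average(imp, 5), oracle_running_mean(imp, 5))
  expect_equal(sum(running_average(imp, 5) == 0.2), 5)
  set.seed(9)
  for (w in c(3, 5, 30, 301)) {
    x <- rnorm(400)
    x[sample(400, 20)] <- NA
    expect_equal(running_average(x, w), oracle_running_mean(x, w))
  }
  expect_length(running_average(numeric(0), 5), 0)
})

test_that("group travel direction from centroid displacement", {
  n <- 50
  d <- group_travel_direction(1:n + 0, rep(0, n))        # due east
  expect_equal(unname(d[25, ]), c(1, 0))
  d2 <- group_travel_direction(rep(0, n), rep(0, n))     # stationary
  expect_true(all(is.na(d2[, 1])))
  d3 <- group_travel_direction(1:n + 0, 1:n + 0)         # 45 degrees
  expect_equal(unname(d3[25, ]), c(sqrt(2) / 2, sqrt(2) / 2))
})

test_that("elongation is the travel/perpendicular extent ratio", {
  # 90 m along travel x 30 m across
  x <- c(0, 90, 45, 45)
  y <- c(0, 0, -15, 15)
  expect_equal(group_elongation(x, y, c(1, 0)), 3)
  # axis-aligned square: 1
  expect_equal(group_elongation(c(0, 10, 0, 10), c(0, 0, 10, 10), c(1, 0)), 1)
  # collinear: floored perpendicular extent
  expect_equal(group_elongation(c(0, 50), c(0, 0), c(1, 0)), 50)
  expect_true(is.na(group_elongation(5, 5, c(1, 0))))

  # invariant under translation and joint rotation
  set.seed(13)
  for (k in 1:20) {
    x <- rnorm(10, sd = 20); y <- rnorm(10, sd = 20)
    th <- runif(1, 0, 2 * pi); dd <- c(cos(th), sin(th))
    e1 <- group_elongation(x, y, dd)
    e2 <- group_elongation(x + 100, y - 50, dd)
    rot <- runif(1, 0, 2 * pi)
    xr <- x * cos(rot) - y * sin(rot)
    yr <- x * sin(rot) + y * cos(rot)
    dr <- c(dd[1] * cos(rot) - dd[2] * sin(rot),
            dd[1] * sin(rot) + dd[2] * cos(rot))
    e3 <- group_elongation(xr, yr, dr)
    expect_equal(e1, e2)
    expect_equal(e1, e3)
  }
})

test_that("cohesion rule counts individuals with a close conspecific", {
  set.seed(3)
  x <- runif(13, 0, 20); y <- runif(13, 0, 20)     # tight cluster
  expect_true(cohesion_flag(x, y))
  far <- seq(0, by = 60, length.out = 13)          # all isolated
  expect_false(cohesion_flag(far, rep(0, 13)))
  # exactly 10 clustered, 3 isolated: still cohesive
  x2 <- c(runif(10, 0, 15), 300, 400, 500)
  y2 <- c(runif(10, 0, 15), 0, 0, 0)
  expect_true(cohesion_flag(x2, y2))
  # 9 clustered, 4 isolated: not cohesive
  x3 <- c(runif(9, 0, 15), 300, 400, 500, 600)
  y3 <- c(runif(9, 0, 15), rep(0, 4))
  expect_false(cohesion_flag(x3, y3))
  # monotone: adding an individual inside the cluster never breaks cohesion
  expect_true(cohesion_flag(c(x2, 7), c(y2, 7)))
})

test_that("group state is internally consistent on a synthetic day", {
  state <- small_state()
  expect_true(all(state$polarization >= 0 & state$polarization <= 1,
                  na.rm = TRUE))
  expect_true(all(state$n_present <= 13))
  expect_true(all(state$elongation >= 0, na.rm = TRUE))
  expect_equal(nrow(state), 3 * 3600)
  # centroid is the mean of the individuals present
  ds <- small_dataset()
  sec <- state$t[1000]
  sub <- ds$trajectories[ds$trajectories$t == sec, ]
  expect_equal(state$cx[1000], mean(sub$x))
  expect_equal(state$cy[1000], mean(sub$y))
})
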