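test_that("affiliation matrix is symmetric and rank-coupled", {
  dom <- seq(0, 1, length.out = 13)
  A0 <- make_affiliation_matrix(13, dom, noise_sd = 0, seed = 1)
  expect_true(isSymmetric(A0))
  # zero noise, uniform dominance: constant off-diagonal
  Au <- make_affiliation_matrix(6, rep(0.5, 6), noise_sd = 0)
  off <- Au[row(Au) != col(Au)]
  expect_equal(var(off), 0)
  # the top-ranked pair has the largest expected (seed-averaged) affiliation
  Abar <- Reduce(`+`, lapply(1:100, function(s) {
    make_affiliation_matrix(13, dom, seed = s)
  })) / 100
  ut <- upper.tri(Abar)
  expect_equal(which.max(Abar[ut]),
               which(row(Abar)[ut] == 12 & col(Abar)[ut] == 13))
  expect_error(make_affiliation_matrix(1, 0.5), "at least 2")
})

test_that("planted order: chain recovery against brute-force arrangement", {
  # brute force: permutation minimizing sum A_ij |pos_i - pos_j|
  brute_best <- function(A) {
    n <- nrow(A)
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ]
    cost <- apply(perms, 1, function(p) {
      pos <- order(p)
      sum(A[upper.tri(A)] * abs(outer(pos, pos, "-")[upper.tri(A)]))
    })
    perms[which.min(cost), ]
  }
  set.seed(7)
  for (k in 1:5) {
    n <- 6
    A <- matrix(0.1, n, n)
    for (i in 1:(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 0.9
    eps <- matrix(rnorm(n * n, 0, 0.02), n)
    A <- pmin(pmax(A + (eps + t(eps)) / 2, 0.01), 1)
    diag(A) <- 0
    got <- order(plant_order(A))
    best <- order(brute_best(A))
    expect_true(all(got == best) || all(got == rev(best)))
  }
})

test_that("planted order: hubs are central, reflection is immaterial", {
  hub_sign <- sapply(1:50, function(s) {
    set.seed(s)
    n <- 7
    A <- matrix(0.15, n, n) + matrix(rnorm(n * n, 0, 0.02), n)
    A <- (A + t(A)) / 2
    A[1, ] <- A[, 1] <- 0.9
    diag(A) <- 0
    sl <- plant_order(A)
    cor(abs(sl), rowSums(A)) < 0
  })
  expect_gt(mean(hub_sign), 0.9)
  # a reflected slot vector is an equally valid arrangement: the pairwise
  # slot distances are identical
  A <- make_affiliation_matrix(8, seq(0, 1, length.out = 8), seed = 3)
  sl <- plant_order(A)
  expect_equal(abs(outer(sl, sl, "-")), abs(outer(-sl, -sl, "-")))
  # degenerate constant matrix: seeded arbitrary order, reproducible
  Ac <- matrix(0.4, 5, 5); diag(Ac) <- 0
  expect_equal(plant_order(Ac, seed = 9), plant_order(Ac, seed = 9))
})

test_that("dominance couples to centrality of the planted slots", {
  res <- sapply(1:50, function(s) {
    dom <- seq(0, 1, length.out = 13)
    A <- make_affiliation_matrix(13, dom, seed = s)
    sl <- plant_order(A)
    c(interior = cor(abs(sl), dom), signed = cor(sl, dom))
  })
  expect_true(all(res["interior", ] < 0))        # dominants central
  expect_lt(abs(median(res["signed", ])), 0.3)   # no front-back gradient
})

test_that("baseline movement encodes affiliation in equilibrium distances", {
  cfg <- sim_config(seed = 5)
  dom <- cfg$dominance
  A <- make_affiliation_matrix(13, dom, seed = 5)
  sim <- simulate_baseline(cfg, A, duration = 1200, seed = 6)
  D <- matrix(0, 13, 13)
  for (i in 1:12) for (j in (i + 1):13) {
    D[i, j] <- D[j, i] <- mean(sqrt((sim$X[, i] - sim$X[, j])^2 +
                                      (sim$Y[, i] - sim$Y[, j])^2))
  }
  ut <- upper.tri(A)
  expect_lt(cor(A[ut], D[ut], method = "spearman"), -0.4)
  # constant affiliation: anchor distances carry no preference structure
  Ac <- matrix(0.5, 13, 13); diag(Ac) <- 0
  cfgn <- sim_config(seed = 5, structure = "null")
  simn <- simulate_baseline(cfgn, Ac, duration = 600, seed = 6)
  expect_true(all(is.finite(simn$X)))
})

test_that("a noiseless progression has the planted geometry and order", {
  cfg <- sim_config(seed = 8, gps_noise_sd = 0, jitter_sd = 0)
  A <- make_affiliation_matrix(13, cfg$dominance, seed = 8)
  slots <- plant_order(A, cfg$formation_length)
  sim <- simulate_progression(cfg, slots, duration = 900, heading = 0.6,
                              order_noise_sd = 0, seed = 9)
  mid <- 450   # full formation at the core
  x <- sim$X[mid, ]; y <- sim$Y[mid, ]
  d <- c(cos(0.6), sin(0.6))
  elong <- group_elongation(x - mean(x), y - mean(y), d)
  expect_equal(elong, cfg$formation_length / cfg$formation_width,
               tolerance = 0.05)
  # ranks along the travel axis equal the planted slot ranks
  fb <- (x - mean(x)) * d[1] + (y - mean(y)) * d[2]
  expect_equal(rank(fb), rank(sim$lambda))
  # polarization of the noiseless core exceeds 0.95
  vels_x <- sim$X[mid + 1, ] - sim$X[mid - 1, ]
  vels_y <- sim$Y[mid + 1, ] - sim$Y[mid - 1, ]
  sp <- sqrt(vels_x^2 + vels_y^2)
  expect_gt(polarization(vels_x / sp, vels_y / sp), 0.95)
})

test_that("generation is deterministic: identical seeds, identical bytes", {
  cfg <- sim_config(n_days = 1, day_start = 8, day_end = 10, seed = 33)
  d1 <- generate(cfg)
  d2 <- generate(cfg)
  expect_identical(d1$trajectories, d2$trajectories)
  expect_identical(d1$events, d2$events)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(d1$trajectories, f1)
  write_trajectories(d2$trajectories, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  d3 <- generate(sim_config(n_days = 1, day_start = 8, day_end = 10, seed = 34))
  expect_false(identical(d1$trajectories$x, d3$trajectories$x))
})

test_that("scheduled events fit the day window and the duration bounds", {
  counts <- integer(0)
  for (s in 1:30) {
    cfg <- sim_config(seed = s)
    set.seed(s)
    ev <- troopline:::schedule_events(cfg, 43200)
    counts <- c(counts, nrow(ev))
    if (nrow(ev) > 0) {
      expect_true(all(ev$duration >= cfg$duration_min))
      expect_true(all(ev$duration <= cfg$duration_max))
      expect_true(all(ev$start > 0 & ev$start + ev$duration < 43200))
      if (nrow(ev) > 1) {
        gaps <- ev$start[-1] - (ev$start + ev$duration)[-nrow(ev)]
        expect_true(all(gaps > 0))
      }
    }
  }
  # Poisson(3)-ish schedule intensity
  expect_gt(mean(counts), 2)
  expect_lt(mean(counts), 4)
})

test_that("the default dataset is cohesive nearly all day", {
  state <- default_state()
  expect_gt(mean(state$cohesive), 0.95)
})

test_that("planted affiliations are recoverable from progression-network
           distances", {
  # four days so that per-pair means average over ~10 events
  ds <- generate(sim_config(n_days = 4, seed = 1))
  state <- group_state(ds$trajectories)
  ev <- detect_progressions(state)
  net <- pairwise_mean_distances(ds$trajectories,
                                 progression_mask(state, ev),
                                 context = "progression")
  ut <- upper.tri(ds$affiliation)
  expect_gte(cor(ds$affiliation[ut], -net$mean[ut], method = "spearman"),
             0.7)
})
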