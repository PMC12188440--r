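test_that("progression and rest-of-day masks partition cohesive time", {
  state <- small_state()
  ev <- small_events()
  prog <- progression_mask(state, ev)
  rest <- rest_of_day_mask(state, ev)
  expect_false(any(prog & rest))
  expect_equal(rest, state$cohesive & !prog)
  # progression + rest-of-day + excluded partitions the grid
  excluded <- !state$cohesive & !prog
  expect_equal(sum(prog) + sum(rest) + sum(excluded), nrow(state))
  # seconds inside events are never rest-of-day
  if (nrow(ev) > 0) {
    inside <- state$t >= ev$start_t[1] & state$t <= ev$end_t[1]
    expect_true(all(!rest[inside]))
    expect_true(all(prog[inside]))
  }
  # cohesive seconds outside events are rest-of-day
  outside <- state$cohesive & !prog
  expect_true(all(rest[outside]))
})

test_that("pairwise mean distances match a per-second oracle", {
  tr <- toy_pair_traj()            # constant 3 m apart
  net <- pairwise_mean_distances(tr, tr$t[1:50], context = "all")
  expect_equal(net$mean["A", "B"], 3)
  expect_equal(net$n_seconds["A", "B"], 50L)
  expect_true(isSymmetric(net$mean))

  # two seconds at distances 10 and 20: mean 15
  tr2 <- traj_table(data.frame(id = rep(c("A", "B"), each = 2),
                               t = rep(1000:1001, 2),
                               x = c(0, 0, 10, 20), y = 0))
  net2 <- pairwise_mean_distances(tr2, 1000:1001)
  expect_equal(net2$mean["A", "B"], 15)

  # random walks vs brute force
  set.seed(17)
  n <- 200
  tr3 <- traj_table(data.frame(
    id = rep(c("A", "B"), each = n), t = rep(2000 + 1:n, 2),
    x = c(cumsum(rnorm(n)), cumsum(rnorm(n))),
    y = c(cumsum(rnorm(n)), cumsum(rnorm(n)))
  ))
  keep <- 2000 + sample(n, 80)
  net3 <- pairwise_mean_distances(tr3, keep)
  a <- tr3[tr3$id == "A" & tr3$t %in% keep, ]
  b <- tr3[tr3$id == "B" & tr3$t %in% keep, ]
  expect_equal(net3$mean["A", "B"],
               mean(sqrt((a$x - b$x)^2 + (a$y - b$y)^2)))
})

test_that("association transforms are monotone decreasing in distance", {
  net <- pairwise_mean_distances(toy_pair_traj(), toy_pair_traj()$t)
  w <- to_association_weights(net)
  expect_equal(w$weight["A", "B"], 1 / net$mean["A", "B"])
  net$mean[] <- matrix(c(0, 2, 2, 0), 2)
  expect_equal(to_association_weights(net)$weight["A", "B"], 0.5)
  # weight order is the reverse of distance order, under every transform
  d <- c(5, 10, 20, 40)
  M <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  M[upper.tri(M)] <- c(d[1], d[2], d[3], d[4], d[1], d[2])
  M <- M + t(M)
  fake <- structure(list(context = "x", ids = letters[1:4], mean = M,
                         n_seconds = matrix(1, 4, 4)),
                    class = "distance_network")
  for (tf in c("inverse", "max_minus", "exp")) {
    W <- to_association_weights(fake, tf)$weight
    expect_true(all(diff(W[order(M[upper.tri(M)])][1]) <= 0) ||
                  cor(M[upper.tri(M)], W[upper.tri(W)], method = "spearman") == -1)
  }
  # zero distance breaks 1/d
  M0 <- M; M0[1, 2] <- M0[2, 1] <- 0
  fake$mean <- M0
  expect_error(to_association_weights(fake, "inverse"), "zero distance")
})

test_that("eigenvector centrality matches Perron structure and an oracle", {
  ids <- c("a", "b", "c", "d")
  # complete graph, equal weights: all equal, 1 after normalization
  W <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(W) <- 0
  net <- structure(list(context = "x", ids = ids, mean = W, n_seconds = W,
                        weight = W), class = "distance_network")
  ec <- eigenvector_centrality(net)
  expect_equal(ec$centrality, rep(1, 4))

  # 3-node path: centre strictly highest
  ids3 <- c("a", "b", "c")
  P <- matrix(0, 3, 3, dimnames = list(ids3, ids3))
  P["a", "b"] <- P["b", "a"] <- 1
  P["b", "c"] <- P["c", "b"] <- 1
  net3 <- structure(list(context = "x", ids = ids3,
                         mean = P + t(P) + 1, n_seconds = P, weight = P),
                    class = "distance_network")
  ec3 <- eigenvector_centrality(net3)
  expect_equal(ec3$centrality[ec3$id == "b"], 1)
  expect_lt(max(ec3$centrality[ec3$id != "b"]), 1)

  # arbitrary weighted graph vs power iteration
  set.seed(77)
  W4 <- matrix(runif(16, 0.1, 2), 4)
  W4 <- (W4 + t(W4)) / 2; diag(W4) <- 0
  dimnames(W4) <- list(ids, ids)
  net4 <- structure(list(context = "x", ids = ids, mean = 1 / W4,
                         n_seconds = W4, weight = W4),
                    class = "distance_network")
  ec4 <- eigenvector_centrality(net4)
  expect_equal(ec4$centrality, oracle_power_iteration(W4), tolerance = 1e-8)

  # centrality is invariant under global rescaling of the weights
  net5 <- net4; net5$weight <- W4 * 7.3
  expect_equal(eigenvector_centrality(net5)$centrality, ec4$centrality)

  # disconnected network: error naming components
  D <- matrix(0, 4, 4, dimnames = list(ids, ids))
  D["a", "b"] <- D["b", "a"] <- 1
  D["c", "d"] <- D["d", "c"] <- 1
  net6 <- structure(list(context = "x", ids = ids, mean = D + 1,
                         n_seconds = D, weight = D),
                    class = "distance_network")
  expect_error(eigenvector_centrality(net6), "disconnected")

  # undefined edge: error, not a silent zero
  miss <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(miss) <- 0
  miss["a", "b"] <- miss["b", "a"] <- NA
  net7 <- structure(list(context = "x", ids = ids, mean = miss,
                         n_seconds = miss, weight = miss),
                    class = "distance_network")
  expect_error(eigenvector_centrality(net7), "never co-tracked")
})

test_that("centrality-dominance regression recovers exact linear structure", {
  attrs <- tibble::tibble(id = letters[1:6], sex = "female",
                          dominance = seq(0, 1, length.out = 6))
  cent <- tibble::tibble(id = letters[1:6],
                         centrality = 0.2 + 0.5 * attrs$dominance,
                         context = "progression")
  # a noiseless linear relation makes summary.lm warn about the perfect fit
  fit <- suppressWarnings(centrality_vs_dominance(cent, attrs))
  expect_equal(fit$slope, 0.5)
  expect_equal(fit$r_squared, 1)
  # permuted labels: slope centred on zero
  set.seed(99)
  slopes <- replicate(300, {
    cent2 <- cent
    cent2$centrality <- sample(cent2$centrality)
    centrality_vs_dominance(cent2, attrs)$slope
  })
  expect_lt(abs(mean(slopes)), 0.05)
  # degenerate inputs
  expect_error(centrality_vs_dominance(cent[1:2, ], attrs), "at least 3")
  attrs$dominance <- 0.5
  expect_error(centrality_vs_dominance(cent, attrs), "constant")
})
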