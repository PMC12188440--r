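# three individuals walking east in fixed formation: B is 10 m from A,
# C is 30 m from A on the other side
toy_trio <- function(n = 20) {
  t0 <- 17744 * 86400 + 6 * 3600
  traj_table(data.frame(
    id = rep(c("A", "B", "C"), each = n),
    t = rep(t0 + seq_len(n) - 1, 3),
    x = rep(seq_len(n), 3),
    y = rep(c(0, 10, -30), each = n)
  ))
}

toy_events <- function(n = 20) {
  t0 <- 17744 * 86400 + 6 * 3600
  tibble::tibble(event_id = "E001", date = 17744L,
                 start_t = t0, end_t = t0 + n - 1, duration = n,
                 period = "daytime")
}

test_that("nearest neighbour series matches a brute-force scan", {
  ch <- nearest_neighbour_series(toy_trio(), toy_events(), focal = "A")
  expect_equal(unique(ch$neighbour), "B")   # 10 m beats 30 m
  # exact tie: lexicographically first id
  t0 <- 17744 * 86400 + 6 * 3600
  tie <- traj_table(data.frame(id = c("A", "C", "B"), t = t0,
                               x = c(0, 10, -10), y = 0))
  ev1 <- toy_events(1)
  ch2 <- nearest_neighbour_series(tie, ev1, focal = "A")
  expect_equal(ch2$neighbour, "B")
  # random configurations vs oracle
  set.seed(55)
  for (k in 1:15) {
    ids <- sprintf("I%02d", 1:6)
    xs <- rnorm(6, sd = 40); ys <- rnorm(6, sd = 40)
    tr <- traj_table(data.frame(id = ids, t = t0, x = xs, y = ys))
    ch3 <- nearest_neighbour_series(tr, ev1)
    for (f in ids) {
      expect_equal(ch3$neighbour[ch3$focal == f],
                   oracle_nearest(xs, ys, ids, f))
    }
  }
})

test_that("transition matrix counts within-event transitions only", {
  mk_chain <- function(nb, event = "E001", t0 = 0) {
    tibble::tibble(focal = "A", event_id = event,
                   t = t0 + seq_along(nb) - 1, neighbour = nb)
  }
  tm <- transition_matrix(mk_chain(c("B", "B", "B", "C", "C")))
  expect_equal(tm$probs["B", "B"], 2 / 3)
  expect_equal(tm$probs["B", "C"], 1 / 3)
  expect_equal(tm$probs["C", "C"], 1)
  expect_equal(sum(tm$counts), 4)
  expect_equal(unname(rowSums(tm$probs)), c(1, 1))  # row-stochastic

  tm2 <- transition_matrix(mk_chain(c("B", "B", "B")))
  expect_equal(tm2$probs["B", "B"], 1)

  # two events: no transition across the boundary
  two <- rbind(mk_chain(c("B", "B"), "E001", 0),
               mk_chain(c("C", "C"), "E002", 100))
  tm3 <- transition_matrix(two)
  expect_equal(tm3$counts["B", "C"], 0L)
  expect_equal(tm3$counts["B", "B"], 1L)
  expect_equal(tm3$counts["C", "C"], 1L)

  # a gap in seconds breaks the chain too
  gap <- mk_chain(c("B", "B", "C"))
  gap$t[3] <- gap$t[3] + 10
  tm4 <- transition_matrix(gap)
  expect_equal(tm4$counts["B", "C"], 0L)

  # oracle comparison on a random chain
  set.seed(66)
  nb <- sample(c("B", "C", "D"), 60, replace = TRUE)
  tm5 <- transition_matrix(mk_chain(nb))
  expect_equal(unclass(tm5$probs), unclass(oracle_transitions(nb)),
               ignore_attr = TRUE)
})

test_that("pair and focal consistency follow the Markov diagonal", {
  ch <- tibble::tibble(focal = "A", event_id = "E001", t = 0:4,
                       neighbour = c("B", "B", "B", "C", "C"))
  tm <- transition_matrix(ch)
  expect_equal(pair_consistency(tm, "B"), 2 / 3)
  expect_equal(pair_consistency(tm, "C"), 1)       # absorbing
  expect_true(is.na(pair_consistency(tm, "Z")))    # unseen state
  expect_equal(focal_consistency(ch), 3 / 4)
  # constant chain: 1; alternating chain: 0
  const <- ch; const$neighbour <- "B"
  expect_equal(focal_consistency(const), 1)
  alt <- ch; alt$neighbour <- rep(c("B", "C"), length.out = 5)
  expect_equal(focal_consistency(alt), 0)
  # a neighbour seen once with a switch out scores 0
  once <- tibble::tibble(focal = "A", event_id = "E", t = 0:1,
                         neighbour = c("D", "B"))
  expect_equal(pair_consistency(transition_matrix(once), "D"), 0)
})

test_that("focal consistency equals the count-weighted diagonal", {
  set.seed(44)
  for (k in 1:10) {
    nb <- sample(c("B", "C", "D"), 40, replace = TRUE)
    ch <- tibble::tibble(focal = "A", event_id = "E001", t = seq_along(nb),
                         neighbour = nb)
    tm <- transition_matrix(ch)
    rs <- rowSums(tm$counts)
    weighted <- sum(diag(tm$counts)) / sum(tm$counts)
    expect_equal(focal_consistency(ch), weighted)
    on_diag <- diag(tm$probs)[rs > 0]
    expect_equal(weighted, sum(on_diag * rs[rs > 0]) / sum(rs))
  }
})

test_that("consistency model table matches per-event recomputation", {
  attrs <- tibble::tibble(id = c("A", "B", "C"), sex = "female",
                          dominance = c(0.1, 0.5, 0.9))
  tr <- toy_trio()
  ev <- toy_events()
  chains <- nearest_neighbour_series(tr, ev)
  cm <- consistency_model_data(chains, attrs, ev)
  expect_true(all(c("id", "neighbour", "event_id", "consistency",
                    "dominance", "sex", "date") %in% names(cm)))
  # recompute one row with pair_consistency on the focal's chain
  for (i in seq_len(nrow(cm))) {
    sub <- chains[chains$focal == cm$id[i] & chains$event_id == cm$event_id[i], ]
    expect_equal(cm$consistency[i],
                 pair_consistency(transition_matrix(sub), cm$neighbour[i]))
  }
  # a missing pair yields no row
  expect_false(any(cm$id == "A" & cm$neighbour == "C"))  # A always keeps B
})
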