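# Shared fixtures, generated once per session and cached: several tests
# need the same synthetic dataset and its derived group state.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# small fast dataset: 1 day, 3 daytime hours
small_dataset <- function() {
  cached("small_ds", generate(sim_config(n_days = 1, day_start = 8,
                                         day_end = 11, seed = 11)))
}

small_state <- function() {
  cached("small_state", group_state(small_dataset()$trajectories))
}

small_events <- function() {
  cached("small_events", detect_progressions(small_state()))
}

# the default-condition dataset used by the acceptance checks (2 days)
default_dataset <- function() {
  cached("default_ds", generate(sim_config(seed = 1)))
}

default_state <- function() {
  cached("default_state", group_state(default_dataset()$trajectories))
}

default_events <- function() {
  cached("default_events", detect_progressions(default_state()))
}

# simple hand-built trajectory: two individuals walking east 1 m/s, 3 m
# apart, 100 s
toy_pair_traj <- function() {
  t0 <- 1533110400
  traj_table(data.frame(
    id = rep(c("A", "B"), each = 100),
    t = rep(t0 + 0:99, 2),
    x = c(0:99, 0:99),
    y = rep(c(0, 3), each = 100)
  ))
}
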