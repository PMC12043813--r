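# Shared fixtures and independent oracles, built in code at test time.

default_cfg <- default_parameter_set()

# Individual-level microsimulation oracle: simulates n_patients through the
# given per-cycle 9x9 transition matrices and returns occupancy proportions
# at each cycle start. Independent of the cohort engine's update rule.
microsim_occupancy <- function(matrices, start_dist, n_patients, seed) {
  set.seed(seed)
  n_states <- ncol(matrices[[1]])
  state <- sample.int(length(start_dist), n_patients, replace = TRUE,
                      prob = start_dist)
  occ <- matrix(0, length(matrices) + 1L, n_states)
  occ[1L, ] <- tabulate(state, n_states) / n_patients
  for (t in seq_along(matrices)) {
    cum <- t(apply(matrices[[t]], 1L, cumsum))
    u <- runif(n_patients)
    state <- rowSums(u > cum[state, , drop = FALSE]) + 1L
    occ[t + 1L, ] <- tabulate(state, n_states) / n_patients
  }
  occ
}

# Per-cycle transition matrices for a strategy, assembled through the
# public single-cycle operations (not the cohort engine's internal fast
# path).
strategy_matrices <- function(config, strategy, n_cycles) {
  years <- (seq_len(n_cycles) - 1L) * config$cycle_length_years
  ages <- config$start_age + years
  lapply(seq_len(n_cycles), function(t) {
    m <- effect_trajectory(config, strategy, years[t])
    q <- cycle_death_prob(ages[t], config$mortality, config$male_fraction,
                          config$cycles_per_year)
    build_matrix(cycle_change_probs(m), q)
  })
}

# Brute-force frontier oracle: a strategy is on the cost-effectiveness
# frontier iff it maximises NMB for some willingness-to-pay threshold.
# Candidate thresholds are midpoints between consecutive pairwise ICERs
# (exact for instances in general position).
brute_force_frontier_set <- function(df) {
  n <- nrow(df)
  icers <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dq <- df$qalys[j] - df$qalys[i]
    dc <- df$cost[j] - df$cost[i]
    if (dq > 0 && dc > 0) icers <- c(icers, dc / dq)
  }
  icers <- sort(unique(icers))
  lambdas <- c(icers[1] / 2, (head(icers, -1) + tail(icers, -1)) / 2,
               max(icers) * 2)
  winners <- unique(unlist(lapply(lambdas, function(l) {
    v <- df$qalys * l - df$cost
    df$name[abs(v - max(v)) < 1e-9]
  })))
  sort(winners)
}

# Random strategy-set instances for frontier property tests.
random_ce_instance <- function(n = 6) {
  data.frame(name = paste0("S", seq_len(n)),
             cost = runif(n, 5000, 40000),
             qalys = runif(n, 10, 13),
             stringsAsFactors = FALSE)
}

# A small configuration with an immortal cohort (zero death probability),
# used to isolate the visual-transition dynamics.
immortal_config <- function(config = default_cfg, horizon_age = 66) {
  lt <- config$mortality$life_table
  lt$qx <- 0
  config$mortality$life_table <- lt
  config$horizon_age <- horizon_age
  config
}
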