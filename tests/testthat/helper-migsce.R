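# Shared fixtures built in code.

# Deterministic life tables for exact-arithmetic checks.
zero_mortality_table <- function() gen_life_table(makeham_a = 0, gompertz_b = 0)
certain_death_table <- function() {
  suppressWarnings(gen_life_table(makeham_a = 1e6, gompertz_b = 0))
}

default_inputs <- function(config = default_config()) {
  migsce:::build_inputs(config)
}

# Hand-rolled trace object for payoff-accumulation unit tests.
manual_trace <- function(occupancy, entry = rep(0, nrow(occupancy)),
                         half_cycle = FALSE) {
  colnames(occupancy) <- migs_states()
  structure(list(occupancy = occupancy, entry = entry,
                 ages = seq_len(nrow(occupancy)),
                 config = cohort_config(half_cycle = half_cycle)),
            class = "migs_trace")
}

# Independent individual-level microsimulation with the same per-cycle
# transition matrices as the cohort model; oracle for trace equivalence.
microsim_trace <- function(strat, tmodel, life_table, config, n_ind = 5000) {
  states <- migs_states()
  state <- rep(match(config$start_state, states), n_ind)
  ages <- config$start_age:config$max_age
  occ <- matrix(0, length(ages), 5, dimnames = list(NULL, states))
  occ[1, ] <- tabulate(state, 5) / n_ind
  for (t in seq_len(length(ages) - 1)) {
    m <- build_transition_matrix(ages[t], tmodel, strat, life_table, config)
    old <- state
    for (s in which(tabulate(old, 5) > 0)) {
      idx <- which(old == s)
      state[idx] <- sample.int(5, length(idx), replace = TRUE, prob = m[s, ])
    }
    occ[t + 1, ] <- tabulate(state, 5) / n_ind
    if (all(state == 5)) {
      occ[(t + 1):length(ages), 5] <- 1
      break
    }
  }
  occ
}
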