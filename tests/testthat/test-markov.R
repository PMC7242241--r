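test_that("five-year to annual probability conversion is exact and invertible", {
  expect_equal(five_year_to_annual(0), 0)
  expect_equal(five_year_to_annual(1), 1)
  expect_equal(five_year_to_annual(0.36), 0.0853899, tolerance = 1e-6)
  p5 <- seq(0.02, 0.98, by = 0.08)
  expect_equal(1 - (1 - five_year_to_annual(p5))^5, p5, tolerance = 1e-12)
  expect_error(five_year_to_annual(1.2), "\\[0, 1\\]")
})

test_that("IOP-to-progression mapping slows but never inverts progression", {
  expect_equal(progression_multiplier(0), 1)
  expect_equal(apply_progression_effect(0, progression_multiplier(4)), 0)

  # independently coded rate transform: p -> rate -> scaled rate -> p
  r <- -log(1 - 0.124)
  p_expect <- 1 - exp(-r * (1 - 0.0031)^2.8)
  got <- apply_progression_effect(0.124, progression_multiplier(2.8))
  expect_equal(got, p_expect, tolerance = 1e-12)
  expect_equal(round(got, 6), 0.122996)
  expect_lt(got, 0.124)

  # linear mode and its clamp
  expect_equal(progression_multiplier(2.8, mode = "linear"), 1 - 0.0031 * 2.8)
  expect_warning(m <- progression_multiplier(400, mode = "linear"), "clamped")
  expect_equal(m, 0)
  expect_error(progression_multiplier(-1), ">= 0")
})

test_that("sex-mixed mortality is the weighted mean of the life-table rows", {
  lt <- data.frame(age = 60:70, q_female = rep(0.01, 11),
                   q_male = rep(0.02, 11))
  lt$q_female[11] <- 1; lt$q_male[11] <- 1
  lt <- migsce:::validate_life_table(lt)
  expect_equal(mixed_mortality(65, 1, lt), 0.01)
  expect_equal(mixed_mortality(65, 0.442, lt), 0.442 * 0.01 + 0.558 * 0.02)
  expect_equal(mixed_mortality(200, 0.5, lt), 1)  # beyond terminal age
  lt2 <- migsce:::validate_life_table(
    data.frame(age = 60:70, q_female = c(rep(0.03, 10), 1),
               q_male = c(rep(0.03, 10), 1)))
  expect_equal(mixed_mortality(64, 0.7, lt2), 0.03)  # equal sexes: any mix
})

test_that("transition matrices are row-stochastic with the specified structure", {
  tm <- read_transitions()
  expect_equal(unname(tm$p_stay["early"] + tm$p_progress["early"]), 1)

  lt0 <- zero_mortality_table()
  cfg <- cohort_config()
  m <- build_transition_matrix(70, tm, NULL, lt0, cfg)
  expect_equal(unname(m["early", ]), c(0.915, 0.085, 0, 0, 0))
  expect_equal(unname(m["moderate", ]), c(0, 0.876, 0.124, 0, 0))
  expect_equal(rowSums(m), setNames(rep(1, 5), migs_states()))
  # blindness only to itself or death; no backward transitions
  expect_equal(unname(m["blind", c("early", "moderate", "advanced")]), rep(0, 3))
  expect_true(all(m[lower.tri(m)] == 0))

  # zero progression and zero mortality: identity
  tm0 <- transition_model(p_stay = c(early = 1, moderate = 1, advanced = 1),
                          p_progress = c(early = 0, moderate = 0, advanced = 0))
  expect_equal(build_transition_matrix(70, tm0, NULL, lt0, cfg),
               diag(5), ignore_attr = TRUE)

  # certain death maps every living state to dead
  m1 <- build_transition_matrix(70, tm, NULL, certain_death_table(), cfg)
  expect_equal(unname(m1[, "dead"]), rep(1, 5))
})

test_that("cohort traces satisfy occupancy invariants", {
  inp <- default_inputs()
  tr <- run_cohort(NULL, inp$tmodel, inp$life_table, inp$cohort)
  expect_equal(rowSums(tr$occupancy), rep(1, nrow(tr$occupancy)),
               tolerance = 1e-9)
  expect_true(all(tr$occupancy >= 0 & tr$occupancy <= 1))
  expect_true(all(diff(tr$occupancy[, "dead"]) >= 0))

  # single cycle from early with no deaths reproduces the transition row
  tr1 <- run_cohort(NULL, inp$tmodel, zero_mortality_table(), inp$cohort)
  expect_equal(unname(tr1$occupancy[2, ]), c(0.915, 0.085, 0, 0, 0))

  # certain death at start age: fully dead after one cycle
  trd <- run_cohort(NULL, inp$tmodel, certain_death_table(), inp$cohort)
  expect_equal(unname(trd$occupancy[2, "dead"]), 1)
  expect_equal(nrow(trd$occupancy), 2L)

  # zero progression, zero mortality: constant trace
  tm0 <- transition_model(p_stay = c(early = 1, moderate = 1, advanced = 1),
                          p_progress = c(early = 0, moderate = 0, advanced = 0))
  trc <- run_cohort(NULL, tm0, zero_mortality_table(), inp$cohort)
  expect_true(all(trc$occupancy[, "early"] == 1))
})

test_that("a zero VF coefficient reproduces the reference trace bit-exactly", {
  inp <- default_inputs()
  ref <- run_cohort(strategy("cataract_alone", "moderate", 0, 224.84),
                    inp$tmodel, inp$life_table, inp$cohort)
  st <- strategy("two_tmbs", "moderate", extra_iop_reduction = 2.8,
                 intervention_cost = 937.34, vf_coefficient = 0)
  alt <- run_cohort(st, inp$tmodel, inp$life_table, inp$cohort)
  expect_identical(alt$occupancy, ref$occupancy)
  expect_identical(alt$entry, ref$entry)
})

test_that("larger IOP effects never reduce pre-progression occupancy or QALYs", {
  inp <- default_inputs()
  effects <- c(0, 0.5, 1, 2, 3.5, 5)
  qalys <- numeric(length(effects))
  stay_mass <- numeric(length(effects))
  for (i in seq_along(effects)) {
    st <- strategy("x", "moderate", effects[i], 0)
    tr <- run_cohort(st, inp$tmodel, inp$life_table, inp$cohort)
    qalys[i] <- accumulate(tr, inp$payoffs, 0, 0.03)$qaly
    stay_mass[i] <- sum(tr$occupancy[, c("early", "moderate")])
  }
  expect_true(all(diff(qalys) >= 0))
  expect_true(all(diff(stay_mass) >= 0))
})

test_that("cohort trace agrees with an individual-level microsimulation", {
  inp <- default_inputs()
  st <- strategy("two_tmbs", "moderate", 2.8, 937.34)
  tr <- run_cohort(st, inp$tmodel, inp$life_table, inp$cohort)
  set.seed(2021)
  n_ind <- 5000
  micro <- microsim_trace(st, inp$tmodel, inp$life_table, inp$cohort, n_ind)
  n <- nrow(tr$occupancy)
  p <- tr$occupancy
  se <- sqrt(p * (1 - p) / n_ind)
  d <- abs(micro[seq_len(n), ] - p)
  # per-cell occupancy is binomial, but cells along a path are correlated, so
  # allow rare 3-4 SE excursions while bounding everything at 4 SE
  expect_true(all(d <= pmax(4 * se, 0.005)))
  expect_gte(mean(d <= pmax(3 * se, 0.004)), 0.98)
})

test_that("discounted life-years match the closed-form life-table annuity", {
  inp <- default_inputs()
  tm0 <- transition_model(p_stay = c(early = 1, moderate = 1, advanced = 1),
                          p_progress = c(early = 0, moderate = 0, advanced = 0))
  tr <- run_cohort(NULL, tm0, inp$life_table, inp$cohort)
  pay <- stage_payoffs(utility = c(early = 1, moderate = 1, advanced = 1,
                                   blind = 1),
                       annual_cost = c(early = 0, moderate = 0, advanced = 0,
                                       blind = 0))
  got <- accumulate(tr, pay, 0, 0.03)$qaly
  want <- life_expectancy(inp$life_table, 63, 0.442, 0.03)
  expect_equal(got, want, tolerance = 1e-9)
})
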