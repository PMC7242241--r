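#' Model health states
#'
#' The five mutually exclusive states of the cohort model: the three POAG
#' severity stages of the Hodapp-Parrish-Anderson classification (early,
#' mean deviation better than -6 dB; moderate, to -12 dB; advanced, beyond),
#' blindness (mean deviation at or beyond -22 dB) and death. Death is
#' absorbing; blindness admits no recovery.
#'
#' @return Character vector of state names, in progression order.
#' @export
migs_states <- function() c("early", "moderate", "advanced", "blind", "dead")

#' Convert a 5-year progression probability to an annual one
#'
#' Standard constant-rate conversion: `1 - (1 - p5)^(1/5)`.
#'
#' @param p5 Probability over five years, in `[0, 1]`.
#' @return Annual probability.
#' @export
five_year_to_annual <- function(p5) {
  if (any(!is.finite(p5) | p5 < 0 | p5 > 1)) {
    stop("five_year_to_annual: p5 must lie in [0, 1]", call. = FALSE)
  }
  1 - (1 - p5)^(1 / 5)
}

#' Annual rate multiplier for extra IOP reduction
#'
#' Each additional mmHg of IOP reduction slows perimetric progression by a
#' fraction `coefficient` (default 0.31% per year per mmHg). The default
#' multiplicative mapping compounds the slowing on the annual progression
#' *rate*: `m = (1 - coefficient)^extra_iop`, applied as
#' `p' = 1 - (1 - p)^m` (i.e. `r' = m * r` on the log scale), which keeps
#' probabilities in `[0, 1]` and reduces to the identity at zero effect. The
#' `linear` mode uses `m = 1 - coefficient * extra_iop`, clamped at 0 with a
#' warning if the product reaches 1.
#'
#' @param extra_iop Extra IOP reduction vs the reference strategy (mmHg, >= 0).
#' @param coefficient Fractional progression slowing per mmHg per year.
#' @param mode `"multiplicative"` (default) or `"linear"`.
#' @return Rate multiplier in `[0, 1]`.
#' @export
progression_multiplier <- function(extra_iop, coefficient = 0.0031,
                                   mode = c("multiplicative", "linear")) {
  mode <- match.arg(mode)
  if (any(extra_iop < 0)) {
    stop("progression_multiplier: extra_iop must be >= 0", call. = FALSE)
  }
  if (mode == "multiplicative") {
    (1 - coefficient)^extra_iop
  } else {
    m <- 1 - coefficient * extra_iop
    if (any(m < 0)) {
      warning("linear mapping clamped to zero progression rate")
      m <- pmax(m, 0)
    }
    m
  }
}

#' Apply a rate multiplier to an annual probability
#'
#' @param p Annual probability.
#' @param multiplier Rate multiplier from [progression_multiplier()].
#' @return Adjusted annual probability `1 - (1 - p)^multiplier`.
#' @export
apply_progression_effect <- function(p, multiplier) {
  1 - (1 - p)^multiplier
}

#' Stage transition model
#'
#' Annual stay/progress probabilities for the three POAG stages under
#' standard of care. Each stage's pair must sum to 1 (mortality is applied
#' separately, per cycle).
#'
#' @param p_stay,p_progress Named numeric vectors over
#'   `c("early", "moderate", "advanced")`.
#' @return An object of class `migs_transitions`.
#' @export
transition_model <- function(p_stay, p_progress) {
  stages <- c("early", "moderate", "advanced")
  p_stay <- p_stay[stages]; p_progress <- p_progress[stages]
  if (anyNA(p_stay) || anyNA(p_progress)) {
    stop("transition_model: need probabilities for early, moderate, advanced",
         call. = FALSE)
  }
  if (any(p_stay < 0 | p_stay > 1 | p_progress < 0 | p_progress > 1)) {
    stop("transition_model: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(p_stay + p_progress - 1) > 1e-9)) {
    stop("transition_model: stay + progress must equal 1 per stage",
         call. = FALSE)
  }
  structure(list(p_stay = p_stay, p_progress = p_progress),
            class = "migs_transitions")
}

#' Read stage transition probabilities from CSV
#'
#' Columns `stage`, `p_stay`, `p_progress`; `#` lines are comments.
#'
#' @param path CSV path; defaults to the packaged standard-of-care table.
#' @return A [transition_model()].
#' @export
read_transitions <- function(path = migs_fixture("table4_transitions.csv")) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  transition_model(stats::setNames(d$p_stay, d$stage),
                   stats::setNames(d$p_progress, d$stage))
}

#' Read an age/sex life table from CSV
#'
#' Columns `age`, `q_female`, `q_male` (annual death probabilities), one row
#' per integer age, contiguous, with `q = 1` at the terminal age.
#'
#' @param path CSV path.
#' @return A data frame of class `migs_life_table`.
#' @export
read_life_table <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_life_table(d)
}

validate_life_table <- function(d) {
  need <- c("age", "q_female", "q_male")
  if (!all(need %in% names(d))) {
    stop("life table needs columns age, q_female, q_male", call. = FALSE)
  }
  d <- d[order(d$age), ]
  if (any(diff(d$age) != 1L)) stop("life table ages must be contiguous", call. = FALSE)
  q <- c(d$q_female, d$q_male)
  if (any(!is.finite(q) | q < 0 | q > 1)) {
    stop("life table probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (d$q_female[nrow(d)] != 1 || d$q_male[nrow(d)] != 1) {
    stop("life table must end with q = 1 at the terminal age", call. = FALSE)
  }
  class(d) <- c("migs_life_table", "data.frame")
  d
}

#' Sex-mixed annual mortality
#'
#' Weighted mean of the female and male annual death probabilities at a given
#' age; ages beyond the terminal age return 1.
#'
#' @param age Age in whole years (vectorized).
#' @param female_fraction Proportion of females in the cohort.
#' @param table A life table from [read_life_table()] or [gen_life_table()].
#' @return Annual death probability.
#' @export
mixed_mortality <- function(age, female_fraction, table) {
  if (female_fraction < 0 || female_fraction > 1) {
    stop("mixed_mortality: female_fraction must lie in [0, 1]", call. = FALSE)
  }
  idx <- match(age, table$age)
  q <- female_fraction * table$q_female[idx] +
    (1 - female_fraction) * table$q_male[idx]
  q[age > max(table$age)] <- 1
  if (anyNA(q)) stop("mixed_mortality: age below table range", call. = FALSE)
  q
}

#' Cohort configuration
#'
#' @param start_age Cohort age at model start (years).
#' @param female_fraction Proportion female.
#' @param start_state Initial state (default `"early"`).
#' @param max_age Age cap for the lifetime horizon.
#' @param discount_rate Annual discount rate applied to costs and QALYs after
#'   year one.
#' @param half_cycle Use half-cycle-corrected state membership when
#'   accumulating payoffs (default `FALSE`: payoffs accrue at cycle start).
#' @return An object of class `migs_cohort_config`.
#' @export
cohort_config <- function(start_age = 63, female_fraction = 0.442,
                          start_state = "early", max_age = 110,
                          discount_rate = 0.03, half_cycle = FALSE) {
  if (female_fraction < 0 || female_fraction > 1) {
    stop("cohort_config: female_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (discount_rate < 0) stop("cohort_config: discount_rate must be >= 0", call. = FALSE)
  if (!start_state %in% migs_states()[1:4]) {
    stop("cohort_config: start_state must be a living state", call. = FALSE)
  }
  if (max_age <= start_age) stop("cohort_config: max_age must exceed start_age", call. = FALSE)
  structure(list(start_age = start_age, female_fraction = female_fraction,
                 start_state = start_state, max_age = max_age,
                 discount_rate = discount_rate, half_cycle = half_cycle),
            class = "migs_cohort_config")
}

#' Treatment strategy
#'
#' A comparator arm of the cost-utility analysis: the stage at which the
#' (combined) surgery is performed, the extra 1-year IOP reduction relative
#' to the reference of cataract surgery alone, and the one-off intervention
#' cost booked at stage entry.
#'
#' @param name Strategy name.
#' @param application_stage `"moderate"` or `"advanced"`.
#' @param extra_iop_reduction Extra IOP reduction vs reference (mmHg, >= 0).
#' @param intervention_cost One-off cost (EUR) booked when cohort mass enters
#'   the application stage.
#' @param vf_coefficient Progression slowing per mmHg per year.
#' @param vf_mapping `"multiplicative"` or `"linear"` (see
#'   [progression_multiplier()]).
#' @return An object of class `migs_strategy`.
#' @export
strategy <- function(name, application_stage = c("moderate", "advanced"),
                     extra_iop_reduction = 0, intervention_cost = 0,
                     vf_coefficient = 0.0031,
                     vf_mapping = c("multiplicative", "linear")) {
  application_stage <- match.arg(application_stage)
  vf_mapping <- match.arg(vf_mapping)
  if (extra_iop_reduction < 0) {
    stop("strategy: extra_iop_reduction must be >= 0", call. = FALSE)
  }
  structure(list(name = name, application_stage = application_stage,
                 extra_iop_reduction = extra_iop_reduction,
                 intervention_cost = intervention_cost,
                 vf_coefficient = vf_coefficient, vf_mapping = vf_mapping),
            class = "migs_strategy")
}

# Progression probabilities with the strategy's effect applied to the
# application stage and all later stages. Because the cohort starts no later
# than the application stage and never moves backward, any mass occupying
# those stages has entered them, hence carries the treatment effect.
treated_progression <- function(tmodel, strat = NULL) {
  p <- tmodel$p_progress
  if (is.null(strat) || strat$extra_iop_reduction == 0) return(p)
  m <- progression_multiplier(strat$extra_iop_reduction, strat$vf_coefficient,
                              strat$vf_mapping)
  if (m == 1) return(p)
  stages <- c("early", "moderate", "advanced")
  affected <- stages[match(strat$application_stage, stages):3]
  p[affected] <- apply_progression_effect(p[affected], m)
  p
}

#' Annual transition matrix at a given age
#'
#' Death is applied first: every living state moves to `dead` with the
#' sex-mixed annual probability; the surviving mass is split by the
#' stay/progress probabilities, with the strategy's progression slowing
#' applied to its application stage and all later stages. `blind` transitions
#' only to itself or to `dead`; there are no backward transitions.
#'
#' @param age Cohort age at cycle start.
#' @param tmodel A [transition_model()].
#' @param strat A [strategy()] or `NULL` for standard of care.
#' @param life_table Life table.
#' @param config A [cohort_config()].
#' @return A 5x5 row-stochastic matrix over [migs_states()].
#' @export
build_transition_matrix <- function(age, tmodel, strat = NULL, life_table,
                                    config = cohort_config()) {
  q <- mixed_mortality(age, config$female_fraction, life_table)
  p <- treated_progression(tmodel, strat)
  s <- migs_states()
  m <- matrix(0, 5, 5, dimnames = list(s, s))
  surv <- 1 - q
  m["early", "early"] <- surv * (1 - p[["early"]])
  m["early", "moderate"] <- surv * p[["early"]]
  m["moderate", "moderate"] <- surv * (1 - p[["moderate"]])
  m["moderate", "advanced"] <- surv * p[["moderate"]]
  m["advanced", "advanced"] <- surv * (1 - p[["advanced"]])
  m["advanced", "blind"] <- surv * p[["advanced"]]
  m["blind", "blind"] <- surv
  m[s[1:4], "dead"] <- q
  m["dead", "dead"] <- 1
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("build_transition_matrix: rows do not sum to 1", call. = FALSE)
  }
  m
}

#' Run the lifetime cohort simulation
#'
#' Iterates the cohort in yearly cycles from the starting age until the age
#' cap or extinction of the living mass. Row `t` of the trace is the state
#' occupancy at the start of year `t` (row 1 is the initial distribution);
#' the transition during year `t` uses the mortality of age
#' `start_age + t - 1`. The `entry` vector records the cohort mass newly
#' arriving in the strategy's application stage at the start of each year
#' (initial occupancy of that stage counts as entering in year 1); one-off
#' intervention costs are booked against it.
#'
#' @param strat A [strategy()] or `NULL` for standard of care (no entry
#'   accounting).
#' @param tmodel A [transition_model()].
#' @param life_table Life table.
#' @param config A [cohort_config()].
#' @return An object of class `migs_trace`: list with `occupancy` (years x 5
#'   matrix), `entry`, `ages`.
#' @export
run_cohort <- function(strat = NULL, tmodel, life_table,
                       config = cohort_config()) {
  s <- migs_states()
  q_age <- config$start_age:config$max_age
  q <- mixed_mortality(q_age, config$female_fraction, life_table)
  p <- treated_progression(tmodel, strat)
  pe <- p[["early"]]; pm <- p[["moderate"]]; pa <- p[["advanced"]]
  app <- if (is.null(strat)) NA_character_ else strat$application_stage

  n_max <- length(q_age)
  occ <- matrix(0, n_max, 5, dimnames = list(NULL, s))
  entry <- numeric(n_max)
  x <- stats::setNames(numeric(5), s)
  x[config$start_state] <- 1
  if (!is.na(app)) entry[1] <- x[[app]]

  t <- 1L
  occ[1L, ] <- x
  while (t < n_max && x[["dead"]] <= 1 - 1e-12) {
    surv <- 1 - q[t]
    xn <- c(
      early    = x[["early"]] * surv * (1 - pe),
      moderate = surv * (x[["early"]] * pe + x[["moderate"]] * (1 - pm)),
      advanced = surv * (x[["moderate"]] * pm + x[["advanced"]] * (1 - pa)),
      blind    = surv * (x[["advanced"]] * pa + x[["blind"]]),
      dead     = x[["dead"]] + q[t] * (1 - x[["dead"]])
    )
    t <- t + 1L
    occ[t, ] <- xn
    if (!is.na(app)) {
      entry[t] <- switch(app,
                         moderate = x[["early"]] * surv * pe,
                         advanced = x[["moderate"]] * surv * pm)
    }
    x <- xn
  }
  occ <- occ[seq_len(t), , drop = FALSE]
  structure(list(occupancy = occ, entry = entry[seq_len(t)],
                 ages = config$start_age + seq_len(t) - 1L,
                 config = config),
            class = "migs_trace")
}

#' @export
print.migs_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  cat(sprintf("Cohort trace: %d yearly cycles, ages %d-%d; final dead share %.4f\n",
              n, x$ages[1], x$ages[n], x$occupancy[n, "dead"]))
  invisible(x)
}
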