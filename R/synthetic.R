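#' Path to a packaged input table
#'
#' @param name File name under the package's `extdata` directory; with no
#'   argument, all packaged fixtures are listed.
#' @return File path(s).
#' @export
migs_fixture <- function(name = NULL) {
  if (is.null(name)) {
    return(list.files(system.file("extdata", package = "migsce"),
                      full.names = TRUE))
  }
  p <- system.file("extdata", name, package = "migsce")
  if (p == "") stop("no packaged fixture named '", name, "'", call. = FALSE)
  p
}

#' Generate a Gompertz-Makeham life table
#'
#' Synthetic all-cause mortality by age and sex, used in place of a national
#' life table: hazard `h(age) = a + b * exp(c * age)` for females, multiplied
#' by `male_multiplier` for males, converted to annual probabilities
#' `q = 1 - exp(-h)`. Defaults are tuned so that remaining life expectancy at
#' age 63 is around 19-20 years, in the range of recent German values. The
#' table is deterministic given its parameters; `q` is forced to 1 at the
#' terminal age.
#'
#' @param makeham_a Age-independent baseline hazard per year.
#' @param gompertz_b Hazard scale of the senescent component.
#' @param gompertz_c Log-hazard slope per year of age.
#' @param male_multiplier Multiplier on the male hazard.
#' @param ages Integer ages covered; the last is the terminal age.
#' @return A `migs_life_table` data frame (`age`, `q_female`, `q_male`).
#' @export
gen_life_table <- function(makeham_a = 2e-4, gompertz_b = 1e-5,
                           gompertz_c = 0.103, male_multiplier = 1.6,
                           ages = 0:110) {
  h_f <- makeham_a + gompertz_b * exp(gompertz_c * ages)
  h_m <- male_multiplier * h_f
  q_f <- 1 - exp(-h_f)
  q_m <- 1 - exp(-h_m)
  if (any(q_f[-length(ages)] >= 1) || any(q_m[-length(ages)] >= 1)) {
    warning("gen_life_table: probabilities clamped below the terminal age")
  }
  q_f <- pmin(q_f, 1); q_m <- pmin(q_m, 1)
  q_f[length(ages)] <- 1; q_m[length(ages)] <- 1
  validate_life_table(data.frame(age = ages, q_female = q_f, q_male = q_m))
}

#' Remaining (optionally discounted) life expectancy from a life table
#'
#' Annuity sum over the survival curve with the model's cycle-start
#' convention: a year is credited to everyone alive at its start, so the
#' undiscounted value is `sum_{t>=1} S(t-1)` with `S(0) = 1`.
#'
#' @param table Life table.
#' @param age Starting age.
#' @param female_fraction Sex mix.
#' @param rate Discount rate (0 for plain life expectancy); discounting
#'   starts after year one, as in the cohort model.
#' @return Expected (discounted) life years.
#' @export
life_expectancy <- function(table, age, female_fraction = 0.5, rate = 0) {
  ages <- age:max(table$age)
  q <- mixed_mortality(ages, female_fraction, table)
  surv <- cumprod(c(1, 1 - q))[seq_along(ages)]
  sum(discount_factor(seq_along(ages), rate) * surv)
}

#' Simulate a two-arm trial with a known true effect
#'
#' Draws per-subject correlated (baseline, year-1) IOP pairs for an
#' intervention and a control arm. The control arm's mean change is
#' `control_effect` (the cataract-alone effect); the intervention arm's mean
#' change is shifted by `true_effect` (negative = larger IOP reduction).
#' Summaries are returned in the same per-arm format as the published trial
#' table, with arm sizes, so standard errors propagate.
#'
#' @param true_effect True relative effect, intervention minus control change
#'   (mmHg).
#' @param n_per_arm Subjects per arm (>= 2).
#' @param baseline_mean,baseline_sd Baseline IOP distribution (mmHg).
#' @param followup_sd Year-1 SD; defaults to `baseline_sd`.
#' @param control_effect Mean change in the control arm (mmHg).
#' @param rho Within-subject baseline/follow-up correlation.
#' @param study_id Identifier attached to the trial.
#' @param seed Optional seed for reproducibility.
#' @return A [two_arm_trial()] carrying a `true_effect` attribute.
#' @export
gen_trial <- function(true_effect, n_per_arm = 100, baseline_mean = 19,
                      baseline_sd = 3, followup_sd = baseline_sd,
                      control_effect = -2.05, rho = 0.5,
                      study_id = "synthetic", seed = NULL) {
  if (n_per_arm < 2) stop("gen_trial: n_per_arm must be >= 2", call. = FALSE)
  if (baseline_sd <= 0) stop("gen_trial: baseline_sd must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  draw_arm <- function(label, delta) {
    b <- stats::rnorm(n_per_arm, baseline_mean, baseline_sd)
    f <- baseline_mean + delta +
      rho * (followup_sd / baseline_sd) * (b - baseline_mean) +
      stats::rnorm(n_per_arm, 0, followup_sd * sqrt(1 - rho^2))
    trial_arm(label, mean(b), stats::sd(b), mean(f), stats::sd(f),
              n = n_per_arm)
  }
  tr <- two_arm_trial(study_id,
                      draw_arm("intervention", control_effect + true_effect),
                      draw_arm("control", control_effect),
                      rho = rho)
  attr(tr, "true_effect") <- true_effect
  tr
}
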