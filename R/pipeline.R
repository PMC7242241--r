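#' Read stage utilities from CSV
#'
#' @param path CSV with columns `state`, `utility`, `utility_sd`.
#' @return Data frame with one row per state.
#' @export
read_utilities <- function(path = migs_fixture("table3_utilities.csv")) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("state", "utility", "utility_sd") %in% names(d))) {
    stop("read_utilities: need columns state, utility, utility_sd", call. = FALSE)
  }
  d
}

#' Read stage cost components from CSV and total them
#'
#' @param path CSV with columns `stage`, `component`, `mean`, `sd`.
#' @return List with `components` (as read) and `totals` (data frame `stage`,
#'   `mean`, `sd` recomputed with [stage_cost_total()]).
#' @export
read_costs <- function(path = migs_fixture("table5_costs.csv")) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stages <- unique(d$stage)
  totals <- do.call(rbind, lapply(stages, function(s) {
    tot <- stage_cost_total(d$mean[d$stage == s], d$sd[d$stage == s])
    data.frame(stage = s, mean = tot$mean, sd = tot$sd)
  }))
  list(components = d, totals = totals)
}

#' Read one-off intervention costs from CSV
#'
#' @param path CSV with columns `intervention`, `migs_procedure`,
#'   `cataract_surgery`.
#' @return Data frame with a recomputed `total` column.
#' @export
read_interventions <- function(path = migs_fixture("table6_interventions.csv")) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  d$total <- d$migs_procedure + d$cataract_surgery
  rownames(d) <- d$intervention
  d
}

#' Read published anchored effects (with CIs) from CSV
#'
#' Standard errors are back-derived from the normal-approximation 95% CIs;
#' they parameterize effect uncertainty in the probabilistic analysis, since
#' the underlying per-trial SEs were never published.
#'
#' @param path CSV with columns `strategy`, `mean`, `ci_low`, `ci_high`,
#'   `k`, `i2`.
#' @return Data frame with an added `se` column.
#' @export
read_anchored_effects <- function(path = migs_fixture("table2_anchored_effects.csv")) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  d$se <- (d$ci_high - d$ci_low) / (2 * stats::qnorm(0.975))
  rownames(d) <- d$strategy
  d
}

#' Default analysis configuration
#'
#' All tunable settings of the pipeline with their base-case values: packaged
#' input tables, change-score correlation 0.5, DerSimonian-Laird pooling,
#' published cataract-alone anchor (-2.05 mmHg, 95% CI -3.38 to -0.72),
#' multiplicative IOP-to-progression mapping with coefficient 0.0031 per
#' mmHg per year, 3% annual discounting after year one, a cohort starting in
#' early POAG at age 63 with 44.2% females, a Gompertz-Makeham synthetic
#' life table, and a 10,000-iteration PSA at the willingness-to-pay
#' threshold of 43,433.87 EUR/QALY (1 GDP per capita). The PSA block uses
#' the key `n_iterations` (YAML would read a bare `n` key as a boolean).
#'
#' @return Nested named list of class `migs_config`.
#' @export
default_config <- function() {
  structure(list(
    paths = list(trials = NULL, transitions = NULL, utilities = NULL,
                 costs = NULL, interventions = NULL, life_table = NULL,
                 anchored_effects = NULL),
    rho = 0.5,
    meta_method = "random_dl",
    anchor = list(mean = -2.05, ci_low = -3.38, ci_high = -0.72),
    vf_mapping = "multiplicative",
    vf_coefficient = 0.0031,
    discount_rate = 0.03,
    cohort = list(start_age = 63, female_fraction = 0.442,
                  start_state = "early", max_age = 110, half_cycle = FALSE),
    blind_cost = NULL,
    blind_cost_sd = NULL,
    transition_sd_frac = 0.2,
    life_table = list(makeham_a = 2e-4, gompertz_b = 1e-5,
                      gompertz_c = 0.103, male_multiplier = 1.6),
    psa = list(n_iterations = 10000, seed = 20190101, wtp = 43433.87)
  ), class = "migs_config")
}

merge_config <- function(base, user, prefix = "") {
  for (k in names(user)) {
    key <- paste0(prefix, k)
    if (!k %in% names(base)) {
      stop("load_config: unknown key '", key, "'", call. = FALSE)
    }
    if (is.list(base[[k]]) && !is.null(user[[k]])) {
      if (!is.list(user[[k]])) {
        stop("load_config: '", key, "' must be a mapping", call. = FALSE)
      }
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(key, "."))
    } else if (!is.null(user[[k]])) {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  chk(cfg$rho >= -1 && cfg$rho <= 1, "rho must lie in [-1, 1]")
  chk(cfg$meta_method %in% c("random_dl", "fixed"),
      "meta_method must be 'random_dl' or 'fixed'")
  chk(cfg$vf_mapping %in% c("multiplicative", "linear"),
      "vf_mapping must be 'multiplicative' or 'linear'")
  chk(cfg$vf_coefficient >= 0 && cfg$vf_coefficient < 1,
      "vf_coefficient must lie in [0, 1)")
  chk(cfg$discount_rate >= 0, "discount_rate must be >= 0")
  chk(cfg$cohort$female_fraction >= 0 && cfg$cohort$female_fraction <= 1,
      "cohort.female_fraction must lie in [0, 1]")
  chk(cfg$cohort$max_age > cfg$cohort$start_age,
      "cohort.max_age must exceed cohort.start_age")
  chk(cfg$transition_sd_frac >= 0, "transition_sd_frac must be >= 0")
  chk(cfg$psa$n_iterations >= 1, "psa.n_iterations must be >= 1")
  chk(cfg$psa$wtp > 0, "psa.wtp must be > 0")
  cfg
}

#' Load (and validate) an analysis configuration from YAML
#'
#' Missing keys fall back to [default_config()]; unknown keys raise an error
#' (typo protection); out-of-domain values raise an error naming the field.
#' An empty file yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `migs_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(structure(cfg, class = "migs_config"))
}

#' Save an analysis configuration to YAML
#'
#' @param config A `migs_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Map a strategy name to its one-off intervention cost (EUR). Class-level
# exploratory strategies take the mean of their members' device costs.
intervention_cost_for <- function(name, interventions) {
  tot <- function(k) interventions[k, "total"]
  switch(name,
         cataract_alone = tot("cataract_alone"),
         one_tmbs = tot("one_migs_device"),
         is = tot("one_migs_device"),
         two_tmbs = tot("two_migs_devices"),
         one_or_two_tmbs = mean(c(tot("one_migs_device"), tot("two_migs_devices"))),
         migs_class = mean(c(tot("one_migs_device"), tot("two_migs_devices"),
                             tot("one_migs_device"))),
         stop("no intervention cost mapping for strategy '", name, "'",
              call. = FALSE))
}

# Assemble every model input the cohort/economic stages need from a config:
# transition model, life table, payoffs (with the blindness cost defaulting
# to the least-squares extrapolation of the three stage cost totals, the same
# technique the blindness utility uses), utilities, intervention costs and
# published effect uncertainty.
build_inputs <- function(config = default_config()) {
  p <- config$paths
  tmodel <- if (is.null(p$transitions)) read_transitions() else
    read_transitions(p$transitions)
  lt <- if (is.null(p$life_table)) {
    do.call(gen_life_table, config$life_table)
  } else read_life_table(p$life_table)
  ut <- if (is.null(p$utilities)) read_utilities() else read_utilities(p$utilities)
  costs <- if (is.null(p$costs)) read_costs() else read_costs(p$costs)
  iv <- if (is.null(p$interventions)) read_interventions() else
    read_interventions(p$interventions)
  eff_pub <- if (is.null(p$anchored_effects)) read_anchored_effects() else
    read_anchored_effects(p$anchored_effects)

  stages <- c("early", "moderate", "advanced")
  u <- stats::setNames(ut$utility[match(stages, ut$state)], stages)
  u_sd <- stats::setNames(ut$utility_sd[match(stages, ut$state)], stages)
  u_blind <- extrapolate_blind_utility(u)
  u_blind_sd <- if ("blind" %in% ut$state) ut$utility_sd[ut$state == "blind"] else
    max(u_sd)

  ctot <- stats::setNames(costs$totals$mean[match(stages, costs$totals$stage)],
                          stages)
  csd <- stats::setNames(costs$totals$sd[match(stages, costs$totals$stage)],
                         stages)
  c_blind <- if (is.null(config$blind_cost)) {
    fit <- stats::lm(y ~ x, data = data.frame(x = 1:3, y = ctot))
    unname(stats::predict(fit, data.frame(x = 4)))
  } else config$blind_cost
  c_blind_sd <- if (is.null(config$blind_cost_sd)) csd[["advanced"]] else
    config$blind_cost_sd

  payoffs <- stage_payoffs(
    utility = c(u, blind = u_blind),
    annual_cost = c(ctot, blind = c_blind))

  list(tmodel = tmodel, life_table = lt, payoffs = payoffs,
       utilities = c(u, blind = u_blind),
       utility_sds = c(u_sd, blind = u_blind_sd),
       costs = c(ctot, blind = c_blind),
       cost_sds = c(csd, blind = c_blind_sd),
       interventions = iv, published_effects = eff_pub,
       cohort = do.call(cohort_config, c(config$cohort,
                                         list(discount_rate = config$discount_rate))),
       config = config)
}

# Extra IOP reduction (mmHg, >= 0) of a strategy vs the cataract-alone
# anchor, from a synthesized effects table.
extra_iop_for <- function(name, effects, anchor_mean) {
  m <- effects$mean[effects$strategy == name]
  if (length(m) != 1L) stop("no synthesized effect for '", name, "'", call. = FALSE)
  max(0, anchor_mean - m)
}

#' Run one strategy through the cohort and economic stages
#'
#' @param name Strategy name (must have a synthesized effect and an
#'   intervention-cost mapping).
#' @param stage Application stage, `"moderate"` or `"advanced"`.
#' @param inputs Model inputs from `build_inputs()` (internal) or
#'   [run_pipeline()]'s `inputs` element.
#' @param extra_iop Extra IOP reduction vs reference (mmHg).
#' @param intervention_cost One-off cost (EUR).
#' @return List `cost`, `qaly`, `trace`, `strategy`.
#' @export
run_strategy <- function(name, stage, inputs, extra_iop, intervention_cost) {
  st <- strategy(name, application_stage = stage,
                 extra_iop_reduction = extra_iop,
                 intervention_cost = intervention_cost,
                 vf_coefficient = inputs$config$vf_coefficient,
                 vf_mapping = inputs$config$vf_mapping)
  tr <- run_cohort(st, inputs$tmodel, inputs$life_table, inputs$cohort)
  acc <- accumulate(tr, inputs$payoffs, intervention_cost,
                    inputs$config$discount_rate)
  list(cost = acc$cost, qaly = acc$qaly, trace = tr, strategy = st)
}

#' Build a parameterized cost-effectiveness model for sensitivity analyses
#'
#' Packages one strategy-vs-reference comparison as a function of a named
#' parameter vector (utilities, annual stage costs, annual progression
#' probabilities, the extra IOP effect and the two one-off intervention
#' costs), together with the [param_spec()] table describing each
#' parameter's base value, sampling SD, distribution family and domain.
#' Utilities and probabilities sample from beta distributions, costs from
#' gamma, the IOP effect from a normal truncated at zero (the surgery is
#' assumed not to raise pressure relative to its own control arm);
#' parameters with SD 0 (the intervention tariffs, which have no published
#' uncertainty) stay fixed. Transition-probability SDs default to
#' `transition_sd_frac` (20%) of the mean, mirroring the deterministic
#' analysis range, because the source reports none.
#'
#' @param name,stage Strategy and application stage.
#' @param inputs Model inputs from [run_pipeline()]'s `inputs` element.
#' @param extra_iop Base-case extra IOP reduction (mmHg).
#' @param extra_iop_se Its standard error (mmHg) for probabilistic sampling.
#' @param intervention_cost Strategy one-off cost (EUR).
#' @return List with `fun` (parameter vector -> `migs_ce`) and `params`
#'   (a [param_spec()]).
#' @export
make_ce_model <- function(name, stage, inputs, extra_iop, extra_iop_se,
                          intervention_cost) {
  ref_cost <- intervention_cost_for("cataract_alone", inputs$interventions)
  states4 <- c("early", "moderate", "advanced", "blind")
  stages3 <- c("early", "moderate", "advanced")
  pp <- inputs$tmodel$p_progress

  params <- param_spec(
    name = c(paste0("u_", states4), paste0("c_", states4),
             paste0("p_prog_", stages3),
             "extra_iop", "intervention_cost_alt", "intervention_cost_ref"),
    mean = c(inputs$utilities[states4], inputs$costs[states4], pp[stages3],
             extra_iop, intervention_cost, ref_cost),
    sd = c(inputs$utility_sds[states4], inputs$cost_sds[states4],
           inputs$config$transition_sd_frac * pp[stages3],
           extra_iop_se, 0, 0),
    family = c(rep("beta", 4), rep("gamma", 4), rep("beta", 3),
               "normal", "gamma", "gamma"),
    lo = c(rep(0, 4), rep(0, 4), rep(0, 3), 0, 0, 0),
    hi = c(rep(1, 4), rep(Inf, 4), rep(1, 3), Inf, Inf, Inf)
  )

  cfg <- inputs$config
  cohort <- inputs$cohort
  tmpl <- inputs$tmodel
  lt <- inputs$life_table

  fun <- function(par) {
    payoffs <- stage_payoffs(
      utility = stats::setNames(par[paste0("u_", states4)], states4),
      annual_cost = stats::setNames(par[paste0("c_", states4)], states4))
    tm <- transition_model(
      p_stay = 1 - stats::setNames(par[paste0("p_prog_", stages3)], stages3),
      p_progress = stats::setNames(par[paste0("p_prog_", stages3)], stages3))
    eff <- max(0, par[["extra_iop"]])
    st_alt <- strategy(name, application_stage = stage,
                       extra_iop_reduction = eff,
                       intervention_cost = par[["intervention_cost_alt"]],
                       vf_coefficient = cfg$vf_coefficient,
                       vf_mapping = cfg$vf_mapping)
    st_ref <- strategy("cataract_alone", application_stage = stage,
                       extra_iop_reduction = 0,
                       intervention_cost = par[["intervention_cost_ref"]],
                       vf_coefficient = cfg$vf_coefficient,
                       vf_mapping = cfg$vf_mapping)
    alt <- accumulate(run_cohort(st_alt, tm, lt, cohort), payoffs,
                      par[["intervention_cost_alt"]], cfg$discount_rate)
    ref <- accumulate(run_cohort(st_ref, tm, lt, cohort), payoffs,
                      par[["intervention_cost_ref"]], cfg$discount_rate)
    icer(alt, ref)
  }
  list(fun = fun, params = params)
}

#' Run the full cost-utility pipeline
#'
#' Evidence synthesis (change scores, pooling, Bucher anchoring), lifetime
#' cohort runs for every strategy and application stage with cataract
#' surgery alone as the reference, discounted cost/QALY accumulation and
#' ICERs, and (optionally) the deterministic tornado and probabilistic
#' sensitivity analyses for a chosen comparison.
#'
#' @param config A `migs_config` (see [default_config()], [load_config()]).
#' @param strategies Strategy names to evaluate.
#' @param stages Application stages to evaluate.
#' @param dsa Run the one-way deterministic sensitivity analysis.
#' @param run_psa Run the probabilistic sensitivity analysis.
#' @param sa_strategy,sa_stage Comparison used for the sensitivity analyses.
#' @param psa_n Override of `config$psa$n` (e.g. for quick runs).
#' @param out_dir Optional output directory: writes `effects.csv`,
#'   `results.csv`, and `tornado.csv`/`psa_samples.csv`/`ceac.csv` when the
#'   corresponding analyses ran. Monetary values are rounded to 2 decimals
#'   at report time only.
#' @return List of class `migs_pipeline`: `effects`, `results`, `dsa`,
#'   `psa`, `inputs`.
#' @export
run_pipeline <- function(config = default_config(),
                         strategies = c("one_tmbs", "two_tmbs", "is",
                                        "one_or_two_tmbs", "migs_class"),
                         stages = c("moderate", "advanced"),
                         dsa = FALSE, run_psa = FALSE,
                         sa_strategy = "two_tmbs", sa_stage = "moderate",
                         psa_n = NULL, out_dir = NULL) {
  config <- validate_config(config)
  inputs <- build_inputs(config)

  trials <- if (is.null(config$paths$trials)) read_trials(rho = config$rho) else
    read_trials(config$paths$trials, rho = config$rho)
  anchor <- effect_estimate(
    config$anchor$mean,
    se = (config$anchor$ci_high - config$anchor$ci_low) /
      (2 * stats::qnorm(0.975)))
  effects <- synthesize_effects(trials, anchor, method = config$meta_method)

  rows <- list()
  for (stg in stages) {
    ref <- run_strategy("cataract_alone", stg, inputs, 0,
                        intervention_cost_for("cataract_alone",
                                              inputs$interventions))
    rows[[length(rows) + 1L]] <- data.frame(
      strategy = "cataract_alone", stage = stg, cost = ref$cost,
      inc_cost = 0, qaly = ref$qaly, inc_qaly = 0, icer = NA_real_,
      label = "reference", stringsAsFactors = FALSE)
    for (s in strategies) {
      eff <- extra_iop_for(s, effects, config$anchor$mean)
      ic <- intervention_cost_for(s, inputs$interventions)
      alt <- run_strategy(s, stg, inputs, eff, ic)
      ce <- icer(alt, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = s, stage = stg, cost = alt$cost, inc_cost = ce$inc_cost,
        qaly = alt$qaly, inc_qaly = ce$inc_qaly, icer = ce$icer,
        label = ce$label, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)

  dsa_out <- NULL; psa_out <- NULL
  if (dsa || run_psa) {
    eff <- extra_iop_for(sa_strategy, effects, config$anchor$mean)
    pub <- inputs$published_effects
    se_anchor <- pub["cataract_alone", "se"]
    se_alt <- pub[sa_strategy, "se"]
    eff_se <- sqrt(max(se_alt^2 - se_anchor^2, 0))
    model <- make_ce_model(sa_strategy, sa_stage, inputs, eff,
                           eff_se,
                           intervention_cost_for(sa_strategy,
                                                 inputs$interventions))
    if (dsa) dsa_out <- one_way_dsa(model$fun, model$params, delta = 0.20)
    if (run_psa) {
      psa_out <- psa(model$fun, model$params,
                     n = if (is.null(psa_n)) config$psa$n_iterations else psa_n,
                     seed = config$psa$seed, wtp = config$psa$wtp)
    }
  }

  out <- structure(list(effects = effects, results = results, dsa = dsa_out,
                        psa = psa_out, inputs = inputs),
                   class = "migs_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eff <- x$effects
  num <- vapply(eff, is.numeric, logical(1))
  eff[num] <- lapply(eff[num], round, 2)
  utils::write.csv(eff, file.path(out_dir, "effects.csv"), row.names = FALSE)

  res <- x$results
  for (col in c("cost", "inc_cost", "icer")) res[[col]] <- round(res[[col]], 2)
  for (col in c("qaly", "inc_qaly")) res[[col]] <- round(res[[col]], 4)
  utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)

  if (!is.null(x$dsa)) {
    utils::write.csv(x$dsa, file.path(out_dir, "tornado.csv"),
                     row.names = FALSE)
  }
  if (!is.null(x$psa)) {
    utils::write.csv(x$psa$samples, file.path(out_dir, "psa_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(x$psa$ceac, file.path(out_dir, "ceac.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.migs_pipeline <- function(x, ...) {
  cat("Anchored 1-year IOP changes (mmHg):\n")
  print(x$effects, digits = 3)
  cat("\nLifetime discounted results vs cataract surgery alone:\n")
  res <- x$results
  res$cost <- round(res$cost, 2); res$inc_cost <- round(res$inc_cost, 2)
  res$qaly <- round(res$qaly, 4); res$inc_qaly <- round(res$inc_qaly, 4)
  res$icer <- round(res$icer, 2)
  print(res)
  invisible(x)
}
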