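#' Moment-matched beta parameters
#'
#' Method-of-moments (alpha, beta) for a beta distribution with the given
#' mean and SD. When the SD is infeasible for the mean (variance bound
#' `mean * (1 - mean)`), the SD is shrunk to 95% of the bound with a warning,
#' so that sampling remains possible.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation.
#' @return List with `alpha`, `beta`, and the `sd` actually used.
#' @export
beta_params <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) stop("beta_params: mean must lie in (0, 1)", call. = FALSE)
  bound <- sqrt(mean * (1 - mean))
  if (sd >= bound) {
    warning(sprintf("beta_params: SD %.3f infeasible for mean %.3f; shrunk to %.3f",
                    sd, mean, 0.95 * bound))
    sd <- 0.95 * bound
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  list(alpha = mean * nu, beta = (1 - mean) * nu, sd = sd)
}

#' Moment-matched gamma parameters
#'
#' @param mean Mean (> 0).
#' @param sd Standard deviation (> 0).
#' @return List with `shape` and `rate`.
#' @export
gamma_params <- function(mean, sd) {
  if (mean <= 0 || sd <= 0) stop("gamma_params: mean and sd must be > 0", call. = FALSE)
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Parameter specification table for sensitivity analyses
#'
#' @param name Parameter names.
#' @param mean Base-case values.
#' @param sd SDs for probabilistic sampling (0 = not sampled).
#' @param family Distribution family per parameter: `"beta"` (utilities and
#'   probabilities), `"gamma"` (costs), `"normal"` (IOP effects),
#'   `"fixed"`.
#' @param lo,hi Domain bounds used to clamp deterministic perturbations.
#' @return Data frame of class `migs_param_spec`.
#' @export
param_spec <- function(name, mean, sd, family, lo = -Inf, hi = Inf) {
  fam_ok <- c("beta", "gamma", "normal", "fixed")
  if (!all(family %in% fam_ok)) {
    stop("param_spec: unknown family", call. = FALSE)
  }
  d <- data.frame(name = name, mean = mean, sd = sd, family = family,
                  lo = lo, hi = hi, stringsAsFactors = FALSE)
  rownames(d) <- d$name
  class(d) <- c("migs_param_spec", "data.frame")
  d
}

# Deterministic per-parameter stream seed, derived from the master seed and
# the parameter's name (not its position), so adding a parameter does not
# reshuffle the draws of the others.
param_stream_seed <- function(master_seed, name) {
  h <- sum(utf8ToInt(name) * (seq_along(utf8ToInt(name)) %% 7 + 1))
  (as.integer(master_seed) %% 1000003L) * 1009L + as.integer(h %% 100003L)
}

draw_parameter <- function(n, mean, sd, family, seed) {
  if (family == "fixed" || sd == 0) return(rep(mean, n))
  set.seed(seed)
  switch(family,
         beta = {
           p <- beta_params(mean, sd)
           stats::rbeta(n, p$alpha, p$beta)
         },
         gamma = {
           p <- gamma_params(mean, sd)
           stats::rgamma(n, shape = p$shape, rate = p$rate)
         },
         normal = stats::rnorm(n, mean, sd))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the model with each parameter in turn at `(1 - delta)` and
#' `(1 + delta)` times its base value (clamped to the parameter's domain with
#' a warning), all others held at base, and ranks parameters by the absolute
#' ICER spread. A perturbation that makes the model infeasible is recorded as
#' a failed scenario (`status`), not silently dropped.
#'
#' @param model_fun Function taking a named parameter vector and returning a
#'   `migs_ce` (see [icer()]).
#' @param params A [param_spec()] table.
#' @param delta Relative perturbation (default 0.20).
#' @return Data frame `parameter`, `low_value`, `high_value`, `low_icer`,
#'   `high_icer`, `spread`, `status`, sorted by decreasing spread.
#' @export
one_way_dsa <- function(model_fun, params, delta = 0.20) {
  base <- stats::setNames(params$mean, params$name)
  run_at <- function(par) {
    tryCatch(model_fun(par)$icer, error = function(e) NA_real_)
  }
  rows <- lapply(seq_len(nrow(params)), function(i) {
    vals <- base[i] * c(1 - delta, 1 + delta)
    clamped <- pmin(pmax(vals, params$lo[i]), params$hi[i])
    if (any(clamped != vals)) {
      warning("one_way_dsa: '", params$name[i], "' clamped to its domain")
    }
    icers <- vapply(clamped, function(v) {
      par <- base; par[i] <- v; run_at(par)
    }, numeric(1))
    data.frame(parameter = params$name[i],
               low_value = clamped[1], high_value = clamped[2],
               low_icer = icers[1], high_icer = icers[2],
               spread = abs(icers[2] - icers[1]),
               status = if (anyNA(icers)) "failed" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), , drop = FALSE]
}

#' Probabilistic sensitivity analysis (Monte Carlo)
#'
#' Draws every stochastic parameter from its moment-matched distribution
#' (independent streams spawned from the master seed, one per parameter),
#' runs the full model per iteration, and records the incremental cost and
#' QALY of the alternative versus the reference. Summaries include the
#' fraction of iterations cost-effective at the willingness-to-pay threshold
#' and a cost-effectiveness acceptability curve.
#'
#' @param model_fun As in [one_way_dsa()].
#' @param params A [param_spec()] table.
#' @param n Number of iterations.
#' @param seed Master seed.
#' @param wtp Willingness-to-pay threshold (EUR/QALY).
#' @param thresholds Threshold grid for the acceptability curve.
#' @return Object of class `migs_psa`: `samples` (data frame `iteration`,
#'   `inc_cost`, `inc_qaly`, `icer`, `label`), `draws`, `frac_ce`, `ceac`,
#'   `wtp`, `n`, `seed`.
#' @export
psa <- function(model_fun, params, n = 10000, seed = 1,
                wtp = 43433.87, thresholds = seq(0, 100000, by = 2500)) {
  if (n < 1) stop("psa: n must be >= 1", call. = FALSE)
  draws <- vapply(seq_len(nrow(params)), function(i) {
    draw_parameter(n, params$mean[i], params$sd[i], params$family[i],
                   param_stream_seed(seed, params$name[i]))
  }, numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1L)
  colnames(draws) <- params$name

  res <- lapply(seq_len(n), function(it) {
    ce <- model_fun(draws[it, ])
    list(ce$inc_cost, ce$inc_qaly, ce$icer, ce$label)
  })
  samples <- data.frame(
    iteration = seq_len(n),
    inc_cost = vapply(res, function(r) r[[1]], numeric(1)),
    inc_qaly = vapply(res, function(r) r[[2]], numeric(1)),
    icer = vapply(res, function(r) r[[3]], numeric(1)),
    label = vapply(res, function(r) r[[4]], character(1))
  )
  curve <- ceac(samples$inc_cost, samples$inc_qaly, thresholds)
  structure(list(samples = samples, draws = draws,
                 frac_ce = frac_cost_effective(samples$inc_cost,
                                               samples$inc_qaly, wtp),
                 ceac = curve, wtp = wtp, n = n, seed = seed),
            class = "migs_psa")
}

#' Fraction of simulations cost-effective at a threshold
#'
#' An iteration counts as cost-effective when it gains QALYs at a cost per
#' QALY below the threshold, including dominant iterations (QALY gain at
#' cost saving).
#'
#' @param inc_cost,inc_qaly Incremental samples.
#' @param wtp Willingness-to-pay threshold (EUR/QALY).
#' @return Proportion in `[0, 1]`.
#' @export
frac_cost_effective <- function(inc_cost, inc_qaly, wtp) {
  mean(inc_qaly > 0 & (inc_cost <= 0 | inc_cost / inc_qaly < wtp))
}

#' Cost-effectiveness acceptability curve
#'
#' @param inc_cost,inc_qaly Incremental samples from a PSA.
#' @param thresholds Willingness-to-pay grid (EUR/QALY).
#' @return Data frame `threshold`, `probability`; the probability is
#'   monotone non-decreasing in the threshold.
#' @export
ceac <- function(inc_cost, inc_qaly, thresholds = seq(0, 100000, by = 2500)) {
  if (length(inc_cost) == 0L) stop("ceac: empty sample set", call. = FALSE)
  data.frame(threshold = thresholds,
             probability = vapply(thresholds, function(l) {
               frac_cost_effective(inc_cost, inc_qaly, l)
             }, numeric(1)))
}

#' @export
print.migs_psa <- function(x, ...) {
  cat(sprintf(
    "PSA: %d iterations (seed %d); mean inc cost %.2f EUR, mean inc QALY %.4f\n",
    x$n, x$seed, mean(x$samples$inc_cost), mean(x$samples$inc_qaly)))
  cat(sprintf("Fraction cost-effective at %.2f EUR/QALY: %.3f\n",
              x$wtp, x$frac_ce))
  invisible(x)
}
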