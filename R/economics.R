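#' Total annual stage cost from components
#'
#' Sums the component means (medications, examinations, visits). Component
#' SDs are summed too, matching how the source cost table aggregates its
#' uncertainty; the SD is carried only as a sampling parameter for the
#' probabilistic analysis, never propagated into deterministic results.
#'
#' @param mean Component cost means (EUR/year).
#' @param sd Component cost SDs (optional).
#' @return List with `mean` and `sd`.
#' @export
stage_cost_total <- function(mean, sd = NULL) {
  if (any(mean < 0)) stop("stage_cost_total: negative component", call. = FALSE)
  list(mean = sum(mean), sd = if (is.null(sd)) NA_real_ else sum(sd))
}

#' Extrapolate the blindness utility from the three POAG stage utilities
#'
#' Ordinary least-squares line through the utilities at stage indices 1..3,
#' evaluated at index 4 and rounded to two decimals, following the decreasing
#' trend of quality of life with severity.
#'
#' @param stage_utilities Utilities for early, moderate, advanced (length 3).
#' @param digits Rounding applied to the reported value (default 2).
#' @return Extrapolated blindness utility.
#' @export
extrapolate_blind_utility <- function(stage_utilities, digits = 2) {
  if (length(stage_utilities) != 3L || anyNA(stage_utilities)) {
    stop("extrapolate_blind_utility: need the three stage utilities",
         call. = FALSE)
  }
  fit <- stats::lm(u ~ x, data = data.frame(x = 1:3, u = stage_utilities))
  round(unname(stats::predict(fit, data.frame(x = 4))), digits)
}

#' Discount factor for a model year
#'
#' Costs and health benefits are discounted after year one: year 1 has
#' factor 1, year `t` thereafter `(1 + rate)^-(t - 1)`.
#'
#' @param year 1-based model year (vectorized).
#' @param rate Annual discount rate.
#' @return Discount multiplier.
#' @export
discount_factor <- function(year, rate = 0.03) {
  if (any(year < 1)) stop("discount_factor: year must be >= 1", call. = FALSE)
  ifelse(year <= 1, 1, (1 + rate)^-(year - 1))
}

#' Stage payoffs (utility weights and annual costs)
#'
#' @param utility Named vector over the four living states (`early`,
#'   `moderate`, `advanced`, `blind`), each in `[0, 1]`.
#' @param annual_cost Named vector of annual direct costs (EUR) over the same
#'   states.
#' @return Object of class `migs_payoffs`: data frame over all five states
#'   (`dead` fixed at utility 0, cost 0).
#' @export
stage_payoffs <- function(utility, annual_cost) {
  living <- migs_states()[1:4]
  utility <- utility[living]; annual_cost <- annual_cost[living]
  if (anyNA(utility) || anyNA(annual_cost)) {
    stop("stage_payoffs: need utility and annual_cost for all living states",
         call. = FALSE)
  }
  if (any(utility < 0 | utility > 1)) {
    stop("stage_payoffs: utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(annual_cost < 0)) {
    stop("stage_payoffs: costs must be >= 0", call. = FALSE)
  }
  d <- data.frame(state = migs_states(),
                  utility = c(utility, 0),
                  annual_cost = c(annual_cost, 0))
  rownames(d) <- d$state
  class(d) <- c("migs_payoffs", "data.frame")
  d
}

#' Discounted lifetime cost and QALY accumulation
#'
#' Per model year: occupancy-weighted utility and annual cost (accrued at
#' cycle start, or as the mean of adjacent cycles under the half-cycle
#' switch), plus the one-off intervention cost booked against the mass newly
#' entering the application stage that year; each term is discounted with
#' [discount_factor()].
#'
#' @param trace A `migs_trace` from [run_cohort()].
#' @param payoffs A [stage_payoffs()].
#' @param intervention_cost One-off cost (EUR) per unit of entering mass.
#' @param rate Annual discount rate.
#' @return List with discounted `cost` (EUR) and `qaly`.
#' @export
accumulate <- function(trace, payoffs, intervention_cost = 0, rate = 0.03) {
  stopifnot(inherits(trace, "migs_trace"), inherits(payoffs, "migs_payoffs"))
  occ <- trace$occupancy
  if (nrow(occ) == 0L) return(list(cost = 0, qaly = 0))
  if (isTRUE(trace$config$half_cycle) && nrow(occ) > 1L) {
    occ <- (occ[-nrow(occ), , drop = FALSE] + occ[-1L, , drop = FALSE]) / 2
  }
  u <- payoffs[colnames(occ), "utility"]
  cc <- payoffs[colnames(occ), "annual_cost"]
  df <- discount_factor(seq_len(nrow(occ)), rate)
  qaly <- sum(df * (occ %*% u))
  cost <- sum(df * (occ %*% cc)) +
    sum(discount_factor(seq_along(trace$entry), rate) * trace$entry *
          intervention_cost)
  list(cost = cost, qaly = qaly)
}

#' Incremental cost-effectiveness ratio
#'
#' Incremental cost divided by incremental effectiveness of the alternative
#' versus the standard therapy. Dominance is labelled instead of a quotient:
#' `"dominated"` (no QALY gain at extra or equal cost), `"dominant"` (QALY
#' gain at no extra cost), `"equivalent"` (no difference at all).
#'
#' @param alt,ref Lists with `cost` and `qaly` computed under identical
#'   settings.
#' @return List of class `migs_ce`: `inc_cost`, `inc_qaly`, `icer` (numeric,
#'   `NA` when labelled), `label`.
#' @export
icer <- function(alt, ref) {
  dc <- alt$cost - ref$cost
  dq <- alt$qaly - ref$qaly
  if (dq == 0 && dc == 0) {
    lab <- "equivalent"; value <- NA_real_
  } else if (dq > 0 && dc <= 0) {
    lab <- "dominant"; value <- NA_real_
  } else if (dq <= 0 && dc >= 0) {
    lab <- "dominated"; value <- NA_real_
  } else {
    lab <- "icer"; value <- dc / dq
  }
  structure(list(inc_cost = dc, inc_qaly = dq, icer = value, label = lab),
            class = "migs_ce")
}

#' @export
print.migs_ce <- function(x, ...) {
  cat(sprintf("Incremental cost %.2f EUR, incremental QALY %.4f: %s\n",
              x$inc_cost, x$inc_qaly,
              if (x$label == "icer") sprintf("%.2f EUR/QALY", x$icer) else x$label))
  invisible(x)
}
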