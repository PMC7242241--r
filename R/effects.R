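#' Trial arm summary
#'
#' Container for the per-arm IOP summaries of a randomized trial: baseline and
#' 1-year follow-up mean (SD), with an optional arm size. When the arm size is
#' unknown (as for the published trial tables shipped with the package) only
#' point estimates can be propagated downstream.
#'
#' @param label Arm label, e.g. `"intervention"` or `"control"`.
#' @param mean_baseline,sd_baseline Baseline IOP mean and SD (mmHg).
#' @param mean_followup,sd_followup Year-1 IOP mean and SD (mmHg).
#' @param n Optional arm size (>= 2).
#' @return An object of class `migs_trial_arm`.
#' @export
trial_arm <- function(label, mean_baseline, sd_baseline,
                      mean_followup, sd_followup, n = NA_integer_) {
  for (v in c("mean_baseline", "sd_baseline", "mean_followup", "sd_followup")) {
    x <- get(v)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("trial_arm: '", v, "' must be a finite number", call. = FALSE)
    }
  }
  if (sd_baseline <= 0 || sd_followup <= 0) {
    stop("trial_arm: SDs must be positive", call. = FALSE)
  }
  if (!is.na(n) && n < 2) stop("trial_arm: n must be >= 2 when given", call. = FALSE)
  structure(
    list(label = label, n = if (is.na(n)) NA_integer_ else as.integer(n),
         mean_baseline = mean_baseline, sd_baseline = sd_baseline,
         mean_followup = mean_followup, sd_followup = sd_followup),
    class = "migs_trial_arm"
  )
}

#' Effect estimate (mean IOP change, mmHg)
#'
#' Negative values are IOP reductions. The confidence interval is the normal
#' approximation `mean +/- z * se` and is omitted when no standard error is
#' available.
#'
#' @param mean Mean change (mmHg).
#' @param se Standard error (mmHg), `NA` when unknown.
#' @param conf Confidence level for the interval.
#' @return An object of class `migs_effect` with fields `mean`, `se`,
#'   `ci_low`, `ci_high`.
#' @export
effect_estimate <- function(mean, se = NA_real_, conf = 0.95) {
  if (!is.finite(mean)) stop("effect_estimate: mean must be finite", call. = FALSE)
  if (!is.na(se) && se < 0) stop("effect_estimate: se must be >= 0", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else mean + c(-1, 1) * z * se
  structure(list(mean = mean, se = se, ci_low = ci[1], ci_high = ci[2]),
            class = "migs_effect")
}

#' @export
print.migs_effect <- function(x, ...) {
  cat(sprintf("IOP change: %.2f mmHg", x$mean))
  if (!is.na(x$se)) cat(sprintf(" (SE %.3f; 95%% CI %.2f to %.2f)",
                                x$se, x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Two-arm trial
#'
#' @param study_id Study identifier.
#' @param intervention,control [trial_arm()] objects.
#' @param rho Baseline/follow-up correlation used for the change-score SD.
#' @return An object of class `migs_trial`.
#' @export
two_arm_trial <- function(study_id, intervention, control, rho = 0.5) {
  stopifnot(inherits(intervention, "migs_trial_arm"),
            inherits(control, "migs_trial_arm"))
  if (!is.finite(rho) || rho < -1 || rho > 1) {
    stop("two_arm_trial: rho must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(study_id = study_id, intervention = intervention,
                 control = control, rho = rho),
            class = "migs_trial")
}

#' Within-arm 1-year change from baseline
#'
#' The single efficacy endpoint of the comparison: mean follow-up IOP minus
#' mean baseline IOP. The SD of the change is reconstructed as
#' `sqrt(sd_b^2 + sd_f^2 - 2 rho sd_b sd_f)`; the SE is only available when
#' the arm size is known.
#'
#' @param arm A [trial_arm()].
#' @param rho Baseline/follow-up correlation (default 0.5, a conventional
#'   conservative choice when the within-subject correlation is unpublished).
#' @return A [effect_estimate()].
#' @export
arm_change <- function(arm, rho = 0.5) {
  stopifnot(inherits(arm, "migs_trial_arm"))
  sd_change <- sqrt(arm$sd_baseline^2 + arm$sd_followup^2 -
                      2 * rho * arm$sd_baseline * arm$sd_followup)
  se <- if (is.na(arm$n)) NA_real_ else sd_change / sqrt(arm$n)
  effect_estimate(mean = arm$mean_followup - arm$mean_baseline, se = se)
}

#' Within-trial relative effect (intervention vs control)
#'
#' Difference of the two arms' changes from baseline; the variance is the sum
#' of the arm-change variances when both are available.
#'
#' @param trial A [two_arm_trial()].
#' @param rho Optional override of the trial's correlation.
#' @return A [effect_estimate()].
#' @export
trial_relative_effect <- function(trial, rho = NULL) {
  stopifnot(inherits(trial, "migs_trial"))
  if (is.null(rho)) rho <- trial$rho
  ei <- arm_change(trial$intervention, rho)
  ec <- arm_change(trial$control, rho)
  se <- if (is.na(ei$se) || is.na(ec$se)) NA_real_ else sqrt(ei$se^2 + ec$se^2)
  effect_estimate(mean = ei$mean - ec$mean, se = se)
}

#' Inverse-variance meta-analysis
#'
#' Pools effect estimates by fixed-effect or DerSimonian-Laird random-effects
#' inverse-variance weighting and reports Cochran's Q, tau-squared and the
#' I-squared heterogeneity percentage. A single study is passed through
#' unchanged with `i2 = NA`. When none of the inputs carries a standard error
#' the unweighted mean of the point estimates is returned (se `NA`, weights
#' equal), flagged via `weighting = "unweighted"`; this is what the published
#' trial tables allow, since arm sizes were not reported.
#'
#' @param effects A list of [effect_estimate()] objects (or a data frame with
#'   columns `mean` and `se`).
#' @param method `"random_dl"` (default) or `"fixed"`.
#' @param conf Confidence level.
#' @return An object of class `migs_pooled` with fields `mean`, `se`,
#'   `ci_low`, `ci_high`, `k`, `q_stat`, `tau2`, `i2`, `weights`, `method`,
#'   `weighting`.
#' @export
meta_pool <- function(effects, method = c("random_dl", "fixed"), conf = 0.95) {
  method <- match.arg(method)
  if (is.data.frame(effects)) {
    effects <- lapply(seq_len(nrow(effects)), function(i) {
      effect_estimate(effects$mean[i], effects$se[i], conf = conf)
    })
  }
  k <- length(effects)
  if (k == 0L) stop("meta_pool: no effects supplied", call. = FALSE)
  y <- vapply(effects, function(e) e$mean, numeric(1))
  s <- vapply(effects, function(e) e$se, numeric(1))
  z <- stats::qnorm(1 - (1 - conf) / 2)

  if (k == 1L) {
    e <- effects[[1L]]
    out <- list(mean = e$mean, se = e$se, ci_low = e$ci_low, ci_high = e$ci_high,
                k = 1L, q_stat = NA_real_, tau2 = NA_real_, i2 = NA_real_,
                weights = 1, method = method, weighting = "single")
    return(structure(out, class = "migs_pooled"))
  }

  if (all(is.na(s))) {
    out <- list(mean = mean(y), se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, k = k, q_stat = NA_real_, tau2 = NA_real_,
                i2 = NA_real_, weights = rep(1 / k, k), method = method,
                weighting = "unweighted")
    return(structure(out, class = "migs_pooled"))
  }
  if (anyNA(s)) {
    stop("meta_pool: mixture of effects with and without standard errors",
         call. = FALSE)
  }
  if (any(s == 0)) {
    stop("meta_pool: zero standard error with k > 1 gives degenerate weights",
         call. = FALSE)
  }

  w <- 1 / s^2
  mu_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_fe)^2)
  df <- k - 1
  i2 <- max(0, 100 * (q - df) / q)
  if (q == 0) i2 <- 0

  if (method == "fixed") {
    tau2 <- 0
    wr <- w
  } else {
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df) / cc)
    wr <- 1 / (s^2 + tau2)
  }
  mu <- sum(wr * y) / sum(wr)
  se <- sqrt(1 / sum(wr))
  structure(list(mean = mu, se = se, ci_low = mu - z * se, ci_high = mu + z * se,
                 k = k, q_stat = q, tau2 = tau2, i2 = i2,
                 weights = wr / sum(wr), method = method,
                 weighting = "inverse_variance"),
            class = "migs_pooled")
}

#' @export
print.migs_pooled <- function(x, ...) {
  cat(sprintf("Pooled IOP change (%s, k = %d): %.2f mmHg", x$method, x$k, x$mean))
  if (!is.na(x$se)) cat(sprintf(" (95%% CI %.2f to %.2f)", x$ci_low, x$ci_high))
  if (!is.na(x$i2)) cat(sprintf("; I2 = %.0f%%", x$i2))
  cat("\n")
  invisible(x)
}

#' Bucher-adjusted anchored effect
#'
#' Converts a relative effect (MIGS + cataract vs cataract alone) into an
#' absolute 1-year IOP change by adding the pooled change of the common
#' cataract-alone comparator. Under the independence assumption of the
#' adjusted indirect comparison the variances add; when either side lacks a
#' variance, the mean is still returned and the CI is omitted.
#'
#' @param relative A [effect_estimate()] or `migs_pooled` relative effect.
#' @param anchor A [effect_estimate()] or `migs_pooled` change of the common
#'   comparator.
#' @param conf Confidence level.
#' @return A [effect_estimate()].
#' @export
bucher_anchor <- function(relative, anchor, conf = 0.95) {
  m <- relative$mean + anchor$mean
  se <- if (is.na(relative$se) || is.na(anchor$se)) NA_real_ else
    sqrt(relative$se^2 + anchor$se^2)
  effect_estimate(mean = m, se = se, conf = conf)
}

#' Read trial-arm summaries from CSV
#'
#' One row per arm with columns `strategy`, `study_id`, `arm`
#' (`intervention`/`control`), `n` (blank allowed), `mean_baseline`,
#' `sd_baseline`, `mean_followup`, `sd_followup`. Lines starting with `#` are
#' comments. The packaged fixture encodes the published trial table.
#'
#' @param path CSV path; defaults to the packaged trial table.
#' @param rho Baseline/follow-up correlation attached to each trial.
#' @return A named list of [two_arm_trial()] objects; each carries a
#'   `strategy` attribute.
#' @export
read_trials <- function(path = migs_fixture("table1_trials.csv"), rho = 0.5) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("strategy", "study_id", "arm", "n", "mean_baseline", "sd_baseline",
            "mean_followup", "sd_followup")
  if (!all(need %in% names(d))) {
    stop("read_trials: missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  trials <- list()
  for (id in unique(d$study_id)) {
    rows <- d[d$study_id == id, ]
    arms <- lapply(c("intervention", "control"), function(a) {
      r <- rows[rows$arm == a, ]
      if (nrow(r) != 1L) stop("read_trials: study ", id, " needs exactly one '",
                              a, "' arm", call. = FALSE)
      trial_arm(a, r$mean_baseline, r$sd_baseline, r$mean_followup,
                r$sd_followup, n = if (is.na(r$n)) NA_integer_ else r$n)
    })
    tr <- two_arm_trial(id, arms[[1L]], arms[[2L]], rho = rho)
    attr(tr, "strategy") <- rows$strategy[1L]
    trials[[id]] <- tr
  }
  trials
}

#' Synthesize anchored per-strategy effects
#'
#' Full evidence-synthesis step: change scores per arm, relative effects per
#' trial, meta-analytic pooling of the relative effects within each strategy,
#' and Bucher anchoring on the common cataract-alone change. Exploratory
#' class-level strategies (one-or-two stents; all MIGS) pool the member
#' trials' relative effects before anchoring.
#'
#' @param trials List from [read_trials()].
#' @param anchor Anchor effect (pooled cataract-alone change) as a
#'   [effect_estimate()]. When `NULL`, the anchor is pooled from the trials'
#'   control-arm changes, which requires arm sizes.
#' @param method Pooling method passed to [meta_pool()].
#' @param rho Correlation override for the change scores.
#' @param classes Named list of exploratory strategy classes mapping a class
#'   name to the member strategy names; `NULL` for none.
#' @return A data frame with columns `strategy`, `mean`, `se`, `ci_low`,
#'   `ci_high`, `k`, `i2` (first row: the anchor itself).
#' @export
synthesize_effects <- function(trials, anchor = NULL,
                               method = c("random_dl", "fixed"), rho = NULL,
                               classes = list(
                                 one_or_two_tmbs = c("one_tmbs", "two_tmbs"),
                                 migs_class = c("one_tmbs", "two_tmbs", "is"))) {
  method <- match.arg(method)
  if (is.null(anchor)) {
    ctrl <- lapply(trials, function(tr) {
      arm_change(tr$control, if (is.null(rho)) tr$rho else rho)
    })
    if (any(vapply(ctrl, function(e) is.na(e$se), logical(1)))) {
      stop("synthesize_effects: anchor cannot be pooled without arm sizes; ",
           "supply `anchor` explicitly", call. = FALSE)
    }
    anchor <- meta_pool(ctrl, method = method)
  }

  strat <- vapply(trials, function(tr) attr(tr, "strategy"), character(1))
  rel <- lapply(trials, trial_relative_effect, rho = rho)

  pool_and_anchor <- function(members) {
    p <- meta_pool(rel[strat %in% members], method = method)
    a <- bucher_anchor(p, anchor)
    data.frame(mean = a$mean, se = a$se, ci_low = a$ci_low, ci_high = a$ci_high,
               k = p$k, i2 = p$i2)
  }

  out <- data.frame(strategy = "cataract_alone", mean = anchor$mean,
                    se = anchor$se,
                    ci_low = if (is.null(anchor$ci_low)) NA_real_ else anchor$ci_low,
                    ci_high = if (is.null(anchor$ci_high)) NA_real_ else anchor$ci_high,
                    k = if (is.null(anchor$k)) NA_integer_ else anchor$k,
                    i2 = if (is.null(anchor$i2)) NA_real_ else anchor$i2)
  for (s in unique(strat)) {
    out <- rbind(out, cbind(strategy = s, pool_and_anchor(s)))
  }
  if (!is.null(classes)) {
    for (cn in names(classes)) {
      out <- rbind(out, cbind(strategy = cn, pool_and_anchor(classes[[cn]])))
    }
  }
  rownames(out) <- NULL
  out
}
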