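test_that("arm change scores reproduce the published means and edge cases", {
  fern <- trial_arm("intervention", 24.2, 1.6, 17.6, 2.8)
  expect_equal(arm_change(fern)$mean, -6.6)
  expect_true(is.na(arm_change(fern)$se))

  same <- trial_arm("x", 18, 3, 18, 3)
  expect_equal(arm_change(same)$mean, 0)

  # perfectly correlated equal-SD change has zero SD, hence zero SE
  a <- trial_arm("x", 20, 2.5, 18, 2.5, n = 50)
  expect_equal(arm_change(a, rho = 1)$se, 0)
  # known n propagates the reconstructed change SD
  expect_equal(arm_change(a, rho = 0.5)$se, 2.5 / sqrt(50))
})

test_that("within-trial relative effects match arithmetic on the trial table", {
  trials <- read_trials()
  expect_length(trials, 4L)
  # typo-corrected Craven control arm reads 17.0 at year one
  expect_equal(trials$Craven2012$control$mean_followup, 17.0)

  rel <- vapply(trials, function(tr) trial_relative_effect(tr)$mean, numeric(1))
  expect_equal(unname(rel["FernandezBarrientos2010"]), -2.8)
  expect_equal(unname(rel["Pfeiffer2015"]), -0.2)
  expect_equal(unname(rel["Craven2012"]), -0.7)
  expect_equal(unname(rel["Fea2010"]), -2.0)

  arm <- trial_arm("x", 18, 3, 16, 2)
  expect_equal(trial_relative_effect(two_arm_trial("t", arm, arm))$mean, 0)
})

test_that("DerSimonian-Laird pooling matches the closed-form oracle", {
  # hand-computed: w = 4 each, Q = 3.38, C = 4, tau2 = 0.595,
  # w* = 1/0.845, mean = -1.35, se = 0.65, I2 = 100 * 2.38 / 3.38
  p <- meta_pool(data.frame(mean = c(-0.7, -2.0), se = c(0.5, 0.5)))
  expect_equal(p$mean, -1.35)
  expect_equal(p$q_stat, 3.38)
  expect_equal(p$tau2, 0.595)
  expect_equal(p$se, 0.65)
  expect_equal(p$i2, 100 * 2.38 / 3.38)

  skip_if_not_installed("metafor")
  m <- metafor::rma(yi = c(-0.7, -2.0), sei = c(0.5, 0.5), method = "DL")
  expect_equal(p$mean, as.numeric(m$beta), tolerance = 1e-10)
  expect_equal(p$se, m$se, tolerance = 1e-10)
  expect_equal(p$tau2, m$tau2, tolerance = 1e-10)
  expect_equal(p$i2, m$I2, tolerance = 1e-6)
})

test_that("pooling edge cases behave as contracted", {
  e <- effect_estimate(-2.8, 0.4)
  single <- meta_pool(list(e))
  expect_equal(single$mean, e$mean)
  expect_equal(single$se, e$se)
  expect_true(is.na(single$i2))

  twin <- meta_pool(list(effect_estimate(-1.2, 0.3), effect_estimate(-1.2, 0.3)))
  expect_equal(twin$mean, -1.2)
  expect_equal(twin$se, 0.3 / sqrt(2))
  expect_equal(twin$i2, 0)

  expect_error(meta_pool(list()), "no effects")
  expect_error(meta_pool(data.frame(mean = c(1, 2), se = c(0, 1))),
               "degenerate")

  # no SEs anywhere: unweighted mean of point estimates, flagged
  un <- meta_pool(list(effect_estimate(-0.7), effect_estimate(-2.0)))
  expect_equal(un$mean, -1.35)
  expect_identical(un$weighting, "unweighted")
})

test_that("pooled fixed-effect SE never exceeds the smallest input SE and
          equal-weight pooling averages the means", {
  set.seed(42)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    y <- rnorm(k, -2, 1)
    s <- runif(k, 0.2, 1.5)
    p <- meta_pool(data.frame(mean = y, se = s), method = "fixed")
    expect_lte(p$se, min(s) + 1e-12)
    eq <- meta_pool(data.frame(mean = y[1:2], se = rep(s[1], 2)))
    expect_equal(eq$mean, mean(y[1:2]))
  }
})

test_that("I2 is invariant to rescaling effects and SEs by a common factor", {
  set.seed(7)
  for (i in 1:20) {
    y <- rnorm(4, -2, 1); s <- runif(4, 0.2, 1)
    a <- meta_pool(data.frame(mean = y, se = s))
    b <- meta_pool(data.frame(mean = 3.7 * y, se = 3.7 * s))
    expect_equal(a$i2, b$i2, tolerance = 1e-10)
    expect_equal(a$q_stat, b$q_stat, tolerance = 1e-10)
  }
})

test_that("Bucher anchoring adds means and variances", {
  anchor <- effect_estimate(-2.05, 0.6786)
  a <- bucher_anchor(effect_estimate(-2.8, 0.9), anchor)
  expect_equal(a$mean, -4.85)
  expect_equal(a$se, sqrt(0.9^2 + 0.6786^2))
  expect_gte(a$se, max(0.9, 0.6786))  # variance sum never shrinks

  b <- bucher_anchor(effect_estimate(-0.2, 0.5), anchor)
  expect_equal(b$mean, -2.25)

  # a zero relative effect with zero variance leaves the anchor unchanged
  c0 <- bucher_anchor(effect_estimate(0, 0), anchor)
  expect_equal(c0$mean, anchor$mean)
  expect_equal(c0$se, anchor$se)

  # missing variance: mean returned, CI omitted
  d <- bucher_anchor(effect_estimate(-2.8), anchor)
  expect_equal(d$mean, -4.85)
  expect_true(is.na(d$ci_low))
})

test_that("synthesized strategy table anchors the packaged trials correctly", {
  trials <- read_trials()
  anchor <- effect_estimate(-2.05, 0.6786)
  eff <- synthesize_effects(trials, anchor)
  expect_equal(eff$mean[eff$strategy == "two_tmbs"], -4.85)
  expect_equal(eff$mean[eff$strategy == "is"], -2.25)
  expect_equal(eff$k[eff$strategy == "one_tmbs"], 2L)
  expect_equal(eff$k[eff$strategy == "migs_class"], 4L)
  # class pools are built from member relative effects before anchoring
  expect_equal(eff$mean[eff$strategy == "one_or_two_tmbs"],
               mean(c(-0.7, -2.0, -2.8)) - 2.05)
})

test_that("DL interval coverage recovers a known true effect", {
  # 120 replicate meta-analyses of 4 homogeneous trials each; nominal 95%
  # coverage should hold to within binomial noise (a wider full-scale run
  # backs the acceptance check)
  set.seed(11)
  truth <- -2
  covered <- vapply(1:120, function(r) {
    eff <- lapply(1:4, function(i) {
      trial_relative_effect(gen_trial(truth, n_per_arm = 100))
    })
    p <- meta_pool(eff)
    p$ci_low <= truth && truth <= p$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 1.00)
})
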