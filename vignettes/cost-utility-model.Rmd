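---
title: "A lifetime cost-utility model of MIGS combined with cataract surgery in POAG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime cost-utility model of MIGS combined with cataract surgery in POAG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migsce)
```

# The decision problem

Primary open-angle glaucoma (POAG) progresses irreversibly from early through
moderate and advanced visual-field loss towards blindness; lowering
intraocular pressure (IOP) is the only modifiable way to slow it. For POAG
patients who also need cataract surgery, a minimally invasive glaucoma
surgery (MIGS) device — one or two trabecular micro-bypass stents (TMBS), or
an intracanalicular scaffold (IS) — can be implanted during the same
operation at moderate extra cost. `migsce` asks: which device, implanted at
which disease stage, buys the most quality-adjusted life years (QALYs) per
euro compared with cataract surgery alone?

The package chains four stages, each usable on its own:

1. **Evidence synthesis** — each candidate device has only been randomized
   against cataract surgery alone, never head-to-head. One-year change from
   baseline in IOP (mmHg) is the single shared endpoint. Per-arm change
   scores are differenced within trials, pooled across trials of the same
   device by DerSimonian–Laird (DL) random-effects meta-analysis, and
   anchored on the pooled cataract-alone change via the Bucher adjusted
   indirect comparison, which sums means and variances of the two component
   comparisons.
2. **Disease-transition model** — a five-state Markov cohort (early,
   moderate, advanced, blindness, death) iterated in yearly cycles over a
   lifetime horizon, with age- and sex-mixed all-cause mortality applied
   before stage progression.
3. **Economics** — stage utilities and annual costs are accumulated over the
   trace, discounted at 3% per year after year one, and summarized as
   incremental cost-effectiveness ratios (ICERs) against cataract alone.
4. **Sensitivity analysis** — one-way ±20% deterministic (tornado) and
   Monte Carlo probabilistic analysis with a cost-effectiveness
   acceptability curve (CEAC).

# Evidence synthesis

For an arm with baseline summary $(\bar{x}_b, s_b)$ and year-one summary
$(\bar{x}_f, s_f)$, the change score is $\bar{x}_f - \bar{x}_b$ (negative =
pressure reduction) with
$s_\Delta^2 = s_b^2 + s_f^2 - 2\rho\, s_b s_f$. The published trial table
reports no arm sizes and no change SDs, so two conventions matter:

* **`rho = 0.5`** (configurable per trial): a conservative conventional
  default for the unpublished baseline/follow-up correlation. Point
  estimates do not depend on it; reconstructed SEs do.
* **Unweighted fallback**: with no SEs at all, `meta_pool()` returns the
  unweighted mean of the member point estimates and flags
  `weighting = "unweighted"`. This is why the package's pooled one-TMBS
  estimate (−3.40 mmHg) differs from the published −3.15 mmHg, which was
  computed with the original (unpublished) trial weights. Single-trial
  strategies are passthroughs, so their anchored estimates (−4.85, −2.25)
  reproduce the published table exactly.

The anchor itself — the pooled cataract-alone change of −2.05 mmHg (95% CI
−3.38 to −0.72) — is supplied as a configured input for the same reason: the
four control-arm SEs needed to re-pool it were never published. With
synthetic trials (arm sizes known) the package pools the anchor itself from
the control arms.

Heterogeneity is summarized by Cochran's $Q$, the DL moment estimator
$\hat\tau^2 = \max\{0, (Q - (k-1))/C\}$, and
$I^2 = \max\{0, 100\,(Q - (k-1))/Q\}\%$. Fixed-effect pooling is available
behind `method = "fixed"`.

# The disease-transition model

States follow the Hodapp–Parrish–Anderson severity bands on the visual-field
mean deviation: early (better than −6 dB), moderate (to −12 dB), advanced
(beyond −12 dB), plus blindness (deviation at or beyond −22 dB) and death.
Progression is strictly forward; blindness admits only death as an exit.
Annual stay/progress probabilities for standard of care (91.5/8.5, 87.6/12.4,
81.4/18.6 % for the three stages) were derived in the source from 5-year
percentages via the standard constant-rate conversion
$p_1 = 1 - (1 - p_5)^{1/5}$, exposed as `five_year_to_annual()`.

Within a cycle, death is applied first (probability from the life table,
mixed as 44.2% female at the cohort's current age), then the surviving mass
splits between staying and progressing. The order matters in the third
decimal and is fixed as death-first; payoffs accrue to the state occupied at
cycle start (a half-cycle switch exists in `cohort_config()` but defaults
off, as the source describes none). The cohort starts in early POAG at age
63 and runs to age 110, by which point the life table forces extinction.

## Mapping IOP reduction to slowed progression

Each extra mmHg of IOP reduction (relative to cataract alone) is credited
with slowing perimetric progression by 0.31% per year. The package's default
mapping compounds this on the annual progression *rate*: with
$r = -\ln(1-p)$,

$$r' = r\,(1 - 0.0031)^{\Delta \text{IOP}}, \qquad p' = 1 - e^{-r'},$$

applied to the application stage and all later stages. This form was chosen
because it keeps probabilities in $[0,1]$ for any effect size, reduces to
the identity at zero effect, and composes sensibly (two successive 1-mmHg
effects equal one 2-mmHg effect). A linear-on-rate alternative
($r' = r(1 - 0.0031\,\Delta\text{IOP})$, clamped at zero) is available via
`vf_mapping = "linear"`; at the effect sizes in play the two differ in the
fifth decimal. Any such reconstruction is the package's own: the exact
functional form used in the source analysis is not recoverable from its
text, so lifetime costs, QALYs and ICERs should be compared with the
published ones in ordering and order of magnitude, not digit by digit. The
incremental QALYs the default produces (0.001–0.01) are indeed the published
order of magnitude.

Because the cohort starts in early POAG and never moves backward, every
individual occupying the application stage or a later one has entered it,
so applying the treated probabilities to those stages in every cycle is
exact cycle-of-entry accounting. The one-off intervention cost is booked
against the mass newly entering the application stage each year (discounted
accordingly); the reference strategy books its cataract-surgery cost at the
same point, which keeps the comparison symmetric. The treatment effect is
assumed constant for the remaining lifetime; mortality is state-independent
because the source provides no state-specific hazard.

# Economics

Stage utilities (HUI-3, German POAG sample) are 0.85, 0.75, 0.58 for the
three stages; the blindness utility is the least-squares extrapolation of
that decreasing trend to the fourth stage index,
`extrapolate_blind_utility(c(0.85, 0.75, 0.58))` = 0.46. Annual stage costs
(2019 EUR) are recomputed from their medication/examination/visit components:
323.19, 356.13, 513.42. The component sum for the moderate stage differs
from the printed total by one cent; components are treated as authoritative.
No blindness-stage cost is published, so the default applies the same
least-squares extrapolation used for the blindness utility to the three
stage totals, giving 587.81 EUR/year (override with `blind_cost` in the
configuration). One-off intervention totals are recomputed from procedure
plus cataract components: 224.84 (cataract alone), 638.42 (one device),
937.34 (two devices). Exploratory class strategies (one-or-two TMBS; MIGS as
a class) take the mean of their members' device costs, a package choice the
source does not specify.

Discounting uses a single 3% rate for costs and effects, applied after year
one: `discount_factor(t) = 1.03^-(t-1)` with factor 1 in year 1. The ICER is
the quotient of incremental cost by incremental QALYs versus cataract alone;
quadrants without a meaningful quotient are labelled `dominant`,
`dominated`, or `equivalent`. Monetary outputs are rounded to cents only at
report time.

# Sensitivity analyses

The tornado analysis perturbs each parameter by ±20% (clamped to its domain,
e.g. utilities at 1), holding the rest at base, and ranks by ICER spread.
Parameters of the early stage have zero leverage by construction — early
occupancy is identical across arms — which doubles as an internal
consistency check.

The probabilistic analysis samples utilities and transition probabilities
from moment-matched beta distributions, costs from gamma, and the extra IOP
effect from a normal truncated at zero (the device is assumed not to raise
pressure against its own control arm). Published SDs parameterize utilities
and costs; transition probabilities, which have no published SDs, default to
SD = 20% of the mean, mirroring the deterministic range; intervention
tariffs have no published uncertainty and stay fixed. Effect-uncertainty SEs
are back-derived from the published 95% CIs. Parameters are sampled
independently (no correlation structure is published), each from its own
stream spawned deterministically from the master seed and the parameter's
*name*, so adding a parameter never reshuffles the others' draws.

A consequence of sampling the published population SDs (0.15–0.40 on the
utilities) independently deserves emphasis: in roughly a third of
iterations the drawn utilities are non-monotone in severity (e.g. advanced
above moderate), so slowing progression loses QALYs and the iteration is
dominated. The fraction of simulations under the 43,433.87 EUR/QALY
threshold is correspondingly far below the "over 95%" reported by the
source analysis — with these distributional choices, prescribed as they
are, no IOP-to-progression mapping could reach it, since the fraction with
any QALY gain is already ≈0.63. Treating the published SDs as population
rather than parameter (standard-error) uncertainty, plus the unrecoverable
progression mapping, are the two candidate explanations; both are inputs a
user can change (`transition_sd_frac`, the payoff SD columns) without
touching code.

# The synthetic life table and simulated trials

No mortality table ships with the package; `gen_life_table()` generates a
Gompertz–Makeham stand-in, $h(x) = a + b\,e^{cx}$ per year for females with
a 1.6× male hazard, converted to annual probabilities and forced to $q = 1$
at age 110. The defaults ($a = 2\times10^{-4}$, $b = 10^{-5}$, $c = 0.103$)
were set once so that remaining life expectancy at 63 (≈21.7 years at the
cohort's sex mix) and the age pattern of $q$ sit near recent German values;
no attempt is made to replicate an actual national table, and lifetime
absolute costs/QALYs shift accordingly (the package's discounted lifetime
QALYs run ≈1.5 higher than the published ones, consistent with a slightly
longer-lived synthetic cohort).

`gen_trial()` simulates two-arm trials with bivariate-normal
(baseline, year-1) IOP pairs, a configurable control-arm change (default
−2.05 mmHg) and a known true relative effect, returning summaries in the
same per-arm format as the packaged trial table — with arm sizes, so SEs
propagate and the full pipeline (anchor pooling included) can be exercised
against known truth. What the generator does *not* emulate: dropout,
measurement rounding, medication washout, regression to the mean from
entry-pressure eligibility thresholds, and any correlation between baseline
severity and response. Passing recovery tests therefore demonstrate correct
arithmetic and calibration of the pipeline under clean sampling noise, not
robustness to real-trial artefacts.

# Numerical conventions and test scale

* Trace rows are validated to sum to 1 within $10^{-9}$; the cohort stops
  early once the dead share exceeds $1 - 10^{-12}$.
* A rate multiplier of exactly 1 (zero effect or zero coefficient) bypasses
  the log/exp round trip so a null strategy reproduces the reference trace
  bit-for-bit.
* Degenerate PSA inputs: an SD of 0 short-circuits to the point value; a
  beta SD at or above its feasibility bound is shrunk to 95% of the bound
  with a warning.
* The test suite exercises the model at its natural size (48-cycle
  lifetime), compares the cohort trace against a 5,000-individual
  microsimulation (cells within 4 SE, 98% within 3 SE), checks DL interval
  coverage over 500 replicate meta-analyses of four 100-per-arm trials, and
  runs the probabilistic analysis at 1,000 iterations in the test suite and
  10,000 in the acceptance script — sizes chosen so the whole suite runs in
  seconds while Monte Carlo error stays well inside the asserted bands.

# Limitations

* The IOP-to-progression mapping is a principled reconstruction, not the
  source's (undisclosed) one; lifetime ICER magnitudes differ even though
  orderings (moderate-stage application beats advanced; two TMBS beats the
  other devices) are reproduced.
* No adverse events, re-operations, bilateral-eye structure, effect waning
  (a hook exists but defaults off), state-dependent mortality, or societal
  costs.
* Indirect comparisons inherit the strong assumption that trial populations
  are exchangeable across the star of comparisons; with one trial per
  device arm for two of the three devices, heterogeneity cannot even be
  estimated there.
* All costs are 2019 German payer tariffs; transfer to other settings
  requires replacing the payoff tables wholesale.
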