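---
title: "Methods: joint heat and PM2.5 case-crossover analysis"
author: "heatpmcc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint heat and PM2.5 case-crossover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatpmcc)
```

## The design

`heatpmcc` implements a time-stratified case-crossover analysis of the joint
short-term effect of heat and fine particulate matter (PM2.5) on
hospitalization. The case-crossover design is self-matched: each person's
exposure on the day of their hospital admission (the case day) is compared
with their exposure on nearby control days, so every time-invariant personal
and neighborhood characteristic cancels by construction. Control days are
*time-stratified*: all dates in the same calendar month and year that share
the case day's weekday. A Monday admission in July 2014 is matched to the
other Mondays of July 2014, which yields 3 or 4 controls for every possible
calendar date and removes both seasonal and long-term trends and
day-of-week structure from the comparison.

With one case day and a handful of control days per stratum, the natural
likelihood is the conditional logistic one,

$$
\ell(\beta) \;=\; \sum_s \Big[\, x_{s,\mathrm{case}}^\top\beta \;-\;
\log \sum_{d \in s} \exp(x_{s,d}^\top\beta) \Big],
$$

which eliminates the per-stratum nuisance intercepts. The fitted
coefficients are log odds ratios for the exposure-basis columns.

## Exposures

**Heat index.** Perceived heat combining temperature and relative humidity,
computed with the National Weather Service algorithm: below an apparent
temperature of about 80 °F a simple Steadman average applies; above it, the
nine-coefficient Rothfusz regression with separate low-humidity
(RH ≤ 13%, 80–112 °F) and high-humidity (RH > 85%, 80–87 °F) adjustments.
The hand-off between the two formulas is discontinuous by construction; we
measured the jump at moderate humidities and document a 1.5 °F bound, which
is within the regression's own stated error of ±1.3 °F. Inputs are daily
maximum temperature and daily minimum relative humidity, which are the two
ZIP-day summaries exposure surfaces typically provide.

**Climate-localized percentiles.** The same absolute heat index means
different things in different climates. Each ZIP is assigned a
Köppen–Geiger climate subtype (18 subtypes in the contiguous US, grouped
into Arid, Continental, Temperate and Tropical), and the heat index is
re-expressed as a percentile of the subtype's pooled warm-season
distribution — pooled across all ZIPs of the subtype and all study years,
case and control days alike. We use the right-continuous empirical CDF,
$100 \cdot \#\{v \le x\}/n$, with a nearest-rank inverse, so 0 maps to the
subtype minimum and 100 to the maximum exactly. Ties share a percentile.
Analyses are run on the percentile scale; "extreme heat" means the 99th
percentile.

**Aggregation and smoothing.** Gridded surfaces are attached to ZIPs as
unweighted means of the mapped grid cells (`aggregate_grid_to_zip()`);
polygon-weighted aggregation is out of scope, and the mapping table is an
explicit input. The optional 3-day moving average (a sensitivity analysis)
is a trailing window — day $t$ averages days $t$, $t-1$, $t-2$ — because
exposure precedes admission; late-April rows make the first warm-season
days well defined, otherwise they are missing and the stratum day is
dropped.

## Cohort construction

Eligibility mirrors a claims-based workflow: cohort entry is the first
admission carrying a qualifying diagnosis code among the **first ten**
billing positions; the outcome is the first warm-season (May–September)
admission at least 30 days after cohort entry, with no further admission
within 30 days of the outcome discharge, not originating from a skilled
nursing facility, and admitted from a non-healthcare setting, clinic
referral or the emergency room. The 30-day washout is anchored at the
qualifying *admission* date by default; the anchor is configurable
(`eligibility_rules(washout_anchor=)`) because admission- and
discharge-anchored readings are both defensible. Every filter count is
logged so the cohort flow can be audited (`build_cohort(verbose = TRUE)`).

## Exposure bases and the interaction crossbasis

Single-exposure and joint models use either a linear term or a cubic
B-spline without intercept (the stratum conditioning absorbs the
intercept). Knots sit at equally spaced quantiles of the observed stratum
day exposures and boundary knots at the observed range, extended when a
configured reference level (5 µg/m³ PM2.5) falls outside it. Evaluation
outside the boundary clamps to the nearest boundary value, and reported
curves/surfaces are capped at the observed 99th percentile, where
right-skewed PM2.5 data become too sparse to support inference.

The interaction model uses a tensor-product crossbasis: with marginal bases
$b_1$ (heat percentile, 3 df) and $b_2$ (PM2.5, 3 df), the design row is

$$
\big(\,b_1(h),\; b_2(p),\; b_1(h) \otimes b_2(p)\,\big),
$$

15 columns, with the interaction block flattened in row-major order
(column $(i-1)\,\mathrm{df}_2 + j$ is $b_{1i}b_{2j}$); the ordering is
fixed and round-trips through the YAML serialization bit-exactly. All
odds ratios are row-difference contrasts against a fixed reference pair —
median heat percentile and 5 µg/m³ PM2.5 — so the reported OR for any
exposure configuration is $\exp\{[x(\mathrm{target}) -
x(\mathrm{ref})]^\top\beta\}$ with a delta-method 95% interval. Centering
the basis instead would give identical ORs; row differences keep the basis
untouched. Degrees of freedom are chosen by AIC ($2k - 2\ell$; ties go to
the smaller df).

## Fitting

The conditional likelihood is maximized by Newton–Raphson with
step-halving, log-sum-exp stabilization, and the observed information
$\sum_s (E_s[xx^\top] - E_s[x]E_s[x]^\top)$ as Hessian (ridge-stabilized if
numerically non-PD). Convergence requires a relative log-likelihood change
below 1e-10 *and* a gradient sup-norm below 1e-6. Under complete
separation the conditional likelihood is unbounded: coefficients drift,
the gradient decays to numerical zero, and the fitted case-day
probabilities approach 1. We therefore flag a coefficient magnitude above
15 *combined with* near-degenerate fitted case probabilities as a
separation diagnostic rather than returning a silently huge estimate; a
large coefficient with diffuse fitted probabilities is a weakly identified
basis column (it comes with a huge standard error) and is left alone. The
fitter is validated against an exhaustive grid search and against
`survival::coxph(method = "exact")`, which computes the same conditional
likelihood by an independent route.

## The two-stage dependence contrast

Heat and PM2.5 are positively correlated in summer (photochemistry,
stagnant air), so "move heat, hold PM2.5 fixed" is not the only contrast of
interest. The two-stage analysis asks what happens when PM2.5 moves along
with heat:

1. **Stage 1** regresses PM2.5 on a 4-df B-spline of the heat exposure by
   OLS, pooled over all stratum days, independently of the outcomes.
2. The **combined contrast** plugs the stage-1 predictions into the
   crossbasis model:
   $\log\mathrm{OR} = [x(h_t, \hat p(h_t)) - x(h_r, \hat p(h_r))]^\top\beta$.

The point estimate is the deterministic plug-in value. Uncertainty from
*both* models is propagated by Monte Carlo: 5,000 iterations each draw
$\gamma^* \sim N(\hat\gamma, V_\gamma)$ and
$\beta^* \sim N(\hat\beta, V_\beta)$ independently and recompute the
contrast; the empirical 2.5/97.5 percentiles form the interval. Drawing the
two parameter vectors independently is an approximation — the models share
exposure data, though the outcome model conditions on exposure — and is
documented as such; simulation shows 95% intervals cover a known truth at
the nominal rate (95% ± 4% over 200 replicates). With both covariances
zero the interval collapses to the plug-in point exactly, and interval
widths are stable to under 2% across seeds at 5,000 iterations.

## The synthetic study generator

No claims data can ship with a package like this, so the generator builds a
fully controlled stand-in world with the features that matter for the
method:

- **Heat**: per-ZIP daily maximum temperature = climate-subtype baseline +
  seasonal sinusoid (default half-range 12 °C, peaking July 26) + AR(1)
  noise (default marginal SD 3 °C, lag-1 correlation 0.6 — values typical
  of mid-latitude daily summer temperature anomalies).
- **Humidity**: Gaussian (mean 55%, SD 18%) truncated to [5, 100]%.
- **PM2.5**: median $\mu(t) = 6 + 0.25\,t$ µg/m³ times a lognormal
  multiplicative error (log-SD 0.45), hence strictly positive, right-skewed
  and positively coupled to heat; the defaults put warm-season means near
  10–14 µg/m³, the range ambient monitoring reports for the 2000s US.
- **Admissions**: qualifying admissions with the cohort-defining code
  placed within (or, for negative controls, just beyond) the first ten
  diagnosis positions, plus skilled-nursing flags and non-qualifying
  source codes injected at configurable rates, so every eligibility filter
  is exercised.
- **Case days**: within each stratum the case is drawn with probability
  proportional to $\exp(x_d^\top\beta_{\mathrm{true}})$ — the exact inverse
  of the conditional-logit model — so parameter recovery is exact-model by
  construction.

One root seed drives per-operation child streams (panel: seed+1,
admissions: seed+2, and so on), so each module is independently
reproducible and reruns are byte-identical. Enrollees keep a fixed ZIP:
strata span one month, within which residence is constant anyway.

What the generator does *not* emulate: spatial correlation between ZIPs,
wildfire episodes, realistic US geography, co-pollutants, and outcome
dependence on anything but the modeled exposures. Passing recovery tests
therefore demonstrates that the estimation machinery is correct under the
stated model, not that the model captures every feature of claims data.

## Validation study sizes and numerical choices

The test suite validates the chain at sizes chosen to balance statistical
resolution against desk-scale runtime: the linear heat model recovers a
true extreme-heat OR of 1.015 over 100 replicates of 50,000 strata
(mean within ±0.002, CI coverage 91–99/100); an injected separable synergy
$k\,g_1(h)\,g_2(p)$ (k chosen so the interaction log-OR is 0.35) is
recovered as a super-multiplicative OR surface in ≥95% of 50 replicates of
12,000 strata; two-stage interval calibration uses 200 replicates of 2,000
strata at 5,000 Monte Carlo iterations; AIC df selection uses 50 replicates
of 20,000 strata per truth shape. Stratum-day heat percentiles in these
recovery studies are drawn independently uniform on [0, 100] — pooled
subtype percentiles are uniform by construction, and independent days
reflect pooling across ZIPs and the season.

Numerical conventions collected in one place: percentile ECDF is
right-continuous with nearest-rank inverse; basis evaluation clamps at
boundary knots; moving-average windows trail; Newton tolerances are 1e-10
(relative log-likelihood) and 1e-6 (gradient); AIC ties break toward the
smaller df; confidence intervals use 1.96; the Monte Carlo center is the
plug-in estimate (mean/median are available); the "marginal" OR of the
linear interaction model is evaluated with the co-exposure held at its
observed median (a marginal effect in an interaction model is undefined
without such a choice; the level is an explicit argument).

## Limitations

Single-day (or pre-averaged) exposures only — no distributed-lag dimension;
no penalized splines; one case per stratum; no robust/cluster variance; no
formal mediation decomposition of the heat–PM2.5 pathway (the two-stage
contrast accounts for the dependence without decomposing it); grid-to-ZIP
aggregation is unweighted. These match the scope of the motivating design
rather than software constraints, except the lag dimension, which would be
the natural next extension.
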