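---
title: "Modelling vitamin D RCTs on the serum-status scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling vitamin D RCTs on the serum-status scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdrct)
```

## The problem

Randomized trials of vitamin D have mostly been designed the way drug
trials are: pick a dose, randomize, count events. Vitamin D violates both
assumptions behind that template. Participants arrive with substantial and
heterogeneous endogenous 25-hydroxyvitamin D (25(OH)D), and the serum
response to a fixed oral dose is strongly non-linear, flattening as status
rises (the catabolic enzyme CYP24A1 is upregulated with increasing serum
concentration). A trial that enrols mostly replete participants and gives
a modest dose moves almost nobody along the risk curve and is doomed to a
null result regardless of the true biology. `vdrct` makes that arithmetic
explicit at design time.

## Model components and assumptions

### Dose-response curve

Disease odds as a function of serum 25(OH)D (ng/mL) are modelled as a
power law, by default $\mathrm{OR}(c) = 18.3\,c^{-0.833}$, a pooled
breast-cancer case-control relation used here as the all-cancer proxy.
The assumptions are (i) the cross-sectional odds-concentration relation is
causal and transportable to an intervention, and (ii) breast-cancer
gradients stand in for all-cancer gradients. Both are assumptions of the
design model, not facts the package can verify.

The power law diverges at zero concentration, so evaluation is floored at
`min_concentration` (default 1 ng/mL, far below any concentration the
model is used at); a request below the floor is an *error*, not a clamp —
silent clamping would hide unit mistakes (nmol/L passed as ng/mL is the
classic one; `ng_ml_to_nmol_l()` exists, and is never applied implicitly).
The default constants are stored at their published precision (18.3,
−0.833) and not re-derived, since the underlying study-level points are
not available; `fit_power_law()` provides the log-log least-squares
machinery for users with their own points.

### Status-response model

Two backends predict achieved 25(OH)D from (baseline, daily dose):

* **Calibration table** (default): achieved concentrations for the ten
  reference-population decile baselines at 400/1000/2000/4000 IU/d,
  from community-cohort before/after measurements. It is canonical for
  reproducing the reference results. Off-grid queries use bilinear
  interpolation (linear in dose, including from the implicit identity
  column at dose 0, then linear in baseline) and flat clamping outside
  the grid — extrapolating a rise beyond 4000 IU/d would invent data.
  The grid contains one internally inconsistent cell (baseline 11 ng/mL
  at 400 IU/d, achieved 25, exceeding the next decile's 18). We store it
  verbatim — fidelity to the source over plausibility — and flag it with
  a data-validation warning at construction (`check_calibration()`
  reports it; `check = FALSE` silences the warning once acknowledged).
  A plausible monotone value near 16 ng/mL would better match some of
  the source's downstream decile-1 numbers; we do not silently correct
  it.

* **Parametric**: the rise per 1000 IU/d at current concentration $c$ is
  $g(c) = A e^{-c/\tau} + B$, with $(A, \tau, B)$ solved exactly from
  three anchors — a 13 ng/mL rise at $c=0$, 4 at 28, 2 at 140 — giving
  $A \approx 11.00$, $\tau \approx 16.43$, $B \approx 2.00$. The
  exponential-plus-floor form is the simplest smooth, positive, strictly
  decreasing three-parameter family through the anchors. Achieved
  concentration integrates $dc/dD = g(c)/1000$ by fixed-step RK4 with a
  100 IU/d step; because any dose that is a multiple of the step uses
  the identical step sequence, integrating 2000 IU/d in one pass equals
  two sequential 1000 IU/d passes to well under the 10⁻⁶ tolerance.

The two backends disagree in places (the parametric model gives
≈24.7 ng/mL achieved at baseline 14 and 2000 IU/d where the table says
33): the table reflects measured community responses, the parametric form
the three stated anchors. The calibration table cannot be derived from
the anchors by integration, which is precisely why both are kept; use the
table to reproduce the reference tables, the parametric form for novel
doses and baselines.

### Expected cases and normalization

For decile $i$ with per-arm person-years $N_i$ and background incidence
$r$ (default 0.0176 cases/person-year, the all-cancer rate at ages
65–69 of 1760 per 100,000/yr):

$$n_i = \frac{r\,N_i\,\mathrm{OR}(c_i)}{\overline{\mathrm{OR}}},$$

where $\overline{\mathrm{OR}}$ is the arithmetic mean of the baseline
odds ratios over the **full** ten-decile reference population — always,
even when the enrolled cohort is a subset or a single concentration. This
calibrates the model so the unsupplemented full population accrues
exactly $r \times$ total person-years of cases (a conservation identity
tested to 10⁻⁹), and it is the reading that reproduces the reference
per-decile values (e.g. 10.1 expected cases at baseline 14 ng/mL with
400 person-years). A literal sum-normalization differs only by the
factor 10/number-of-deciles and does not reproduce those values.
Expected counts stay fractional end-to-end; rounding to one decimal is
display-only.

### 2×2 statistics

With $a$ treatment cases, $b = N_t - a$ non-cases, $c$, $d$ likewise for
control: $\mathrm{OR} = (a/b)/(c/d)$, Woolf interval
$\exp(\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/a+1/b+1/c+1/d})$, normal
two-sided p on $\ln\mathrm{OR}/SE$, and $\mathrm{RR} = (a/N_t)/(c/N_c)$.
Design choices: fractional cells are evaluated as-is (the model feeds
expected counts like 22.5 into the same formulas used for observed
integers); the exact normal quantile (1.959964…) is used rather than
1.96; no continuity correction and no exact test — a zero cell is an
error, since expected-count inputs should never produce one at realistic
sizes. Published trial reports in this area label this estimate "RR"
although the printed numbers are odds ratios; both are returned
explicitly to avoid the ambiguity.

### Required sample size

`required_n()` declares a design adequate at the smallest person-years
per arm (a multiple of `step`, default 100) where the Woolf upper bound
falls below 1. Since expected counts scale linearly with exposure, the
odds ratio is constant in $N$ and the upper bound decreases
monotonically, so the crossing is unique and an exact grid scan suffices
— we deliberately do not fit a smooth curve through CI points, which
could only add error to a quantity computable exactly at any $N$. The
CI-crossing criterion corresponds to roughly 50% power at the boundary
(the simulator confirms this empirically), which is worth keeping in
mind when using the returned $N$: it is a significance threshold on the
expected outcome, not an 80%-power size. The default search cap is 10⁶
person-years, with an explicit not-reached sentinel beyond it and an
explicit no-solution error when the modelled odds ratio is ≥ 1.

### Monte Carlo simulator

`simulate_trial()` allocates person-years across deciles
deterministically (by the scenario weights) and draws case events as
binomials with the analytic per-person-year probabilities
$r\,\mathrm{OR}(c_i)/\overline{\mathrm{OR}}$ — only the event noise the
analytic model ignores is simulated, which is the point. One documented
RNG stream derives from the user's seed, and the caller's RNG state is
restored afterwards. Replicates with a zero case cell are counted as
non-significant rather than dropped (material only at tiny arm sizes).
Person-year Bernoulli events, rather than per-participant multi-year
survival, keep the hazard scale identical to the analytic bookkeeping.

## What the built-in conditions emulate — and what they do not

The presets reproduce the reference study conditions: the Canadian
ages-50–79 decile baselines (11–40 ng/mL), 0.0176 cases/person-year,
2000 IU/d designs for the deficient (lowest five deciles) and replete
(highest five) cohorts, the unequal-arm 1000 IU/d comparison with the
2007 Nebraska trial (266 vs 403 participants over 3–4 years, entered as
exact person-year products 798/1209 and 1064/1612), the Women's Health
Initiative no-prior-supplement counts, and the 2017 Nebraska trial at
4128 person-years per arm. The single-cohort presets `fig3` and `fig4`
use baseline 14 → achieved 34 and baseline 26 → achieved 42; the 34 is
the source's stated achieved value for that design (its table prints 33
for that cell — both are preserved, the text value in the preset; with
either value the solver returns 900 person-years per arm, consistent
with the published "about 1000" read as an upper bound).

Passing tests therefore show internal consistency with those published
conditions, not field validity. Real trials add what this model omits by
design: within-decile heterogeneity, seasonality and assay variation in
25(OH)D, compliance drift and control-arm contamination, body-weight and
genetic response modifiers, lag between status change and risk change,
competing risks, and time-to-event structure (the published hazard
ratios are compared against 2×2 odds ratios here). Where the source's
printed tables contain small internal inconsistencies (sums of rounded
cells, an extra-digit constant upstream, the decile-1 calibration cell),
we reproduce the cells that are internally consistent and document the
rest rather than tuning toward them.

## Numerical choices

* Woolf z from `qnorm(1 - alpha/2)`; all 2×2 algebra in double
  precision, no corrections.
* Parametric anchors solved by `uniroot` on $\tau$ to 10⁻¹²; RK4 dose
  integration at 100 IU/d steps, partial final step for non-multiple
  doses.
* Grid scan for `required_n`; ties cannot occur (strict monotonicity),
  degenerate inputs error early with named offenders.
* Problem sizes in the tests: simulator checks use 400–2000 replicates
  at the preset arm sizes, where binomial standard errors are small
  enough to separate signal from noise while the whole suite stays
  interactive (a few seconds).

## Known limitations

The dose-response constants carry the causal and transportability
assumptions above; the odds ratio approximates the hazard ratio only for
modest cumulative incidence; the calibration grid is bounded at
4000 IU/d and flat-clamped beyond; and the required-N criterion is a
significance boundary, not a power target — multiply accordingly when
planning a real trial.
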