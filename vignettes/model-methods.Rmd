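---
title: "Model and methods: patient costs of organ preservation in rectal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: patient costs of organ preservation in rectal cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nomcea)
```

## The question

Patients with locally advanced rectal cancer who reach a clinical complete
response after total neoadjuvant therapy (TNT) can be managed
non-operatively ("watch and wait", NOM) instead of undergoing radical
resection after chemoradiotherapy (CRT). Organ preservation avoids a
definitive ostomy and its quality-of-life burden, but demands intensified
surveillance — and surveillance travel is not reimbursed by German statutory
health insurance (SHI). `nomcea` models the *patient-borne* economics of
this trade-off: out-of-pocket costs (co-payments, driving, care
supplements, loss of income) and quality-adjusted life years (QALYs) over a
five-year horizon, for patients insured with a German SHI.

The package separates two layers deliberately:

* an **exact arithmetic layer** (ICER, net monetary benefit, threshold
  analysis) that is closed-form and reproducible to the cent from aggregate
  inputs, and
* a **model layer** (Markov engine plus cost model) whose per-state inputs
  rest on declared assumptions and is therefore validated by calibration
  and structural properties, not cell-by-cell reproduction.

## The Markov model

Six health states: stable disease (A), stable after successful salvage
(B), local recurrence (C), distant recurrence (D), combined local and
distant recurrence (E), and death (F, absorbing). Five cycles of one year.
Both strategies start fully in A; the resection arm applies the 4 %
perioperative mortality of the primary resection at entry, the NOM arm
applies it at salvage resection instead (in the source parameter table the
perioperative risk is footnoted as belonging to resection for local
recurrence).

Published risks arrive as cumulative probabilities at 2-, 3- or 5-year
anchors. They are converted to per-cycle probabilities under a
piecewise-constant hazard: within the first anchor interval the annualized
first anchor applies, between anchors the conditional incremental risk
$(c_2 - c_1)/(1 - c_1)$ is annualized over the interval length
(`annualize(p, h) = 1 - (1 - p)^{1/h}`).

### Arrow set and mortality wiring

The source describes, but does not enumerate, the transition diagram; the
implemented arrow set is the minimal one consistent with the parameter
table: A→C/D/E/F, C→B/E/F, D→B/F, B→C/F, E→F, self-loops everywhere but
death. Three wiring choices deserve explanation because the published
parameters over-determine the model:

* **Synchronous presentation.** The conditional fractions "distant
  recurrence when local recurrence occurred" (0.18) and "local recurrence
  when distant recurrence occurred" (0.54) are applied *once, at recurrence
  onset*, splitting incident recurrences between the single-site states
  (C, D) and the combined state (E). Treating them instead as annual
  per-cycle C→E / D→E rates inflates occupancy of the highest-mortality
  state so far that five-year mortality reaches 20 % / 22.5 % (NOM /
  resection) — irreconcilable with the overall-survival anchors (0.85 /
  0.79) the model must honour. Subsequent progression from C to E uses the
  time-framed "distant recurrence after local recurrence" risk (0.11 over
  3 years, annualized).
* **Post-salvage mortality.** Patients salvaged for local recurrence move
  to B. Their subsequent risk is represented by the pathway itself:
  perioperative death at salvage, re-recurrence from B (0.13 over 5 years,
  annualized) and background mortality. The literature's 50 % five-year
  mortality *after local recurrence and salvage* is available as an
  explicit additional hazard on B (`post_salvage_mortality: explicit` in
  the profile) but is off by default: with it, NOM five-year mortality
  rises to 19–20 %, again contradicting the survival anchors. The 70 %
  five-year mortality of unsalvaged local recurrence applies to the
  unsalvaged fraction on the C row; distant and combined recurrence carry
  their 80 % five-year mortality.
* **Competing risks.** Exits from a state are composed additively, with
  other-cause mortality (0.02/year) as a competing exit everywhere; the
  residual is assigned to remaining in the state. If the raw exits exceed
  1, the row is renormalized (a warning flags excesses beyond 1.25; with
  the bundled profile the worst row excess is about 1 %).

With these defaults the deterministic cohort reaches the mortality the
source trials report, which the test suite asserts within two percentage
points:

```{r calibration}
p <- load_params()
for (strat in c("nom", "resection")) {
  r <- run_cohort(build_matrices(strat, p), p$utilities[[strat]],
                  build_state_costs(strat, p, "mixed"))
  cat(strat, "five-year death:", round(100 * r$occupancy[5, "F"], 1), "%\n")
}
```

### Accounting conventions

Utilities and costs accrue on the *end-of-cycle* occupancy and are
discounted at 3.5 %/year by $(1+r)^{-t}$, $t = 1,\dots,5$; with utility 1
everywhere and no deaths the five-year QALY total is
$\sum_t 1.035^{-t} \approx 4.515$, which pins the convention down in a
unit test. No half-cycle correction is applied by default (the source
reports none); it is available as `half_cycle_correction: true`. The
initial-state utility (0.80 NOM / 0.61 resection) applies to stable
disease in cycle 1 only; the long-term stable utility (0.80 / 0.70)
thereafter. The microsimulation samples individual trajectories from the
same matrices with one seeded generator and is bit-reproducible per seed;
since rewards are state-by-cycle constants its accounting coincides with
the cohort accounting applied to the observed occupancy fractions.

## The patient cost model

Four components per state, strategy, scenario and year; all rules are
statutory except where marked assumed:

* **Co-payments**: 10 EUR per unit, in-patient nights at 10 EUR/night
  capped at 280 EUR/year, everything capped at the exemption limit — 2 % of
  adjusted annual gross household income generally, 1 % for chronic
  disease (applied from year 2 and in recurrence states). Combined
  recurrence (E) is costed *at* the chronic limit, reflecting continuous
  therapy. The per-year unit counts (10 in the primary treatment year, 1
  per follow-up year, 20 in recurrence years) are assumed and echoed by
  every report.
* **Driving**: 26.3 km one-way at 0.20 EUR/km, doubled for the round trip
  (assumed; a visit implies return travel). Covered series (CRT, CTx)
  cost the patient only the 5 EUR taxi co-payment for the first and last
  drive; follow-up travel is entirely out of pocket. The surveillance
  schedules are assumed: 6/6/3/2/2 visits per year under NOM —
  three-monthly clinical/endoscopic review in the first two years, as
  watch-and-wait protocols require — versus 2/2/1/1/1 after resection.
  The package enforces the structural premise that NOM surveillance
  exceeds the resection schedule in every year.
* **Supplements**: 10 EUR/month for ostomy care products and
  non-prescription medication, attached to every state of the resection
  strategy and to the post-salvage state B in both arms (salvage here is
  an abdominoperineal resection with definitive ostomy).
* **Loss of income**: zero for retired patients; for employed patients,
  full salary continuation for six weeks of absence, then 30 % of gross
  income lost for up to 72 further weeks. Absence durations are assumed:
  8 weeks in the NOM treatment year, 16 weeks after primary resection, 26
  weeks around salvage. Combined recurrence implies permanent disability:
  the personal net income is replaced by the reduced-earning-capacity
  pension (925 EUR/month). The mixed scenario multiplies the employed loss
  by the cohort employment rate (28.2 %) rather than simulating two
  subpopulations, matching how that rate was constructed.

Because the per-state cost inputs are assumption-laden, the package does
*not* promise the published aggregate cost cells; it asserts the published
*structure* instead — resection dearer than NOM in every scenario, employed
> mixed > retired within each strategy, driving the dominant stable-state
item except for employed NOM patients, where loss of income dominates.

## Demographic derivations

Employment rate and gross income are incidence-weighted means over four
age bands. The source table reports band shares at one-decimal percentage
precision and suppresses the near-empty under-25 band ("< 0.5 %"); its
derived values (28.2 % employment, 4409 EUR gross income) are reproducible
only with those printed-precision weights, which `weighted_mean()`
therefore uses by default (`mode = "exact"` gives the raw-share mean,
which differs below the reporting precision). The blended net household
income mixes retired households (two pensions of 1048 EUR; 80 % of the
pension is taxable but falls under the 10,347 EUR allowance, so it passes
untaxed) with working-age households (gross income scaled by a
net-conversion factor). The source never states its gross-to-net function;
the factor (0.7882) is declared in the profile, calibrated so the default
blend reproduces the published 2580 EUR/month, and echoed by reports.
Co-payment exemption limits follow
$(12 \cdot \text{gross} - 2 \cdot 5922) \cdot \text{rate}$, giving 821.28
EUR (2 %) and 410.64 EUR (1 %) — the source prints the rounded 822/411 and
labels them per month, but the defining rule is annual, so the package
treats them as EUR/year.

## The synthetic survey cohort

`generate_cohort()` draws records matching the published marginals of the
reference survey subgroup (N = 44 rectal cancer patients; 38 SHI-insured):
age from a piecewise-linear quantile function through the published
median (67) and IQR (58–75) with assumed support 32–92; independent
categorical draws for gender, insurance, employment, income bracket,
loss-of-income bracket, extra-expense bracket and financial difficulty.
Survey items are populated only for SHI-insured records, and expense
causes (multi-select) only for records that report expenses, with mention
probabilities taken from the published tallies (17/10/10/1 mentions among
16 reporters; the co-payment tally exceeds the reporter count, so its
probability caps at 1). Fields are drawn *independently* because only
marginals are published — the generator reproduces marginal structure, not
the joint dependence of real survey data, so passing marginal-recovery
tests says nothing about correlations (e.g. between employment and income
loss). "Not reported" is retained as an explicit category throughout, and
financial difficulty is summarized against both the full SHI denominator
and the responders-only denominator, since the source uses both.

`consistency_check()` closes the loop descriptively (the source performed
no hypothesis test on this small cohort): the modelled net household
income of 2580 EUR falls inside the cohort's median income bracket
(1701–2600 EUR), and the modelled 28.2 % employment rate sits within a few
points of the surveyed 32 %:

```{r consistency}
s <- summarize_cohort(generate_cohort(10000, seed = 1))
consistency_check(s, load_params()$economics)
```

## Numerical choices and problem sizes

* Thresholds (`cost_threshold()`, `qaly_threshold()`) are closed-form —
  NMB is affine in cost and effectiveness — so no numeric search is
  involved; infeasible equivalence points (negative cost, more than 5
  QALYs in 5 years) are flagged, never clamped.
* Monetary quantities are carried at full precision; only table renderers
  round.
* The bundled microsimulation size is 100,000 patients (the size the
  base-case analysis simulated), which the acceptance script uses; unit
  tests use 1,000–20,000 patients, with Monte-Carlo agreement asserted at
  3-sigma binomial bounds against the deterministic cohort.
* Synthetic-cohort checks use n = 10,000, where every marginal is
  recovered within 3-sigma.

## Known limitations

* Per-state cost values depend on the declared assumption set; aggregate
  cost cells are order-of-magnitude comparable to the published ones but
  not reproduced cell-by-cell, and the package does not claim otherwise.
* The transition diagram is a reconstruction; alternative wirings of the
  conditional recurrence fractions are defensible, and one (the explicit
  post-salvage hazard) ships behind a profile switch.
* QALY totals are sensitive to the accrual convention; the end-of-cycle
  convention used here is conservative relative to half-cycle-corrected
  accounting.
* The model covers SHI-insured patients only; private insurance benefits
  are heterogeneous and out of scope, as is the insurer (third-party)
  perspective.
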