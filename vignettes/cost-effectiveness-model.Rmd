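---
title: "A decision-tree + Markov model for repeat delayed imaging after negative angiography in spontaneous SAH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree + Markov model for repeat delayed imaging after negative angiography in spontaneous SAH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahcea)
```

## The decision problem

About one in six patients with spontaneous subarachnoid hemorrhage (SAH)
whose initial CTA and confirmatory DSA are negative nevertheless harbors a
causative aneurysm. Two management strategies compete:

* **No repeat imaging** — discharge after the negative work-up. Patients
  with an occult aneurysm remain at risk of re-rupture; a re-bleed triggers
  emergency repair with poor outcomes.
* **Repeat delayed CTA** — keep the patient in hospital for seven days and
  rescan. CTA positives are confirmed by DSA (treated as a perfect
  reference test, so false positives cost a DSA but nothing more) and the
  aneurysm is repaired electively (coiling or clipping).

`sahcea` evaluates both strategies for a cohort entering at age 55, from a
healthcare-payer perspective, in 2020 GBP, with costs and QALYs discounted
at 3.5% per year over a lifetime horizon.

## Model structure

Each arm is resolved in two stages.

**Short-term decision tree** (`short_term_pathway()`): branch probabilities
are the aneurysm prevalence (0.173) and the CTA's sensitivity (0.98) and
specificity (1.00). The tree yields an upfront cost, incurred undiscounted
at time 0, and a distribution of the cohort over four long-term states:

* *at risk* — occult untreated aneurysm, no re-bleed yet (utility 0.60, no
  annual cost);
* *favorable* — modified Rankin Scale 0–2 after treatment or without an
  aneurysm (utility 0.87, no annual cost);
* *unfavorable* — mRS 3–5 (utility 0.44, annual nursing cost £84,346.39);
* *dead* — absorbing, utility 0.

**Markov cohort process** (`run_cohort()`): one-year cycles from age 55
until age 100. Per cycle,

* at-risk patients re-bleed with the years-since-presentation probability
  from the re-bleed schedule. A re-bleed costs the emergency
  coiling/clipping mix in that cycle and its survivors enter favorable or
  unfavorable per the re-bleed outcome vector, earning that state's reward
  the same cycle (no zero-reward tunnel). Non-re-bleeders die at the
  background life-table rate or stay;
* favorable and unfavorable patients die at their state-specific annual
  probability combined with background mortality as independent hazards,
  `1 − (1 − p_state)(1 − q_age)`, or stay (the default movement rule; a
  full annual transition matrix with favorable↔unfavorable crossover can be
  supplied instead);
* rewards accrue on end-of-cycle occupancy at discount exponent equal to
  the cycle index; the terminal cycle forces background mortality to 1 so
  the horizon closes.

## Parameters and their second-order distributions

`default_parameters()` ships the complete base case: diagnostic accuracy,
outcome vectors over (favorable, unfavorable, dead), unit costs (CTA £331,
DSA £1,919, hospital day £380.75 × 7 days, elective coiling/clipping
£14,030.80/£13,212.19, emergency £19,983.87/£20,275.02, annual nursing
£84,346.39) and utilities. Each uncertain parameter carries a `dist_spec`:
Beta for probabilities and utilities, Gamma for costs, Dirichlet for
outcome vectors. All cost Gammas share shape 144, i.e. a coefficient of
variation of 1/12; `derive_gamma_spec(mean)` reconstructs any of them from
its mean, which keeps the PSA centred on a user-overridden cost.

Several published distribution specifications disagree with their own
base-case values, and the package reproduces both columns as given rather
than reconciling them: the prevalence Beta has mean ≈ 0.200 against a base
of 0.173, the favorable-outcome utility Beta mean ≈ 0.775 against 0.87,
and the no-aneurysm unfavorable Beta mean ≈ 0.0079 against 0.0792.
`audit_parameter_distributions()` lists every such mismatch without
treating it as an error. Two structural quirks deserve note:

* the re-bleed outcome triple is published as (0.0752, 0.3948, 0.4700),
  which sums to 0.94. The base case keeps the explicitly printed favorable
  and unfavorable probabilities and assigns death the remainder (0.53);
  the death share subsumes peri-procedural mortality in any case. The PSA
  Dirichlet keeps the printed concentrations verbatim.
* the outcome Dirichlets have concentrations summing to ≈ 1, so PSA draws
  from them are extremely dispersed (most mass near the simplex corners).
  That is what the published specification says, so it is what is sampled.

The coiling/clipping mix is not published; it defaults to 0.5/0.5
(symmetric ignorance), is configurable, and is registered for one-way
sensitivity analysis over [0, 1]. The "mortality of functional outcome"
Dirichlet (0.1067, 0.7778, 0.1155) is interpreted as the annual death
probability of the favorable and unfavorable states respectively, the
third element being a residual that only keeps the Dirichlet well-formed.
The hospital-stay cost is sampled as the whole 7-day block (Gamma mean
£2,665.25) and divided by the length of stay, which is the only reading
consistent with its published Gamma rate.

## Synthetic stand-in inputs

Two inputs the analysis needs are not published anywhere in the main text
and are shipped as clearly labelled synthetic fixtures (`# source: fixture`
headers; `write_fixture_files()` regenerates them):

* **Background mortality**: a Gompertz life table
  `qx(age) = min(1, 2.3e-5 · e^(0.095·age))`, closed at age 100 — an
  adult-mortality shape of the right order for a high-income population,
  not a national table.
* **Annual re-bleed schedule**: years 1–10 = 0.35, 0.10, 0.05, 0.04, then
  0.03, constant beyond year 10. This encodes the classic natural history
  of conservatively managed ruptured aneurysms — high residual first-year
  risk for patients who have already survived the first week, settling to
  roughly 3% per year — chosen once on those grounds.

Replication against real sources is a documented user path: pass
`life_table`, `rebleed_schedule` or `transitions` CSVs to the `cmd_*`
functions or construct a `transition_model()` directly.

Because these stand-ins (and the structural interpretation above) replace
an unpublished supplement, passing tests demonstrate the engine's internal
correctness — mass conservation, closed-form limits, agreement with an
independent microsimulation — not agreement with the original TreeAge
model's hidden inputs. Under this package's reading, the favorable state
carries an annual death probability of 0.1067 for everyone in it,
including electively treated patients, which makes elective repair
(outcome mix 0.51/0.34/0.15 across states worth ≈ 5.1/0.12/0 discounted
QALYs) less valuable than remaining at risk under the default schedule.
The published base case, in which repeat imaging gains 0.283 QALYs, is
only reachable if treated patients follow a substantially more benign
long-term transition rule than the printed state-mortality vector — a
treated/untreated distinction the four-state structure cannot express.
The package therefore reports, on its own inputs, a *dominated* repeat
strategy (more costly, fewer QALYs), and its replication tests against the
published table document exactly which quantities agree (the no-repeat
arm's cost and effectiveness, within 8% and 3%; the repeat arm's cost,
within 15%) and which do not (the repeat arm's effectiveness and
everything downstream of the QALY difference: ICER sign, acceptability at
£20,000, threshold crossings).

## Sensitivity analysis

`one_way()` sweeps any registered scalar over a grid (published ranges by
default, ±25% where none is published). Components of outcome vectors are
registered individually; sweeping one rescales its siblings proportionally
so the vector stays on the simplex, except the no-aneurysm outcome, whose
favorable/unfavorable probabilities are independent with death as the
remainder. Sweeping `start_age` shifts the life-table lookup and shortens
the horizon; nothing else depends on age. `tornado()` evaluates both ends
of each range and orders bars by span; where an endpoint is dominant or
dominated the span is computed on the signed willingness-to-pay gap
(dominant → −∞, dominated → +∞, clamped), so dominance still ranks.

`threshold_search()` bisects the signed gap `ICER(x) − WTP` after a
41-point scan of the bracket. Multiple sign changes return the crossing
nearest the base value with a `multiple` flag; the bisection stops when
the bracket has shrunk by 1e-4 of its width.

`run_psa()` draws all distributed parameters independently (the published
specification states no correlation beyond each Dirichlet row), evaluates
both arms on the same draw, and is bit-reproducible from its seed: one RNG
stream, draws consumed in the fixed order of the `dist` map. The CEAC
awards each willingness-to-pay point to the strategy with the strictly
larger net monetary benefit, ties split equally, so the two curves sum
to one.

## Numerical conventions and degenerate inputs

* No half-cycle correction by default (the original model's setting is
  unknown); `half_cycle = TRUE` averages start- and end-of-cycle occupancy
  for state rewards only.
* Runs stop early once living mass falls below 1e-9; an exhausted re-bleed
  schedule applies its tail rule (constant-last by default) rather than
  raising.
* Simplex sums are enforced to 1e-9; CEAC complementarity to 1e-12.
* The microsimulation oracle (`microsim_oracle()`) re-derives expected
  values by direct per-individual sampling of every branch and transition
  under identical accounting, on its own RNG stream. The test suite holds
  the cohort engine to within 3 Monte-Carlo standard errors of it at
  n = 200,000 on the base case and on five PSA-drawn parameter sets.
* Problem sizes used by the shipped tests: 45-cycle horizon, 100-configuration
  fuzz suite, 200,000-individual oracle runs, 5,000-iteration PSA.

## Known limitations

* The four-state structure cannot give treated and untreated survivors
  different long-term prognoses (see above); that is the main obstacle to
  replicating the published incremental results and is inherent to the
  printed parameterization.
* The no-re-bleed utility (0.60) is lower than the favorable-outcome
  utility (0.87), which penalizes the at-risk state relative to successful
  treatment on utility grounds alone; the original authors flag the same
  assumption as a limitation.
* Costs are 2020 GBP throughout; no inflation indexing or currency
  conversion is provided.
* CTA complications (allergy, contrast nephropathy) are not modelled.
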