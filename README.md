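# sahcea

Cost-effectiveness modelling of **repeat delayed CTA imaging** versus **no
repeat imaging** for patients with spontaneous subarachnoid hemorrhage (SAH)
whose initial CTA and DSA found no aneurysm. Roughly 17% of these patients
harbor an occult aneurysm; a repeat scan a week later can catch it before it
re-ruptures, at the price of a seven-day hospital stay, the scan, a
confirmatory DSA and elective repair. The package is aimed at health
economists and neurovascular researchers who want a transparent, fully
scriptable implementation of this decision problem — every input is a plain
R object or a small YAML/CSV file, and every published quantity is
recomputable from the command line.

## The model

Each strategy is a short-term decision tree feeding a four-state Markov
cohort process (at risk, favorable mRS 0–2, unfavorable mRS 3–5, dead) run
in one-year cycles from age 55 to 100 from a healthcare-payer perspective,
2020 GBP, both costs and QALYs discounted at 3.5%/yr:

* expected discounted cost and effectiveness per strategy,
  `E[C] = C_upfront + Σ_t (1+r)^(−t) Σ_s π_s(t) c_s` and likewise
  `E[Q] = Σ_t (1+r)^(−t) Σ_s π_s(t) u_s`, with π(t) the cohort occupancy;
* the incremental cost-effectiveness ratio `ICER = ΔC/ΔQ` and net monetary
  benefit `NMB(λ) = λ·ΔQ − ΔC` against the NICE willingness-to-pay band
  (λ = £20,000–30,000/QALY);
* one-way deterministic sensitivity analysis, tornado ordering and
  willingness-to-pay threshold search (bisection on `ICER(x) − λ`);
* probabilistic sensitivity analysis (Beta/Gamma/Dirichlet draws, 5,000
  iterations) with cost-effectiveness acceptability curves;
* an individual-level microsimulation oracle that independently validates
  the cohort engine.

Background mortality and the annual re-bleed schedule are not published in
the source analysis; the package ships clearly labelled synthetic stand-ins
and accepts user CSVs for replication against real tables. See the
`cost-effectiveness-model` vignette for the full model description and for
which published quantities these stand-ins can and cannot reproduce.

## Worked example

```r
library(sahcea)

p  <- default_parameters()        # full published base case
tm <- default_transition_model()  # packaged life table + re-bleed schedule

evaluate_strategy("no_repeat", p, tm)
#> <strategy_result> no_repeat: cost £8018.61, effectiveness 4.525 QALY
```

The trace behind that number shows the cohort draining out of the at-risk
state (re-bleeds) and the unfavorable state (its 0.78 annual mortality):

```r
head(evaluate_strategy("no_repeat", p, tm)$trace[, 1:6], 3)
#>   cycle age    at_risk favorable unfavorable      dead
#> 1     1  55 0.11196930 0.6451148 0.038396670 0.2045193
#> 2     2  56 0.10029865 0.5744140 0.012912182 0.3123751
#> 3     3  57 0.09479117 0.5108487 0.004834151 0.3895260
```

The full comparison, from the shell:

```sh
Rscript inst/cli/sahcea.R base-case
```

```text
Strategy                              Cost (£)        QALYs     Incr. cost    Incr. Q ICER (£/QALY)
No repeat delayed imaging              8,018.61        4.525              -          -            -
Repeat delayed imaging (CTA)           8,584.90        4.180         566.29     -0.345    dominated
NMB at £20,000/QALY: £-7,461.38
NMB at £30,000/QALY: £-10,908.93
```

On the packaged synthetic inputs the repeat strategy costs £566 more and
loses 0.345 QALYs, so it is dominated — the vignette explains why this
differs from the source analysis (electively treated patients inherit the
same high state mortality as everyone else under the printed parameters)
and which arm-level quantities do replicate. Sensitivity and probabilistic
analyses follow the same pattern:

```r
one_way("cta_sensitivity", p = p, tm = tm)         # sweep over 0.20..0.99
tornado(p = p, tm = tm)                            # all registered parameters
threshold_search("prevalence_aneurysm", wtp = 20000, p = p, tm = tm)
print(run_psa(p, tm, n = 200, seed = 1))
#> <psa_result> 200 iterations (seed 1)
#>   P(repeat CTA cost-effective at £20,000/QALY) = 0.4150
```

Everything is also reachable through the CLI (`base-case`, `dsa`, `psa`,
`threshold`, `fixtures-write` subcommands with `--config`, `--seed`,
`--wtp`, `--out-dir`, `--json`).

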