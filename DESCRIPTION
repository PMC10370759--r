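Package: sahcea
Title: Cost-Effectiveness of Repeat Delayed Imaging After Negative Initial
    Angiography in Spontaneous Subarachnoid Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model comparing repeat delayed
    CTA imaging against no repeat imaging for patients with spontaneous
    subarachnoid hemorrhage whose initial CTA and DSA were negative. Computes
    lifetime discounted costs and quality-adjusted life-years per strategy,
    incremental cost-effectiveness ratios and net monetary benefit;
    deterministic one-way sensitivity analysis with tornado ordering and
    willingness-to-pay threshold search; probabilistic sensitivity analysis
    with Beta/Gamma/Dirichlet parameter draws and cost-effectiveness
    acceptability curves; and an individual-level microsimulation used to
    validate the cohort engine. Ships a complete default parameter set with
    clearly labelled synthetic stand-ins for inputs (background-mortality
    life table, annual re-bleed schedule) that the analysis requires but
    that must otherwise be supplied from external sources.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
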