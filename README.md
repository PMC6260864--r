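# repopsig

Does forcing a complete turnover of microglia — depleting them with a CSF1R
antagonist and letting the niche repopulate — reset the transcriptional
signature of brain aging? `repopsig` implements the inference chain behind
that question as a tested, reusable R pipeline: negative-binomial contrast
testing on gene × sample count matrices, false-discovery-rate control, the
age-signature definition, the four-way reversal taxonomy, the LPS-response
taxonomy for inflammation panels, and comparative-CT (ΔΔC&#8324;) qPCR fold
changes. A factorial count simulator plants recoverable per-gene structure so
every stage can be validated by parameter recovery on a desktop.

It is aimed at analysts working with microglial (or other bulk/panel)
expression data from 2×2 age × treatment designs who want the classification
rules to be explicit, testable functions rather than a one-off script.

## The model

Counts are modeled per gene as negative binomial with gene-wise dispersion,

> K<sub>gj</sub> ~ NB(mean = s<sub>j</sub> µ<sub>gj</sub>, var = µ + α<sub>g</sub> µ²),

with per-sample size factors s<sub>j</sub> estimated by the median-of-ratios
rule (the median, over zero-free genes, of a sample's counts divided by the
gene's geometric mean). Each contrast fits a log-link NB GLM with log s
offsets and tests the group coefficient with a Wald test (two-sided normal on
coef/SE, standard errors from the observed information); p-values are
adjusted with the Benjamini–Hochberg step-up rule over tested genes.
Dispersions come from a method-of-moments estimate pooled within design
cells, shrunk 50/50 in log space toward a fitted mean–dispersion trend.

The decision rules on top of the statistics are:

* **Age signature** — genes with adjusted P < 0.05 and |fold change| > 1.5
  between aged controls and adult controls (plus a baseMean > 10 expression
  prefilter), split into increased/decreased.
* **Reversal taxonomy** — per signature gene, with nominal P at α = 0.05:
  no significant repopulation-vs-aged change → *unaffected*; significant and
  in the same direction as the age effect → *exacerbated*; significant,
  opposing, and no longer different from adult controls → *reversed*;
  otherwise → *partially reversed*.
* **LPS taxonomy** — *exacerbated by age* (induced by LPS in adults, further
  increased in aged), *unique to aged* (induced only in aged), *adult only*,
  *nonresponsive*; aged-responsive genes whose induction fails after
  repopulation are flagged *prevented by repopulation*.
* **ΔΔC&#8324;** — fold change = 2^−(ΔCT − mean control ΔCT), with
  ΔCT = CT<sub>target</sub> − CT<sub>reference</sub>.

## A worked example

```r
library(repopsig)

# simulate the reference design: adult/aged × control/repopulation,
# 6 mice per group, 10,000 genes, ~500 planted age-signature genes
sim <- simulate_reversal_experiment(sim_config(seed = 1))

sf   <- estimate_size_factors(sim$counts)
disp <- estimate_dispersions(sim$counts, sim$design, sf)
age  <- fit_contrast(sim$counts, sim$design, "group",
                     "aged_control", "adult_control",
                     size_factors = sf, dispersions = disp)
rva  <- fit_contrast(sim$counts, sim$design, "group",
                     "aged_repopulation", "aged_control",
                     size_factors = sf, dispersions = disp)
rvad <- fit_contrast(sim$counts, sim$design, "group",
                     "aged_repopulation", "adult_control",
                     size_factors = sf, dispersions = disp)

sig <- define_age_signature(age)           # P_adj < 0.05, |FC| > 1.5
cls <- classify_reversal(sig, rva, rvad)   # four-way taxonomy
evaluate_recovery(sim$truth, cls)
```

```
Recovery report
  signature: planted 506 | called 533 | sensitivity 1 | empirical FDR 0.0507
  per-category recall:
    reversed             0.937
    partially_reversed   0.981
    exacerbated          0.947
    unaffected           0.912
```

All 506 planted signature genes are found (sensitivity 1) with an empirical
false discovery rate of ~5%, matching the nominal adjusted-P cutoff, and each
planted reversal category is recalled at 91–98%. `summarize_categories(cls)`
tallies the calls, `autoplot(age)` draws the MA plot, and
`autoplot(cls)` the category bars. Real data enter the same way through
`read_count_matrix()` and `read_sample_key()`; `run_classify_reversal()`
wires the whole procedure from a YAML config, and
`inst/cli/repopsig.R` exposes it as shell subcommands.

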