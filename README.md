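# coprescribenet

Network analysis of opioid doctor shopping from longitudinal claims data.

Threshold rules ("more than k prescribers per quarter") miss the relational
side of doctor shopping: drug-seeking patients concentrate around a minority
of at-risk prescribers, so *which* prescribers a patient reaches carries
signal beyond *how many*. `coprescribenet` implements the network
alternative end to end, for epidemiologists and health-services researchers
working with prescription claims:

1. **Co-prescription network.** Per focal quarter T, non-MAT opioid fills
   from quarters {T−2, T−1, T} are pooled; patients are tied when they share
   a prescriber, with weight w_ij = number of unique shared prescribers.
2. **Prominence.** Weighted PageRank
   `PR(i) = (1−d)/N + d Σ_j w_ij PR(j)/s_j` (d = 0.85, undirected edges
   treated as two directed edges, dangling mass redistributed so Σ PR = 1),
   reported as percentiles; plus degree, log-degree, z-scored PageRank and
   bipartite Co-HITS scores as sensitivity metrics.
3. **Outcomes.** Per patient-quarter: opioid fill count, maximum daily
   morphine-milligram-equivalent dose (day-grid over concurrent fills) with
   a strict MME > 90 mg flag, and ICD-10–based overdose and opioid-use-
   disorder indicators.
4. **Panel models.** Prominence is decomposed into between-person
   (BP = person mean / 10) and within-person (WP = deviation / 10)
   components and the four outcomes are fit with random-intercept
   negative-binomial / logistic models plus state fixed effects, reporting
   IRRs/ORs per 10 percentile points, latent-scale ICC, BIC and
   Gauss–Hermite-averaged predicted margins.
5. **Synthetic claims generator.** Real claims of this kind are proprietary;
   a seeded generator emulates their structure (at-risk prescriber stratum,
   latent shoppers, skewed hub-heavy degree distribution, realistic outcome
   rates) and plants known effect sizes so every stage is testable by
   parameter recovery.

## Worked example

```r
library(coprescribenet)
library(data.table)

cfg <- synth_config(n_patients = 300, n_prescribers = 50, seed = 42)
sy  <- synth_claims(cfg)                      # two-stage generation
rx  <- filter_opioid_claims(sy$rx)            # drop MAT fills
ct  <- centrality_table(rx, panel_quarters(cfg),
                        patients = sort(unique(rx$patient_id)),
                        n_quarters = cfg$n_quarters)
panel <- assemble_panel(sy$patients, sy$rx, sy$dx, ct, panel_quarters(cfg))
fit <- fit_glmm(panel, model_spec("mme_gt90"))
fit$coefficients[term %in% c("bp", "wp"),
                 .(term, OR = round(exp_estimate, 2),
                   ci = sprintf("%.2f-%.2f", ci_lo, ci_hi))]
#>      term    OR        ci
#>    <char> <num>    <char>
#> 1:     bp  1.57 1.36-1.80
#> 2:     wp  1.18 1.00-1.41
```

The generator planted a BP odds ratio of 1.88 and a WP odds ratio of 1.27
per 10 PageRank percentile points on the MME > 90 outcome; at this small
sample the fitted ORs of 1.57 (BP) and 1.18 (WP) recover the direction and
rough magnitude, and the full recovery suite (2,000-patient panels, 20
replicates) verifies nominal 95% CI coverage.

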