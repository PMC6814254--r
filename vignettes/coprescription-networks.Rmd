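---
title: "Co-prescription networks and opioid-risk panel models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-prescription networks and opioid-risk panel models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coprescribenet)
library(data.table)
```

## The problem

Doctor shopping — soliciting controlled-substance prescriptions from many
clinicians — is usually detected with threshold rules on the number of
prescribers a patient visits. Those rules miss the *relational* structure of
the behavior: shoppers cluster around a minority of at-risk prescribers and
share information about them, so which prescribers a patient reaches can be
as informative as how many. This package operationalizes that idea: it
builds a patient–patient **co-prescription network** from longitudinal
opioid claims, measures each patient's structural prominence in it, and
relates prominence to quarterly opioid-risk outcomes with random-intercept
panel models.

## The network

For a focal quarter $T$, non-MAT opioid fills from quarters $\{T-2, T-1,
T\}$ are pooled. The bipartite patient–prescriber graph has an edge when a
patient received at least one fill from a prescriber in that window (fill
multiplicity is ignored). Projecting onto patients gives an undirected
graph in which the tie weight between two patients is the number of unique
prescribers they share — two patients prescribed opioids by the same three
providers have a tie of weight 3. Medication-assisted-treatment agents
(e.g., buprenorphine) are excluded first, so that clustering around scarce
MAT-licensed providers cannot masquerade as prominence.

Two design points that the construction leaves open:

* **Early-window truncation.** Focal quarters with fewer than two
  predecessors pool whatever exists (`policy = "truncate"` in
  `pooled_window()`); `"drop"` refuses them instead. Truncation avoids
  discarding early panel quarters and is the default.
* **Isolates are nodes.** Most patients share no prescriber in a window.
  They stay in the graph with strength 0, so the PageRank $N$ matches the
  panel and percentiles are defined for everyone.

## Prominence metrics

**Weighted PageRank.** The score solves
$PR(i) = \frac{1-d}{N} + d \sum_{j \in M(i)} \frac{w_{ij}}{s_j} PR(j)$
with damping $d = 0.85$, each undirected edge treated as two directed
edges, and $s_j$ the strength of $j$. Power iteration starts uniform and
stops when the L1 change drops below $10^{-10}$. Isolates are dangling
nodes: the literal recursion would give them exactly $(1-d)/N$ and the
total mass would fall below one, contradicting the interpretation of
PageRank as a stationary distribution. The default therefore redistributes
dangling mass uniformly (`dangling = "uniform"`), which keeps
$\sum_i PR(i) = 1$; the literal variant remains available as a flag.

Raw PageRank is strongly right-skewed, so models use the **percentile
transform** $100(r_i - 0.5)/N$ with midranks for ties (every percentile
vector then averages exactly 50; a min-rank alternative is available), or
the **z-score** (sample SD). **Degree** is the count of distinct
co-prescribed patients; its log uses $\log(\text{degree}+1)$ because
isolates are in the panel.

**Co-HITS.** The bipartite sensitivity metric couples patient scores $x$
and prescriber scores $y$ with all edge weights 1:
$x_p = \frac{1-\lambda_p}{N_p} + \lambda_p \sum_{d \in N(p)} y_d /
\deg(d)$, and symmetrically for $y$. The per-side damping has no published
value for this application; the defaults mirror the PageRank damping
($\lambda = 0.85$) and are exposed in `centrality_params()`. Patient
scores are percentile-transformed per quarter, consistent with the
one-mode pipeline.

## Outcomes

Four dependent variables per patient-quarter: the count of opioid fills;
an indicator that the maximum daily morphine-milligram-equivalent dose
exceeded 90 mg; an overdose indicator from accidental-poisoning ICD-10
codes (the inclusive measure also counts "unspecified drug" poisonings,
since nonspecific coding is known to undercount opioid overdoses); and an
opioid-use-disorder indicator from abuse/dependence codes.

Daily MME is dose × CDC conversion factor, summed over concurrently
active fills. The source data define neither overlap handling nor exact
code lists, so the package makes both explicit and configurable:

* **Day-grid concurrency.** Each fill is active from its fill day for its
  days' supply (clipped to the 90-day quarter); daily totals are summed
  across active fills and the quarter maximum is taken. The flag is strict
  (90.0 exactly does not count as exceeding 90).
* **Code lists as reconstructions.** Defaults: T40.0x–T40.4x and T40.6x
  (opioid poisoning) and T50.9x (unspecified) with accidental-intent
  character '1'; F11.1x/F11.2x for OUD; C00–C96 for the cancer control.

The panel includes every patient with at least one non-MAT opioid fill in
the observation window; each contributes one row per panel quarter
(zero-fill quarters included). The high-risk sensitivity sample drops
patients — whole panels, not single quarters — who never saw more than one
prescriber in any quarter; patient-level dropping is what keeps the
restricted sample balanced (observations = patients × quarters).

## Panel models

A time-varying prominence metric $x_{it}$ is decomposed into a
between-person component $BP_i = \bar{x}_i / 10$ and a within-person
component $WP_{it} = (x_{it} - \bar{x}_i)/10$. The per-10-percentile
scaling lives in the decomposition, so reported coefficients are odds or
rate ratios per 10 percentile points; standardized and logged metrics use
scale 1. WP is analogous to a fixed-effects estimate: it compares a
patient to their own average and absorbs all time-invariant patient-level
confounding.

Each outcome is regressed on BP, WP, gender, age (per 10 years),
insurance dummies (reference "Other"), state fixed effects (reference
West Virginia), cancer history, and the number of unique prescribers in
the quarter, with a patient-level random intercept. Binary outcomes use a
logistic mixed model and the count outcome a negative-binomial mixed
model (nbinom2), both fit by Laplace-approximate maximum likelihood via
`glmmTMB`; `lme4::glmer` is available as an alternative logistic backend
and the two agree to estimation tolerance. The estimation backend is a
contract, not a commitment: any maximum-likelihood fitter that passes the
parameter-recovery suite is conformant. Constant
covariates (e.g., a state with no observations in a sparse subsample) are
dropped automatically with a note.

**ICC.** For logit models the latent-scale
$\sigma_u^2/(\sigma_u^2 + \pi^2/3)$. Count models have no exact analogue;
the package uses the lognormal-Poisson approximation
$\sigma_u^2/(\sigma_u^2 + \ln(1 + 1/\bar\mu + \alpha))$ with $\alpha$ the
nbinom2 overdispersion, and labels it as such — cross-family comparisons
are qualitative.

**Margins.** Predicted outcomes over a BP (or WP) grid spanning ±1 SD of
its sample distribution, other covariates at sample means, averaged over
the random intercept by 30-node Gauss–Hermite quadrature, with
delta-method confidence bands.

## The synthetic claims generator

Real claims of this kind are proprietary, so the generator is first-class,
tested code that emulates the statistical structure the analysis assumes:

* ~13% of prescribers form an at-risk stratum with Zipf-like popularity;
  latent shoppers (default 10% of patients) visit their home prescriber
  plus a Poisson number (mean 3) of extra prescribers drawn
  preferentially from that stratum. This produces the skewed
  shared-prescriber degree distribution with hub patients; non-shoppers
  mostly use 0–1 prescribers per quarter.
* Defaults: 7 observed quarters with the last 4 forming the panel; the
  generator's population size defaults to 2,000 patients and 200
  prescribers, a scale at which every stage (including 20-replicate
  recovery studies) runs on a single CPU in minutes while preserving the
  qualitative structure (isolate-heavy networks, hubs, rare outcomes).
* Baseline outcome rates mirror a commercial opioid cohort: mean 1.26
  fills per patient-quarter, 8% MME>90, 1.2% OUD, 0.16% overdose.
  Planted prominence effects default to published per-10-percentile
  magnitudes (BP 1.18/1.88/1.20/2.00, WP 1.15/1.27/1.10/1.11 for
  counts/MME/overdose/OUD) — realistic magnitudes for recovery tests, not
  ground truth to be reproduced.

Generation is **two-stage**: claims are generated first, a truth pass
computes each patient's realized PageRank percentile, and outcomes are
then drawn from linear predictors in the realized BP/WP (intercept +
$\beta_{BP}(BP-5) + \beta_{WP} WP + u_i$, logit or negative-binomial
link, $u_i \sim N(0, \sigma_u)$). BP is centered at 5 (the population
mean percentile over 10) so configured baseline rates are the rates at
average prominence and $u_i = 0$; marginal rates are higher once
$\sigma_u > 0$, as in any log/logit random-intercept model.

Planted draws are realized back into the claims under two coherence
constraints: cells with no prescriber contact stay empty, and each cell
keeps one structural fill per (patient, prescriber) pair with the planted
negative-binomial draw added as refills attributed to prescribers already
seen — so the bipartite edge set, and therefore every downstream
centrality score, is exactly the truth-pass value. The realized count is
thus structural fills plus the planted draw, and zero in
prescriber-free cells; exact parameter recovery is tested on
`simulate_panel()`, which plants the identical model directly on a
simulated percentile panel with no claims layer, while full-pipeline
model checks are sign- and direction-level.

One attenuation is inherent rather than incidental: in any coherent
claims table the fill count is at least the prescriber count (every fill
names a prescriber), so with the number of prescribers held constant —
as the models require — the between-person prominence effect on fill
counts can only travel through the refill channel and is strongly
attenuated toward null. Within-person count effects and both components
of the binary outcomes are transmitted cleanly. Real claims escape this
bind to the extent that dose and refill behavior vary between patients
independently of prescriber counts.

**What the generator does not emulate:** real NDC drug coding, cash or
Medicaid payment channels, calendar dates within quarters beyond a
uniform fill day, geographic clustering below the state level, and any
social contagion dynamics. Passing tests show the pipeline recovers what
was planted under the stated structure — not that the structure is a
complete model of real claims.

## Numerical choices and degenerate inputs

* Convergence in L1 with uniform starts makes PageRank and Co-HITS
  deterministic to tolerance; non-convergence raises an error carrying
  the final residual.
* Percentile ties use midranks; `standardize()` rejects zero-variance
  input rather than returning NaN.
* All randomness flows from one root seed through fixed stream offsets
  (population +0, claims +1, outcome planting +2, claims rewrite +3,
  direct panel simulation +4), so every artifact is reproducible from
  `(config, seed)` and the caller's RNG state is never disturbed.
* Problem sizes in the test suite (graphs ≤ 60 patients for brute-force
  oracles, 2,000-patient panels for recovery, 20 replicates) were chosen
  as the smallest sizes at which the checked properties are informative.

## Known limitations

* The Laplace approximation can bias variance components for very rare
  binary outcomes (overdose at 0.16%); recovery tests use outcomes with
  enough events per replicate to be identified.
* The count-model ICC is an approximation, not an estimand with a closed
  form.
* The high-risk restriction and the MME day grid implement one reading of
  ambiguous source definitions; both are documented above and
  configurable where reasonable.
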