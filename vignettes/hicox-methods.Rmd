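---
title: "Methods: two-phase high-order gene-smoking interaction analysis"
author: "hicox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase high-order gene-smoking interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Smoking dose (pack-years) modifies how DNA methylation at specific CpG
sites relates to survival in early-stage non-small-cell lung cancer
(NSCLC). Beyond pairwise gene-environment effects, *high-order*
interactions — three or four factors acting jointly — may carry prognostic
signal that no marginal analysis can see. hicox implements the full
analytical machinery for finding and exploiting such interactions on an
epigenome-wide scale:

1. probe- and sample-level QC of beta-value methylation matrices;
2. a histology-stratified Cox proportional-hazards engine with a full
   factorial interaction expansion;
3. a hill-climbing scan that escalates a validated order-(k−1) interaction
   to order k by testing every remaining probe in the free slot, with
   Benjamini–Hochberg FDR control and a two-phase
   (discovery/validation) decision rule;
4. the TRIUNE integrated risk score (the fitted linear predictor combining
   covariates and all interaction components), its quartile subgroups,
   Kaplan–Meier and forest-plot analyses, and the conditional
   hazard-ratio surface of the top probe;
5. nested prognostic-model comparison by IPCW time-dependent ROC/AUC and
   the concordance index;
6. methylation-expression cis-regulation follow-up and the interaction
   re-test at the expression level.

Because real multi-center cohorts cannot ship with a package, a
first-class synthetic-data module generates cohorts with the same
structure — multi-center, LUAD-dominant discovery (~524 samples, ~48%
censoring) and a single-center, heavily censored validation cohort (~468
samples, ~76% censoring) — with interaction signals planted on the
log-hazard scale, so every stage is testable end to end.

## The model

For subject $i$ with histology stratum $s(i)$, the hazard is

$$\lambda_i(t) = \lambda_{0,s(i)}(t)\,
  \exp\Big(\sum_j \alpha_j\,\mathrm{Cov}_{ij} +
  \sum_{S \subseteq \{E, G_1, G_2, X\},\, S \neq \emptyset}
  \beta_S \prod_{v \in S} v_i\Big)$$

where $E$ is pack-years of smoking and $G_1, G_2, X$ are CpG methylation
levels on the 0–100 percent scale, so every methylation coefficient is a
log-hazard per 1 percentage point and its exponential the familiar
"per-1%" hazard ratio. Covariates are age, sex, smoking status
(never/ever/current), clinical stage (I/II) and study center; histology
(LUAD/LUSC) stratifies the baseline hazard. The four-way interaction
effect is the Wald test of $\beta_{EG_1G_2X}$.

Two term schemes are available. `full_factorial` (default) uses all
$2^k - 1$ subset products, respecting the interaction hierarchy that a
scan must maintain. `as_printed` reproduces the 14-term integrated-score
formula in which the $E \times G_2 \times X$ triple is absent; the
discrepancy between the two is deliberate and surfaced to the user rather
than silently resolved, since hierarchy-respecting scans need the full
set while the published score omits one triple.

### Numerical choices

* Partial-likelihood maximization is delegated to the Newton iteration of
  the survival package (Efron tie handling by default, Breslow optional;
  iteration cap 100). Percent-scale factorial products span eight orders
  of magnitude, so design columns are standardized to unit SD internally
  and coefficients/covariance rescaled afterwards; this keeps the
  information matrix well conditioned and makes the scale-equivariance
  property (scaling a column by $c$ divides its coefficient by $c$) hold
  to machine rounding.
* Confidence intervals use the fixed multiplier 1.96.
* Singular designs (collinear or constant columns) raise an error naming
  the offending terms; monotone-likelihood escapes (|standardized
  coefficient| > 20) and iteration-cap hits flag the fit as
  non-converged. In scans, non-converged candidate fits are recorded with
  missing p and excluded from the FDR denominator, with counts logged.
* Missing data: complete cases per model, with the dropped count stored
  on the fit.

## The scan and the two-phase rule

`scan_order_k()` fits one order-$k$ model per candidate probe,
conditional on the fixed winner set, and records the highest-order term's
Wald statistics. Benjamini–Hochberg q-values are computed over the
successfully tested candidates. `two_phase_decide()` then passes a
candidate only if (a) discovery FDR-q ≤ 0.05 and validation p ≤ 0.05 and
(b) the coefficient signs agree between phases; passers are refit on the
pooled cohort with the validation phase entering as its own center.
Under a global null, requiring p ≤ 0.05 in two independent phases gives a
per-probe false-positive rate of about $0.05^2 = 0.0025$ — the quantity
the acceptance simulation recomputes.

`hill_climb()` iterates the scan from order 2 upward, appending at each
order the passer with the smallest discovery p (a tie-break that must be
defined even though a well-powered design typically has a single passer)
and stopping at the first order with none.

## The synthetic cohorts

The generator's defaults are the study conditions, not tuning knobs:

* **Cohort structure.** Discovery: four centers (131 samples each by
  default), 81% LUAD, censoring target 0.479. Validation: one center
  (468 samples), 48.5% LUAD, no never-smokers, censoring target 0.7607.
  Age ~ N(66.7, 10²); pack-years among smokers ~ Gamma matched to mean
  43.36 / SD 31.10, never-smokers exactly 0.
* **Methylation.** Each probe has its own Beta(a, b) spanning hypo-,
  hemi- and hyper-methylated regimes (means 0.15–0.85, precision 15–60).
  The three planted probes are mid-range and variably methylated
  (Beta(2, 2), SD ≈ 0.22): only dispersed CpGs can carry a detectable
  interaction, and the generator guarantees their CV stays above the 5%
  QC rule. A per-center Gaussian location shift (SD 0.01) is the only
  batch-effect realism; values are clipped to [0, 1].
* **Survival.** Event times are drawn by inverse transform from
  per-histology exponential baselines (LUAD 0.12/yr, LUSC 0.18/yr)
  multiplied by `exp(lp)`. The linear predictor is mean-centred before
  exponentiation — a constant is absorbed into the baseline hazard, so
  the implied Cox model is unchanged while raw-scale products cannot
  overflow. Censoring is the minimum of an administrative horizon (12
  years) and an independent exponential whose rate is calibrated by
  root-finding so the expected censoring fraction hits the target.
* **Planted interactions.** A pure four-way coefficient on raw-scale
  products is essentially untestable: the raw product is almost
  collinear with its lower-order terms, so the hazard is distorted long
  before the four-way Wald test gains power. `planted_interaction()`
  therefore plants the signal on the *centered* product
  $\beta\,(E-\mu_E)(G_1-50)(G_2-50)(X-50)$ and expands it onto all 15
  raw-scale coefficients; the highest-order coefficient equals $\beta$
  and the signal loads on the four-way-unique direction.
* **Calibrated effect size.** `planted_four_way_default()` returns
  −9.5e-7 (log-hazard per pack-year × 1%³), calibrated by simulation so
  that the *end-to-end two-phase detection* — discovery FDR-q ≤ 0.05
  among 2000 scanned probes at n = 1000, then validation p ≤ 0.05 at
  n = 500 — succeeds in roughly 80% of replicates. (For reference, a
  single Wald test at α = 0.05 and n = 1000 reaches 80% power already at
  −3.5e-7.) The value was fixed once, before the acceptance artifacts
  were built, and is not revisited.
* **Expression.** Each planted probe gets one cis gene
  $r\,\mathrm{std}(\beta) + \sqrt{1-r^2}\,\varepsilon$ (default
  r = 0.455) plus independent noise genes; all genes standardized.
* **Covariate effects** (age 0.02/yr, male 0.2, ever/current smoker
  0.1/0.3, stage II 0.5) are plausible placeholders — the source cohorts'
  real covariate effects are not published, so these are generator
  conventions, not estimates.

What the generator does *not* emulate: array chemistry (type I/II probe
designs, color channels), genome-scale probe correlation structure, the
bimodality of real 450K beta distributions, informative censoring, or
center-specific covariate-outcome confounding. Passing tests therefore
demonstrate the correctness and calibration of the *machinery* under a
well-specified hazard model, not robustness to the full messiness of
real multi-center methylation data.

### Small-sample behavior of the four-way Wald test

Two finite-sample effects are documented and quantified by the test
suite rather than hidden. First, at n = 300 per cohort the four-way Wald
test is slightly anticonservative in the multi-center discovery layout
(type-I rate ≈ 0.06 at nominal 0.05), so the simulated two-phase null
rate lands near 0.0028 rather than exactly 0.0025. Second, the
information about a four-way product concentrates in the few subjects in
the product's tails, which makes the Wald pivot t-like: 95% CIs cover
the planted coefficient in roughly 85–90% of replicates at n = 1000
(closer to nominal at stronger signal or larger n). Both effects shrink
with sample size; neither is specific to this implementation.

## QC rules

Probes are removed if any of the following fires, attributed to the
first failing rule in this order: (a) detection p > 0.05 in strictly
more than 5% of samples; (b) coefficient of variation (SD/mean on the
beta scale) < 5%; (c) methylated or unmethylated in all samples,
operationalized as all betas ≥ 0.9 or all ≤ 0.1 (configurable — the rule
has no canonical numeric definition); (d) SNP flag; (e) cross-reactive
flag; (f) failing any data-driven rule (a–c) within any single center.
Whether the "more than 5%" rules are strict or inclusive is not
canonical; strict inequalities are used and tested at the boundary.
Samples are removed for > 5% undetectable probes or missing pack-years.
Batch alignment is a deliberate per-probe location/scale stand-in for
array-normalization pipelines (quantile normalization, type-II
correction, empirical-Bayes batch removal are out of scope at desk
scale); it is exact on constant shifts and idempotent on a single batch.

## TRIUNE and its subgroups

TRIUNE is exactly the fitted model's uncentered linear predictor — a
weighted combination of all covariates and all configured interaction
components. Quartile cutoffs are the empirical 25/50/75 percentiles with
boundary ties assigned to the lower group, so 992 distinct scores give
four groups of 248. Group hazard ratios (vs the lowest quartile) are
marginal by default, with a covariate-adjusted option, since the
published subgroup display appears unadjusted. The forest analysis
reports the score per 1 SD (computed once on the full sample) because a
per-unit log-hazard of a linear predictor is scale-dependent and
uninterpretable. Median-survival CIs use log-log transformed curve
bounds. When weights and groups come from the same cohort the scoring is
in-sample (circular), exactly as in the original design; honest
out-of-sample scoring is available by passing `newdata`.

The conditional effect surface evaluates the model-implied log hazard
ratio of the top probe per 1% as a closed form in (pack-years, G1) with
G2 fixed at the median of each of its median-split subgroups — the
literal model-implied conditional effect, since no canonical grid or
reference normalization exists for such displays.

## Discrimination evaluation

`timed_auc()` implements the cumulative/dynamic IPCW estimator: cases
are events by the horizon, controls those at risk beyond it, and
subjects censored earlier are weighted out by the Kaplan–Meier estimate
of the censoring distribution (pooled, not stratified). Its variance
comes from the full influence-function representation, including the
term for estimating the censoring distribution; with no censoring the
estimator reduces exactly to the binary Mann–Whitney AUC and the
influence terms collapse to the classical two-sample components.

Comparing time-dependent AUCs with a test designed for binary outcomes
is not literally defined under censoring. The package's rule: when no
subject is censored at or before the horizon the reduction to correlated
binary ROC curves is exact and DeLong's test is applied; otherwise a
Wald contrast on the AUC difference uses the joint influence-function
variance. The output labels which route was taken. The concordance index
is Harrell's estimator (usable pairs under censoring, half-credit score
ties), reported raw by default with the symmetric max(c, 1−c) convention
behind a flag. Evaluation is in-sample by default, matching the original
design's reporting; this overstates absolute discrimination but
preserves the nested-model contrasts of interest.

## cis-regulation follow-up

Methylation-expression pairs are tested by covariate-adjusted linear
regression (one QR decomposition per probe shared across genes), BH
adjusted over all tested pairs. By design the probe set defaults to the
score's probes against all genes, not all probes × all genes. A pair is
a cis candidate when the probe lies within 1 kb of the gene interval
(1-based inclusive coordinates, gene-body anchored, strand ignored —
TSS-anchored windows are an undefined alternative) and p ≤ 0.05, both
boundaries inclusive. One probe may map to several genes. The
expression-level interaction re-test reuses the same factorial Cox
machinery with standardized expression (`value_scale = 1`).

## Problem sizes used by the shipped checks

The packaged test-suite and acceptance script run at desk scale, chosen
once: the null two-phase simulation uses 500-probe cohorts of n = 300
(40 pairs in the test suite, 200 in the acceptance script); the
planted-recovery experiment uses 2000 probes, n = 1000 discovery / 500
validation over 15 replicate seeds; estimator oracles run on 1000 random
fixtures; null calibration uses 1000 replicate fits. Epigenome-scale
matrices (450k probes) pose no algorithmic obstacle — the scan is linear
in probes with one Cox fit (~ms) per candidate — only time.

## Known limitations

* The Wald-based scan inherits the small-sample behaviors quantified
  above; a likelihood-ratio variant would calibrate better at small n
  but would not match the single-coefficient reporting convention.
* The IPCW AUC contrast under censoring is a pragmatic extension of
  DeLong's idea, not a canonical test.
* The batch-alignment step is a stand-in; real pipelines should run
  dedicated normalization before import.
* In-sample TRIUNE grouping and AUC evaluation are faithful to the
  original design but optimistic; use the out-of-sample options for
  honest assessment.
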