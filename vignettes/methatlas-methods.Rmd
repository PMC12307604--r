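---
title: "Models and design choices in methatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in methatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

methatlas builds a reference atlas of acute-leukemia methylomes from CpG
beta-value matrices and uses it for three things: calling the diagnostic
subtype of a new sample, estimating its probability of death within five
years, and scoring it on a compact CpG survival signature. This vignette
explains the models behind each step, the tunable parameters and their
defaults, what the synthetic cohorts do and do not emulate, and the design
decisions taken where more than one reasonable construction existed.

## The data model

The substrate is a samples-by-probes matrix of beta values — the fraction of
methylated signal at each CpG, in [0, 1], with `NA` marking missing calls —
plus a sample table carrying batch, tissue, diagnostic label and survival
endpoints (overall survival and event-free survival as months plus a 0/1
event flag). A `cpg_reference` pins every probe to a forward-strand CG
dinucleotide on the genome (0-based half-open, so each locus spans exactly
two bases) and fixes the column order that every component of a trained
atlas shares. For survival modeling, beta values are moved to the logit
scale: `M = log2(beta / (1 - beta))`, clamped at `epsilon = 1e-6` so fully
methylated or unmethylated calls — routine in low-coverage nanopore data —
stay finite. M-values are the right scale for linear hazard models because
they decompress the variance near the 0 and 1 boundaries where beta values
saturate.

## Quality control and harmonization

The QC cascade applies six exclusions in a fixed order, because the stage
counts are order-dependent and a run's accounting should be reproducible:
masked sex-linked/non-CpG probes, masked unreliable probes, listed samples
that failed upstream array QC, probes with more than `missing_threshold`
(default 5%) missing calls, listed non-hematopoietic samples, and PCA
outlier samples. Detection-p-value sample failure happens at IDAT level in
array-processing software, outside this package's scope, so stage three
consumes an externally supplied list. The PCA outlier rule — no standard
criterion exists — flags samples whose distance in the space of the top
`pca_components` (default 2) principal-component scores, each standardized
by its score standard deviation, exceeds `pca_k_sd` (default 4). Both knobs
are in `atlas_config()`.

Remaining missing values are filled by the batch mean of the same probe
(falling back to the global probe mean when a batch never observed the
probe), and batch structure is then removed by empirical-Bayes
location/scale adjustment (`sva::ComBat`, parametric prior, batch-only
design — no biological covariates, because the subtype signal must survive
correction untouched by design-matrix choices). Correction runs on the beta
scale with output clamped back to [0, 1]; the M-scale alternative is
equivalent away from the boundaries, and the beta scale keeps the corrected
matrix directly interpretable. One caveat worth knowing: EB shrinkage
corrects the *distributional* batch effect, so the per-probe *empirical*
batch-mean difference after correction is not exactly zero — it shrinks
with cohort size (mean residual ~0.004 at 600 samples for a planted 0.1
shift) but individual probes retain mean-estimation noise. Tests therefore
check the mean absolute residual, not a per-probe maximum.

## The embedding

Classification does not happen in the full probe space. The QC'd matrix is
compressed to two coordinates for visualization and five for modeling. The
package uses principal-component analysis of the probe-centered beta matrix
as its dimension-reduction backend. This was a deliberate design choice
among neighbor-graph manifold methods and linear projections: PCA gives a
deterministic fit with no optimizer state, an exact linear out-of-sample
transform — a new sample identical to a training sample lands exactly on
its training coordinate, which is the property single-specimen clinical
inference leans on — and it preserves cluster geometry whenever subtypes
separate by mean methylation shifts, which is the regime methylation
subtyping operates in (hundreds of probes shifted by 0.2–0.4 beta). The
cost is that PCA will not unroll nonlinear manifold structure; for the
classification task here the clusters only need to remain linearly
separated, and the gradient-boosted classifier downstream is itself
nonlinear. Component signs are normalized (largest-magnitude loading
positive) so fits are reproducible across platforms.

## Subtype and mortality classifiers

Both classifiers are gradient-boosted decision-tree ensembles (xgboost) on
the five embedding coordinates. Hyperparameters are tuned by stratified
5-fold cross-validation over a small grid of L1 (`reg_alpha` in {0, 1}) and
L2 (`reg_lambda` in {10, 20}) penalty strengths, with inverse-frequency
instance weights so rare subtypes are not swamped; the base learner is
fixed at depth 2, learning rate 0.02, 40% row and column subsampling, and
150 rounds. This base learner is deliberately much softer than a
performance-tuned booster, and the reason is the confidence gate: an
unregularized boosted ensemble drives its margins to saturation, so a
specimen lying in the empty space between two clusters — the clinically
ambiguous case the gate exists for — can be assigned near-certain
probability for a single class whose decision region happens to swallow
the gap. Shallow, slow, heavily subsampled boosting keeps the summed leaf
values small where training data are sparse, so probabilities spread
across classes off the data manifold while in-cluster calls remain
essentially perfect (the five coordinates separate the subtypes by many
within-cluster standard deviations, so accuracy does not pay for the
softness). Penalty strength stays in the CV grid because it is the knob
that matters for calibration; every grid corner behaves equivalently on
the package's study cohorts, so the CV choice cannot tip the gate.

The subtype model reports the full class-probability vector, the top and
second labels, and a confidence gate: a call is reported only when the top
probability reaches `confidence_cutoff = 0.5`; below that the sample is
displayed as "Not confident". The mortality model is binary: a sample is
labeled dead if its death event occurred at or before `horizon_months`
(default 60), alive if follow-up reached the horizon, and excluded from
training — but still scored at inference — if censored earlier, since its
5-year status is genuinely unknown. The high/low risk grouping uses a 0.5
probability cutoff by default.

## The CpG survival signature

The signature is derived in three stages on the survival-annotated samples,
with all times administratively censored at 60 months first, so every
association targets 5-year time-to-death.

1. **Risk-adjusted Cox EWAS.** One proportional-hazards model per CpG:
   time-to-death on the CpG M-value plus the clinical risk group as a
   categorical covariate (Efron tie handling). Wald p-values are reported;
   degenerate probes (constant M, non-convergence) are flagged with p = 1
   rather than dropped silently.
2. **Candidate thresholding.** Probes with p < `ewas_alpha` enter the
   candidate pool. The default is 1e-5; the threshold notation in common
   use is ambiguous between 1e-5 and 1e-4, so the package defaults to the
   Manhattan-plot convention and leaves the literal alternative one
   argument away.
3. **Stability selection.** `stability_iters` (default 1000) iterations of
   an L1-penalized Cox fit; each iteration draws an 80% subsample of the
   cohort, reshuffles a 10-fold assignment, and picks the penalty on a
   shared log-spaced path by cross-validated partial likelihood under the
   one-standard-error rule. Probes with non-zero coefficients in at least
   `freq_threshold = 0.95` of iterations are kept.

Two choices in stage three deserve their rationale. First, the penalty
rule: the CV-optimal penalty (`lambda.min`) maximizes predictive partial
likelihood but is well known to over-select — on the package's planted
simulations (600 samples, 200 candidates, 10 planted effects of |log-HR|
0.8) its active set carries roughly 28 spurious probes alongside the 10
real ones, which makes a 95%-frequency rule meaningless. The
one-standard-error rule is the standard parsimony choice and recovers
exactly the planted set; `lambda_rule = "min"` remains available. Second,
the subsampling: if every iteration refits the *same* cohort and only the
fold assignment changes, the selected set at the chosen penalty is an
almost deterministic function of the data — a noise probe that enters once
enters always, and its selection frequency saturates at 1. Subsampling is
what makes selection frequency measure stability against cohort
perturbation; it is the established form of the procedure, and with it the
pure-noise case correctly yields an empty selection (raised as an error)
instead of a fabricated signature. `subsample = 1` recovers the
fold-reshuffle-only behavior.

The kept probes get final coefficients from a joint unpenalized Cox refit
on the full cohort (a lightly ridge-stabilized fit, theta = 1e-4, is the
fallback on singularity), defining the linear hazard score
`score = sum(coef_i * M_i)`. The dichotomization cutoff is the median
training score, so the discovery cohort splits 50/50 into high and low
groups; a score strictly above the cutoff is "high".

## Nanopore ingest

A modkit-style bedMethyl file is parsed (9 core columns, extended count
columns used when present, records inconsistent between their percent and
count fields excluded), filtered to 5mC calls, and collapsed onto the
reference: the forward-strand record at the locus start and the
reverse-strand record one base downstream pool their modified/valid counts,
and the pooled fraction is the locus beta. `min_coverage` defaults to 1 —
the design mirrors an imputation-over-thresholding philosophy, since
low-pass sequencing is exactly the use case — and loci below it are filled
with the discovery-cohort mean of the training run, with per-locus
provenance kept. Inference is gated: the subtype call comes first, and the
mortality and signature models are applied only when the confident top
call is a myeloid class (label matching `myeloid_pattern`). A report warns
when fewer than 10% of reference loci were directly observed.

## The synthetic cohorts

The generator exists so that every stage is testable without any external
download. Its defaults are the package's study conditions: 600 samples by
2,000 CpGs, 6 subtypes with 100 marker probes each at beta offset 0.4, two
batches with a +0.05 shift, 2% missing calls, and 200 survival-candidate
probes of which 10 carry planted per-M-value log hazard ratios of ±0.8
under an exponential baseline (0.02/month) with ~30% uniform censoring —
sized to mirror the 200-candidates-to-compact-signature selection geometry
at a scale that runs in minutes on one CPU. Baseline betas are bimodal
(Beta(1,8)/Beta(8,1), component fixed per probe) as real methylomes are;
candidate probes are mid-range (Beta(4,4)) so their M-values vary
continuously. The clinical risk group is assigned independently of the
planted CpGs and carries its own hazard term (log-HR 0.5 per step), so a
risk-adjusted EWAS retains the full CpG signal — the signature is
information *beyond* the clinical assignment, which is the point of
adjusting. Survival ties to the planted CpGs only, not to subtype; the
mortality classifier on embedding coordinates is therefore near-chance on
these cohorts by construction, and its discriminative behavior is tested
on purpose-built cohorts whose hazard is linked to the coordinates.

What the generator does not emulate: probe-chemistry artifacts (type I/II
bias), cell-composition mixtures, clonal evolution, non-proportional
hazards, and informative censoring. Passing tests show the pipeline's
machinery is correct under its stated statistical assumptions; they do not
certify performance on real cohorts, where those unmodeled features are
the hard part.

## Numerical conventions and degenerate inputs

Beta values outside [0, 1] are rejected at read time with the offending
cell named. The M-value clamp is `epsilon = 1e-6`. Ties in partial
likelihoods use the Efron approximation (Breslow selectable). Confidence
intervals on hazard ratios are Wald intervals on the log scale. The AUC is
the Mann–Whitney pair probability with half credit for ties, so it accepts
both continuous scores and binary high/low codings. Chi-squared tests are
Pearson without continuity correction unless asked. A hazard score exactly
at the cutoff is "low"; a top probability exactly at 0.5 is confident. A
probe constant across samples is non-estimable and flagged wherever it
appears. Every stochastic component — fold draws, subsamples, boosting —
derives its stream from one master seed, and refitting with the same seed
reproduces the serialized bundle byte for byte.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the default 600 × 2,000
cohort for the end-to-end paths, 200 stability-selection iterations over
five generator seeds for the signature (the full 1000 is the training
default), 100 simulated specimens at 30× mean coverage for the nanopore
round trip, and 50 ambiguous midpoint specimens for the confidence gate —
sizes chosen so the whole suite completes in well under half an hour on a
single CPU while keeping every statistical margin wide.

## Known limitations

The embedding is linear; strongly nonlinear cluster geometry would call
for a manifold method with a native transform, at the cost of
determinism. The mortality classifier inherits whatever outcome signal the
embedding coordinates carry — if survival structure is orthogonal to the
methylation clusters, it cannot do better than chance, and the signature
path is the right tool. ComBat assumes batch effects are additive in
location/scale per probe. The bedMethyl reader targets the modkit dialect;
other pileup formats need conversion. The package never calls variants,
estimates tumor purity, or processes raw signal — it starts at beta values
and bedMethyl tallies.
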