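---
title: "Models and conventions of the batch-effect workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions of the batch-effect workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoBatchQC)
```

# The problem and the data model

Large quantitative proteomics studies acquire samples over long instrument
schedules. Two technical signals contaminate the feature matrix: a
*continuous* one — MS signal drift, a smooth change of measured intensity
with acquisition order as chromatography and ion optics degrade between
maintenance events — and a *discrete* one — feature-specific level shifts
between batches (digestion plates, MS maintenance blocks, acquisition
sites). Adjustment is a two-stage affair: sample-wide **normalization**
first, then feature-level **batch-effect correction**. Everything in this
package operates on log2 intensities; the additive models below are only
sensible on that scale.

The central container, `BatchExperiment`, extends `SummarizedExperiment`:
the `intensity` assay holds the log2 matrix with `NA` for unobserved cells,
`colData` carries a *unique, dense integer* `run_order` plus the annotation
factors, and `metadata` records which columns are technical batch factors,
biological factors and the replicate-group label. Missing measurements are
absent records — the package never stores sentinel zeros, because zero
filling on a log scale injects enormous, usually batch-correlated,
artefacts into every complete-matrix method (see the hazard section).
Duplicate acquisition timestamps must be resolved by the user before
import; every operation that touches running order requires a total order.

# Normalization

Three samplewise normalizers are provided; selecting one is an explicit
analysis decision (heterogeneous cohorts can violate the "bulk proteome
unchanged" assumption behind quantile normalization, and informative
outlier proteins argue for milder location-only adjustment):

* `normalizeMedian` shifts each sample's median to the **median of the
  per-sample medians** rather than zero, preserving the absolute log2
  scale; this keeps unlogged quantities (CVs, fold changes against
  reference channels) interpretable downstream. The operation is
  idempotent and exact.
* `normalizeQuantile` on complete data is the classical procedure: each
  sample's sorted vector becomes the vector of per-rank cross-sample
  means. The classical method is undefined under missingness, so the
  package pins down one extension: each sample's empirical quantile
  function is linearly interpolated onto a common grid of
  `max(n_observed)` points, the reference is the per-rank mean of those
  interpolated functions, and each observed value maps to the reference
  quantile at its within-sample fractional rank (ties get average ranks).
  With no missing values this reduces exactly to the classical result.
* `normalizeZscore` standardises each sample to mean 0, sd 1 (denominator
  `n − 1` everywhere in the package, with small replicate groups in mind);
  it is the right tool only when sample variances genuinely differ.

All normalizers preserve the missingness pattern exactly and refuse
degenerate samples (no observations; zero variance) by name.

# Two-step batch-effect correction

## Step 1: LOESS drift removal

For every feature and every batch independently, a LOESS curve is fitted to
the observed log2 values over run order and subtracted. The local
regression is implemented in the package with a pinned convention, because
classical implementations differ in window truncation and the drift
contract needs reproducible semantics: the window of each target point is
its `ceiling(span * n)` nearest neighbours, weights are tricube in the
distance scaled by the window radius, the local polynomial has degree 2 by
default (degree 1 available), and there are no robustness iterations. A
local fit of degree *d* reproduces any global polynomial of degree ≤ *d*
exactly, which is the anchor of the unit tests.

`span` (fraction of points per window, default 0.75) is the one knob that
must be chosen per dataset: too small overfits and *overcorrects* (it eats
real signal), too large misses genuine trends. It is exposed on every
interface. Each feature×batch with fewer than `minPoints = 8` observations
is left untouched and logged as a fallback — fitting a curve through a
handful of points is overcorrection by construction — and any batch smaller
than 25 samples triggers a warning for the same reason.

After subtraction the fit is re-anchored at the feature×batch **median of
the observed values**, so the output of step 1 is drift-free data whose
per-batch levels still differ — exactly the input the discrete step
expects. (The re-anchoring constant is a package convention; for a constant
feature it makes step 1 the identity, and under noise it moves the
per-batch median by far less than the noise floor.)

## Step 2: discrete correction

`centerDiscrete` equalises each feature's per-batch median (or mean) to its
global statistic over observed values. It is exact, idempotent, needs only
one observation per feature×batch, and is therefore the robust choice under
batch-specific missingness.

`combatAdjust` implements the parametric empirical-Bayes location–scale
model: standardise each feature by its grand mean (plus optional
categorical covariates protecting biological groups) and pooled variance;
estimate per-batch locations γ̂ and scales δ̂²; moment-match a normal prior
on the locations and an inverse-gamma prior on the scales across features
within each batch; iterate the conditional-posterior updates until the
maximum relative parameter change falls below `tol = 1e-4` (at most 100
sweeps); remove the shrunk γ*, δ*² and back-transform. All parameters are
returned in a `CombatParams` object. The estimator details follow the
standard parametric variant exactly (pooled variance with denominator *n*,
batch variances with *n − 1*, the usual moment estimators for the priors),
and the test suite verifies cell-level agreement with an independent
implementation of the same model to 1e-6. Preconditions are enforced
loudly: at least two batches, two samples per batch, and **every feature
observed at least twice in every batch** — run
`completenessFilter(scope = "per_batch")` first, or prefer median
centering. The nonparametric prior variant is not implemented.

Only a single batch factor is corrected per call. When two technical
factors are heavily confounded (a common acquisition-schedule pathology),
no correction can separate them; `confoundingReport` quantifies the
association with Cramér's V and flags V = 1 as inseparable. The package
never merges factors silently.

# Diagnostics

PCA, hierarchical clustering and PVCA all require complete features. The
default `missing_policy` drops incomplete features and *reports the count
prominently*; zero/min filling is available only through the explicit,
warning-emitting `imputeValues`, which also returns the imputation mask.

PVCA works as follows: feature-centred PCA; retain the smallest set of
leading components whose cumulative variance reaches `varianceThreshold`
(default 0.6); per retained component, fit a REML random-intercepts model
(`lme4`) of the scores on the requested factors and, optionally, their
pairwise interactions; normalise the variance components (REML already
truncates them at zero) within each component; average across components
with eigenvalue-fraction weights. Proportions sum to 1 and a residual is
always present.

One property matters for interpretation and guided the validation design:
with a *partial* threshold the decomposition describes only the leading,
structured slice of the variance. Batch structure has rank at most
(number of batches − 1) and concentrates in the top components, so the
batch share among retained components is systematically larger than the
batch share of total variance. The package's parameter-recovery validation
therefore runs PVCA with `varianceThreshold = 1.0` — decomposing the whole
spectrum — where the eigenvalue-weighted average converges to the
total-variance decomposition and recovers a constructed batch share
(0.6 by construction in the test) within the stochastic tolerance. The 0.6
default is kept for diagnostics because the leading-variance view is what a
screening plot should show; users comparing PVCA numbers across settings
should keep the threshold fixed.

Degenerate inputs are handled explicitly: factor pairs inducing identical
sample partitions are rejected as inseparable; components whose scores
break the mixed-model fit are attributed entirely to the residual;
numerically null components (eigenvalue < 1e-12 of the maximum) are never
modelled.

# Quality control

The controls are deliberately proximity-based. Criteria of the form "more
significant hits after correction" are not computed anywhere: they cannot
distinguish restored signal from leaked batch structure.

* **Sample correlations** (`sampleCorrelationSummary`): Pearson over
  pairwise-complete features, pairs classified replicate / within-batch /
  between-batch. Pairs sharing fewer than `minOverlap = 50` features are
  excluded and counted — correlations over a handful of shared peptides are
  noise. Expectation: replicates sit clearly above unrelated pairs at every
  stage; the within-vs-between gap is the batch effect and should shrink
  after correction.
* **Peptide correlations** (`peptideCorrelationSummary`): same-protein
  pairs should stay positively correlated (they quantify the same
  molecule); unrelated pairs should be near zero. Shared drift inflates
  unrelated-pair correlations before correction. Unrelated pairs are
  subsampled (`maxPairs`) with a mandatory seed.
* **Replicate CVs** (`cvByAbundance`): sd/mean of *unlogged* intensities
  within replicate groups, averaged per feature and binned by mean log10
  abundance — CV is only meaningful on the ratio scale, and precision is
  abundance-dependent.
* `qcCompare` runs all of the above plus PVCA on a before/after pair over
  an identical feature/sample universe and reports paired summaries and
  deltas; swapping the inputs negates every delta.

# The synthetic-data generator

`simulateExperiment` draws
`intensity = baseline + bioeffect + shift + sensitivity × drift + noise`,
then applies missingness. Defaults describe a mid-sized discovery cohort
and are fixed once: 100 proteins × 3 peptides + 10 spike-ins, 90 samples in
3 contiguous batches, exponential signal decay restarting at each batch
boundary with amplitude 1.0 log2 units, per-feature drift sensitivity
U(0.3, 1.5) (drift manifests differently per peptide), per-feature discrete
shifts N(0, 0.5), a two-level biological group with sum-to-zero per-protein
contrasts N(0, 0.5), per-specimen per-protein individual variation
N(0, 0.3), noise N(0, 0.3), and 5 specimens injected twice at random run
positions. "Amplitude" follows the sinusoid convention uniformly across the
drift families: the centred unit shape has max |s| = 1, so a curve spans
about twice the amplitude.

Two generator choices deserve their rationale spelled out. First,
*individual biological variation*: with only group-level effects, two
same-group specimens would be biologically identical and replicate
re-injections statistically exchangeable with unrelated same-group samples
— replicate-based QC would be testing nothing. Real cohorts are made of
distinct organisms; the individual component (shared by all peptides of a
protein and by all injections of a specimen) is what makes replicates
special, and it is stored in the ground truth's `bioeffect` term. Second,
*feature-level batch dropout* (`missingFeatureBatchRate`): cell-level
logistic missingness (base rate, batch odds multiplier, abundance slope)
exposes every feature, so no complete-feature subset survives for
comparison analyses; the empirically dominant pattern — a peptide entirely
absent from one batch — is modelled as its own component and is exactly the
failure mode of complete-matrix methods.

All randomness flows from one mandatory master seed through fixed named
substreams, so enabling one component never perturbs the draws of another;
identical specs give bit-identical outputs. The ground truth stores every
additive component, and their sum reproduces the pre-missingness matrix to
machine precision.

What the generator does **not** emulate: correlated (non-white) noise,
retention-time structure, interference-driven missingness independent of
abundance, nonlinear saturation at the detector, protein-level roll-up
effects, and multi-site heterogeneity of whole distributions. Tests passing
on simulated data show that the estimators recover the structures they
target under this additive model — not that any real dataset satisfies the
model.

# Validation design and problem sizes

The test suite validates every operation against independent oracles
(explicit weighted normal equations for local regression; a naive O(n³)
agglomeration for average linkage; direct enumeration for quartiles and
Tukey fences; a separately coded interpolation scheme for quantile
normalization; an established independent implementation of the parametric
EB model) and runs simulation recovery checks at the default study
conditions above. Simulation-based checks use 90 × 310 matrices or
smaller, up to 20 seeds per property — sizes chosen to make sampling noise
negligible relative to the tested margins while keeping the default test
run fast. `scripts/acceptance.R` recomputes the headline quantities from
scratch at a user-supplied seed.

# Known limitations

* Drift correction assumes enough observations per feature×batch to
  support a curve; sparse cells fall back to no correction (logged), which
  leaves their drift in place for the discrete step to partially absorb.
* The EB corrector requires per-batch completeness; on very incomplete
  data the practical choice is median centering, at the cost of not
  adjusting scale differences.
* PVCA with few batch levels estimates a variance component from very few
  group means; its numbers are screening diagnostics, not inferential
  statements.
* Correction is supported at the feature (peptide/fragment) level only;
  correcting after protein roll-up conflates peptide-specific drift with
  protein quantification.
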