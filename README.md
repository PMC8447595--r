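# ProteoBatchQC

Diagnosis, correction and quality control of batch effects in large-scale
quantitative proteomics.

Modern DIA/SWATH and TMT studies measure hundreds of samples over weeks of
instrument time. Two kinds of technical bias accumulate: **continuous MS
signal drift** — intensity decays with running order as the LC/MS system
degrades between cleanings — and **discrete batch effects** — feature-specific
shifts between sample-preparation or acquisition batches. Left untreated,
these dominate PCA, clustering and downstream statistics. This package
implements the full five-step adjustment workflow for peptide/fragment-level
log2 intensity matrices:

1. **Initial assessment** — per-sample intensity summaries in running order
   (`sampleOrderSummary`), correlation structure of replicates vs unrelated
   samples (`sampleCorrelationSummary`).
2. **Normalization** — sample-wide scale alignment: `normalizeMedian`,
   `normalizeQuantile` (missing-value aware), `normalizeZscore`. The choice
   is deliberately the user's; there is no single-click default.
3. **Diagnostics** — `pcaScores`, `hierarchicalCluster`, principal variance
   component analysis (`pvca`), per-feature/spike-in trends
   (`featureTrend`), and a confounding report (`confoundingReport`,
   Cramér's V).
4. **Batch-effect correction** — the two-step procedure: per-feature,
   per-batch LOESS drift removal over running order (`correctDrift`, with a
   pinned tricube local-polynomial fit `fitLoess`), then discrete correction
   by median/mean centering (`centerDiscrete`) or parametric empirical-Bayes
   location–scale adjustment (`combatAdjust`); `adjustTwoStep` chains them.
5. **Quality control** — replicate / within-batch / between-batch sample
   correlations, same-protein vs unrelated peptide correlations, replicate
   CVs by abundance, and a paired before/after report (`qcCompare`).

The model for the discrete step is the empirical-Bayes location–scale
model: after per-feature standardisation, feature *g* in batch *b* has
location γ<sub>gb</sub> and scale δ²<sub>gb</sub>; a normal prior on γ and
an inverse-gamma prior on δ² are moment-matched across features per batch,
the conditional posteriors are iterated to convergence, and the shrunk
estimates γ*, δ*² are removed. All parameters are returned in a
`CombatParams` object.

Missing values are first-class: they are *absent records*, never zeros.
`missingnessByBatch` quantifies batch-coupled missingness,
`completenessFilter` (overall or per-batch) establishes the completeness
preconditions, and `imputeValues` is opt-in, loud, and returns an
imputation mask so QC can exclude imputed cells.

A seeded synthetic-data generator (`simulationSpec` / `simulateExperiment`)
produces matrices with exactly the structures the workflow diagnoses —
per-batch drift with feature-specific sensitivity, discrete shifts,
protein-grouped peptides, constant-amount spike-ins, replicate
re-injections, batch/abundance-coupled missingness — plus the full additive
ground truth for recovery testing.

Data live in a `BatchExperiment`, a `SummarizedExperiment` holding the log2
`intensity` assay, the sample annotation (unique integer `run_order`, batch
factors, biological factors, replicate group) and the feature annotation
(`protein_id`, `is_spike_in`). Delimited-text readers/writers
(`readBatchExperiment`, `readLongTable`, `readWideMatrix`, ...) cover the
long and wide TSV conventions, with factor roles declared in a small YAML
file.

## Worked example

The package ships a tiny hand-checkable dataset (6 proteins × 2 peptides,
12 samples in 2 batches, 2 cross-batch replicate pairs):

```r
library(ProteoBatchQC)
be <- workedFixture()
be
#> BatchExperiment: 12 features x 12 samples (0.0% missing)
#>   batch factors: MS_batch
#>   bio factors:   diet
#>   replicates:   column replicate_group

pvca(be, c("MS_batch", "diet"))
#> PvcaResult: 1 PCs retained (cumulative variance >= 0.60)
#>   MS_batch                  0.724
#>   diet                      0.264
#>   residual                  0.012
#>   MS_batch:diet             0.000

norm <- normalizeMedian(be)
res  <- adjustTwoStep(norm, "MS_batch", span = 0.9)
qcCompare(be, res$corrected, "MS_batch", minOverlap = 5, seed = 1)
#> QcComparison
#>   delta of per-category median sample correlation:
#>  within_batch between_batch     replicate
#>       -0.0048        0.0658        0.1561
#>   delta of PVCA proportions:
#>      MS_batch          diet MS_batch:diet      residual
#>       -0.7236        0.7284        0.0000       -0.0047
#>   delta of median replicate CV: -0.22601
```

Reading the report: before correction the leading variance is technical
(PVCA attributes 72% to `MS_batch`); after the two-step adjustment the
batch share drops to zero and the biological factor dominates, the
between-batch and replicate correlations rise (unrelated and replicate
samples become comparable across batches), and the median replicate CV
falls by 0.23 — the negative and positive controls of a successful
adjustment.

A YAML-configured runner (`runWorkflow`) executes any subset of the five
steps on TSV inputs and writes per-step outputs plus a JSON run log; a thin
command-line wrapper with the same subcommands is installed at
`inst/cli/proteobatchqc`.

## Vignette

`vignettes/batch-effect-workflow.Rmd` documents the models, the parameter
choices and their units, what the simulator does and does not emulate, and
the package's numerical conventions.
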