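# DiffPert

Conditional diffusion transformers for predicting how a chemical
perturbation changes a bulk transcriptome.

## What problem this solves

Given a cell's **pre-perturbation (control) expression profile**, a drug's
**SMILES** string and a **dose** in micromoles, DiffPert predicts the
**post-perturbation expression profile** over a fixed gene panel. It is
aimed at computational biologists working with drug-perturbation
compendia (L1000-style paired control/treated profiles over landmark
genes) who want a generative, multi-conditional model of perturbation
response together with a rigorous evaluation and benchmarking harness.

The backbone is a denoising diffusion probabilistic model (DDPM). The
forward chain corrupts the perturbed profile x₀ with Gaussian noise,

    x_t = √ᾱ_t · x₀ + √(1 − ᾱ_t) · ε,   ε ~ N(0, I),

and a transformer noise predictor ε_θ(x_t, t | c_pre, c_pert) — conditioned
on the control profile c_pre and a text-derived perturbation embedding
c_pert — is trained by minimising ‖ε − ε_θ‖². Prediction runs the learned
reverse chain from pure noise. Four transformer-layer variants fuse the
conditions differently: **CrossDiT** (cross-attention onto control and
perturbation tokens), **CatCrossDiT** (per-gene concatenation +
self-attention + perturbation cross-attention), **CatonlyCrossDiT**
(concatenation only) and **AdaDiT** (adaptive layer normalization driven
by a pooled perturbation vector).

Perturbations are represented as text: a molecule description plus the
dose prompt *"The dosage is ... micromoles"*, embedded token-wise
(a deterministic stub embedder is built in; adapters accept external
encoders or precomputed caches). A log₁₀-dose-weighted circular
fingerprint path is included as the baseline representation.

Evaluation follows a 10-measure grid: R² and the Pearson correlation of
log fold changes, PCC(lnFC), each at five grouping granularities
(drug, drug_dose, cov_drug, cov_drug_dose, per_sample), plus
DEG-restricted per-gene PCC(lnFC). Split utilities provide 5-fold
random/cell/drug cross-validation and a five-way out-of-distribution
benchmark (train / val / Drug_unseen / Cell_unseen / Both_unseen).

## Worked example

```r
library(DiffPert)

# Synthetic study conditions with known ground truth:
# 50 genes, 12 drugs x 6 cell lines x 3 doses x 4 replicates (864 records)
gd <- generateDataset(syntheticSpec())
pe <- gd$pe

# Train the CatCrossDiT denoiser (T = 50 desk-scale schedule)
sched <- makeSchedule(50L, beta_start = 1e-3, beta_end = 0.25)
cfg <- denoiserConfig("catcrossdit", n_gene = 50L, d_model = 64L,
                      n_layers = 2L, n_heads = 4L, d_ff = 256L)
ck <- runTrain(pe, cfg, sched, epochs = 150L, lr = 2e-3, restarts = 3L,
               seeds = list(model = 1L, train = 2L, embed = 3L))

# Sample predictions and evaluate the ten-measure grid on every 3rd record
idx <- seq(1, ncol(pe), by = 3)
pred <- runPredict(ck, pe, records = idx, sampling_seed = 11)
evaluateAll(pe[, idx], pred)
```

On one CPU this trains in about 7 minutes and prints:

```
MetricReport (2 metrics x 5 grouping strategies):
           drug drug_dose cov_drug cov_drug_dose per_sample
R2       0.9992    0.9972   0.9899        0.9781     0.9795
PCC_lnFC 0.9966    0.9888   0.9440        0.9052     0.8674
```

Reading these numbers: per-sample R² of 0.98 means sampled profiles
almost perfectly reconstruct held signal at the individual-record level
(a mean-profile baseline reaches 0.69 here), and per-sample PCC(lnFC) of
0.87 means the *direction and shape of the drug effect* is recovered —
close to the ceiling for this dataset: the Bayes-optimal oracle
predictor attains 0.96 by the analytic attenuation
s/√(s² + 2σ²) (`analyticOraclePcc()`), and a single stochastic sample
from even a perfect model sits a few points below that. Coarser
groupings average replicate noise away, so their values are higher.

## Command-line interface

A thin wrapper over the package functions lives at
`inst/cli/diffpert.R` with subcommands `synth`, `prepare`, `split`,
`embed`, `train`, `predict`, `evaluate`, a `--config` YAML and a
`--seed` flag. Datasets travel as a CSV trio (expression matrix,
metadata, control pairing); see `?readPerturbationCSV`.

## Package layout

- `R/data-core.R` — `PerturbationExperiment` (a `SummarizedExperiment`
  with paired `control`/`perturbed` assays), log-normalization, control
  pairing, compound filtering, DEG computation, CSV container I/O.
- `R/pert-repr.R` — SMILES canonicalization, molecule description, dose
  prompt, token/pooled text embeddings, dose-weighted fingerprints,
  embedding cache.
- `R/diffusion-core.R` — noise schedules, forward/reverse diffusion,
  training loss, ancestral sampling.
- `R/denoiser.R`, `R/backprop.R`, `src/denoiser.cpp` — the four
  transformer variants, forward and reverse-mode gradients (R reference
  + compiled fast path).
- `R/train.R`, `R/pipeline.R` — AdamW training with warm restarts and
  EMA, prediction, checkpoints, orchestration.
- `R/metrics.R` — the ten-measure grid and DEG-level correlations.
- `R/splitting.R` — benchmark and cross-validation splits.
- `R/synthetic.R` — ground-truth generator and oracle references.

The methods vignette (`vignettes/diffpert-methods.Rmd`) documents the
model, the design decisions and the limitations of the synthetic
conditions.
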