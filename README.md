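# piradsnet

Classification of clinically significant prostate cancer (csPCa, Gleason
score ≥ 7) from multiparametric MRI lesion patches, comparing a plain
decision-level-fusion 3D CNN (**M1**) with a PI-RADS knowledge-encoded
architecture (**M2**) whose output routing and training loss follow the
zone-dependent dominant-sequence rules of prostate mpMRI reading.

## Who this is for

Researchers studying *domain-knowledge encoding* in network architectures
for medical imaging: the package provides the full pipeline — findings
tables, volume input, VOI extraction, intensity normalisation, offline and
online augmentation, the two model architectures, the composite training
objective, repeated cross-validation with AUC learning curves, ensembling,
and per-epoch Wilcoxon model comparison — plus a synthetic mpMRI phantom
generator, so everything runs end to end with no external imaging data.

## The models

Both models share a common feature extractor: one VGG-style 3D CNN per
series (T2W transverse/sagittal/coronal with an extra convolution block,
DWI, ADC, K-Trans), each emitting a `2c`-element vector by global average
pooling; per modality group these are concatenated with a 5-element zone
one-hot and reduced by dense layers to a 32-element feature vector.

* **M1** concatenates the three 32-element vectors into one dense softmax
  layer.
* **M2** appends an auxiliary 2-class head per modality group and forms its
  final logits by the PI-RADS routing rule

  `NET = (DA + DCE)/2` for PZ lesions, `NET = (T2 + DA)/2` for TZ/AFS/SV,

  training with the composite objective

  `l = Σ l_i w_i / Σ w_i + 0.1 · l_L2 / n_L2`

  whose zone-dependent minor-loss weights (NET 100; DCE 20/5; T2 5/20;
  DWI_ADC 12.5) concentrate auxiliary supervision on each zone's dominant
  sequence.

## Worked example

```r
library(piradsnet)

# a small synthetic cohort with zone-aligned contrast structure
comp <- data.frame(zone = c("PZ", "PZ", "TZ", "TZ"),
                   significant = c(FALSE, TRUE, FALSE, TRUE),
                   count = c(100L, 50L, 100L, 50L))
cohort  <- generate_cohort(phantom_config("tiny", composition = comp), seed = 1)
samples <- cohort_samples(cohort)          # normalise + extract 3 cm VOIs
cohort
#> <phantom cohort  300 findings (100 significant) in 184 patients, tiny profile>

plan <- make_cv_plan(cohort, k = 5, repeats = 2, seed = 1)
plan
#> <cv_plan  5-fold x 2 repeats = 10 splits>

s   <- plan$splits[[1]]
fit <- train_model("M2", samples, s$train, s$validation,
                   config = train_config(epochs = 20L, batch_size = 16L,
                                         learning_rate = 0.05, momentum = 0.5,
                                         weight_constraint = 0,
                                         backbone_lr_scale = 0.001),
                   augment = NULL, c = 4L, seed = 1L)
fit
#> <mpcnn_fit M2  237 train / 63 validation  20 epochs  best val AUC 0.834 (epoch 20)>

auc_score(vapply(samples[s$validation], `[[`, integer(1), "label"),
          predict(fit, samples[s$validation]))
#> [1] 0.8337766
```

The printed numbers say: the knowledge-encoded model, trained for twenty
epochs on 237 phantom findings, ranks held-out significant above
insignificant lesions with probability 0.83 — driven by the ADC signal in
the peripheral zone and the T2W signal in the transition zone, which is
the structure its routing hardwires.

The architecture itself can be inspected symbolically:

```r
infer_shapes(subnet_spec(c = 16, extra_block = TRUE), c(60, 60, 10))
#> ...
#> 10    Pool 2     8      8     6       32     # depth: floor(10/2) + 1
#> 11        FC    NA     NA    NA       32     # the 2c feature vector
```

## Layout

- `R/` — implementation: cohort I/O and geometry, normalisation,
  augmentation, network builders and hand-derived backpropagation
  (compiled convolution kernels under `src/`), composite objective,
  training protocol and statistics, phantom generator.
- `tests/testthat/` — unit, property and end-to-end suites, including
  finite-difference gradient checks and exact-enumeration statistical
  oracles.
- `vignettes/knowledge-encoded-mpmri-cnn.Rmd` — the methods vignette: the
  science, the design decisions and the phantom's assumptions.
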