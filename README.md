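# dbnn — dual-branch convolutional networks for longitudinal ultrasound response prediction

`dbnn` is an R package for the early prediction of pathologic complete
response (pCR) to neoadjuvant chemotherapy (NAC) in breast cancer from
**paired** B-mode ultrasound images: one image taken before treatment
(NAC_pre) and one after the first chemotherapy cycle (NAC_1). The
diagnostic signal lives in how the lesion changes between the two
timepoints, so the model is a *dual-branch* convolutional network whose
branches exchange features while staying independently parameterized.

It is aimed at methods researchers in medical image analysis who want a
fully inspectable, dependency-light reference implementation of the
two-timepoint architecture family, complete with a synthetic cohort
generator so every stage runs without any clinical data.

## The model

Each branch applies nine 3×3 convolutions in four blocks
(64/128/256/512 channels), each followed by batch normalization and ReLU,
with 2×2 max-pooling after layers {2, 4, 7, 9} (128 → 64 → 32 → 16 → 8).
At the **feature-sharing layers** j ∈ {2, 4, 6, 9} the input of each
branch's convolution is the combination of both branches' previous maps,

    C_j  = σ(ω_j  ∗ (C_{j−1} + C'_{j−1}) + b_j)        (element-wise sum, FSS)
    C'_j = σ(ω'_j ∗ (C'_{j−1} + C_{j−1}) + b'_j)

(channel concatenation, FSC, is the alternative). Each branch flattens to
a 1024-unit fully connected feature vector (dropout 0.5), and the two
vectors are fused by a **weighted convex combination**

    F(Z) = α·F(X) + β·F(Y),   (α, β) = (0.2, 0.8),

followed by a linear softmax head over (pCR, non-pCR). Training is
cross-entropy with Adam (lr 0.001), batch size 8, a fixed epoch budget,
and full seed control. The CNN engine (convolution as nine shifted GEMMs,
fused batch-norm/ReLU, max-pooling, analytic backprop, Adam) is written
from scratch in Rcpp + BLAS and is verified in the test suite against a
brute-force direct-summation oracle (forward, 1e-5) and central finite
differences (gradients, 1e-3).

The package also implements the surrounding pipeline: a seeded speckle
phantom generator for paired two-stage cohorts, frame
extraction/QC/pairing, ROI crop + median denoise + 128×128
standardization, the three imbalance augmentations (geometric, Mixup,
minority upsampling), the evaluation panel (confusion metrics,
F1 = 2TP/(2TP+FP+FN), ROC/AUC, DeLong CIs and paired tests,
Mann-Whitney U), and ablation sweep runners over depth, sharing mode,
fusion weights, augmentation strategy and single- vs dual-stage inputs.

## Worked example

Generate a desk-scale synthetic cohort (100 patients, 34.2% pCR
prevalence, 64×64 frames, class signal concentrated in the between-stage
lesion change), train the dual-branch model for 30 epochs, and compare it
with the two single-stage baselines:

```r
library(dbnn)
prof <- deskProfile(seed = 1)            # synth + model + hyperparam configs
man  <- synthesizeDataset(prof$synth, "cohort1")   # renders PGMs + manifest
out  <- runSingleVsDual(man, prof$hp, prof$model)
out$results[, c("model", "accuracy", "sensitivity", "auc")]
```

A run of the equivalent comparison over five seeds prints:

```
seed 1: pre 0.220 post 0.984 dual 1.000
seed 2: pre 0.514 post 0.986 dual 1.000
seed 3: pre 0.549 post 0.981 dual 1.000
seed 4: pre 0.368 post 0.973 dual 1.000
seed 5: pre 0.429 post 1.000 dual 1.000
medians: pre 0.429 post 0.984 dual 1.000
```

Read: a model shown only the pre-treatment image hovers near chance
(median AUC 0.43) because the generator draws stage-1 lesions identically
for both classes; a model shown only the post-cycle-1 image is good but
imperfect (0.984) because absolute lesion size overlaps between classes;
the dual-branch model separates the test set perfectly (1.0) because the
stage-1 → stage-2 *shrinkage ratio* is what defines the classes. That is
the longitudinal premise of the architecture, recovered end to end.

The printed-panel arithmetic also checks out against the published test
composition (75 pCR / 117 non-pCR pairs): accuracy 87.50% and sensitivity
90.67% reconstruct uniquely to (tp 68, fp 17, fn 7, tn 100), giving

```r
classificationMetrics(reconstructConfusion(87.50, 90.67, 75, 117)$counts)
#  f1 0.850, ppv 0.800, npv 0.9346  (the published 0.850 / 80.00% / 93.46%)
```

## Command line

A thin CLI ships in `inst/scripts/dbnn`:

```sh
dbnn synth   --config cfg.json --out data/ --seed 7
dbnn train   --config cfg.json --manifest data/manifest.csv --out run/
dbnn eval    --checkpoint run/checkpoint.rds --manifest data/manifest.csv --out eval/
dbnn ablate  --sweep fusion --config cfg.json --manifest data/manifest.csv --out abl/
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from
scratch: it reconstructs the printed confusion panel, builds and traverses
the reference architecture, then synthesizes the desk-profile cohort,
trains the dual-branch model and reports the held-out metric panel, all
derived from `--seed`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/synthetic.R` — seeded speckle phantom cohorts (`SyntheticConfig`,
  `generateCohort`, `generatePairedDataset`, `splitPatients`)
* `R/preprocess.R` — frame extraction, QC selection, sequential pairing,
  ROI crop, median denoise, standardization
* `R/model.R`, `src/dbnn_ops.cpp` — the dual-branch network
  (`ModelConfig`, `buildModel`, `forwardPass`, `branchFeatures`,
  `architectureSummary`)
* `R/augment.R` — geometric / Mixup / minority-upsampling strategies
* `R/train.R` — `trainModel`, `evaluateLoss`
* `R/evaluate.R` — `predictPairs`, `confusionCounts`,
  `classificationMetrics`, `rocCurve`, `delongCi`, `delongTest`,
  `mannWhitneyU`, `reconstructConfusion`
* `R/experiments.R` — `runDepthSweep`, `runFusionGrid`,
  `runAugmentationSweep`, `runSingleVsDual`, `deskProfile`

See the vignette (`vignettes/dual-branch-response-prediction.Rmd`) for the
model assumptions, the synthetic world's design and its limits, and every
numerical choice made where the architecture description is silent.
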