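---
title: "Volumetric convolutional autoencoders: models, phantoms, and explanation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric convolutional autoencoders: models, phantoms, and explanation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`voxcae` implements a complete, small-scale pipeline for classifying 3D
structural brain volumes with volumetric convolutional neural networks and
for explaining what such a classifier looks at. The pipeline has five
stages: unsupervised convolutional-autoencoder pretraining, supervised
fine-tuning, source-to-target transfer learning for a subtler second task,
gradient class-saliency mapping, and supervoxel occlusion analysis — all
evaluated under nested cross-validation. Because clinical cohorts such as
ADNI are access-restricted, the package ships a phantom generator that
plants ground-truth disease effects into synthetic brain-like volumes, so
every stage can be validated against a known answer.

## The classification problem

The motivating application is the binary classification of
template-registered, intensity-normalized T1 brain MRI: Alzheimer's
disease (AD) versus normal controls (NC), and the harder problem of
progressive versus stable mild cognitive impairment (pMCI vs sMCI), where
pMCI subjects convert to AD within a follow-up window. Volumes are assumed
spatially normalized to a common grid (the reference resolution is
120 x 160 x 120 voxels) and min-max normalized to [0, 1]; the package
consumes them post-registration via `read_volume()` and performs
normalization (`normalize_intensity()`) and trilinear resampling
(`resample()`) itself.

## Network architectures

Two architectures are provided, both operating on a single-channel 3D
tensor and ending in a 2-unit softmax:

* **CAE classifier** — three 3x3x3 convolution blocks with 10 feature maps
  each (convolution with scale-preserving padding, Gaussian dropout, ReLU,
  2x2x2 max-pool), then fully connected layers of 32 and 16 SELU units and
  the output layer. At 120 x 160 x 120 this is 1,446,294 trainable
  parameters, dominated by the first dense layer.
* **ICAE classifier** — two convolution blocks, a 3D inception module, a
  final pooling stage, and the output layer directly on the flattened maps
  (no hidden dense layers): 371,562 parameters.

The inception module runs four parallel branches over the same input — a
1x1x1 convolution; 1x1x1 then 3x3x3; 1x1x1 then two 3x3x3 (a factorized
5x5x5); and a 3x3x3 stride-1 max-pool followed by a 1x1x1 convolution —
each emitting 10 maps that are concatenated to 40 channels. With only 10
input channels there is no room for a narrower bottleneck, so the 1x1x1
stages keep the input width; this allocation reproduces the ~371 K
parameter count cited for the reference design. `count_parameters()`
reports the exact integer count for any network.

The autoencoder variants mirror their encoders with upsampling decoders
(convolution, dropout, ReLU, 2x nearest-neighbour upsampling per stage)
and a sigmoid reconstruction head, so reconstructions live in (0, 1).
Encoder and decoder weights are untied. `pretrain_autoencoder()` minimizes
the voxelwise reconstruction cross-entropy

$$E = -\frac{1}{N}\sum_i \left[x_i \log x_i' + (1 - x_i)\log(1 - x_i')\right]$$

(mean over voxels and scans, with $0\log 0 := 0$), and
`build_classifier(init = )` copies the trained encoder into a classifier
whose dense layers are freshly initialized.

Numerical conventions worth recording: Gaussian dropout with drop-rate
$p$ multiplies activations by $N(1, p/(1-p))$ noise during training only
(inference is deterministic); the drop-rate reading of the reference
design's "ratio 0.8" is assumed, and the rate is configurable. Dropout is
applied to the pre-activation maps inside each convolution block; the
between-block placement was also implemented and compared during
development, and trained visibly less stably on small cohorts, so the
in-block order is the package default. Hidden dense layers use SELU; fresh
weights are variance-scaling (fan-in) normal draws under a caller-supplied
seed. Max-pooling breaks ties toward the first voxel in scan order, making
every forward and backward pass bit-reproducible.

## Training, regularization and transfer

`train_config()` defaults follow the reference setup: Adam with learning
rate 1e-4, first- and second-moment decays both 0.9 (the unusual second
moment is kept as printed but is configurable), decoupled weight decay
1e-5, mini-batches of 10, up to 200 epochs. The grid-searched elastic-net
penalty `l1_weight * sum(|w|) + l2_weight * sum(w^2)` (biases excluded) is
kept separate from the fixed weight decay, mirroring how the two appear in
the reference description. The optimized objective is exactly
classification (or reconstruction) loss plus `regularization_penalty()`,
which the tests verify by evaluating the two parts separately.

Transfer learning for the subtle task re-uses the convolutional stack:
`transfer_weights()` copies every convolution/inception layer of the
source model bitwise into a fresh target network, re-initializes the
dense head, and leaves all layers trainable for joint fine-tuning —
no freezing.

On-the-fly augmentation (`augment()`) draws, per epoch and scan, a
rotation per axis in [-5, 5] degrees, a translation of up to 10% of each
axis extent, an isotropic rescale in [0.8, 1.2] and brightness/contrast
jitter, composed into one trilinear resampling pass with zero fill and
clipping to [0, 1]. Saturation/hue jitter has no analogue for
single-channel MRI, so intensity jitter is restricted to brightness
(additive) and contrast (multiplicative about the mean).

### Desk-scale protocol

The test suite and the acceptance script train on 24 x 32 x 24 phantoms
(same 3:4:3 aspect as the reference grid, three integral pooling stages)
with cohorts of 20-30 scans per class. A reference-scale run takes ~6,800
optimizer steps (batch 10, ~340 scans, 200 epochs); a 40-scan desk cohort
yields only 4 steps per epoch, so the desk protocol compensates with a
proportionally larger step size and the strongest grid point of the
regularizers: learning rate 1e-3, L1 = L2 = 1e-3, Gaussian dropout 0.3,
100 epochs for classifiers and 30 for pretraining. (The transfer
comparison runs both arms without dropout for 30 epochs — at four
optimizer steps per epoch even mild multiplicative noise dominates the
subtle MCI signal.) These desk-scale choices appear in the worked
examples and the acceptance script only; `train_config()` itself keeps
the reference values. Problem sizes used by the acceptance script:
cohorts of 20/20 (AD-like task) and 30/30 (MCI-like task), 10-scan
validation groups for saliency, and 2-5 independent seeds per
experiment.

## The phantom generator

`phantom_config()` describes a head ellipsoid filled with smooth tissue
texture (Gaussian-blurred white noise, standardized, amplitude 0.18
around a baseline of 0.55), voxelwise Gaussian noise (SD 0.1), and two
planted ellipsoidal effect regions. AD-like scans subtract
`delta_ad * noise_sd` (default 4 SD) inside the AD lesion; pMCI-like
scans subtract the subtler `delta_mci * noise_sd` (default 1.5 SD) inside
a region whose centre is shifted so it overlaps but does not coincide
with the AD lesion — transfer from the AD task is therefore helpful but
not trivially sufficient, and the saliency focus is expected to move
between tasks. Negative intensities are truncated at zero before min-max
normalization; besides being physically sensible for magnitude images,
this anchors the normalization at the background for every class. (An
earlier draft of the generator skipped the truncation, and the global
minimum of diseased scans was then set by the lesion floor — the class
signal leaked into the global intensity scale and nothing forced a
classifier to look at the lesion. The truncation removes that confound;
the residual max-side anchor is driven by the texture tail, which is
class-independent.)

Because the texture is spatially smooth, the lesion-mean statistic varies
between subjects far more than the voxel noise alone would suggest; the
4 SD AD effect is still separated almost perfectly, while the 1.5 SD MCI
effect leaves substantial class overlap — qualitatively matching the
accuracy ordering of the clinical tasks. What the phantoms deliberately
do not model: deformation-based atrophy, bias fields, partial-volume
effects, multi-site variation. Passing tests on phantoms therefore
demonstrate that the pipeline recovers a planted, localized intensity
effect — not that it would reach any particular accuracy on clinical
data.

`oracle_classify()` provides the closed-form reference: threshold the
mean intensity inside the planted mask, calibrated at the midpoint of the
two class means (`calibrate_oracle()`). It bounds what any classifier can
learn from the planted effect and anchors the occlusion tests. Under the
default configuration the oracle separates the AD-like task almost
perfectly and reaches roughly 80% on the MCI-like task.

The MCI effect region shares about half its volume with the AD region
(centres 2.5 voxels apart), reflecting that early-conversion pathology
sits in the same medial-temporal territory as established disease with a
shifted focus. A cautionary finding from development is worth recording:
on these phantoms, transferring the AD-task convolutional stack to the
MCI-like task yields only a small mean test-accuracy gain over scratch
training (~2 points across seeds and epoch budgets). The phantom's
convolutional features — local darkening detectors over a smooth texture
— are learnable from scratch within a few hundred optimizer steps, so
feature reuse contributes little, and the freshly initialized output head
faces the same small-sample estimation problem in both arms. Transfer
learning's large reported benefits arise when feature learning itself is
the bottleneck (high-resolution, heterogeneous real data); that regime is
exactly what a desk-scale phantom does not emulate, so phantom results
bound the machinery's correctness, not the size of the clinical effect.

## Saliency and occlusion

`instance_saliency()` implements the first-order attribution
$M = |\partial f_c / \partial X|$ by backpropagating from the
*pre-softmax* score of the target class (softmax gradients saturate once
the model is confident; the logit is differentiated instead — for an
affine scorer the map is then exactly $|\omega|$, which the tests assert
to machine precision). `group_saliency()` smooths each instance map (box
mean filter, default side 9, the reference choice at 120 x 160 x 120;
Gaussian smoothing is available), sums over the scans of the target class
and min-max normalizes, so duplicated scans leave the map unchanged.
`threshold_roi()` cuts the map at a fraction of its maximum (default
80%).

At desk scale the smoothing side is better matched to the grid (9 voxels
is over a third of a 24-voxel axis); the worked examples use sides 3-7.
Development diagnostics showed that localization sharpness depends
strongly on initialization: autoencoder-pretrained models concentrate the
saliency map on the planted lesion, while scratch-trained models of equal
training accuracy spread it widely — the same qualitative story told for
the reference models. Two structural caveats apply at 24 x 32 x 24: the
one-voxel halo around a ~230-voxel lesion contains roughly 180 voxels,
and max-pooling routes gradients to the brightest voxel of each 2x2x2
cell, which for cells straddling the lesion boundary lies just *outside*
the mask. The top-percentile of a group map therefore includes a border
ring even for a well-localized model (in development runs ~94% of top
voxels lay within one voxel of the mask), and the in-mask fraction of the
top-1% set varies considerably between training seeds. The lesion is kept
at a realistic relative size rather than enlarged to absorb the halo.

`supervoxel_segment()` is a 3D SLIC-style clustering on (intensity,
position): centres initialized on a grid, iterative local k-means with
distance $d_I^2/m^2 + d_s^2/S^2$ (compactness $m$, default 0.1 for
intensities in [0, 1]; spacing $S$), followed by a connectivity pass that
absorbs fragments smaller than a quarter of the expected segment volume
into an adjacent segment. `occlusion_simulation()` zeroes one supervoxel
at a time — the stated shrinkage simulation uses the value 0, with no
mean-imputation variant — and counts prediction flips from a source to a
target class, accumulated over scans.

## Evaluation protocol

`confusion_metrics()` computes ACC, SEN, SPE and BAC = (SEN + SPE)/2;
ratios with zero denominators are reported as `NA`, never silently as 0.
Specificity uses TN/(TN + FP); the NPV-style denominator TN + FN that
sometimes appears in print is available as an option for comparability.
`roc_auc()` computes the Mann-Whitney AUC from average ranks (ties count
one half) plus monotone curve points; the tests check it against a
brute-force pairwise oracle and an established reference implementation.

`nested_cv()` implements the nested k-fold protocol: per repeat, a fresh
stratified outer split; per outer fold, a grid search by stratified inner
cross-validation confined to the outer-training portion (selection by
mean inner accuracy, ties broken toward the stronger regularization);
retraining on the full outer-training portion; one evaluation on the
held-out fold. Both fold counts default to 5; repeats are independent and
re-randomize folds and model initialization. Fold membership is recorded
per repeat so `cv_audit()` can mechanically verify the partition and the
absence of subjects shared between a test fold and the search data that
selected its model. AUC is aggregated as the mean of per-fold AUCs.
Splits are by subject; with one scan per subject here the two notions
coincide, but the membership log keys on subject ids so multi-scan data
would stratify correctly.

## Known limitations

* The optimizer follows the printed second-moment decay of 0.9 rather
  than the conventional 0.999; both are available.
* Whether the printed "weight decay 1e-5" and the grid-searched L2 factor
  are one mechanism in the reference description is ambiguous; they are
  implemented as two (decoupled decay plus explicit penalty).
* Training is single-threaded and CPU-bound; the full 120 x 160 x 120
  scale is supported for construction, counting and inference, but
  training at that scale is far outside the desk budget.
* The phantom's disease effect is an intensity decrement, not a
  deformation; geometric atrophy modelling is out of scope.
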