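---
title: "Methods: thick-slice WMH segmentation with a lightweight 2D encoder-decoder"
author: "wmhseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thick-slice WMH segmentation with a lightweight 2D encoder-decoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

White matter hyperintensities (WMH) are bright lesions on FLAIR and
T2-weighted MRI, strongly associated with cerebral small vessel disease,
cognitive decline and stroke risk. In routine clinics the relevant scans are
*thick-slice* 2D axial series — around 5 mm slice thickness, 16–20 slices,
sub-millimetre in-plane — across heterogeneous scanners. `wmhseg` implements
a complete quantification pipeline for this regime: multi-modal (T1w, T2w,
FLAIR) segmentation of WMH and coexisting non-WMH lesions with a lightweight
fully convolutional network, the label-fusion protocol that turns two
imperfect human delineations into a weighted training target, a lesion-aware
evaluation suite, ventricle-distance subclassification of the segmented WMH,
and the statistics linking WMH volumes to ordinal visual ratings.

Bias-field correction, inter-modality registration and skull stripping are
deliberately outside the package: they belong to established external tools,
and every entry point asserts that its inputs are already co-registered and
skull-free (identical array geometry), failing loudly otherwise.

## Preprocessing

Intensities are normalized per modality by the quantile rule: with
$P_{0.001}$ and $P_{0.999}$ the intensities at the 0.1% and 99.9%
nearest-rank quantiles of the sorted voxel values,

$$I' = \begin{cases}0 & I < P_{0.001}\\ 1 & I > P_{0.999}\\
\frac{I - P_{0.001}}{P_{0.999}-P_{0.001}} & \text{otherwise.}\end{cases}$$

Quantiles are estimated **within the brain mask** when one is supplied.
This is a design choice the protocol leaves open: after skull stripping the
background is exactly zero, and pooling it would pin $P_{0.001}$ at 0 for
every subject, so the mask-restricted estimate is the one that actually
standardizes tissue intensities. In-plane resampling to a common pixel
spacing (0.5 mm in the reference protocol) uses bilinear interpolation for
images and nearest-neighbour for labels and masks; the slice axis is never
resampled, because at 5 mm thickness through-plane interpolation manufactures
data.

## Two raters, one target: definite and suspected WMH

Two independent delineations of the same study overlap imperfectly, mostly
at lesion boundaries. The package fuses a rater pair into

* the **union** as ground truth (either rater marking a voxel suffices),
* **definite** WMH — voxels marked by both raters,
* **suspected** WMH — voxels marked by exactly one.

The training loss then trusts the definite region more. Each definite voxel
receives weight 2. A suspected voxel at distance $d$ (mm) from the centre of
the nearest definite component receives $1 + f(d)$ with

$$f(d) = 1 - d / d_{\max},$$

$d_{\max}$ being the largest such distance among the volume's suspected
voxels, so $f$ spans $[0,1]$ exactly: suspected voxels hugging definite
lesions are nearly as trusted as the definite core, remote ones count as
ordinary voxels. Three readings were open here and are fixed as follows:
"centre" is the voxel centroid of a definite 26-connected component (the
only parameter-free centre); the nearest component is chosen by
voxel-to-centroid distance (deterministic); and $d_{\max}$ is taken per
volume, which is what makes $f$ span its full range. With no definite voxels
all suspected weights fall back to 1; a lone suspected voxel sits at
$d = d_{\max}$ and also gets 1. Non-WMH lesions (class 2) always carry
weight 1 — the weighting scheme is defined for WMH only. All distances are
physical (mm), because with 5 mm slices voxel-index distances are
meaningless.

A five-rater consensus ("silver standard") is supported by per-voxel
majority voting with ties broken toward the lower class code
(background-conservative) and counted. The labeling workflow's acceptance
rule — two delineations of a study must reach Dice ≥ 0.5 or be redone — is
implemented as a consistency report; the human discussion loop itself is
not.

## The network

The segmenter is a V-Net-style fully convolutional 2D encoder-decoder.
Five levels; level 1 is full resolution. The contraction path stacks
bottleneck-residual blocks (1×1 reduce by the bottleneck ratio, 3×3, 1×1
expand, residual addition) and halves resolution between levels with 2×2
stride-2 convolutions; the expansion path mirrors it with 2×2 transposed
convolutions, concatenates the same-level encoder features (skip
connection), fuses them with a 3×3 convolution, and continues with further
bottleneck blocks. The output head appends two convolutions (3×3, then 1×1
onto the class channels) and a channel softmax, so each voxel gets a
probability simplex over {background, WMH, other lesion}. 2D kernels are
used throughout: with ~5 mm slices and 16–20 slices per series, adjacent
slices are weakly correlated and 3D kernels would mostly model noise.

Batch normalization and PReLU activations follow the V-Net lineage; the
reference protocol does not specify them, so they are configuration
choices, recorded in the config object. Down-sampling by strided
convolution and up-sampling by transposed convolution likewise follow that
lineage.

The default configuration — channels 16/32/64/128/256, bottleneck ratio 4,
encoder blocks (1,2,3,3,3), decoder blocks (1,1,2,2) — totals **1,079,235
trainable parameters (~1.08 M)**. The per-level block table of the original
design is not publicly available; these widths were chosen to land on the
published parameter budget and are recorded in `vbnet_config()` rather than
hard-coded. `count_parameters()` computes the budget analytically from a
configuration and must agree exactly with the instantiated network — this
is asserted in the test suite.

The whole network, including backward passes, is implemented in the package
(im2col convolution primitives in C++, layer graph in R). Gradients of
every layer type are validated against central finite differences in the
test suite, which is the strongest correctness statement available for
hand-derived backprop.

One structural subtlety: stride-2 down/up-sampling makes any such network
equivariant to translations only in multiples of $2^{\text{levels}-1}$. On
a constant input the interior output field is therefore *periodic* with
that stride, not constant; the test suite asserts the periodicity, which is
the correct sanity check on the convolutional structure.

## Training

The loss is the multi-class soft Dice loss

$$\mathcal{L} = 1 - \frac{1}{C}\sum_c
\frac{2\sum_i w_i\, p_i^c g_i^c}{\sum_i w_i (p_i^c)^2 + \sum_i w_i (g_i^c)^2 + \varepsilon},$$

with the per-voxel weight map $w$ of the previous section applied inside
every accumulator. This is the reading of the weighted loss that actually
uses the per-voxel map and collapses *exactly* to the unweighted Dice loss
at $w \equiv 1$ (asserted to 1e-6 on random fixtures). The smoothing
$\varepsilon = 10^{-6}$ sits in the denominator only. A softmax head feeds
the loss — the classes are mutually exclusive, which the protocol leaves
implicit.

Optimization: Kaiming-normal initialization, Adam with moment coefficients
(0.9, 0.999) and learning rate 0.001. The reference protocol trains on
randomly sampled 256×256 patches with mini-batches of 48 on GPUs; the
package ships that protocol as the default `train_config()` values scale to
a CPU: 64×64 patches, batch 8, 400 steps, constant learning rate with
periodic validation and best-validation checkpointing (epoch counts and
schedules are unstated in the protocol; a fixed step budget is the recorded
choice). Axial slices containing lesions are oversampled 5:1 during patch
sampling — WMH occupy well under 1% of voxels and uniform sampling would
starve the lesion classes; the factor is a configuration decision. Training
is deterministic given the seed.

Inference is patch-free: the network is fully convolutional, so each slice
is processed at full resolution (padded symmetrically to the next multiple
of $2^{\text{levels}-1}$), the per-voxel argmax taken with ties broken
toward the lower class code, and everything outside the brain mask forced
to background.

## Evaluation metrics

Voxel level: Dice $2TP/(2TP+FP+FN)$, recall $TP/(TP+FN)$, precision
$TP/(TP+FP)$, plus recall restricted to the definite-WMH region. Lesion
level: lesions are 3D 26-connected components; a truth lesion counts as
detected if at least one predicted voxel overlaps it (the minimal reading —
no overlap fraction is specified anywhere, and this is also the convention
of the public WMH challenge); lesion recall, precision and their harmonic
mean (lesion F1) follow. Volume: AVD $= |A-B|/B \times 100\%$. Surface:
Hausdorff95, the larger of the two directed 95th-percentile (nearest-rank)
nearest-neighbour distances in mm, anisotropy respected.

Degenerate inputs follow explicit conventions rather than sentinels: both
masks empty means perfect agreement (1, or 0 for distances/AVD); a metric
whose denominator set is empty on one side only is NaN and flagged. Cohort
aggregation averages per-subject values (not pooled voxels), dropping NaN
entries.

Every metric is cross-checked against an independent brute-force oracle
(exhaustive distance minimization, BFS flood fill, direct tallies) on
hundreds of random fixtures.

## Subclassification

From a ventricle mask the package builds an exact Euclidean distance map
(separable lower-envelope transform, anisotropic spacing in mm; voxels in
the ventricle are at 0). Segmented WMH voxels are then partitioned:

* **4-class** — juxtaventricular (≤ 3 mm from ventricle), periventricular
  (3–13 mm), then for the remainder juxtacortical (≤ 4 mm from the
  corticomedullary junction) and deep (the rest). Ventricle bands take
  precedence over the juxtacortical band when both criteria hold — the
  criteria are stated ventricle-first and define "deep" residually.
* **2-class** — periventricular (≤ 10 mm of the ventricle) vs deep.

All interval edges are inclusive on the far side ("within N mm" reads
≤ N); this openness is unstated in the source criteria and is recorded here
so results are reproducible. The corticomedullary junction is supplied as a
mask: phantoms generate it explicitly (inner edge of a 3 mm cortical
ribbon); on real data it comes from an external cortical segmentation — the
package does not segment cortex. Per-class volumes (voxel count × voxel
volume) are reported absolutely and as % of intracranial volume, and sum
exactly to the total WMH volume.

## Correlation with visual ratings

WMH burden is clinically rated on the Fazekas scale (periventricular 0–3
plus deep 0–3, total 0–6). The package computes Spearman correlations
between volumes (%ICV) and scores and compares the manual-volume
correlation to the algorithm-volume correlation by
$\Delta r = r_\text{manual} - r_\text{algo}$ with a **paired** bootstrap:
subjects are resampled with replacement as whole (manual, algo, score)
triples, $\Delta r$ recomputed per replicate (default 1000), and the 95%
percentile interval taken; the difference is significant when the interval
excludes 0. The pairing matters — both correlations share subjects, so
resampling them together is what captures the dependence. Percentile (not
BCa) intervals are the minimal reading of the stated procedure; replicates
with a degenerate (constant) resampled vector are dropped and counted; no
multiplicity correction is applied, matching the exploratory framing of the
source analysis.

## The phantom generator

Everything above is testable without clinical data through a seeded phantom
module. A phantom is an ellipsoidal brain (default 128×128×18 voxels at
(1,1,5) mm — the thick-slice regime; training runs use 64×64×18 at
(2,2,5) mm, preserving the ~128 mm head) containing two lateral-ventricle
ellipsoids, a 3 mm cortical ribbon whose inner edge is the corticomedullary
junction, WMH lesions placed in requested ventricle-distance bands, and
non-WMH lesions in cortical/juxtacortical locations. Lesions are irregular
thresholded-noise blobs, not ellipsoids, so connected-component code faces
realistic shapes; each blob is confined to its band, so band membership is
verifiable by brute force. Intensity means per tissue emulate the clinical
contrast pattern: WMH bright on FLAIR (configurable margin over white
matter, default +0.4) and T2, near-iso on T1; non-WMH (perivascular-space
-like) lesions bright on FLAIR/T2 but near-CSF dark on T1 — so the classes
are only separable multi-modally, which is precisely what the network must
learn. Gaussian noise (default σ = 0.05 of the intensity range) and a mild
in-plane smoothing (partial volume) are added.

Simulated raters perturb only the one-voxel in-plane boundary shell of each
lesion: each rater independently drops inner-shell voxels with the
disagreement probability, and each outer-shell voxel is pre-assigned to one
rater who may add it. At disagreement 0 both raters equal the truth; at 1
their intersection is exactly the eroded core. The exclusive-outer-shell
construction is what makes the latter identity hold — fully independent
additions would put shared false positives in the intersection.

What the phantoms do *not* model: MR physics (bias fields, motion,
ghosting), skull, registration error, realistic lesion texture, or any
calibrated lesion size/shape distribution (no public characterization
exists for the non-WMH class). Passing tests on phantoms therefore
demonstrates the correctness of the pipeline's computations and the
learnability of the multi-modal contrast rule — not clinical-grade accuracy
on real MRI.

## Numerical choices and problem sizes

* EDT: exact separable algorithm; parabola envelopes anchored only at
  finite sites (the textbook scan divides ∞−∞ when a scanline is empty).
* Nearest-rank quantiles throughout (sorted data, smallest value at or
  above the target rank) — reproducible across platforms, no interpolation.
* Argmax and majority-vote ties break toward the lower class code.
* Batch-norm uses batch statistics in training and running statistics
  (momentum 0.1) at inference.
* Test and acceptance problem sizes: 100 random ≤ 14³ fixtures for metric
  oracles, 50 phantoms for subclass conservation, 20 training + 2 held-out
  phantoms (64×64×18) for the end-to-end run, 20 bootstrap simulations at
  n = 100 subjects with 1000 replicates. These sizes make the full suite
  run in minutes on a single CPU while keeping every check statistically
  meaningful.

## Known limitations

* The hand-written training loop is CPU-bound; the full 256×256/batch-48
  protocol is expressed in configuration but impractical without a GPU
  framework.
* The default architecture matches the published parameter budget, not the
  (unavailable) original per-layer table; segmentation behaviour at full
  scale may differ from the original network even at identical size.
* Phantom realism bounds what the end-to-end tests can claim (see above).
* The package consumes registration/skull-stripping output; garbage
  geometry in, hard error out.
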