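---
title: "Methods: white-blood-cell segmentation and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: white-blood-cell segmentation and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbcpipe)
```

This vignette is the package's own account of its methods: the models and
their assumptions, the parameters that matter, the numerical choices made
where the design was genuinely open, and what the synthetic-data tests do
and do not establish about real microscopy.

## Nucleus segmentation

### Model

A stained smear contains three dominant color populations: pale background,
pale-red erythrocytes (RBCs), and the purple-stained leukocyte nuclei
(platelets stain similarly to nuclei but are far smaller). Treating each
pixel as an RGB 3-vector, segmentation reduces to finding a direction in
color space that annihilates the non-nucleus populations and maximally
aligns with the stain. Given reference colors $v_1, \dots, v_{k-1}$
(background, RBC) and a nucleus color $v_k$, Gram-Schmidt
orthogonalization of the leading colors gives $u_1, \dots, u_{k-1}$ and the
weight vector

$$w_k = v_k - \sum_{j<k} \operatorname{proj}_{u_j}(v_k),$$

which satisfies $\langle w_k, v_j\rangle = 0$ for $j<k$ while keeping the
largest possible projection on $v_k$. The projection image
$\langle w_k, \cdot\rangle$ is thresholded on its histogram, three such
masks from three nucleus-color candidates are fused by a pixelwise AND, and
small components are removed. The assumptions are: (a) the three color
populations are linearly independent in RGB; (b) nuclei are the most
"purple" population, measured by the score $R + B - 2G$; (c) platelets are
smaller than every nucleus.

### Reference-color estimation

The references are estimated per image by 3-cluster k-means in RGB over a
seeded subsample of `n_sample = 5000` pixels (`nstart = 5`, up to 50
iterations). The cluster whose center maximizes $R + B - 2G$ is the nucleus
cluster; the remaining centers are the background and RBC references,
larger cluster first.

Nuclei typically cover only a few percent of a smear, and k-means with
three centers can absorb them into the RBC cluster (the two populations are
closer to each other than either is to the background). The raw
percentile rule for nucleus-color candidates then picks RBC colors and the
fused mask collapses to empty. The package therefore refines the nucleus
cluster before drawing candidates: the within-cluster purpleness scores are
split by Otsu's criterion, and if the two sub-populations' mean colors are
more than 50 RGB units apart the cluster is deemed contaminated — the
non-purple part's mean color becomes the RBC reference (it is exactly the
population that leaked in) and candidates are drawn from the purple part
only. When the split separates by less than 50 units it is mere stain
variation and the cluster is kept whole. The 50-unit floor sits well below
the nucleus-to-RBC distance of typical stains (>100) and well above
within-nucleus tint variation (~15).

The three candidates are the mean colors of cluster pixels in ±5-percentile
bands around the 10th, 25th and 50th percentiles of the purpleness score:
three plausible stain intensities, so the AND of their masks tolerates
staining and illumination differences between cells.

### Thresholding, fusion, cleanup

Each projection is min-max normalized and thresholded by Otsu's
between-class-variance criterion on a 256-bin histogram (cumulative-moment
form; ties resolved to the lowest cut; a constant projection yields an
all-false mask with a warning). Fusion is a pixelwise AND of the three
masks. Small-object removal runs **after** fusion — fusion only shrinks
regions, so a single final cleanup suffices — clearing every 8-connected
component below `min_area_frac = 0.001` of the image area (≈49 px at
256×192; comfortably between platelet areas (≲20 px) and nucleus areas
(≳300 px)). Connected components use 8-connectivity and BFS flood fill;
coordinates are 0-based, row-major, throughout the package.

Degenerate inputs: a uniform image has no color contrast and raises an
error (or returns an empty mask when `on_no_contrast = "empty"`, the
pipeline's setting); basis sets are rejected as linearly dependent below a
rank tolerance of 1e-8 on unit-scaled columns.

## SIFT features

Keypoints are local extrema of a difference-of-Gaussians (DoG) scale space:
4 octaves of 5 levels, base scale $\sigma_0 = 1.6$, level scales
$\sigma_0 2^{i/s}$ with $s = 3$, each octave seeded by downsampling the
$2\sigma_0$ level of the previous one. Gaussian kernels are truncated at
$5\sigma$, which keeps the semigroup property of successive blurs accurate
to about $10^{-7}$ — tight enough that DoG levels are consistent across the
two blur routes. A point is a keypoint iff strictly larger (or smaller)
than all 26 neighbours of its 3×3×3 scale-space neighbourhood; one
quadratic-fit step refines position and scale (offsets clamped to ±0.5).

Two filters the detector needs but the basic recipe leaves open: a contrast
threshold (|DoG| ≥ 0.03 on [0,1] images) and an edge test (principal
curvature ratio ≤ 10 via the 2×2 Hessian); without them, noise and edges
flood the detector. Both are configurable, and `edge_ratio = Inf` disables
the edge test (used by the tests to compare against a pure extremum
oracle).

Orientation is the dominant bin of a 36-bin gradient-orientation histogram
over a Gaussian-weighted window of radius $3 \times 1.5\sigma$, smoothed
twice with a circular $[1,1,1]/3$ kernel and refined parabolically; a
gradient-free window yields orientation 0 with a warning. The descriptor
samples gradients on a 16×16 grid rotated to that orientation (spacing
proportional to the within-octave scale), accumulates them by trilinear
interpolation into 4×4 spatial cells × 8 orientation bins with a Gaussian
spatial weight ($\sigma$ = half the window, an interpretation the basic
recipe leaves unstated), L2-normalizes, clamps entries at 0.2 and
renormalizes (illumination robustness). Keypoints whose sampling window is
more than half outside the image, or with no gradient signal, are dropped.
Gray conversion uses ITU-R 601 luminance. The whole chain involves no
randomness.

## Convolutional feature extractor

Architecture: one valid 3×3 convolution (no zero padding anywhere, so each
spatial axis shrinks by 2) with `n_filters` kernels and ReLU, two 2×2
stride-2 max-pooling layers, a fully connected hidden layer (ReLU) that
serves as the learned feature vector, and a linear output layer used only
during training (softmax + crossentropy). One convolution with two pooling
layers is deliberately small: the nuclei crops carry coarse shape/texture
information, and the final classification is delegated to the
sparse-representation classifier rather than a softmax.

Numerical choices: convolution is implemented as cross-correlation (the
filters are learned, so the flip is immaterial); pooling ties go to the
first maximal element in scan order (deterministic backprop routing); He
initialization and minibatch order both derive from one seed, so training
is bit-reproducible; plain SGD with `lr = 0.01`, `batch = 16` by default.
Crops default to 48×48 grayscale in [0,1], bilinearly resized from
component bounding boxes (border-touching cells are kept and zero-padded —
convolutional features do not require seeing the whole object).
Analytic gradients are verified against central finite differences to
≤ 1e-5 relative error in the test suite.

## WTPTSSR classification

Training samples are columns of $A \in \mathbb{R}^{m\times N}$; columns and
test samples are L2-normalized (an all-zero column is an error naming the
offending index). Phase 1 solves the locality-weighted ridge system
$X = (A^\top A + t\,W^\top W)^{-1} A^\top y$ with
$W = \mathrm{diag}(\lVert y - a_i\rVert^k)$, scores each column by
$\mathrm{con}_i = \lVert y - a_i x_i \rVert^2$ and keeps the $M$ best
(ties to the lowest index). Phase 2 solves the plain ridge system on the
kept dictionary, and the per-class squared reconstruction residual decides
the class (ties to the lowest class id; classes absent from the selection
get $\lVert y\rVert^2$). With $k = 0$ the locality weights are the
identity and the method is exactly TPTSR — the test suite checks this
reduction against an independently written TPTSR to $10^{-10}$.

Defaults — $t = 0.01$, $\gamma = 0.01$, $k = 2$,
$M = \min(40, \lfloor N/2\rfloor)$ — are conventional ridge weights and a
neighbourhood that keeps a handful of samples per class; all are exposed.
Feature fusion, the one step with no canonical recipe, pools a cell's
variable-size SIFT descriptor set to 256 fixed values (elementwise mean,
then max, concatenated; zeros when the cell has no keypoints) and appends
the CNN feature vector. This choice is an interpretation and is flagged as
such.

The evaluation harness is stratified 5-fold cross-validation with seeded
fold assignment; inside `run_pipeline()` the CNN is retrained within each
fold so that held-out predictions never see test data during feature
learning.

## Segmentation metrics

For automatic mask area $A_a$ and manual area $A_m$:
$TS = 100\,\lvert A_a \cap A_m\rvert / \max(\lvert A_a\rvert, \lvert
A_m\rvert)$. (The union sometimes seen in print in place of the
intersection would force $TS \ge 100$ for every input and is read as a
typo.) RDE averages the two root-mean-square nearest-neighbour distances
between the 4-connected inner boundaries of the two masks; a
`rde_variant = "mean_square"` flag provides the literal no-root reading for
comparison. With $Q_p$ the manual pixels missing from the automatic mask,
$U_p$ the spurious automatic pixels and $D_p$ the manual object size:
$OR = Q_p/(U_p+D_p)$, $UR = U_p/(U_p+D_p)$, $ER = (Q_p+U_p)/D_p$ — the
$(U_p + D_p)$ denominators are implemented exactly as the definitions
state, although parts of the literature normalize by $D_p$ alone.
Identical masks give $TS = 100$ and $RDE = OR = UR = ER = 0$; both masks
empty (TS) or an empty manual mask (OR/UR/ER) are errors.

## Synthetic data: what it emulates, what it does not

`make_smear()` paints non-overlapping nuclei (unions of 1–3 tilted
ellipses, ~10–16 px radius), RBC disks with central pallor, and platelet
specks on a pale background, then adds Gaussian pixel noise (σ = 4 by
default). The palette is chosen once so the nucleus projection has at least
3:1 contrast over background at that noise level — the regime the
color-projection model assumes. The ground-truth mask marks exactly the
painted nucleus pixels. `make_cell_crops()` varies lobe count,
eccentricity and band-limited texture across five classes as a coarse
proxy for leukocyte morphology. `make_clusters()` draws isotropic Gaussian
classes whose means sit pairwise `separation` × the within-class RMS
radius ($\sqrt{m}\sigma$) apart — the ratio at which clusters just touch is
1, so separation 5 is unambiguous class structure; separation 0 is
class-blind data. That RMS-radius convention (rather than per-dimension
σ) is deliberate: it makes "separation 5" mean the same degree of overlap
at every feature dimension, and a recovery test at that separation probes
the implementation, not the statistical frontier.

All generators are pure functions of spec + seed. What passing tests on
these data do **not** show: robustness to uneven illumination, stain
batches with hue shifts beyond the triple-weight scheme's reach, touching
or overlapping cells, focus blur, or the texture statistics of real
Giemsa-stained smears. Results on the synthetic smears are an upper bound
on clean-data behaviour, not a claim about clinical imagery. On these
clean synthetic smears the segmentation typically recovers the ground-truth
mask exactly (the acceptance script recomputes this).

## Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which every property is meaningful: 256×192 smears (20
for the segmentation study), 128×128 SIFT fixtures, 9×9–12×12 CNN gradient
fixtures, 150-sample cluster dictionaries, and cross-validation over a few
dozen crops. All sizes are configurable upward; nothing in the
implementation is specific to these dimensions.

## Known limitations

- Basis estimation assumes exactly three dominant color populations;
  smears with heavy debris or a fourth stain population would need a
  larger k.
- The AND-fusion is conservative: under-segmentation (eroded nucleus rims)
  is the expected failure mode on weakly stained cells, not
  over-segmentation.
- SIFT keypoints are sparse on small, texture-poor nuclei; the fused
  feature vector then degenerates to the zero-padded SIFT block plus CNN
  features.
- WTPTSSR solves a dense $N \times N$ system per test sample; dictionaries
  beyond a few thousand samples would need a factorization cache.
- The CNN is a feature extractor, not a state-of-the-art classifier; its
  role is to complement SIFT with learned context under the sparse
  classifier.
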