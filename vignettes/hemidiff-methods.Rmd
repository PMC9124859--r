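---
title: "Decoding motor imagery from the cortical hemispheric difference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery from the cortical hemispheric difference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

Imagined movement (motor imagery, MI) produces a lateralized decrease of
band-limited oscillatory power over sensorimotor cortex — event-related
desynchronization (ERD) of the mu (8–13 Hz) and beta (14–30 Hz) rhythms.
Imagining the left fist desynchronizes the right hemisphere, the right fist
the left hemisphere, both fists both hemispheres, and foot imagery produces a
spectrally distinct pattern. A brain–computer interface must recover which of
these four conditions (labelled T1–T4) generated a 4 s, 64-channel scalp EEG
trial sampled at 160 Hz.

`hemidiff` implements a source-space decoding chain: scalp epochs are mapped
to cortical current dipoles by a weighted minimum-norm inverse built on a
spherical forward model, nine symmetric left/right pairs of motor-cortex
"scout" regions provide 18 virtual-electrode time series, and a dual-branch
convolutional network classifies the trial after *subtracting* the two
hemispheres' learned feature vectors — the hemispheric difference is the
classifier's input representation, which directly encodes the lateralization
that distinguishes the classes.

## Forward model

The scalp potential is linear in the cortical dipole amplitudes,
$y = Lx + \varepsilon$, with $L$ the sensors × sources gain matrix. The
package computes $L$ analytically for three concentric spheres (brain, skull,
scalp) via the Legendre-series solution: for each spherical-harmonic degree
$n$ the radial boundary-value problem (potential and current continuity at
the two inner interfaces, insulating outer boundary) is solved as a 5 × 5
linear system whose basis functions are rescaled per compartment so all
matrix entries stay O(1) — the naive $r^n$ / $r^{-(n+1)}$ parameterization
overflows and loses conditioning above $n \approx 100$. Defaults: radii
0.080/0.085/0.092 m, conductivities 0.33/0.0042/0.33 S/m (standard
three-shell values), series truncated at `n_terms` with a tail check that
warns when the final term still exceeds 1e-10 of the accumulated potential
(superficial sources converge slowly; the pipeline default is
`n_terms = 150`, the function default 60). An average reference is applied,
after which every gain column sums to zero. Sources are radial unit dipoles
on a cortical shell (default 1200 quasi-uniform Fibonacci-lattice points at
radius 0.076 m, mirrored across the mid-sagittal plane so the grid is exactly
left/right symmetric). In the homogeneous limit (equal conductivities) the
implementation agrees with an independently coded single-sphere analytic
formula to better than 1e-6 relative error — one of the acceptance checks.

Externally computed gain matrices (e.g. from a boundary-element solver on a
realistic mesh, which is out of this package's scope) can be imported from
delimited text with `load_leadfield()`.

The 64-channel 10-10 montage is generated geometrically rather than copied
from a coordinate table: a head-circumference ring at 72° inclination with
18° azimuth steps, midline electrodes every 18° along the nasion–inion arc,
interior rows by great-circle interpolation between ring endpoint and midline
electrode, and T9/T10/Iz one further 18° step beyond their arcs. The
construction is mirror-symmetric by design (the scout symmetry tests rely on
it) and approximates standard positions to a few degrees; since the positions
only feed the spherical forward model and the scout geometry, this
approximation is immaterial to the method.

## Inverse operator

We use the standard weighted minimum-norm estimator (WMNE)

$$K = R_w L^\top (L R_w L^\top + \lambda C)^{-1},
  \qquad R_w = \mathrm{diag}(w)^{-2},$$

the closed-form minimizer of
$\|y - Lx\|^2_{C^{-1}} + \lambda \|\mathrm{diag}(w)\,x\|^2$. Here $C$ is the
sensor noise covariance estimated from per-subject baseline (resting)
segments — demeaned sample covariance with diagonal loading
$C \leftarrow (1-\alpha)C + \alpha\,\overline{\mathrm{diag}(C)}\,I$, default
$\alpha = 0.1$ — and $w_i = \|L_{\cdot i}\|^\gamma$ are depth weights
(default $\gamma = 0.5$; $\gamma = 0$ recovers plain MNE). Deep sources have
small gain columns, hence small $w_i$ and large prior variance $R_w$,
compensating the superficial bias of the unweighted solution. The
regularization default follows an SNR rule,
$\lambda = \mathrm{tr}(L R_w L^\top) / (\mathrm{tr}(C)\,\mathrm{snr})$ with
assumed power SNR 9 (amplitude SNR 3), the common minimum-norm convention;
every quantity is configurable. Whitening is implicit in the
$(\cdot + \lambda C)^{-1}$ form; no separate whitener is exposed. The
operator is validated against directly solved regularized normal equations
to 1e-8 on random problems.

## Scouts and the network input

Each of the 18 named electrodes (FC5…CP1 left, FC6…CP2 right) is projected
radially onto the cortical shell; its scout is the 20 nearest source
vertices. Overlap is resolved greedily in the fixed pair order (left before
right within a pair), so scouts are disjoint — whether the original regions
overlap is unknowable from the source description, and disjointness keeps the
virtual electrodes statistically distinct. Each scout's time series is the
sign-aligned mean of its 20 vertex series: signs are chosen so every vertex
series correlates non-negatively with the scout's first principal direction
(preventing cancellation of opposed dipole orientations), with the overall
sign anchored to the first vertex; a PCA aggregation is available behind
`method = "pca"`.

The network input stacks, per pair, the 640-sample left series on top of the
right series (column $j$ of a 1280 × 9 matrix); the network's first operation
splits this back into two 640 × 9 branch arrays. `assemble_input()` and
`split_branches()` are exact mutual inverses.

## The dual-branch network

Each branch applies four unpadded stride-1 convolutions with 25/50/100/200
feature maps and time-kernel 11 — the first kernel spans all 9 columns,
collapsing the channel axis — each followed by max pooling with time extents
3/3/3/2 under floor division. The branch output (4 × 1 × 200) flattens to
800 features; the element-wise difference of the left and right feature
vectors feeds one fully connected layer of 128 rectified units and a 4-way
softmax. `shape_propagate()` reproduces the full shape chain
(640×9 → 630/210/200/66/56/18/8/4 → 800 → 800 → 128 → 4) by pure arithmetic
and is pinned exactly by the acceptance suite.

Design choices where the method description leaves freedom:

* **Weight sharing.** Default: independent branches (initialized
  identically, updated independently); a shared mode aliases both branches to
  one parameter set. With shared weights in evaluation mode the difference
  features are exactly antisymmetric under swapping the hemispheres — a
  structural property the tests pin down.
* **Regularization placement.** Batch normalization after each convolution,
  before the rectifier (conv biases are dropped under BN, where they are
  redundant); spatial dropout — zeroing whole feature maps — after each
  pooling layer, rate 0.5.
* **The dropout/batch-norm variance shift.** Inverted dropout inflates the
  second moment of the activations during training, so BN running statistics
  collected then mis-scale the dropout-free evaluation pass; with four
  stacked blocks the feature magnitudes shrink several-fold and the head
  biases dominate. After the final iteration the running statistics are
  therefore recalibrated with one dropout-free pass over the training set.
  This is a known disharmony of the two techniques; recalibration preserves
  the stated layer placement.
* **Optimization.** Adam (learning rate 1e-3, β = 0.9/0.999), batch size 32,
  categorical cross-entropy; "iterations" are mini-batch updates drawn from
  reshuffled epochs. 600 iterations is the default training length, by which
  the learning curves plateau. All unstated by the method description and
  config-exposed.
* **Input standardization.** Inputs are z-scored with a center and scale
  estimated from the training set and stored in the fitted model.
  Source-space amplitudes are O(nA·m) — around 1e-9 in SI units — and
  without standardization the batch-norm ε (1e-5) would swamp the batch
  variances and no learning occurs.
* **Initialization.** He-scaled Gaussian weights; the softmax head starts
  near zero so an untrained model predicts the uniform distribution and the
  initial loss is ≈ log 4 (a test anchor).
* **Ties.** Max pooling takes the first maximum in a window; argmax
  prediction takes the first of tied classes.

The whole forward/backward pass is implemented in compiled code (im2col +
BLAS GEMM) with gradients verified against central finite differences on a
down-scaled architecture.

## Synthetic data: what it emulates and what it does not

The generator reproduces the *structure* of the public 64-channel
motor-imagery recordings — 160 Hz, 4 s trials, 21 trials per class, 84 per
subject, T1–T4 cue annotations, per-subject rest segments, EDF files — with
a physiologically motivated but deliberately simple source model: per scout
region, amplitude-modulated sinusoids with random frequencies and phases in
the mu (10–12 Hz) and beta (18–25 Hz) bands over a 1/f pink background. ERD
is oscillation-amplitude suppression: active regions have their band
amplitude multiplied by $1-\mathrm{erd\_depth}$, so the active/inactive
band-power ratio is $(1-\mathrm{erd\_depth})^2$ (a test oracle, measured by
periodogram band power). Class templates: T1 → right-hemisphere set,
T2 → left, T3 → both, and T4 → both but beta-band only. The T4 convention
stands in for foot-area sources, which lie outside the fixed 18-scout set;
it is a simulation convention, not a physiological claim. Sensor noise is
spatially white at a configurable SNR, defined as mean 8–30 Hz signal band
power across channels over noise power in the same band; a zero signal
receives noise at an absolute floor variance (default (1 µV)²). Source
dipole moments default to 10 nA·m, giving microvolt-scale scalp signals.

Limitations to keep in mind when reading green tests: the generator places
its activity exactly on the scout vertices that the pipeline later extracts
(a deliberately favourable "inverse-crime" geometry), uses a spherical head
and no artifacts (EOG/EMG/line noise), no inter-subject anatomical
variability, and class differences far cleaner than real recordings. Passing
the end-to-end criteria therefore demonstrates that the chain is wired
correctly and can recover a genuine ERD effect through the inverse — not
that real-data accuracies are reproduced. Reproducing published real-data
numbers would require downloading the public recordings and long training,
which the test surface deliberately excludes; the EDF ingestion path exists
for that use.

## Evaluation

`compute_metrics()` computes the confusion matrix from argmax predictions,
accuracy, Cohen's kappa $(p_o - p_e)/(1 - p_e)$ with $p_e$ from the
marginals, per-class and macro-averaged precision/recall/F1 (macro chosen
because a single number is reported for a 4-class problem; a class with no
predicted positives has precision 0), and one-vs-rest ROC AUC by trapezoidal
integration of the tie-grouped empirical ROC — equal to the Wilcoxon rank
statistic, and cross-checked against an independent ROC implementation in
the tests.

The subject-level split is stratified: per class,
$\mathrm{round}((1-f)\,n_c)$ trials (at least one) are held out; with 84
balanced trials and $f = 0.9$ that is 76/8 (19/2 per class). The group-level
scheme partitions each subject's trials into 10 near-equal parts (sizes
differ by at most one — 84 is not divisible by 10, so "equal parts" is
realized as 6 parts of 8 and 4 of 9), pools one random part per subject into
the test set, and shuffles both pools. The ablation grid trains the full
model and the no-dropout / no-BN / neither variants on identical splits and
seeds.

## Problem sizes and determinism

The test suite exercises the full-scale study conditions once (one subject,
84 trials, 1200 sources, 600 iterations — a few minutes) and otherwise uses
reduced sizes chosen to keep the suite quick: a 500-source forward model,
2–3 trials per class, 15–150 training iterations, and a down-scaled network
for the finite-difference gradient check. These sizes are the package's own
testing choices; every operation is size-generic. All randomness flows
through R's RNG (the compiled dropout kernel draws from it too), so every
dataset, split, and fit is bit-reproducible from its seed, and the pipeline
propagates one master seed to each stage through fixed offsets.

## Known limitations

No realistic (BEM/FEM) forward solver, free-orientation sources, or
dSPM/sLORETA variants; no artifact rejection; no hyperparameter search; no
statistical testing across subjects; no real-time operation. The spherical
montage construction approximates, rather than reproduces, surveyed
electrode coordinates. The printed form of the inverse estimator in the
method's source description leaves its weighting symbols undefined; this
package implements the standard WMNE estimator above and documents the
mapping (noise-covariance scaling ↔ the regularizer, source weighting ↔ the
diagonal prior) rather than guessing another interpretation.
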