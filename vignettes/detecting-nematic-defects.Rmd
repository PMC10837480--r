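---
title: "Detecting nematic defects in confluent cell layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nematic defects in confluent cell layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(nemadef)
```

## The model

A confluent cell layer carries a nematic orientation field: each cell's
long axis defines a director $\theta \in [0, \pi)$, identified with
$\theta + \pi$ (head–tail symmetry). The input to everything in this
package is the minimal output of segmentation software — per-cell
centroid $(x, y)$ and long-axis orientation $\theta$ in radians,
optionally per-cell velocities — one table per frame.

Topological defects are the points where the director field is
discontinuous. Around a closed counter-clockwise loop the director must
return to itself modulo $\pi$, so the accumulated rotation is $m\pi$ and
the *winding charge* $k = m/2$. The generic defects of a nematic are
$k = +1/2$ (comet-shaped) and $k = -1/2$ (trefoil-shaped). The ideal
director field of a superposition of point defects is
$\theta(p) = \sum_j k_j \phi_j(p) + \theta_0$ with $\phi_j$ the polar
angle around core $j$; this is both what the synthetic generator plants
and what every oracle in the test suite evaluates.

The difficulty specific to epithelial monolayers is that cells are often
nearly isotropic: the field has genuinely disordered patches that carry
no topological charge. A detector must therefore (a) find *candidate*
regions by low nematic order and (b) decide whether each candidate is a
defect at all — a three-class problem (+1/2, none, −1/2), not a binary
one.

## Pipeline and numerical choices

**Director grid.** Orientations are interpolated to a fine regular grid
and smoothed over a square sliding window. All angular averaging happens
on $(\cos 2\theta, \sin 2\theta)$: direct averaging of $\theta$ is wrong
across the $\pi$ wrap, while the double-angle mean respects nematic
symmetry exactly. Interpolation is nearest-cell (Voronoi) lookup. A
linear scatter interpolant would differ only below the smoothing scale:
with the default window (1.5 cell diameters half-width, boxcar weights,
roughly nine cells per window) the window dominates, so the cheaper and
assumption-free scheme is used. Defaults: grid spacing 0.25 cell
diameters (cell diameter estimated as $\sqrt{\text{box area}/n}$),
window half-width 1.5 cell diameters; both are exposed because the right
values scale with cell size, not with pixels.

**One smoothing stage, not two.** The order-parameter field is the
window average of the nematic tensor of the *raw interpolated* field:
$Q_{xx} = \langle\cos 2\theta\rangle$,
$Q_{xy} = \langle\sin 2\theta\rangle$, and
$S = \sqrt{Q_{xx}^2 + Q_{xy}^2}$ — the largest eigenvalue of the 2D
traceless symmetric $Q$, in closed form rather than via an eigensolver.
The smoothed director is the eigen-direction of the same windowed $Q$,
so the director grid and its order field are two readings of one
object. Windowing the already-smoothed directors instead would smooth
twice and report spuriously high order on disordered input (an
isotropic frame would no longer read $S \approx 0.2$ but well above it).

**Candidates.** Connected components (8-connected by default, so
diagonal low-order filaments are not split) of $\{S < S_{th}\}$ with
$S_{th} = 0.15$; each component's centre of mass is a candidate. On
periodic frames the centroid is taken on the circle per axis so regions
straddling the seam are handled. Candidates sit anywhere on the fine
grid — detection is off-lattice up to grid resolution, unlike the
legacy coarse-lattice winding scan (`classify_on_lattice()`), which is
retained as the baseline it is.

**ROIs.** A $9\times9$ patch of directors spanning 6 cell diameters
(midpoint of the 5–7-cell sizing rule: big enough to hold a core, small
enough to isolate one defect), sampled by nearest-grid-node lookup — the
ROI grid is a subsample of the fine grid, not a re-interpolation.
Candidates whose ROI would cross a non-periodic boundary are skipped
with a warning. Overlapping ROIs are all kept: $S_{th}$ is chosen so
regions stay distinct, and suppression would be an extra undocumented
filter.

**Winding classifier.** Successive director differences around the ROI
perimeter (32 nodes, counter-clockwise from the bottom-left corner) are
wrapped into $(-\pi/2, \pi/2]$ — half-open so an exact $\pi/2$ jump
breaks ties deterministically — and summed. Because the loop is closed
the total is an exact multiple of $\pi$ up to rounding; the charge is
accepted as $\pm 1/2$ or $0$ within a tolerance of 0.1 charge units
(noise-free loops are exact; the tolerance only matters for noisy
fields). Outcomes $|k| \ge 1$ are reported as `other` and mapped to
`none` for three-class scoring.

**CNN classifier.** Input encoding is the same double-angle pair per
node (two $9\times9$ channels in $[-1,1]$): raw angles would put an
artificial discontinuity at the wrap for the network to learn around,
and the encoding makes head–tail symmetry exact by construction.
Architecture: two valid $3\times3$ convolutions with 32 feature maps
each ($9 \to 7 \to 5$, no pooling — the input is too small for it), a
100-unit fully connected ReLU layer with 50% inverted dropout, and a
3-way softmax. $3\times3$ is the smallest standard kernel that keeps a
$5\times5$ spatial map ahead of the dense layer. Weights are
Glorot-normal, biases zero. Training: plain SGD (no momentum, no decay),
batch 64, 30 epochs at learning rate 0.025 then 0.005 after epoch 15,
minimizing cross-entropy $C = -\sum_i \sum_c y_{i,c}\log p_{i,c}$;
gradients use the batch mean (the conventional scaling, which keeps
those learning rates in their usual regime; reported losses are
per-item). 10% of the training set is held out and scored at the end of
each epoch with dropout disabled. One seed controls initialization, the
split, shuffling and dropout, so a training run is exactly repeatable.
The class order (+1/2, none, −1/2) and the encoding version are
serialized with the model to forestall label-permutation bugs.
Augmentation (grid rotation by $-\pi/2, \pi, \pi/2$ with the same angle
added to each director mod $\pi$, then reflection about the vertical
centreline with $\theta \to \pi - \theta$) multiplies a training set by
exactly 8 and preserves labels; the choice of vertical rather than
horizontal centreline is immaterial because the two differ by a rotation
already in the group.

**Polarity and oriented averaging.** The +1/2 comet axis is
$\psi = \mathrm{atan2}(p_y, p_x)$ with
$p = (\partial_x Q_{xx} + \partial_y Q_{xy},\;
\partial_x Q_{xy} - \partial_y Q_{xx})$, centred finite differences
averaged over the $3\times3$ node disk around the core. For the ideal
field $\theta = \phi/2 + \theta_0$ both the analytic derivative and a
brute-force finite-difference oracle give $\psi = 2\theta_0$; that
convention is frozen, and the synthetic velocity template plants its jet
along the same $\psi$, so detected and planted polarities agree by
construction (and by test). Fields around defects are averaged by
cropping a window at each core, rotating window and vectors by $-\psi$
so all polarities align with $+x$, bilinearly resampling onto a common
grid and averaging; $|p|$ below tolerance (e.g. a uniform field) is an
explicit error and the defect is excluded. The comparison score between
averaged fields is the mean dot product normalized by the product of RMS
magnitudes — the published form of the single-point correlation leaves
its normalization unstated, and the cosine-type score is scale-free,
bounded in $[-1,1]$, and anchors self-correlation at exactly 1.

## The synthetic generator

The generator stands in for the vertex-model simulation used to produce
the original training data (the simulator itself is out of scope here;
its parameters live outside the main text). It emulates the *format and
failure modes* of segmented tissue, not tissue mechanics:

* cell centres on a jittered triangular lattice at the configured
  density (jitter 0.15 lattice constants, a visually realistic packing);
* orientations from the ideal planted field plus a wrapped von Mises
  perturbation of the double angle with concentration $\kappa$ — one
  dial from isotropic ($\kappa = 0$) to noise-free ($\kappa = \infty$)
  that keeps $\theta$ nematic-valid. Calibration on 20×20-diameter
  frames: $\kappa = 16$ reads as near-clean, $\kappa = 6$ (director
  jitter ≈ 12.5°) as moderately noisy tissue, $\kappa = 2$ as heavily
  disordered; an isotropic frame gives mean $S \approx 0.23$ under the
  default window;
* optional velocities: each +1/2 core contributes a fixed analytic
  template — a Gaussian tail-to-head jet along $\psi$ flanked by two
  counter-rotating Gaussian vortices, normalized to speed $v_0$ at the
  core — plus isotropic Gaussian noise. It is a *recoverable planted
  pattern* for benchmarking oriented averaging, with no claim of
  hydrodynamic fidelity;
* labelled ROI datasets: balanced +1/2 / none / −1/2 patches built
  directly from the analytic field (defect cores sub-node-jittered at
  the patch centre, random phase). No-defect ROIs mix two recipes 50/50,
  matching the hard negatives that motivate the three-class design:
  `disordered` (iid isotropic orientations — low order, no charge) and
  `farfield` (smooth crops of a distant two-defect field). At
  $\kappa = \infty$ only `farfield` is used, because an iid-isotropic
  patch is maximal noise by construction, not a noise-free example.

Everything is a pure function of its config including the seed, and the
generator restores the caller's RNG state.

What passing synthetic tests does *not* show: robustness to the cell
shape irregularity, segmentation errors, curved defect cores, spatially
correlated noise or finite layer thickness of experimental images. The
generator's defects are ideal up to angular noise; the benchmark numbers
below are statements about the pipeline's arithmetic and the relative
behaviour of the two classifiers, not predictions of accuracy on
micrographs.

## Benchmark design and problem sizes

The published comparison of the two classifiers was run on thousands of
manually labelled simulation ROIs and is not reproducible without that
labelled set and its trained weights; what is reproducible is the
*ordering* and the exactness limits. The package's study-scale benchmark
(in `tests/testthat/test-acceptance.R`): 900 base training ROIs (300 per
class, $\kappa \in \{16, 6, 2\}$) augmented to 7,200; the CNN trained
with the default 30-epoch schedule; 600 unseen test ROIs, half
noise-free and half at $\kappa = 6$. Asserted: final validation accuracy
above 0.9; CNN overall accuracy at least that of the winding number; and
both methods exact on the noise-free subset. These sizes train in
roughly a minute on one CPU; they were chosen as the smallest ensemble
where the per-class counts make the ordering stable across seeds, and
the test suite's other simulations (20×20-diameter frames, ~400 cells)
follow the same principle. Oriented averaging is benchmarked on 150
planted templates with vector noise equal to the signal amplitude,
checking normalized correlation ≥ 0.9 with the clean template and
improvement across ensembles of 10, 50 and 150 — mirroring how ensemble
size governs the quality of mean defect flow fields.

## Known limitations

* Nearest-cell interpolation introduces sub-window Voronoi structure;
  irrelevant at default settings, visible if the window is shrunk toward
  the grid spacing.
* The winding tolerance (0.1 charge units) and $S_{th}$ interact: a very
  noisy field can push candidate loops past tolerance into `other`.
  Both are config-exposed.
* Integer ($\pm 1$) defects are out of scope; `other` outcomes are
  reported but not classified.
* The CNN is a small fixed architecture; no hyperparameter search is
  provided, by design.
* Velocity grids average over cells within the window; with fewer than
  ~2 cells per window, nodes can be unsampled and defects near them are
  skipped with a warning.

## A short tour

```{r example, eval = FALSE}
cfg <- synth_config(box = c(20, 20), n_cells = 400,
                    defects = data.frame(x = c(5, 15), y = c(10, 10),
                                         charge = c(0.5, -0.5)),
                    kappa = 8, seed = 42)
sim <- generate_frame(cfg)
grid <- build_director_grid(sim$frame)
plot(order_parameter_field(grid))      # S dips at the two planted cores
detect_defects(sim$frame)              # 2 rows, correct charges

ds <- augment_rois(generate_labeled_rois(150, kappa = c(16, 6, 2), seed = 1))
model <- train_defect_cnn(ds, train_config(epochs = 10, seed = 2))
plot(model)                            # loss / accuracy per epoch
test <- generate_labeled_rois(100, kappa = 6, seed = 3)
classification_report(test$label, predict(model, test), method = "cnn")
```
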