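---
title: "Self-distilled object detection from a single microscopy image"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-distilled object detection from a single microscopy image}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lodestar)
```

## The model

lodestar trains an object detector from **one unlabeled image** of one
object. The trick is that localization has symmetries we know a priori:
translating an image translates the object's position by the same amount,
and likewise for rotations and reflections. A predictor that is exactly
*equivariant* to this group on the orbit of a single image is already a
consistent detector, and if the object's image has a rotational symmetry,
the prediction is pinned to the symmetry center; with only a reflection
symmetry, the error component normal to the mirror axis vanishes. Training
therefore needs no labels — only an equivariance penalty on transformed
copies of one crop.

The predictor is a small fully convolutional network: `n_pre` (default 3)
3x3 convolutions with ReLU, one 2x2 max-pool, `n_post` (default 8) more
3x3 convolutions, and a linear 1x1 head. Its output at stride `k = 2` has
channels `dx`, `dy`, `rho` plus optional extras. Feature pixel `(i, j)`
(0-based) votes for the object position

    x[i, j] = dx[i, j] + i * k - N/2,
    y[i, j] = dy[i, j] + j * k - M/2,

with `N x M` the input size; `rho` is passed through a sigmoid and
normalized to a weight map `w`, and the single-object prediction is the
`w`-weighted average of the vote maps. Because convolutions, pooling and
weighted pooling all commute with integer-`k` translations, the
architecture is translation-equivariant by construction (exactly, away
from the boundary; the zero-padded "same" convolutions keep the index
arithmetic above exact, and boundary rows are excluded from the
equivariance tests).

`N` in the position decode is read as the **input** dimension. The
alternative reading (the feature-map dimension) would make decoded
positions drift with the pooling factor and contradict the top-left pixel
convention used everywhere else; both readings only differ by a constant
the training absorbs, but the input reading keeps positions in input-pixel
units.

## Training

Each mini-batch takes `K = 8` views of the training crop, each view
transformed by an independently sampled group element: translation uniform
in ±8 px per axis, rotation uniform on [0, 2pi), independent axis
reflections, and — when the corresponding extra channels are enabled —
a Fourier-propagation distance `dz` (uniform, ±2 um) and a log
signal-scale `ln s` (uniform, ±log 4; see below). The warp is bilinear
with reflected boundary fill, followed by a center crop. Each view's
pooled prediction is mapped back through the inverse transform, and two L1
losses are minimized with Adam (learning rate 0.001):

* the **consistency loss**: total absolute deviation of the inverted
  predictions from their batch mean, per channel; and
* the **internal loss**: the weighted L1 spread of each vote map around
  its own pooled value, which concentrates the weight map on the object
  and makes the per-pixel votes agree — this is what later powers
  multi-object detection.

The two are summed with equal weight; nothing in the training protocol
suggests a preferred weighting, and the equal-weight sum trains stably.
During training the weight map uses a 1% dropout on the sigmoid weights
plus a floor `eps = 1e-6`, which together prevent collapse onto a single
feature pixel while still rewarding confident, localized weights.

Self-distillation from a single image occasionally locks into a
degenerate basin (the weight map never finds the object and the loss
plateaus 30-60x above its healthy range). Healthy and stuck runs separate
cleanly in training loss within a few hundred mini-batches, so
`train_config(restart_threshold = )` enables an optional stall guard:
if the loss at the probe step (default 600) still exceeds the threshold,
training restarts from a fresh deterministic initialization (at most
twice). The guard reads only the training loss, never an evaluation
metric, and is off by default.

Two declared choices deserve justification:

* **Input normalization.** Intensity crops are standardized (subtract the
  image mean, divide by the image standard deviation). Photon-count images
  with a strong background otherwise enter the network as a percent-level
  ripple on a constant, and we found self-distillation then stalls for
  thousands of mini-batches in biased states. Standardization makes the
  contrast order one and runs seed-stable. For holographic inputs the two
  field planes are expressed relative to the background level and **not**
  standardized — for the scale-symmetric task the per-image amplitude *is*
  the regression target, and any per-image statistic would erase it.
* **Scale range.** The log-scale transform is sampled in ±log 4 rather
  than ±log 2. The bi-dispersed detection task asks one model, trained on
  a 228 nm sphere, to also detect 150 nm spheres whose scattering
  amplitude is 3.5x weaker ((150/228)^3 = 0.29); with a ±log 2 training
  range those particles lie outside the signal range the network has ever
  seen and are simply not detected. ±log 4 covers the population the
  method is claimed to handle.

## Synthetic data

The generator renders five shape classes (point = Gaussian PSF of sigma
2 px; disk r = 6 px; annulus radii 4-7 px; ellipse 8 x 4 px; crescent =
disk r 7 px minus an offset disk r 5 px; solid shapes blurred by a sigma
1 px PSF) on 64 x 64 px grids by default. Rendering is anti-aliased: a
10x supersampled analytic profile, PSF convolution at fine resolution,
then box integration per detector pixel, with the peak normalized on a
shape-centered canonical grid so that the integrated signal mass is
invariant under sub-pixel shifts to below 0.1%. Noise is Poisson per
pixel after rescaling so that

    SNR = (peak expected signal - background) / sqrt(background),

with a default background of 100 expected photons. The SNR convention is
declared, not inferred: shot-noise-limited imaging with the peak-over-
background-sigma ratio makes the Cramer-Rao machinery below directly
computable.

Holograms use a weak-scatterer model: each particle contributes a
diffraction-limited complex point response (uniform pupil cut at the NA,
default 1.3 / 633 nm / 114 nm pixels), positioned by Fourier phase ramps,
defocused by angular-spectrum propagation (carrier removed so the unit
background is propagation-invariant, evanescent components decayed), and
scaled in proportion to its Clausius-Mossotti polarizability
`3V (np^2 - nm^2)/(np^2 + 2 nm^2)`. Complex Gaussian noise is added with
`max|I| / sqrt(sigma_Re^2 + sigma_Im^2) = SNR`. The position-modulated
acquisition mode is emulated as the difference between a particle response
and a copy displaced by the stage-modulation offset, on a suppressed
background. Deliberately out of scope: Mie scattering, aberrations,
vectorial PSFs, camera read noise — the simulator is a weak-scatterer
replica, not a microscope twin, and synthetic F1/MAPE results must be read
with that in mind.

## Detection, linking, quantities

Multi-object detection removes the global pooling: the per-pixel votes
`chi` and the weight map are kept as maps, a clustering map `b` is
computed as the inverse (clamped at `eps_b = 1e-6`) of the summed local
3x3 variance of the vote maps, and the score `w^alpha * b^(1-alpha)`
(default `alpha = 0.1` for homogeneous particles) is searched for
prominent local maxima (h-maxima via grayscale reconstruction, prominence
default `1e-3 * max score`) above the 0.99 score quantile. The quantile
should follow scene density: with objects covering roughly 1% of the
feature map, 0.99 is the aligned choice, and sparser scenes can afford
0.995-0.997 to suppress residual noise maxima — but raising it eats into
recall when a weakly trained model spreads its score mass, so check
recall before tightening. When an
axial channel is trained, its per-pixel votes inflate the clustering
variance, so detection for 3D models works better with more of the score
on the weight map (`alpha = 0.5`). Detections are
refined by re-pooling the votes in a window of half-width 2 feature px
around each maximum (the default is deliberately tight: a wide window
drags detections of nearby particles toward each other in dense scenes).
Frame-to-frame linking is a linear sum assignment (Jonker-Volgenant) with
a hard distance gate (default 1 um) and a minimum-length filter.

The axial channel converts to micrometres through the optics and is
corrected by `n_oil/n_medium` (1.128 for oil/water) when an index mismatch
is declared. The log-scale channel has no absolute anchor — the symmetry
only constrains ratios — so polarizability requires calibrating the
reference log-scale on an observation of known polarizability; per-trace
polarizability is the unweighted mean over the trace's detections.

## The Cramer-Rao oracle

For Poisson noise the Fisher information is
`I = sum_k (dnu/dtheta)^T (dnu/dtheta) / nu_k` over pixels, with
`theta = (x, y, orientation)`. Derivatives are central differences (0.1 px
for positions — one fine-grid pixel — and 0.01 rad for orientation) of the
supersampled, pixel-integrated render, so the oracle shares the renderer
with the data generator but no code with the estimators it bounds. The
localization bound is `sqrt((I^-1_xx + I^-1_yy)/2)` — a **per-axis** RMSE.
For rotationally symmetric shapes the orientation parameter is
uninformative and its singular block is excluded rather than
pseudo-inverted silently. RMSE comparisons against this bound use the
matching per-axis convention (`rmse_localization(..., convention =
"per_axis")`); the Euclidean convention is sqrt(2) larger.

## Problem sizes used by tests and the acceptance script

The published protocol (32-channel backbone, 5000 mini-batches of 8, and
15000 for the propagation task) is the package default. The test suite
and the acceptance script run a reduced desk-scale protocol chosen as the
package's own reproducible-on-a-laptop configuration: 16-channel
backbone; 40 px working crops for shape models and 48 px for holographic
ones; mini-batch counts of 700-1500 for the shape models and 800-2500 for
the holographic models; training holograms at SNR 30
(scale task and modulated crop) and SNR 50 (propagation task, whose
defocused views carry less peak signal); accuracy evaluations over
100-500 test images per condition; and detection F1 averaged over a few
multi-particle frames per SNR in a 15-40 sweep. Where a criterion is
sensitive to the remaining training budget — the sub-0.1 px headline
accuracies, and detection of scatterers well below the trained signal
band, most of all — the desk-scale figure approaches but does not fully
reach the published operating point; the acceptance report states what
this configuration actually measures.

## Known limitations

* Equivariance under the continuous group is approximate: bilinear
  interpolation is not exactly rotation-equivariant, which sets a floor on
  accuracy well below a pixel but above zero.
* Detections near the image boundary (within the receptive-field margin)
  are less reliable; equivariance holds on the interior.
* The crescent has no rotational symmetry, so theory pins only the error
  component normal to its mirror axis; the component along the axis
  converges to a training-dependent anchor point. Its RMSE against the
  nominal shape center is therefore partly an offset, not scatter.
* The weak-scatterer hologram model is linear in polarizability by
  construction; real scatterers at these sizes deviate (Mie corrections),
  so synthetic MAPE understates real-world calibration error.
```
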