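---
title: "Characterizing dynamic DNA origami hinges from TEM micrographs"
author: "origamiflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing dynamic DNA origami hinges from TEM micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(origamiflex)
```

# The problem

A DNA origami hinge is two stiff ~70 nm arms joined by a flexible
single-stranded vertex: effectively a torsional spring with one rotational
degree of freedom. Its mechanics are summarized by the rotational free-energy
landscape $E(\theta)$, obtained from the equilibrium distribution of the
hinge angle $\theta$ by Boltzmann inversion,

$$E(\theta) = -k_BT \, \ln p(\theta) + \text{const},$$

with the torque $\tau(\theta) = -dE/d\theta$. Measuring $p(\theta)$ requires
locating hundreds to thousands of individual, well-folded, isolated particles
in negative-stain TEM micrographs and measuring each particle's angle — a
task traditionally done by hand.

`origamiflex` implements that measurement pipeline in two stages:

1. **Particle detection**: propose bounding boxes for isolated two-arm
   particles, filter them by a confidence threshold (default 0.47), greedy
   non-maximum suppression (IoU 0.3) and a bounding-box-size filter (BBF)
   that removes boxes with aspect ratio above 1.5 and re-squares survivors
   to 50×50 px.
2. **Pose estimation**: on each 200×200 px particle crop, locate named
   keypoints — the two arm tips and the vertex — under a `DeviceSchema`,
   gate them by a keypoint confidence threshold (default 0.92), and compute
   the included angle at the vertex.

The angle ensemble is then binned (default 5° bins over [0°, 180°]),
Boltzmann-inverted, and differentiated into a torque profile.

Both stages are *backend contracts*: trained neural-network detectors and
pose estimators can be plugged in from outside. The package ships classical
image-processing reference backends so the whole pipeline runs, and is
testable end-to-end, with no training data or network weights.

# The synthetic micrograph generator

Real micrographs and trained networks are not required anywhere: the
`synthetic` module (`simulationConfig()`, `generateMicrograph()`,
`generateDataset()`) renders scenes with exact ground truth. Each scene
contains, over a background of base level + low-frequency stain mottle +
Gaussian pixel noise:

* **target hinges** — two bright rectangular arms sharing a vertex, included
  angle drawn from a configurable law (default: truncated Gaussian, mean
  90°, sd 15°, support [0°, 180°]), uniformly random global rotation;
* **rod distractors** — single arms, emulating hinges deposited edge-on so
  the second arm is invisible;
* **aggregates** — 2–3 overlapping hinges;
* **free blobs** — compact bright spots;
* optionally **border hinges** — hinges deliberately clipped by the image
  edge, emulating the boundary clutter that detection filters must remove.

Keypoint ground truth follows the annotation rule used for real data: the
vertex is the intersection of the two *inner* arm edges and the tips are the
inner-edge endpoints. Arm rectangles extend outward from those inner edges.
This convention is one reason tip positions are intrinsically harder to
measure than the vertex: the tip's radial position along the arm is poorly
defined, while the vertex is pinned by two intersecting lines.

Default conditions were chosen once, as a realistic negative-stain scene at
the 960×960 px working scale: 20 target hinges, 3 rods, 2 aggregates and 4
blobs per image; background level 0.25, particle contrast +0.35, noise sd
0.04, mottle of amplitude 0.03 and ~96 px correlation length; arms 70×10 nm
at 1.4 nm/px (so a 70 nm arm is 50 px — consistent with the 50×50 px
annotation-box convention). The calibration `nm_per_px` is a required
configuration value, not a measured one; 1.4 nm/px is a documented
convention for the default geometry.

Everything is deterministic under a single seed: per-image and per-stage
seeds are derived from the master seed by a stable string hash
(`deriveSeed()`), so a fixed configuration yields byte-identical images.

What the generator does *not* emulate: contrast transfer, dose and stain
chemistry, partially folded particles, or continuous aggregation scales.
Passing tests on synthetic scenes therefore demonstrates the pipeline's
*logic* (geometry, filtering, statistics, end-to-end plumbing) — not
performance on real TEM data, which depends on the plugged-in backends.

# The classical detection backend

`classicalDetect()` normalizes intensity, smooths (Gaussian, sd 1.5 px),
thresholds with Otsu's method, cleans the binary map by morphological
opening and closing, and extracts 8-connected components within area bounds.
Each candidate is scored by a monotone confidence in [0, 1]:

$$\text{conf} = \sqrt{\text{areaScore} \times \text{shapeScore}}, \qquad
\text{areaScore} = e^{-\left((A/A_\text{exp}-1)/0.4\right)^2},$$

where $A_\text{exp}$ is the expected two-arm area and the shape score is the
fraction of component pixels within the best two-segment (vertex + two arms)
fit of the component skeleton. Isolated hinges score high on both terms;
rods have high shape score but roughly half the expected area; aggregates
have 2–3 times the area and poor two-segment coverage. With the default
confidence threshold of 0.47 these distractors are rejected.

Box geometry: interior components that pass the two-arm analysis are
reported as *square* boxes (side = larger tight-extent dimension), mirroring
the square-box annotation convention this backend emulates; components
touching the image border keep their clipped tight extent. Boundary-truncated
particles therefore carry high aspect ratios and are removed by the BBF —
the same mechanism by which the filter removes boundary false positives on
real data. An axis-aligned tight box around a V-shaped particle would
otherwise have rotation-dependent aspect ratio (1–2 even for a perfect
hinge), which would make an aspect filter discard a large fraction of true
positives; the square convention keeps the BBF's true-positive cost near
zero while preserving its false-positive removal.

# The classical pose backend

`classicalPose()` binarizes the crop (Otsu after a 3 px smoothing, plus a
morphological closing that bridges the dim pinch that rendering and staining
produce at the vertex corner), keeps the largest component, and thins it to
a 1 px skeleton (Zhang–Suen, implemented in C++). Geometry is then read off
the skeleton's *longest geodesic path*: for a two-arm particle this path
runs tip → vertex → tip and is immune to short spurs and junction clutter.
The path is split at the index minimizing the summed residual of two
total-least-squares line fits (computed in O(n) from prefix moments); each
arm is refitted excluding pixels near the split (where thinning rounds the
corner) and near the crop border (where a cut arm's skeleton follows the
cut, not the arm), with one outlier-trimming pass. The vertex is the
intersection of the two arm lines; tips are the path endpoints projected
onto them.

Numerical tie-breaks and degenerate inputs: a path whose single-line fit has
RMS residual ≤ 1.2 px is classified as a rod (no vertex → all-missing pose);
near-parallel arm fits fall back to the split point as vertex; blank crops
are recognized by foreground fraction and by the Otsu between-class variance
fraction (≥ 0.75 required), since thresholding pure background noise
produces a weakly bimodal split. All failures return an all-missing pose
with confidence 0, never an error.

Keypoint confidence is designed so that the fixed 0.92 gate separates
trustworthy fits from partial-structure ones:

$$\text{conf} = e^{-(\text{rms}/20)^2}\;
\min(1, \text{keepFrac}/0.9)\;
\min\!\left(1, (\text{coverage}/0.9)^4\right)$$

with `rms` the arm-fit residual (px), `keepFrac` the inlier fraction of the
trimmed fit, and `coverage` the fraction of significant foreground explained
by the fitted two-segment model. A fit of one arm of a split mask has
coverage near 0.5 and is rejected decisively; clean fits score 0.95–0.99.
The vertex confidence is the minimum of the two arm confidences, and the
gate requires *all* angle-defining points to pass — an angle computed
through one untrustworthy point is untrustworthy.

Tip labels are assigned deterministically (smaller y first). Because a hinge
has no feature distinguishing its arms, roughly half of all predictions are
"flipped" relative to ground-truth labels; `canonicalizeTipLabels()`
resolves the ambiguity by minimal total tip distance before spatial-error
analysis, and the flip rate is reported. The included angle is invariant
under the swap.

# Device schemas

Generality across devices is carried by `DeviceSchema`: named keypoints,
angle-defining triples, and position-only points.

* `hinge`: `tipA`, `vertex`, `tipB`; one angle.
* `hinge-nucleosome`: adds a `nucleosome` position point, located by the
  classical backend as the brightest compact secondary component near the
  arms.
* `steridyn`: `tipL`, `vertexL`, `vertexR`, `tipR`; two angles. The adopted
  convention measures each arm against the base segment joining the two
  vertices (angle L = tipL–vertexL–vertexR, angle R = tipR–vertexR–vertexL).
  This is an interpretation — four points admit several two-angle
  definitions — and is swappable by supplying a custom `deviceSchema()`.
  The classical pose backend itself only handles two-arm particles; the
  SteriDyn schema is for externally plugged-in estimators and for the
  evaluation machinery.

# Mechanics

`anglesToDistribution()` bins angles into right-open bins $[e_i, e_{i+1})$
over [0°, 180°], the last bin closed at 180°. The bin width (default 5°)
must divide 180 and is reported in all outputs; it is a user-visible choice,
as is the treatment of empty bins: `boltzmannInvert()` leaves
zero-probability bins *undefined* (`NA`) rather than imputing them; a
`pseudocount` option (0.5 counts per bin) exists for users who need a fully
defined landscape. Energies are in units of $k_BT$ and shifted so the
minimum defined energy is zero, with the offset recorded.
`torqueFromEnergy()` uses central finite differences over each contiguous
run of defined bins, one-sided at run boundaries — exact for quadratic
landscapes. `landscapeCurvature()` fits a weighted quadratic; for
Gaussian-distributed angles the analytic curvature is $k_BT/\sigma^2$, which
is the torsional stiffness.

Agreement between two angle ensembles is tested with the two-sample
Kolmogorov–Smirnov test (`ksTwoSample()`), using the asymptotic p-value with
effective sample size $n_a n_b/(n_a+n_b)$ — adequate for the hundreds of
particles typical of these experiments.

# Evaluation

`matchDetections()` performs greedy confidence-ordered one-to-one IoU
matching (threshold 0.3), the standard object-detection convention; ties are
broken deterministically by confidence, then box centre. Precision, recall
and F1 follow the usual confusion-count definitions, with undefined
quantities reported as `NA` rather than silently zeroed. Spatial errors are
reported per keypoint in nm as error-vector clouds, with the two-dimensional
standard deviation defined as $\sqrt{\mathrm{Var}(dx)+\mathrm{Var}(dy)}$
(population variances); the mean radial error is also reported as an
alternative summary since the 2D-std definition is a convention.

# Problem sizes used in the test suite

The package's own checks run on synthetic data sized to exercise the
statistics meaningfully: the end-to-end study set is 20 micrographs of
960×960 px with ~20 target hinges each (~400 particles); the clean-crop
angle-recovery property uses 150 crops; distribution-fidelity and
Boltzmann-identity checks use 10^4–10^5 sampled angles; oracle equivalences
use 1000 random box pairs (IoU vs pixel rasterization), 100 sample pairs
(KS statistic vs brute-force ECDF scan) and 200 random rigid transforms
(angle invariance). On this study set the classical pipeline achieves
detection precision ≈ 0.95, recall ≈ 1.0, mean absolute angle error
≈ 0.6°, and a KS p-value well above 0.05 between recovered and generating
angle ensembles — properties of the synthetic conditions, not claims about
real TEM data.

# Known limitations

* The classical backends assume bright particles on a darker background
  (`invert` flips polarity) and a single dominant particle per crop.
* Angles very close to 180° are indistinguishable from rods and are dropped
  by the rod test; laws concentrated near 180° would be censored.
* The KS comparison at a fixed significance level fails at the nominal rate
  even for a perfect pipeline, because a finite generating draw can itself
  be atypical of its law.
* Tip radial positions are truncated by the 50×50 px crop convention when
  arms extend beyond the box; tip spatial errors are therefore large even
  when angles are near-exact. The vertex, which carries the angle, is
  unaffected.
* The torque at run boundaries uses one-sided differences and is noisier
  there; empty-bin gaps split the profile.
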