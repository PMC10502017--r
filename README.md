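# origamiflex

Measuring the mechanics of dynamic DNA origami nanodevices from
negative-stain TEM micrographs.

Dynamic DNA origami devices — the canonical example being a two-arm
"hinge", ~70 nm stiff arms joined by a flexible single-stranded vertex —
act as torsional springs. Their mechanical characterization rests on the
equilibrium distribution of the hinge angle θ: by Boltzmann inversion,

    E(θ) = -kBT · ln p(θ) + const,        τ(θ) = -dE/dθ,

the angular probability distribution p(θ) yields the rotational free-energy
landscape E(θ) and torque τ(θ). Estimating p(θ) means finding hundreds of
individual, isolated, well-folded particles in micrographs and measuring
each one's angle. `origamiflex` automates that measurement as a two-stage
pipeline:

1. **Particle detection** — bounding-box proposals filtered by a confidence
   threshold (0.47), non-maximum suppression (IoU 0.3) and a
   bounding-box-size filter that removes boxes with aspect ratio > 1.5 and
   re-squares survivors to 50×50 px (boundary clutter removal).
2. **Keypoint pose estimation** — on 200×200 px particle crops, locate the
   two arm tips and the vertex under a device schema, gate keypoints at
   confidence 0.92, and measure the included angle at the vertex.

Detector and pose estimator are pluggable backend contracts (trained
neural networks can be attached externally); the package ships classical
image-processing reference backends, a synthetic micrograph generator with
exact ground truth, and evaluation tools (IoU matching, precision/recall/F1,
angle and per-keypoint spatial errors, tip-flip rate, two-sample
Kolmogorov–Smirnov comparison). Device schemas cover the plain hinge, a
hinge with a tracked nucleosome position, and two-angle four-point devices.

## Worked example

Simulate one micrograph, run both stages, and invert the angle ensemble:

```r
library(origamiflex)

cfg   <- simulationConfig(seed = 42)        # 960x960 px, 20 hinges + clutter
scene <- generateMicrograph(cfg)
scene$micrograph
#> Micrograph: 960 x 960 px, 1.4 nm/px, intensity [0.0259, 1]

boxes <- classicalDetect(scene$micrograph)
boxes <- bbfFilter(nms(filterByConfidence(boxes, 0.47), 0.3))
nrow(boxes)
#> [1] 20

crops <- cropParticles(scene$micrograph, boxes)
poses <- lapply(crops, function(cr)
  mapPoseToMicrograph(
    classicalPose(cr$image, particleId = paste0("p", cr$provenance$index)),
    cr$provenance))
poses  <- filterPoseConfidence(poses, 0.92)
angles <- vapply(poses, function(p) unname(poseAngles(p)[1]), numeric(1))
summary(angles)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   58.70   69.01   83.65   83.88   89.06  121.76

land <- boltzmannInvert(anglesToDistribution(angles, binWidth = 5))
land
#> FreeEnergyLandscape: 11/36 bins defined, max 1.39 kT, offset 1.61 kT
torque <- torqueFromEnergy(land)

tgt <- scene$truth[scene$truth$class == "target_hinge", ]
mt  <- matchDetections(boxes, boundingBoxes(cx = tgt$cx, cy = tgt$cy,
                                            w = tgt$w, h = tgt$h), 0.3)
precisionRecallF1(mt$tp, mt$fp, mt$fn)
#> DetectionMetrics: TP 20, FP 0, FN 0 | Pr 1.00, Re 1.00, F1 1.00
```

All 20 simulated hinges are detected with no false positives, and the
measured angles (here a single image, so a sparse landscape) cluster around
the generating law's 90° mean. `runPipeline()` wraps the same flow over many
images — with stage-count logging, YAML configuration and on-disk outputs —
and evaluates against ground truth when the input is simulated.

A thin command-line wrapper is installed at `exec/origamiflex` with
subcommands `simulate`, `detect`, `pose`, `characterize`, `evaluate` and
`run`, e.g.

```sh
origamiflex detect --image img.png --out labels.txt --conf 0.47 --iou 0.3
```

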