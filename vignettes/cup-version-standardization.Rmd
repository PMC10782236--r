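---
title: "Measuring acetabular cup version, and resolving its sign, from AP pelvis radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular cup version, and resolving its sign, from AP pelvis radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupversion)
```

## The clinical problem

After total hip arthroplasty (THA), the orientation of the acetabular
component — its *inclination* (lateral opening) and *version* (forward or
backward angulation) — is a major determinant of dislocation risk, impingement
and wear. On a plain anteroposterior (AP) pelvis radiograph the circular cup
opening projects as an ellipse, and the ratio of its short to long axis
encodes the magnitude of the version: under a parallel beam,

$$ \sin(\text{version}) = b / a , $$

where $a$ and $b$ are the semi-major and semi-minor axes of the projected
ellipse. The projection is, however, blind to the *sign* of the version: an
anteverted cup (opening tilted anteriorly) and a retroverted cup (tilted
posteriorly by the same amount) cast identical shadows. Retroversion is the
clinically dangerous configuration, and CT — the usual arbiter — costs dose,
money and is useless for retrospective film archives.

This package implements a landmark-based 2-D method that (i) standardizes the
single-film version measurement against pelvic pose using two internal pelvic
references, producing a *pair* of candidate angles (an anteversion candidate
$\theta^+ \ge 0$ and a retroversion candidate $\theta^- \le 0$), and (ii)
resolves the sign by comparing the candidate pairs measured on **two** AP
films taken with different pelvic orientations: the physically correct
candidate re-measures the same cup on both films, while the mirror candidate
drifts with pose, so the candidate pair with the smaller inter-film difference
identifies the truth.

## Inputs

No pixel data are processed. A film is a set of 2-D landmark annotations:

* at least 5 points on the cup-opening rim;
* the left and right radiographic **teardrops** — their join is the
  inter-teardrop line (ITL), the horizontal pelvic reference;
* the mid-point of the **sacrococcygeal junction** (scj) and the center of the
  upper pole of the **pubic symphysis** (ps) — their join is the *pelvic
  radiographic axis*, the standardization reference;
* the operated side and a mm-per-unit scale.

Film coordinates are $x$ toward the patient's left and $y$ superior; the beam
axis $z$ points anteriorly, out of the film. All angles are degrees.

## The measurement chain

### 1. Ellipse fit

`fit_ellipse()` fits the conic $Ax^2+Bxy+Cy^2+Dx+Ey+F=0$ to the rim points by
direct least squares under the ellipse-guaranteeing constraint $4AC-B^2=1$,
using the numerically stable partitioned eigensystem with internal centering
and isotropic scaling. The constrained fit matters because an annotated rim is
often a short noisy arc, for which an unconstrained conic fit can return a
hyperbola. Geometric parameters (center, $a \ge b$, major-axis orientation
$\psi \in [0,180)$) come from the closed-form eigendecomposition of the
quadratic part; for an exact circle the orientation is reported as 0 by
convention so results are deterministic.

### 2. Pelvic pose from the two internal references

A single AP film of a bilaterally symmetric pelvis exposes two pose
parameters:

* **In-plane rotation** (roll about the beam): the signed angle of the
  projected pelvic axis from the film vertical — for a symmetric pelvis this
  equals the tilt of the ITL from the film horizontal.
* **Sagittal flexion/tilt**: recovered from foreshortening of the pelvic
  axis. With $r$ the measured ratio of projected axis length to ITL length,
  and a 3-D anatomy prior providing the axis length $L$, the neutral sagittal
  axis angle $\alpha$ and the inter-teardrop distance $d$, orthographic
  projection gives
  $$ r(\varphi) = \frac{L}{d}\,\cos(\varphi - \alpha), $$
  where $\varphi$ is the flexion. The ITL is the right normalizer because it
  is the one transverse internal length unaffected by flexion and roll. The
  equation is solved on the branch $\varphi < \alpha$, which is unique across
  the clinically plausible range ($\alpha \approx 29^\circ$ for the default
  anatomy). Ratios beyond the attainable maximum are clamped within a 2%
  tolerance (annotation noise) and are an error beyond it.

This is an explicit, documented choice: flexion cannot be observed on one
film without an anatomical prior, so the prior — `pelvis_model()` — is a
first-class, overridable object rather than a hidden constant.

### 3. The paired standardized versions

From the fitted ellipse the unsigned planar version is
$v = \arcsin(b/a)$. The 3-D cup-plane normal is reconstructed up to the sign
of its out-of-film component: in-film direction perpendicular to the major
axis (oriented laterally for the declared side), magnitude $\cos v$;
out-of-film component $\pm\sin v$. Both candidates are rotated back through
the estimated roll and flexion into the standardized pelvic frame, and each
candidate's standardized version is the signed angle between the cup plane
and the standardized coronal plane ($\arcsin$ of the de-rotated normal's
anterior component). At zero flexion and roll the pair is exactly $(+v, -v)$;
under flexion the pair becomes asymmetric, which is precisely the information
the two-film comparison exploits.

### 4. The two-film decision

`decide_version()` computes the inter-film difference of the anteversion
candidates and of the retroversion candidates. The smaller difference marks
the physically correct interpretation; the final angle is the signed mean of
the winning pair, and the label follows its sign.

Two deliberate refinements beyond the bare rule:

* **Indeterminacy is a first-class outcome.** Differences within
  `tie_tol_deg` (default 0.1°) of each other with conflicting signs yield
  `"indeterminate"`: the films were too similarly posed to separate the
  candidates. The package also warns when the two films' estimated 3-D
  pelvic-axis directions differ by less than `min_separation_deg` (default
  1°), operationalizing the requirement that the films have different
  orientations.
* **Crossed pairings.** When a small true version combines with flexion, the
  cup can pass through the face-on configuration between the two films, and
  the true measurement then swaps between the anterior and posterior
  candidate slots. The decision therefore evaluates all four cross-film
  candidate pairings and takes the most self-consistent one. Whenever every
  candidate keeps its nominal sign — the ordinary regime, including the
  package's reference worked example — this reduces exactly to comparing the
  two slot-wise differences.

## The synthetic-radiograph generator

`project_film()` forward-projects a parameterized 3-D pelvis and a circular
cup opening: pose rotations are applied as roll ∘ obliquity ∘ flexion
($R_z\,R_y\,R_x$), projection is orthographic (parallel beam, the same
assumption the measurement model makes; a point-source perspective with a
configurable source-to-film distance is available purely to probe model
mismatch), and isotropic Gaussian noise in film mm is added to every
projected landmark, emulating annotation click error — the dominant error
source for landmark methods. Runs are bit-reproducible given a seed, with
per-film sub-streams.

Default anatomy (one config block, `pelvis_model()`): inter-teardrop distance
124 mm; scj at (0, 45, −35) mm and ps at (0, −55, 20) mm relative to the
ITL mid-point, giving a 114 mm pelvic axis with a neutral sagittal angle of
28.8° and a neutral axis ratio of 0.81; cup radius 25 mm with the opening
center 48 mm lateral, 18 mm superior, 8 mm anterior to the teardrop. These
are mid-range adult dimensions chosen once as documented constants.

What the generator deliberately does **not** emulate: pelvic asymmetry (the
standardization assumes a symmetric pelvis — a known limitation of the
method itself), bone contours and rim-detection difficulty, osteophytes,
magnification calibration error, and photorealistic radiograph appearance.
Passing the synthetic validation therefore demonstrates the *geometric
self-consistency* of the measurement chain and the decision rule, not
clinical accuracy on real films, which additionally depends on annotation
quality and how far a patient's anatomy departs from the symmetric prior.

## Validation surfaces and problem sizes

The package validates itself on three surfaces (sizes chosen to keep the full
suite inside a couple of minutes on one core while covering the clinically
relevant envelope):

* **Recovery grid** (`recovery_grid()`): true inclination {30, 40, 50}° ×
  signed version −25…+25° in 5° steps × film-1 flexion {−10, 0, +10}° ×
  roll {−5, 0, +5}°, film 2 flexed 8° further — 297 noiseless two-film
  pipelines. Expected: 100% sign recovery and winning-angle error below 0.5°
  wherever |version| ≥ 3° (the sign of a near-zero version is not a
  meaningful target; exactly face-on cups project to a degenerate segment and
  are flagged, not measured).
* **Ellipse fit grid**: 192 noiseless parameter combinations recovered to
  better than 10⁻⁶ relative; with 0.2 mm noise on 60 rim points, axes are
  recovered within 0.5 mm.
* **Noise study** (`noise_study()`): 200 replicates per level at annotation
  noise 0, 0.5, 1, 2 mm (true version +15°, films at −5°/+8° flexion), with
  common random numbers across levels. Misclassification is 0 without noise
  and non-decreasing in noise; at 2 mm — pessimistic for modern PACS
  annotation — it stays in the low percent range.

## Numerical choices

* Conic coefficients are normalized to $A + C = 1$; algebraic residuals are
  reported per point.
* Degenerate rims (collinear or coincident points, fewer than 5 points)
  raise classed errors; a face-on cup in the simulator raises a
  `degenerate-projection` warning.
* A circular projected rim returns planar version 90° with a warning flag
  rather than an error: the functions stay total, plausibility is the
  caller's decision.
* Circle orientation ties and the flexion branch choice are fixed as above;
  all angle folds are documented in the function help.

## Limitations

Single-film flexion estimation inherits the anatomy prior's bias: if a
patient's axis-to-ITL proportions differ from the model, the flexion estimate
(and with it the exact candidate angles, though typically not the two-film
sign decision) shifts. Obliquity (axial rotation) is simulated but not
corrected — it perturbs the ITL normalizer. The decision needs two films with
genuinely different pelvic poses; with near-identical poses the method
reports indeterminate rather than guessing. None of this is hidden: the
prior, tolerances and thresholds are arguments with documented defaults.
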