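---
title: "Segmenting subretinal fibrosis by optic-axis uniformity in PS-OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting subretinal fibrosis by optic-axis uniformity in PS-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoctfib)
```

## The problem and the signal

Subretinal fibrosis is a common end stage of neovascular age-related
macular degeneration.  On conventional OCT it hides inside subretinal
hyperreflective material that can equally be blood, fibrin or a
disrupted retinal pigment epithelium (RPE).  What distinguishes mature
fibrotic tissue is its collagenous microstructure: it is *form
birefringent*, so polarization-sensitive OCT (PS-OCT) can see it.

The discriminating signal used here is not the retardation magnitude
(thin lesions accumulate too little) but the *uniformity of the optic
axis orientation*.  Birefringent tissue has a well-defined slow axis
that is locally constant over a patch; polarization-maintaining tissue
and depolarizing tissue show an axis value that is essentially random
from pixel to pixel once the birefringence of everything anterior to
them has been removed.  Segmenting fibrosis therefore reduces to
finding regions of low *circular variance* in a depth-averaged axis
orientation map of the posterior retina.

## Instrument model and parameter extraction

The package models a single-input-state PS-OCT system: a vertically
polarized beam $(0,1)^T$ passes a quarter-wave plate at 45°, the ocular
media, is reflected, and returns through the same elements to a
two-channel polarization-sensitive detection unit.  Every tissue layer
is treated as a linear retarder

$$
J(\delta,\theta)=
\begin{pmatrix}
\cos^2\theta+\sin^2\theta\, e^{-i\delta} &
\cos\theta\sin\theta\,(1-e^{-i\delta})\\
\cos\theta\sin\theta\,(1-e^{-i\delta}) &
\cos^2\theta\, e^{-i\delta}+\sin^2\theta
\end{pmatrix},
$$

unitary and symmetric, with `jones_linear_retarder()` as the package
primitive.  From the measured channel amplitudes $A_H, A_V$ and phase
difference $\Delta\Phi$, `extract_polarization()` computes per voxel

$$
R \propto A_H^2+A_V^2,\qquad
\delta=\arctan(A_V/A_H)\in[0°,90°],\qquad
\theta=(\pi-\Delta\Phi)/2 \in [-90°,90°),
$$

and `compute_dopu()` forms the degree of polarization uniformity from
kernel-averaged normalized Stokes vectors; DOPU < 0.8 marks the
depolarizing RPE.

Two conventions deserve a note because the defining equations fix the
formulas but not the signs:

* **Channel ordering.** With the quarter-wave plate at +45°, the axis
  of a forward-modeled retarder is recovered with the correct sign when
  $\Delta\Phi \equiv \arg E_V - \arg E_H$.  The opposite ordering
  negates all axes.  Either choice is internally consistent (axes are
  relative anyway — the fiber optics add an unknown global offset, so
  every downstream statistic in the package is offset-invariant), but
  the package fixes this one so that phantom ground truth is recovered
  verbatim.
* **What "double-pass retardation" means numerically.** Evaluating the
  full detection chain symbolically shows that
  $\arctan(A_V/A_H)$ equals the retardation *parameter of the per-pass
  Jones matrix* (the round-trip operator is its square).  All
  retardation values exposed by the package — phantom layer specs,
  sampled references, compensated volumes — are therefore this measured
  double-pass value, and the forward model applies the quoted value
  once per pass.  Under this bookkeeping a cornea specified as 20°
  extracts as exactly 20° at a surface just below it, and the
  compensation-accuracy figures below reproduce the published
  magnitudes; halving per pass would halve every measured value and is
  inconsistent with that behavior.

## Compensation of anterior birefringence

Everything anterior to the lesion — cornea, retinal nerve fiber layer
(RNFL), Henle's fiber layer (HFL) — is birefringent too.  By the Jones
reversibility theorem, any stack of linear retarders with negligible
diattenuation is equivalent *in double pass* to one linear retarder, so
the whole anterior segment can be measured at a reference surface just
below the HFL (the IS/OS junction, or the lesion top where the IS/OS is
destroyed): the extracted $(\delta_R,\theta_R)$ there *are* the
effective anterior retarder.  `compensate()` then rebuilds each voxel's
joint retarder from its extracted values and conjugates it with
$J(-\delta_R,\theta_R)$ placed adjacent to the quarter-wave plate on
both sides, exactly mirroring the measurement equation, and re-extracts
$(\delta,\theta)$.

Placement matters: the compensator must sit *outside* the joint sample
retarder (adjacent to the wave plate).  With the compensator placed
inside, the residual axis error of the layered-stack approximation
grows fourfold; the implemented form reproduces the expected bound.

**Single-step accuracy.** A two-layer anterior stack is not a single
linear retarder in single pass, so single-step compensation leaves a
small axis error in the posterior layer.  `axis_error_sweep()`
quantifies it by forward-modeling cornea (20°) + HFL (14°) at all
relative axis orientations and running the package's own extraction and
compensation:

```{r sweep, eval = FALSE}
sw <- axis_error_sweep(delta_cornea = 20, delta_hfl = 14)
sw$max_error_deg   # 1.24 degrees at the default dense sweep
```

The maximum error is 1.24° (independent of the posterior retardation),
the two-step iterative variant (`compensate_iterative()`: cornea at the
ILM, then HFL at the IS/OS) is exact to machine precision, and the
extra circular variance the single-step approximation injects into a
5×5 kernel along a circle of 1.5 mm radius about the fovea — where the
phantom's HFL retardation peaks — is about $2\times10^{-6}$
(`added_variance_on_circle()`), negligible against the 0.21 seed
threshold.  Single-step compensation is therefore the pipeline default.

**Reference sampling is deliberately not smoothed.** An obvious
"improvement" — median-filtering the $(\delta_R,\theta_R)$ maps
transversally before compensating — turned out to be actively harmful
on speckled phantoms: smoothing correlates the small per-column
residual compensation errors across neighboring A-scans, which converts
the polarization-maintaining background from axis-random (kernel
variance ≈ 0.82) into coherent patches (≈ 0.44) that masquerade as
fibrosis.  With the raw per-column reference the residuals are
independent from column to column and the background stays random.
`sample_reference(smooth =)` retains the option; the default is no
smoothing.

## From volumes to lesion areas

1. **Surfaces.** `find_surfaces()` provides phantom-adequate ILM and
   reference surfaces (transversally smoothed reflectivity, persistent
   threshold crossing for the ILM, first strong rising edge for the
   reference so that the bright RPE cannot capture it).  Clinical
   volumes should import externally segmented surfaces via
   `read_surfaces()`.  The lower integration boundary
   (`build_lower_boundary()`) sits 100 px below the reference at the
   map center, decaying to 50 px at the edges along a 2D Gaussian bump
   ($\sigma$ = a quarter of the shorter map dimension, configurable) —
   deep enough to integrate the lesion, shallow enough to exclude the
   birefringent sclera.
2. **Depth-averaged axis map.** `depth_averaged_axis()` averages
   $e^{i2\theta}$ unweighted over the integration span, excluding
   DOPU < 0.8 voxels (RPE) and voxels below twice the intensity noise
   floor (`estimate_noise_floor()`: mean intensity of the top image
   margin, the conventional signal-free region).  Angles are doubled
   because axes are $\pi$-periodic; this also makes the map immune to
   the ±90° wrap and equivariant under the unknown global axis offset.
3. **Variance map and segmentation.** `circular_variance_map()`
   computes $v = 1-\lvert\overline{e^{i2\theta}}\rvert$ in 5×5 kernels
   (valid neighbors only, cropped at borders).  `detect_seeds()` keeps
   8-connected components of $v<0.21$ strictly larger than 100 px
   (≈ 0.019 mm² at the clinical 187.5 µm²/px); `region_grow()` expands
   them to the fixpoint of $v<0.36$, implemented as the components of
   the sub-threshold set that contain a seed (provably the same
   fixpoint, computed in one labeling pass).  Invalid pixels never
   seed nor grow.  `lesion_area()` converts pixel counts with the map
   geometry; `lesion_repeatability()` summarizes repeated measurements
   with the population-SD convention.
4. **Likelihood maps.** `likelihood_map()` reruns the segmentation 18
   times with $th_1 = 0, 0.05, \dots, 0.85$ and $th_2 = th_1 + 0.15$,
   recording per pixel $L_h = 1 - th_2^*$ for the smallest segmenting
   threshold.  Masks provably nest across the sweep, so $L_h$ is
   well-defined.  `variance_bscan()` applies the same statistic in the
   B-scan plane with a 41×41 kernel to visualize the depth "columns"
   of uniform axis in severe fibrosis.

Thresholds ($th_1 = 0.21$, $th_2 = 0.36$), the DOPU cutoff 0.8 and the
2× intensity factor are the published operating point and are exposed
in `segmentation_params()`.  "Larger than 100 pixels" is read as
strictly greater; both variance thresholds are strict.  8-connectivity
was chosen for labeling and growth so diagonal lesion necks are not
split; both choices are stated rather than silently assumed because the
originals leave them open.

## The digital eye phantom

`phantom_spec()` / `generate_phantom()` build a layered eye with full
ground truth so every stage is testable without clinical data:

* a global corneal retarder (default 20° at 30°);
* an RNFL whose axis is the azimuth about an optic-nerve-head center
  4.2 mm nasal of the fovea and whose retardation (default peak 6°)
  decays away from it;
* an HFL doughnut with radial axis about the foveal center and peak
  double-pass retardation 14° at 1.5 mm eccentricity;
* lesion discs with locally uniform axis (default one disc, radius
  1.1 mm ≈ 3.8 mm², cumulative double-pass retardation 30° across a
  40 px depth span) — a medium-sized lesion, comparable to published
  severe-fibrosis examples (7.9 mm²);
* a depolarizing RPE band implemented as an independent random linear
  retarder per voxel (uniform axis, uniform retardation) — enough to
  drive kernel-averaged DOPU below 0.8 in pure Jones formalism;
* fully developed speckle as a *shared* circular complex Gaussian
  factor on both channels (speckle randomizes amplitude and phase but
  preserves the polarization state), plus independent additive complex
  Gaussian channel noise, default `noise_sd = 0.003`, which puts the
  bright reference band ≈ 38 dB above the intensity noise floor —
  representative of a 98 dB-sensitivity spectral-domain system.

The default desk-scale geometry is 256 × 64 × 512 voxels over the
clinical 8 × 6 mm field (axial pitch 1.39 µm); the full 1024 × 250 grid
is available by configuration.  Identical seeds give bit-identical
volumes; the ground truth is seed-independent.

**What the phantom does and does not emulate.** It reproduces the
polarization physics (unitary Jones chains, measured-value bookkeeping,
speckle statistics of a single scattering phase), layered anatomy with
tilt, and the specific confounders the algorithm must overcome
(inherited anterior axis, depolarizing RPE, noise-dominated background
axis).  It does not emulate eye motion, vessel shadows, RPE atrophy,
partially developed speckle, diattenuation, or axis orientation that
varies with depth inside a lesion — so passing tests demonstrate
algorithmic correctness under the stated model, not clinical
performance.  One behavior deserves emphasis: the background's axis
randomness in polarization-maintaining tissue is *noise-driven* (after
perfect compensation the V channel carries only noise, whose phase is
uniform).  A noise-free phantom therefore has no meaningful background
axis statistics, which is physically correct and is why the noise-free
configurations are used only for exactness checks.

## Numerical choices and degenerate inputs

* Angles are radians internally, degrees at user-facing boundaries
  (function arguments, CSV/JSON/PNG exports).
* Voxels with zero signal in both channels are flagged in a separate
  boolean mask, never sentinel-valued; invalid axis pixels enter the
  variance map as "never segmentable" rather than as fake low variance.
* Kernels are cropped at borders with valid-neighbor averaging — no
  padding value can leak into the statistics.
* The likelihood sweep rounds its thresholds to 12 decimals so binary
  round-off in `seq()` cannot cross the strict inequalities.
* Surface finding: edge positions are corrected for the half-window
  advance of the depth smoothing; columns whose peak smoothed
  reflectivity stays below 4× the noise floor are invalid rather than
  guessed.
* Out-of-range or dead reference columns are flagged and passed
  through uncompensated; they are excluded from all en-face statistics
  rather than interpolated.

## Problem sizes used by the test suite

The routine suite runs phantoms of 96 × 32 × 220 voxels; the end-to-end
recovery checks use the full desk-scale default (256 × 64 × 512, three
speckle seeds), where the pipeline recovers the default lesion with
Dice ≈ 0.95, area within 10% of truth, and a seed-to-seed area SD of
about 1%.  The sweep behind the compensation-accuracy figure evaluates
25,920 axis configurations at quarter-degree resolution.

## Known limitations

* The boundary of a segmented lesion is systematically eroded by about
  one variance-kernel half-width, because edge kernels mix random
  background pixels; the relative area deficit grows as lesions shrink
  or sampling coarsens.  At the desk-scale default it is ≈ 8–10%; at
  clinical sampling it is a few percent for medium lesions.
* The built-in surface finder is phantom-grade.  Disrupted anatomy
  (the nAMD case) needs externally segmented surfaces, as the module
  interfaces anticipate.
* Scleral birefringence near the optic nerve head produces genuine
  low-variance regions; the ROI polygon (`roi_mask()`) is the intended
  guard, as in the original procedure.
* Axis orientation is assumed constant with depth inside a lesion;
  depth-resolved axis analysis would require iterative per-layer
  peeling, which is out of scope.
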