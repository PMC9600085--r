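---
title: "Low-dose CT noise and its dosimetric impact on adaptive proton therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-dose CT noise and its dosimetric impact on adaptive proton therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldctadapt)
```

`ldctadapt` studies a simple question with clinical stakes: if the daily CT
used for online plan adaptation of head-and-neck proton treatments is
acquired at a fraction of the standard tube current, does the extra image
noise change the adapted dose? The package implements the full measurement
and evaluation chain on a synthetic digital head phantom, so every stage is
reproducible and testable offline. This vignette documents the models, the
parameter choices and their rationale, the numerical conventions, and what
the synthetic setting can and cannot show.

## The per-HU Gaussian noise model

A CT scanner run twice over the same, perfectly registered object — once at
the standard current and once at a reduced current — yields a paired sample:
for every CT number $h$ in the standard image, the co-located voxels of the
low-dose image form an empirical distribution. Reconstruction noise is well
approximated as Gaussian per CT number, so the model is a lookup table

$$ h \;\mapsto\; \bigl(\mu(h),\, \sigma(h)\bigr), $$

estimated by the *sample mean and sample standard deviation* (with the
$n-1$ denominator) of the paired voxels in each 1-HU bin.
`calibrate_noise()` deliberately uses sample statistics rather than
least-squares Gaussian fits to per-bin histograms: the fit result depends on
the histogram binning, which would need hand-tuning per CT number because
bin populations vary over orders of magnitude, while the sample estimators
are binning-free. `gaussianity_report()` exists to *check* the Gaussian
assumption (it fits a Gaussian to one bin's histogram and reports the
coefficient of determination next to the sample moments), not to calibrate.

Choices the calibration exposes, with defaults:

* **Bin width, 1 HU.** CT numbers are integers; finer bins are meaningless,
  coarser bins would mix genuinely different attenuation levels.
* **Minimum bin population, 100 voxels.** Below that the sample standard
  deviation is too uncertain to be useful (relative standard error
  $\approx 1/\sqrt{2n} > 7\%$). Under-populated bins are filled by linear
  interpolation in $h$ between the nearest well-populated bins (constant
  continuation at the ends) and flagged `interpolated` in the table.
* **Slice selection: 11 central sagittal slices** (the central slice and 5
  to each side). This restricts the calibration to a region that still
  contains essentially all CT numbers of the object while keeping the
  voxel count moderate; it matches how the phantom pair would be analyzed
  on a real scanner. Tests that need maximal statistics pass an explicit
  slice list instead.
* **The reference image is treated as noise-free**: all paired variance is
  attributed to the low-dose image. In reality the standard-protocol image
  carries its own (much smaller) noise, so the calibrated $\sigma$ is
  really the quadrature sum of both — a conservative convention, applied
  consistently. The synthetic generator can emulate either convention
  (`simulate_paired_scan()` at 400 mA produces the small residual noise
  the square-root law predicts; calibration tests may use a noise-free
  reference instead).

### Tube-current scaling

The photon count behind each projection sample is Poisson with mean
proportional to the tube current $I$, so the CT-number noise scales as

$$ \sigma(I) \;=\; \sigma_0 \sqrt{I_{\mathrm{ref}} / I} . $$

`fit_current_scaling()` fits $\log\sigma$ against $\log I$ (free exponent,
nominally $-0.5$; a fixed-exponent mode is provided), and
`noise_anchor()` carries the anchor the package uses throughout:
$\sigma_0 = 20$ HU with a $-0.45$ HU mean shift at HU 0 for the 10 mA
protocol — the noisiest setting of the built-in seven-protocol table
(400 mA/166 mGy down to 10 mA/4.2 mGy at 140 kV, pitch 0.6, 2.5 mm slices;
CTDI_vol is linear in current, a factor of 40 between the extremes).

The anchor pins $\sigma$ at HU 0 only. How $\sigma$ varies with $h$ in the
*synthetic ground truth* is a free modelling choice; the generator uses a
constant $\sigma$ over HU (the simplest assumption consistent with the
anchor), while the calibration side makes no such assumption and estimates
every bin separately.

### Synthesis and its QA

`synthesize_low_dose()` redraws every voxel independently from
$N(\mu(h), \sigma(h))$ of its input CT number, using a single vectorized
standard-normal stream in voxel storage order derived from one seed —
reproducible, and independent of any per-bin iteration order. Stored CT
volumes are integral, so the assigned values are re-quantized
half-away-from-zero and clamped to $[-1024, 3071]$ HU.

The reassignment QA (`qa_synthesis()`) guards against silent coverage gaps
in the lookup table: it requires that at least 99.9 % of voxels received a
new CT number. The comparison is made on the **raw assigned values**
(`integerize = FALSE`), not on the re-quantized ones: with $\sigma = 20$ HU
about 2 % of integerized draws coincide with the original integer CT number
by chance, which would mask exactly the failure mode the QA is looking for.
A freshly drawn continuous value equals the original with probability zero,
so on the raw values the QA cleanly separates "every voxel was resampled"
(fraction ≈ 1) from "some voxels were skipped".

Limitations, stated plainly: noise is spatially white by construction
(per-voxel independent redraws). Real CT noise is correlated by the
reconstruction kernel, direction-dependent (photon starvation), and
scanner-specific; none of that is modelled, so conclusions transfer to a
real scanner only after calibrating that scanner. Streaks, rings and
beam-hardening are likewise out of scope.

## The digital head phantom

`generate_head_phantom()` builds a parametric head-and-neck CT from
geometric primitives: a cranial ellipsoid with bone shell and brain, a
frontal sinus air cavity, a neck cylinder with vertebral column (bone
annulus), spinal canal and an air-filled larynx lumen; compartments sit at
−1000 / ~30 / ~40 / ~1000 HU with 5 HU Gaussian texture (seeded,
re-integerized). The structure set holds nested high-risk and low-risk CTVs
in the neck, spinal cord, brainstem, both parotids, pharyngeal constrictors
and larynx. The default grid is 128×128×64 at 2×2×2.5 mm, centered on the
origin, and the whole phantom is mirror-symmetric about the mid-sagittal
plane — which turns a physical symmetry into a strong end-to-end test of
the dose engine. Because every structure is an analytic primitive, voxel
counts can be checked against closed-form volumes.

The phantom stands in for a physical head phantom and for patient virtual
CTs alike; it does not attempt anthropomorphic realism (no heterogeneous
bone marrow, no dental artifacts, no air-tissue interfaces finer than the
grid).

## The analytic dose surrogate

The dose engine is explicitly a surrogate for Monte Carlo particle
transport. It preserves the properties this study exercises — exact
linearity in spot weights, HU sensitivity entering *only* through
water-equivalent path length, and millimetre-scale lateral and distal
gradients — and nothing else (no nuclear halo, no scatter tails, no
deliverability constraints).

* **HU → RSP.** Piecewise linear through (−1024, 0.001), (−940, 0.001),
  (0, 1.0), (1000, 1.54), (3071, 2.60), constant beyond the ends. The flat
  air segment mirrors clinical stoichiometric curves, which are
  insensitive below lung densities; it matters here because a steep
  segment starting at −1000 HU would rectify zero-mean HU noise in the air
  around the patient (RSP cannot go below air) into a systematic WEPL
  increase of order half a millimetre over the upstream air path — a
  geometry artifact, not the noise physics under study.
* **WEPL.** Exact Siddon voxel traversal (`trace_wepl()`, and a per-voxel
  radiological-depth kernel for whole dose grids): the sum over traversed
  voxels of geometric intersection length times voxel RSP. This is where
  the central-limit behaviour lives: over a path of $N$ voxels the
  relative WEPL spread from i.i.d. HU noise shrinks like $1/\sqrt{N}$,
  which is why 20 HU of voxel noise barely moves proton range.
* **Bragg curve.** A parametric closed form: a rising entrance plateau,
  switched off by a sigmoid just proximal to a Gaussian peak at the
  nominal range. The Gaussian width (2.664 mm) gives an 80–20 % distal
  falloff of 3 mm water; the peak-to-entrance ratio is ≈ 3; dose is zero
  beyond the range plus the falloff width; the curve is renormalized to
  peak 1 at the nominal range.
* **Range–energy.** $R = \alpha E^{p}$ through 65 MeV → 37 mm and
  225 MeV → 325 mm water ($p \approx 1.75$) — implementation constants at
  standard clinical magnitudes. Spot σ in air interpolates linearly from
  6.4 mm at 65 MeV to 2.5 mm at 225 MeV; in depth,
  $\sigma^2(z) = \sigma_{\mathrm{air}}^2 + (0.022\,z)^2$ adds a linear
  multiple-scattering term (~2 mm at 100 mm depth).
* **Geometry.** Gantry 0° has the source anterior; angles increase
  clockwise seen from the feet, so the default three-field arrangement
  60°/180°/300° is two anterior obliques plus a posterior-anterior field.
  Each beam carries a 40 mm water-equivalent range shifter. Beams are
  parallel (no divergence), spots live on a 5 mm lateral grid with 5 mm
  water-equivalent layer spacing covering the target's beam's-eye-view
  projection plus a 5 mm margin.
* **Spot placement ties.** A spot whose nominal axis lies exactly on a
  voxel-boundary plane would have its traversed column decided by an
  arbitrary floating-point tie-break, which breaks mirror symmetry between
  paired oblique beams. Placement therefore averages the target
  entry/exit WEPL over a symmetric 4-ray bundle at ±1 mm diagonal offsets
  around the axis — a finite spot width, and a tie-break-free rule that is
  closed under mirroring.
* **Dose-influence matrix and adaptation.** `build_dij()` stores each
  beamlet's unit-weight dose column sparsely (per-column truncation at
  $10^{-4}$ of the column maximum; reconstruction error below 0.5 % of the
  maximum dose). `adapt_weights()` minimizes a quadratic one-sided penalty
  (per-voxel underdose/overdose for targets, mean-overshoot for parallel
  OARs) over non-negative weights by projected gradient descent with
  backtracking, so the objective trace is non-increasing by construction.
  This optimizer is a stand-in for a clinical TPS re-optimization, and is
  labelled as such; its defaults (uniform voxel weighting, penalty weights
  100/50/1 for HR-CTV / LR-CTV / OARs) are package choices.

Doses are carried directly in Gy(RBE); no separate RBE factor is applied.
The default dose grid is the CT grid (2×2×2.5 mm on the default phantom);
1×1×2.5 mm grids are supported through `resample_to_grid()`/`grid3d()`.

## Evaluation conventions

* **DVH.** $D_x$ is the largest dose $d$ such that at least $x\%$ of the
  structure volume receives $\ge d$, computed by counting sorted voxel
  doses without interpolation (lower-bound convention — exactly testable
  against a brute-force oracle). $D_{1cc}$ is the minimum dose of the
  $\lceil 1\,\mathrm{cc} / v \rceil$ hottest voxels (ceiling errs toward
  "at least 1 cc"); structures smaller than 1 cc fall back to $D_{min}$
  with a warning.
* **Percentage differences.** For target $D_x$ the denominator is the
  prescription dose (70 / 57 Gy(RBE) for HR/LR CTV), so differences live on
  the same scale as clinical goals like $D_{98} \ge 95\%$; for OAR metrics
  the denominator is the reference value. Both conventions are selectable
  and recorded in the output.
* **Gamma.** Default 2 % (global, of the reference maximum) / 2 mm, with a
  10 % low-dose threshold — the common convention, recorded in every
  result. The minimization searches offsets within 3× the distance
  criterion, visited in order of increasing radius with early termination
  (termination is exact: once the pure distance term exceeds the current
  best gamma no further offset can win), sampling the evaluated dose by
  trilinear interpolation at 0.2 mm steps. A deliberately slow exhaustive
  1D oracle ships in the test suite. Gamma is asymmetric in
  (reference, evaluated) and its pass rate is monotone in the criteria;
  both properties are tested.
* **Dice.** $2|A \cap B| / (|A| + |B|)$; two empty masks are defined to
  have Dice 1. Contour-similarity experiments propagate the two CTVs and
  the union of all OARs through two deformation fields (ground-truth
  stand-ins — the package consumes or constructs fields, it does not solve
  deformable registration) and compare the propagations.

## The fraction experiment

`run_fraction_experiment()` evaluates each protocol against the clean
reference with the **same plan and the same contours** on both volumes:
build/calibrate the lookup table, synthesize + QA, compute dose on clean
and low-dose volumes, report DVH percentage differences plus per-beam and
combined gamma. Holding the plan fixed isolates the effect of image noise
on the dose calculation, which is the quantity with a clean interpretation
at phantom scale; an optional `adapt = TRUE` mode additionally re-optimizes
beamlet weights on each volume through the dose-influence matrix, so the
adaptation path itself is exercised. The plan is normalized so the HR-CTV
median dose equals its prescription on the clean volume. No monotone trend
of the differences with protocol dose is asserted anywhere: the differences
are noise-driven and small, and the experiment only bounds them.

Everything downstream of the master seed is deterministic: protocol-level
seeds are derived arithmetically, all random draws are vectorized under
`set.seed`, and two runs with the same configuration produce identical
reports (this is itself a test).

### Problem sizes

The default phantom (1,048,576 voxels), a ~3,000-spot three-field plan and
the full per-protocol chain (calibration on a simulated 11-slice pair,
synthesis, two dose calculations, four gamma evaluations) run in well under
a minute on one CPU; the test suite uses a coarser 64×64×32 phantom for
pipeline-level checks and reserves the full grid for the headline
experiment. These sizes were chosen so that Monte-Carlo tolerances
(2 % on a calibrated σ at $10^5$ voxels, 3 % on per-bin round trips at
$10^4$ voxels/bin) are comfortably resolved.

## What passing tests do and do not show

The synthetic study demonstrates, under white per-voxel Gaussian noise on a
piecewise-constant phantom with an analytic beam model: calibration
recovers the generating noise parameters without bias; synthesis passes the
reassignment QA; and the dosimetric impact of even the noisiest protocol is
bounded by small fractions of the clinical goal scale, because WEPL
averages the noise along each beam path. It does **not** show that a
particular clinical scanner's low-dose images are safe to adapt on: real
noise is correlated and object-dependent, deformable registration (out of
scope here) contributes its own geometric uncertainty, and the dose engine
is a surrogate. The package's role is to make the evaluation chain itself
transparent, deterministic and verifiable, so that replacing the synthetic
inputs with measured ones is a data exercise, not a software one.
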