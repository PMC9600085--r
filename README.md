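# ldctadapt

Low-dose CT noise modelling and dosimetric evaluation for adaptive proton
therapy, at desk scale.

Online plan adaptation needs an image of the day's anatomy, and daily CT
imaging adds dose to healthy tissue — the very thing proton therapy tries to
minimize. Lowering the tube current cuts the imaging dose proportionally
(CTDI_vol ∝ I at fixed kV and pitch) but raises image noise, which could in
principle degrade the two ingredients of adaptation: contour propagation and
dose calculation. `ldctadapt` provides a tested, reproducible pipeline for
quantifying that trade-off:

* **Noise model.** From a paired standard/low-dose scan of the same object,
  each CT number `h` of the reference image maps to the empirical
  distribution of co-located low-dose CT numbers; the noise is well described
  as Gaussian, so a lookup table `h → (μ(h), σ(h))` of per-bin sample means
  and standard deviations captures it. Photon counts are Poisson in the tube
  current, so `σ(I) = σ₀ √(I_ref / I)`; the lowest-dose anchor is
  σ = 20 HU (mean shift −0.45 HU) at HU 0 for 10 mA. Synthetic low-dose
  volumes are produced by redrawing every voxel from
  `N(μ(h), σ(h))`, with a QA check that ≥ 99.9 % of voxels received a new
  CT number.
* **Dose surrogate.** An analytic spot-scanning pencil-beam engine:
  piecewise-linear HU → relative stopping power, exact Siddon ray tracing
  for water-equivalent path length (WEPL), a parametric Bragg depth-dose
  curve, lateral Gaussian spots (σ² = σ_air² + depth broadening), a sparse
  dose-influence matrix `D_ij`, and projected-gradient re-weighting of
  beamlets against one-sided quadratic dose objectives. It deliberately
  replaces Monte Carlo transport while preserving linearity in spot weights,
  WEPL-mediated HU sensitivity, and mm-scale dose gradients.
* **Evaluation.** DVH metrics (D98, D2, Dmean, Dmax, D_1cc), percentage
  differences against prescription or reference, the Dice coefficient, and
  the gamma index (default 2 %/2 mm, global normalization, 10 % low-dose
  threshold) with pass rates per beam and combined.
* **Synthetic data.** A parametric digital head phantom (128×128×64 at
  2×2×2.5 mm) with skull, brain, sinus, vertebral column, spinal canal and
  larynx, nested high/low-risk CTVs and six OARs, plus smooth random
  deformation fields — so the whole pipeline runs and is tested without any
  external data.

## Worked example

```r
library(ldctadapt)
tab <- builtin_protocol_table()            # 400 mA/166 mGy ... 10 mA/4.2 mGy
phantom <- generate_head_phantom(phantom_spec())

# paired scan at the lowest-dose protocol, then calibrate the lookup table
paired <- simulate_paired_scan(phantom$ct, tab[[7]], noise_anchor(), seed = 1)
lut <- calibrate_noise(phantom$ct, paired, protocol = tab[[7]])
lut[lut$reference_hu %in% c(-1000, 30, 1000), ]
#>      reference_hu    mean_hu sigma_hu n_samples interpolated
#> 1           -1000 -999.31301 17.96661     47200            0
#> 1031           30   29.45462 19.92898      1289            0
#> 2001         1000 1000.07851 20.50805       726            0

# synthesize the low-dose volume; QA on the raw assigned CT numbers
low <- synthesize_low_dose(phantom$ct, lut, seed = 2)
qa  <- qa_synthesis(phantom$ct,
                    synthesize_low_dose(phantom$ct, lut, seed = 2,
                                        integerize = FALSE))
#> reassigned: 100.0000% (pass: TRUE)

# three-field plan (60/180/300 deg, 40 mm range shifter), dose on both volumes
plan <- make_plan(phantom$ct, phantom$structures$masks$lr_ctv)
dose_clean <- compute_dose(plan, phantom$ct)
svox <- structure_voxels(phantom$structures, phantom$ct$grid)
plan <- scale_plan(plan, 70 / median(dose_clean$values[svox$hr_ctv]))
dose_clean$values <- dose_clean$values * plan$scale
dose_low <- compute_dose(plan, low)

dvh_metrics(dose_clean, svox$hr_ctv)$d98_gy   # 63.78 Gy
dvh_metrics(dose_low,   svox$hr_ctv)$d98_gy   # 63.88 Gy  (+0.15% of Rx)
gamma_index(dose_clean, dose_low)
#> gamma 2%/2mm (global, 10% threshold): pass rate 100.00% (127068/127068 voxels)
```

The per-HU sigma recovered at soft-tissue CT numbers is the injected 20 HU
(the air bin sits against the −1024 HU clamp, which truncates its
distribution slightly); redrawing every voxel passes the 99.9 % QA; and
despite 20 HU of voxel noise the three-field dose agrees with the clean
calculation at 100 % gamma 2 %/2 mm and a D98 shift of ~0.1 % of the
prescription — HU noise averages out along the beam path, so proton range
is barely perturbed.

`run_fraction_experiment()` packages these stages (per protocol: lookup
table, synthesis + QA, dose on both volumes, DVH differences, per-beam and
combined gamma) behind one seeded, fully deterministic call, and
`cli_main()` / `inst/cli/ldctadapt.R` expose them as shell subcommands
(`phantom`, `calibrate`, `synthesize`, `qa`, `dose`, `dij`, `adapt`, `dvh`,
`dice`, `gamma`, `run-experiment`).

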