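# duravol

3D volumetry of the lumbosacral dural sac and vertebral bodies for the
quantification of dural ectasia, and the diagnostic-accuracy analysis that
compares volumetric indices with the 2D diameter ratios used clinically to
screen for Marfan syndrome (MFS).

Dural ectasia — expansion of the dural sac with erosion of the adjacent
vertebrae — is a systemic criterion for MFS. The current clinical standard
quantifies it per spinal level with the **dural sac diameter ratio**
(DSDR = AP dural sac diameter / AP vertebral body diameter). The volumetric
alternative is the **dural sac volume ratio**

DSVR_ℓ = V_dural(ℓ) / V_vertebra(ℓ),  ℓ ∈ {L3, L4, L5},  DSVR_S1 = V_dural(S1) / V_vertebra(L5),

where the dural sac is partitioned into level segments by clipping planes
through the intervertebral disc spaces. The package implements, as testable
components:

* `phantom` — synthetic 3D lumbosacral volumes (intensity + labels) with
  analytically known volumes, diameters and disc planes; boundary-noise
  perturbation; a plumbing-level threshold segmenter.
* `level_partition` — clipping-plane fitting from vertebral labels and the
  exact half-open partition of the dural sac into L3–S1 segments.
* `morphometry` — voxel-count volumetry (mL), midsagittal AP diameters
  (mm), S1 endplate diameters and scalloping.
* `ratios` — DSVR/DSDR, Du Bois BSA, BMI, BMI-corrected columns.
* `cohort_sim` — synthetic patient cohorts matched to published per-group
  (MFS vs non-MFS) means ± SDs of all indices.
* `diagnostics` — Welch tests; empirical ROC AUC (DeLong CI) and
  closed-form binormal/lognormal AUC, Φ((μ₁−μ₀)/√(σ₁²+σ₀²)); Youden
  cut-offs with sens/spec/PPV/NPV; exact McNemar comparison of paired
  classifications; the per-level evaluation report.
* `run_pipeline()` plus a thin CLI (`inst/cli/duravol.R`) tying the stages
  together.

## Worked example

An ectatic phantom, measured end to end:

```r
library(duravol)

ph     <- build_phantom(phantom_spec(noise_sigma = 0, ectasia_factor = 1.6), seed = 1)
planes <- fit_clipping_planes(ph$labels)
part   <- partition_dural_sac(ph$labels, planes)
m      <- measure_all(ph$labels, part, patient_id = "phantom-01")

m$dural_volume_S1              # 9.55 (mL)   -- truth: 9.53
compute_ratio_table(m)$dsvr_S1 # 0.347
```

The measured S1 dural segment volume (9.55 mL) agrees with the phantom's
analytic ground truth (9.53 mL) to one voxel-layer precision, and the
resulting S1 DSVR of 0.347 is in the ectatic range (non-MFS patients
average ~0.14).

A simulated cohort at the published group distributions, evaluated per
level:

```r
specs <- default_group_specs()
coh   <- sample_cohort(specs$mfs, specs$non_mfs, 63, 81, seed = 1)
rep2  <- evaluate_table2(coh)
rep2[rep2$level %in% c("L5", "S1"), c("auc_dsvr", "auc_dsdr", "mcnemar_p")]
#>   auc_dsvr auc_dsdr mcnemar_p
#> 5    0.807    0.765     0.111
#> 6    0.829    0.858     0.005
```

One draw of n = 63/81 reproduces the published pattern: the volume ratio
discriminates better than the diameter ratio at L5, both discriminate best
at S1, and the McNemar test flags a classification difference at S1 but
not L5. The closed-form binormal AUC computed directly from the published
S1 DSVR group parameters is

```r
auc_closed_form(0.41, 0.28, 0.14, 0.06, "normal")
#> 0.827
```

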