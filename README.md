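# flow4d

Intracardiac 4D flow CMR analysis in R: pathline-based flow-component
decomposition and phasic kinetic-energy quantification of the ventricles,
together with the cine, exercise-test and statistical machinery used to
relate them to right-ventricular remodelling and exercise capacity in
pulmonary arterial hypertension.

## The problem and who this is for

Time-resolved three-directional phase-contrast CMR ("4D flow") samples the
blood velocity vector `v(x, t)` in every voxel at every cardiac phase. For
researchers studying right-ventricular disease, two derived families of
markers matter:

* **Flow components.** Particles seeded in the ventricular blood pool at
  end diastole (ED) are traced forward over systole and backward over the
  preceding diastole through the periodic cycle. With `entered` = outside
  the chamber at some recorded frame of the backward trace and `ejected` =
  outside at some frame of the forward trace:

  | entered | ejected | component |
  |---|---|---|
  | yes | yes | direct flow |
  | yes | no  | retained inflow |
  | no  | yes | delayed ejection flow |
  | no  | no  | residual volume |

  Fractions are percentages of seeded ED blood and always sum to 100; the
  *fractional flow ratio* is direct flow over residual volume.

* **Kinetic energy.** `KE(t) = Σ_voxels ½ ρ V_voxel |v|²`, indexed to
  end-diastolic volume (KEI_EDV, µJ/ml) and summarized at peak systole,
  averaged over systole, and at the E-wave filling peak; *KE discordance*
  is the RV/LV ratio of average systolic KEI_EDV.

Supporting modules compute the cine remodelling index (RVEDV/LVEDV, with
adverse cutoff `mean + 3 SD` of controls), EF, TAPSE, synchrony index, RA
area, GLS at end systole and PA relative area change; CPET metrics (peak
VO2, % predicted, VE/VCO2 slope, default imputation, threshold
stratification) and composite risk grades; and a statistics battery (group
comparisons with Bonferroni families, univariate screen + stepwise
regression on Ln outcomes, ROC/Youden, DeLong AUC comparison, nested
logistic incremental χ², Bland–Altman/CoV). A synthetic-data module
provides analytic flow phantoms with closed-form ground truth and
simulated control/patient cohorts so the whole pipeline is verifiable
without patient data.

## Worked example

```r
library(flow4d)

# Two-channel phantom: a plug-flow channel (chamber length 10 voxels,
# diastolic transit 6, systolic transit 7) beside an equal static channel.
ph  <- make_phantom(phantom_spec("two_channel", L = 10L, a = 6L, b = 7L,
                                 cross_section = c(4L, 4L), margin = c(8L, 8L)))
res <- flow_component_analysis(ph$field, ph$mask, "RV",
                               ed_frame = 0L, es_frame = 12L)
res
#> flow components (RV, 320 particles):
#>   direct_flow             15.00 %
#>   retained_inflow         15.00 %
#>   delayed_ejection_flow   20.00 %
#>   residual_volume         50.00 %
#>   fractional flow ratio  0.300
ph$ground_truth$fractions   # closed form: 15 15 20 50
```

The recovered percentages match the phantom's analytic ground truth: the
flow channel contributes (30, 30, 40, 0)% of its half of the pool —
`direct = max(0, a + b − L) = 3` of 10 unit lengths, and so on — and the
static channel contributes pure residual volume.

```r
adverse_cutoff(mean_value = 0.97, sd_value = 0.10)$cutoff_reported
#> [1] 1.27        # remodelling index above this = adverse RV remodelling

co <- make_cohort(cohort_spec(seed = 7))   # 51 controls, 45 patients
g  <- group_compare(co, "rv_direct", family_size = 9)
#> rv_direct: mann_whitney test, P = 1.06e-11 (family alpha 0.006)

co$pah <- co$group == "PAH"
roc_youden(co, "rv_direct", "pah", direction = "<")
#> ROC for rv_direct (direction <): AUC 0.904
#>   Youden threshold 32.31 -> sens 0.800, spec 0.922 (J = 0.722)

nested_logistic(co, "pah", "rvef", "rv_direct")[c("chi2_base", "chi2_full", "p_value")]
#> chi2 26.28 -> 56.51, incremental P < 1e-4
```

Here the simulated patient group's RV direct flow (planted median 24% vs
37% in controls) is detected far below the 9-comparison family level, its
ROC separates the groups with AUC 0.90, and adding it to an
ejection-fraction logistic model roughly doubles the model χ² — the
qualitative pattern the markers are designed to expose.

See `vignette("flow4d-methods")` for the model assumptions, numerical
choices and the phantom/cohort generators' design.

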