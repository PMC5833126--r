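# lv4dflow

Left-ventricular 4D-flow analysis in R: pathline-based decomposition of the
LV end-diastolic blood volume into the four functional flow components, with
per-component kinetic energy, background phase-offset correction, volumetric
indices, quality control, and the repeatability statistics used in
test-retest imaging studies. A synthetic velocity phantom with exact ground
truth makes the whole pipeline verifiable without patient data.

It is written for researchers processing 4D-flow (three-dimensional,
time-resolved, three-directional phase-contrast) CMR velocity data who need
a transparent, scriptable, fully tested implementation of the
flow-component method and of scan-rescan / interval variability analysis.

## The method

A velocity field $v(x, t)$ over one cardiac cycle forms a closed temporal
loop. From the centre of every voxel of the end-diastolic (ED) LV
segmentation a pathline is integrated (fixed-step RK4) forward to the next
end-systole (ES) and backward to the preceding ES; the two spans tile the
cycle exactly. The pathline's positions at those two ES times, tested
against the ES cavity, give the classification

| previous ES | next ES | component |
|---|---|---|
| outside | outside | direct flow |
| outside | inside  | retained inflow |
| inside  | outside | delayed ejection flow |
| inside  | inside  | residual volume |

Each pathline carries one voxel's blood volume, so component volumes
partition the EDV exactly and are reported as % EDV. Kinetic energy per
component is

$$KE_c(t) = \sum_{p\in c} \tfrac12\,\rho_{blood}\,V_{pathline}\,v^2_{pathline}(t),$$

in µJ, and at ED also per millilitre of component volume. Supporting steps:
third-order polynomial background phase-offset correction fitted on static
tissue; nearest-neighbour resampling of the ED mask onto the flow grid;
EDV/ESV/SV/EF/cardiac output; the inflow-vs-outflow 10% quality-control
rule; within-subject and group coefficients of variation (root-mean-square
method), Bland-Altman limits of agreement, and exact Mann-Whitney tests for
comparing CoV distributions. The methods vignette
(`vignettes/lv4dflow-methods.Rmd`) documents every convention and open
design decision.

## Worked example

```r
library(lv4dflow)

# a synthetic dataset with known truth: 32^3 grid, 3 mm voxels,
# 20 frames of 52 ms, target fractions 38/16/16/30 % EDV
ph  <- generate_phantom(phantom_spec(seed = 1))
fit <- lv4dflow(ph$field, ph$seg, heart_rate = ph$heart_rate,
                subject_id = "phantom01")
fit
```

```
LV 4D-flow analysis: phantom01 / visit1
EDV 64.2 ml, ESV 58.1 ml, SV 6.1 ml, EF 9.5%, CO 0.35 L/min
Flow components:
  direct_flow              24.2 ml   37.7 % EDV  KE(ED)    51.64 uJ    2.13 uJ/ml
  retained_inflow          10.4 ml   16.1 % EDV  KE(ED)    22.13 uJ    2.13 uJ/ml
  delayed_ejection_flow    10.4 ml   16.1 % EDV  KE(ED)    22.13 uJ    2.13 uJ/ml
  residual_volume          19.3 ml   30.0 % EDV  KE(ED)     2.61 uJ    0.14 uJ/ml
QC inflow 34.6 ml vs outflow 34.6 ml: 0.0% difference (pass)
```

The phantom's generator discretised the requested 38/16/16/30% onto whole
voxel layers as 37.7/16.1/16.1/30.0% (`ph$truth`), and the pipeline recovers
those realised fractions exactly on noise-free data — every pathline gets
its ground-truth label. Inflow and outflow agree to machine precision by
construction, so the QC difference is 0%. The KE/ml values reflect the
phantom's transit speed at ED (2.13 µJ/ml for the moving components, 0.14
for the slowly stirring residual volume). The low EF is a deliberate
property of the validation phantom, not of the method (see the vignette).

`plot(fit)` draws the component bars and KE curves; `as.data.frame(fit)` /
`write_component_table()` produce one tidy row per subject and visit.
`simulate_repeatability_study()` runs the two-arm scan-rescan vs interval
design end to end. A thin command-line front end lives at
`inst/cli/lv4dflow.R` (`run`, `phantom`, `repeatability` subcommands).

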