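---
title: "Methods: LV flow-component decomposition and its validation phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LV flow-component decomposition and its validation phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lv4dflow)
```

## The analysis

4D-flow CMR measures a three-directional velocity field over the whole heart,
resolved over one averaged cardiac cycle. Because the acquisition covers the
complete cycle, the data form a closed temporal loop: the frame after the last
is the first. `lv4dflow` implements the pathline-based decomposition of the
left-ventricular end-diastolic blood volume (EDV) into four functional
components, with their kinetic energy:

* a **pathline** is emitted from the centre of every voxel of the LV
  segmentation at end-diastole (ED) and integrated **forward** in time to the
  next end-systole (ES) and **backward** to the preceding ES. The two
  intervals tile exactly one cycle, so together the tracks follow the whole
  EDV through one heartbeat;
* the pathline's positions at the two ES times, tested against the LV cavity
  defined by the ES segmentation, assign it to one of four components:
  **direct flow** (outside at both ES times: enters and leaves within the
  cycle), **retained inflow** (enters but stays), **delayed ejection flow**
  (starts inside, leaves), **residual volume** (inside at both: resides at
  least two cycles);
* each pathline carries the blood volume of one flow voxel, so the four
  component volumes partition the EDV exactly, and are reported as
  percentages of EDV;
* kinetic energy per component is
  $KE_c(t) = \sum_{p \in c} \tfrac12\, \rho_{blood}\, V_{pathline}\,
  v_{pathline}^2(t)$, reported in µJ over the cycle and, at ED, divided by the
  component volume (µJ/ml) to remove the dependence on cavity size.

Quality control compares the inflow volume (direct flow + retained inflow)
with the outflow volume (direct flow + delayed ejection flow); a relative
difference above 10% fails the dataset. We normalise the difference by the
mean of inflow and outflow, a symmetric choice the decomposition itself does
not dictate.

Before tracking, background phase offsets — the spatially smooth velocity
baseline left by eddy currents — are corrected by fitting, per velocity
direction, a full third-order polynomial in space (20 monomials) to the
time-averaged velocity of static tissue, and subtracting it from every frame.
Offsets are temporally static by physical origin, which is why a single
spatial fit per direction suffices.

## Interfaces and conventions

Voxel indices are 0-based; the world position of voxel centre $i$ is
`origin + i * spacing` (mm). All times are in ms, velocities in cm/s,
volumes in ml, energies in µJ; unit conversions happen only inside the KE
computation. Velocity sampling is trilinear in space and linear in time with
periodic wrap; outside the spatial grid it returns the zero vector plus a
flag, and the pathline engine freezes such trajectories at their first
out-of-bounds position (ejected blood legitimately exits the field of view;
a frozen position counts as outside the LV at classification). Mask
resampling onto the flow grid is nearest-neighbour at voxel centres — it
preserves binarity — with the deterministic tie rule that a centre exactly on
a boundary belongs to the lower-index source voxel.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `step` | `frame_interval / 10` (5.2 ms at 52 ms framing) | ms | RK4 at this step makes integration error negligible against the data's own interpolation error; halving it changes endpoints by well under a voxel |
| `static_threshold` | 2 | cm/s | static tissue = temporal SD of speed below the threshold and mean speed below twice it; set it 1.5–2× above the expected velocity noise SD |
| `min_static_voxels` | 200 | voxels | a 20-coefficient fit per direction needs a comfortably over-determined, well-spread domain |
| `rho_blood` | 1060 | kg/m³ | standard literature blood density; configurable |
| QC tolerance | 0.10 | – | the published exclusion rule |

The polynomial basis is evaluated in coordinates centred on the FOV midpoint
and scaled to $[-1,1]$; this conditions the normal equations, and
`coef(model, basis = "world")` converts back exactly when raw-coordinate
coefficients are wanted.

## The integrator

Fixed-step classical Runge–Kutta (RK4), forward and backward (backward
integration advances with negative time steps through the same closed-loop
field; no reversed dataset is built). The final partial step is shortened so
the track ends exactly at ES. On a rigid-rotation test field — linear in
space, hence interpolated exactly — the radius drift over a full cycle at
5 ms steps is below $10^{-5}$ mm, and forward-then-backward integration
returns to the seed within $10^{-7}$ mm; both bounds are asserted by the test
suite. Adaptive stepping is deliberately out of scope: fixed steps keep runs
bit-reproducible and the accuracy budget is dominated by the 52 ms temporal
resolution of the data, not the scheme.

## The synthetic phantom

No public 4D-flow dataset accompanies the decomposition, so validation rests
on a generator whose ground truth is *exact by construction* rather than on a
fluid-dynamics simulation. The phantom emulates the acquisition geometry —
3 mm isotropic voxels, 20 frames of 52 ms (1040 ms cycle), VENC 100 cm/s —
and the healthy-cohort component pattern (38/16/16/30% of EDV by default).

Two column structures run along the flow axis:

* a **transit channel** (8×8 columns) carries a spatially uniform axial
  velocity $u(t) = A + B\sin(2\pi\tau/T) + C\,g(\tau)$. $A$ and $B$ are
  solved so the displacement from ED to the next ES equals the displacement
  from the previous ES to ED (both $D$), which makes inflow and outflow
  match exactly and splits the chamber slab into retained / direct / delayed
  layers of whole voxels. $g$ integrates to zero over both half-cycles, so
  the optional $C$ term (the `ed_speed` control used in the kinetic-energy
  checks) reshapes the ED-time speed without moving any ES endpoint;
* a **residual block** of columns is given the small stir $\varepsilon\,
  g(\tau)$: its blood moves, carries kinetic energy at ED, and returns to
  its starting position exactly at both ES times, so it is residual volume
  by construction.

Because every column's velocity is uniform along the axis and voxel-centre
seeds stay on column centres, each trajectory is an exact translation and
the label of every seed follows from closed-form displacement arithmetic.
All classification thresholds are placed mid-way between voxel centres
(1.5 mm buffers), so the grid pipeline reproduces the truth label of every
seed exactly on noise-free data — the acceptance suite asserts equality, not
approximation — and the dense analytic-field oracle (8 sub-seeds per voxel,
quarter step, no grid interpolation) lands on identical fractions.

Two design features exist purely for robustness to velocity noise, which
disperses trajectories by a few millimetres over a cycle at realistic noise
levels (3 cm/s at VENC 100):

* each block sits inside a wider *motion carrier* of columns sharing its
  velocity, so laterally diffused blood keeps its axial transport instead of
  stalling at a velocity discontinuity;
* the ES cavity pads each block by one voxel ring (and the residual seeds
  are recessed one voxel inside the cavity slab), so endpoint jitter of the
  order of the dispersion does not flip inside/outside decisions.

The padded cavity makes the phantom's ejection fraction unphysiologically
small (about 10%); the phantom trades physiological realism of the *masks*
for exactness and noise-tolerance of the *labels*, which is what the tests
need. Other honest departures from real data: the flow program is a
translation, not a vortical intraventricular flow; the chamber does not
deform; residual blood stirs rather than recirculates; incompressibility
holds trivially (each column's velocity is uniform along its axis, so the
constructed field is divergence-free almost everywhere) rather than through
pressure coupling; and noise is Gaussian per direction (the
phase-difference noise model) without Rician magnitude effects. Passing on
the phantom therefore demonstrates correctness of the *computational
pipeline* — geometry, integration, classification, accounting — not fidelity
to intraventricular haemodynamics.

Requested fractions are discretised onto whole layers and columns by a small
integer search; the realised fractions (reported in the truth object) land
within about half a percentage point of the request, and the `ed_speed`,
noise, background-offset and rigid-shift controls never move the truth.

## The repeatability layer

Within-subject variability of a duplicate pair uses the root-mean-square
identity $s_w = |x_1 - x_2|/\sqrt{2}$, giving a per-subject CoV of
$100\,s_w/\bar{x}$; the group CoV is the RMS of per-subject CoVs. (The
verbal description of this estimator in the source literature is internally
inconsistent — "summing the squares… taking the mean… square rooting" — and
we implement the standard RMS reading.) Bland–Altman limits of agreement are
$\mathrm{bias} \pm 1.96\,\mathrm{SD}(d)$ with the sample SD. Paired mean
differences are reported with the same observed-difference interval by
default, because the published interval widths match limits of agreement
rather than standard errors of the mean; a true CI of the mean is available
via `interval = "ci_mean"`. The Mann–Whitney U test enumerates the exact
null distribution for tie-free samples with $\min(n) \le 8$ and
$n_a + n_b \le 20$, and otherwise uses the normal approximation with tie and
continuity corrections; the threshold is fixed for reproducibility.

`simulate_repeatability_study()` emulates the two-arm design (10 scan-rescan
subjects, 25 interval subjects by default). A rescan pair differs only in
noise realisation and a sub-voxel rigid repositioning; an interval pair
additionally rescales the cycle length by a heart-rate change (SD 7 bpm, the
between-visit variability reported for healthy adults) and jitters the
component fractions (SD 2 percentage points). Simulated acquisition noise
defaults to 3 cm/s, a realistic phase-noise level at VENC 100 cm/s. With
these settings the interval arm shows larger group CoVs than the rescan arm
for every component ratio — the qualitative signature of physiological
variability adding to technique error. Background correction defaults off in
this simulation: the phantoms carry no injected offset, and at the phantom's
modest transit speeds (≈6–13 cm/s) a speed-based static-tissue test cannot
separate slow flow from a 3 cm/s noise floor, so the correction is validated
separately on noise-free and low-noise data with injected offsets.

## Decisions where the design was genuinely open

* **Deterministic pathlines.** Descriptions of pathlines as "probabilistic
  paths" notwithstanding, one trajectory per seed voxel is integrated; no
  stochastic ensemble.
* **Endpoint-only classification.** A pathline that leaves and re-enters the
  cavity before ES is classified by its ES position only; intermediate
  excursions are ignored.
* **Static-tissue definition.** The fit domain for the offset polynomial is
  not prescribed anywhere; temporal-variance thresholding is the explicit,
  testable rule adopted here.
* **Time-averaged regression target.** One spatial polynomial per direction,
  fitted to time-averaged static velocity and subtracted at all frames, on
  the physical grounds that the offset is static.
* **QC denominator.** The 10% rule is stated without a denominator; the
  mean of inflow and outflow is used.
* **ED kinetic energy.** KE at ED uses the velocity sampled at the seed
  position and time, which forward and backward tracks share by
  construction.
* **Empty components** are reported with volume 0 and KE marked unavailable,
  never dropped.

## Problem sizes

The test suite and the acceptance script run the pipeline on the 32³ × 20
phantom (≈2,400 seeds, 5.2 ms steps, ≈2 s per analysis), five noisy
replicates at 3 cm/s, one dense-oracle integration (8× seeding, 1.3 ms
steps) and a 35-subject, 70-dataset repeatability simulation; the whole
acceptance run completes in a few minutes on one CPU.

## Limitations

The phantom validates the pipeline, not the physiology; effect sizes
measured on it (CoV magnitudes, KE levels) characterise the simulation, not
patients. Velocity antialiasing, Maxwell-term and gradient-nonlinearity
corrections, valve tracking and atrial flow are out of scope. Masks are
inputs: segmentation quality and the visual choice of ED/ES frames are
upstream of everything this package computes.
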