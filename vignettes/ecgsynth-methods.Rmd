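---
title: "Mechanistic synthesis of labeled 12-lead ECGs: models and design choices"
author: "ecgsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic synthesis of labeled 12-lead ECGs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ecgsynth` generates labeled synthetic 12-lead electrocardiograms by
chaining five mechanistic stages:

1. **Geometry** — parametric idealized anatomies: the ventricles are two
   truncated prolate ellipsoids (a thick-walled LV, a thin crescent RV)
   voxelized on a regular lattice and equipped with analytic universal
   ventricular coordinates (transmural $\rho$, rotational $\varphi$,
   apico-basal $z$, chamber label $v$); the atria are two spheroidal
   shells of homogeneous 3 mm wall thickness joined by a Bachmann's-bundle
   bridge and a posterior interatrial connection, with band-shaped tags
   for the crista terminalis, pectinate muscles and inferior isthmus.
2. **Cellular electrophysiology** — the Mitchell–Schaeffer two-current
   model produces action-potential templates; $\tau_{close}$ is calibrated
   numerically against a target APD; a weighted linear combination of the
   universal coordinates, min–max normalized onto
   $[APD_{min}, APD_{max}]$, builds the repolarization gradient that
   shapes the T wave.
3. **Activation** — local activation times solve the anisotropic Eikonal
   problem. The solver is a label-correcting shortest-path computation on
   an extended-neighborhood lattice graph (all coprime offsets with
   components up to 2) with edge metric $\|e\|_M$,
   $M = R\,\mathrm{diag}(cv_f^{-2}, cv_s^{-2}, cv_n^{-2})\,R^\top$.
   Ventricular activation starts from five disc-shaped fascicular sites on
   a fast-conducting endocardial layer (2.0 m/s, spanning the middle
   10–90 % of the apico-basal extent); myocardium conducts at 0.6 m/s
   along fibers with a 4:2:1 off-axis ratio; fibers rotate linearly in
   $\rho$ from 60° to −60° (helix) and −65° to 25° (sheet). Atrial
   activation starts at the sinoatrial exit site at the crista
   terminalis / superior vena cava junction with regional transversal
   velocities and anisotropy ratios per structure.
4. **Forward model** — the reaction-Eikonal construction (no diffusion)
   evaluates $V_m(x,t) = \mathrm{tpl}(t - \mathrm{LAT}(x);\,
   \mathrm{APD}(x))$; electrode potentials follow from the infinite
   volume conductor dipole sum
   $\phi(y) = \frac{-\sigma_i}{4\pi\sigma_m}\sum_e
   \nabla V_m \cdot \frac{y - x_e}{\|y - x_e\|^3}\,V_e$, and the standard
   Einthoven/Goldberger/Wilson combinations give the 12 leads in the
   order I, II, III, aVR, aVL, aVF, V1–V6.
5. **Synthesis** — single-beat P waves and QRST complexes are coupled by
   conditional Gaussian draws (amplitudes $R \mid P$; intervals
   $PQ \mid P_{dur}$ and $QT \mid QRS_{dur}, RR$) around published
   clinical lead-II means and standard deviations, concatenated with
   logistic connectors, repeated over a $1/f^\beta$ long-range-correlated
   RR series, warped beat-wise in the $[QRS_{off}, T_{off}]$ interval,
   joined by sigmoidal TP segments into 10 s, 500 Hz records, overlaid
   with composite noise at a 15–20 dB SNR, and bandpass filtered
   (3rd-order Butterworth, 0.5–150 Hz, zero-phase).

Seven pathology families are mechanistic modifiers of the healthy
configuration: complete left/right bundle branch block removes the
fascicular sites of one ventricle; myocardial infarction (six
sub-classes: LAD/LCX/RCA × transmural/subendocardial) grows a geodesic
infarct with an inert core and a slow-conducting border zone; fibrotic
atrial cardiomyopathy replaces 5–45 % of the atrial volume with patches
in which half the elements become passive barriers; interatrial
conduction block inhibits Bachmann's bundle; left atrial enlargement
scales the LA volume; first-degree AV block forces PQ > 200 ms at the
synthesis stage.

# Key parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `cv_myo`, ratio | 0.6, 4:2:1 | m/s | ventricular myocardial conduction |
| `cv_endo` | 2.0 | m/s | isotropic fast endocardial layer |
| $\alpha_{endo}/\alpha_{epi}$ | 60 / −60 | deg | fiber helix rotation |
| $APD_{min}$, $APD_{max}$ | [150, 175], [225, 250] | ms | repolarization range (sampled) |
| MS sinus cell | $V_{gate}$ 0.13, $V_{min}$ −86.2 mV, $V_{max}$ 40 mV, $\tau_{in}$ 0.3, $\tau_{out}$ 5.4, $\tau_{open}$ 80 | — | ventricular myocyte |
| Border-zone cell | $V_{min}$ −73.1 mV, $V_{max}$ 12.5 mV, $\tau_{in}$ 0.45, $\tau_{out}$ 3.6, $\tau_{open}$ 44 | — | infarct rim myocyte |
| Atrial CVs | bulk [0.57, 0.85]; connections [0.46, 0.70]; crista [0.57, 0.85]; pectinate [0.62, 0.92]; isthmus [0.57, 0.85] | m/s | transversal, sampled |
| Anisotropy ratios | 1.94 / 3 / 2.56 / 3.24 / 1 | — | longitudinal = AR × transversal |
| `cv_bz` | 0.15 | m/s | isotropic border zone |
| Pose | rotations ±20°, translations ±10 mm | | atrial placement variability |
| SNR | [15, 20] | dB | noise scaling |
| Record | 12 × 5000 samples, 500 Hz, mV | | output format |

All sampled quantities use Latin hypercube designs so each of $n$
equal-width strata per dimension holds exactly one sample.

# Numerical choices

* **Cell integration.** Explicit stepping at `dt = 0.025` ms (the
  stability precondition is `dt <= 0.1 * tau_in` and the fastest time
  constant is 0.3 ms). Template banks are built on a 1 ms APD grid by one
  vectorized pass over calibrated $\tau_{close}$ values with a secant
  correction; measured APDs match the grid to < 0.1 ms.
* **APD definition.** Time from maximum upstroke slope to the downstroke
  crossing of $v = V_{gate}$; this is self-consistent with the model's
  gate dynamics. The fiducial "end of repolarization" used for T-wave
  ground truth is the 10 %-of-amplitude crossing after the template peak.
* **Eikonal accuracy.** The order-2 coprime stencil (49 half-offsets per
  node) is exact along lattice axes and diagonals and within about 5 %
  along arbitrary directions; an 8 % bound is tested. Inert tissue
  (zero conduction) is excluded from the graph, which yields `+Inf`
  activation times without special-casing.
* **Per-mesh min–max APD normalization.** The weighted coordinate field
  is normalized per mesh; a spatially constant field maps to the
  midpoint of the APD range.
* **Amplitude scale.** A single homogeneous infinite medium
  ($\sigma_{torso}$) serves both chambers, so raw single-beat amplitudes
  are not on the clinical scale. The synthesis stage absorbs this by
  scaling the P wave to a truncated clinical P-amplitude draw
  (floor 0.02 mV) and then scaling the QRST so the dominant lead-II QRS
  deflection meets the conditional $R \mid P$ draw. Full anisotropic
  conductivities are retained as metadata.
* **Heart attitude.** The idealized ventricular frame is tilted
  (−15°, −40°, 0°) relative to the electrode frame so the apex points
  left–anterior–inferior; this produces physiological lead polarities
  (upright I/II, negative V1). The rotational coordinate $\varphi$ is 0
  at mid-septum with anterior positive, so the artery-specific infarct
  sectors land on the clinically expected walls.
* **Filtering.** Zero-phase (forward–backward) application of the
  3rd-order Butterworth filters keeps the ground-truth fiducials aligned
  in the filtered variant; the −3 dB corner of the single-pass prototype
  is at 0.5 Hz.
* **Degenerate inputs.** Zero-radius fascicular discs collapse to the
  nearest node; `d_co = 0` infarcts to a single element; zero-variance
  RR series repeat the mean beat; an SNR of `Inf` returns the raw signal.

# Synthesis-stage calibration

Only the clinical means and standard deviations of the feature blocks
are published; the cross-feature correlations are package calibration
knobs with defaults $\rho(P_{amp}, R_{amp}) = 0.5$,
$\rho(P_{dur}, PQ) = 0.4$, $\rho(QRS, QT) = 0.4$, $\rho(QT, RR) = 0.6$
(the QRS–RR correlation is 0, which keeps the block positive definite).
The mean heart rate of a record is drawn as $RR \mid QT$ from the
interval block, clipped to 50–90 bpm; the direction of this conditioning
is a design choice. The heart-rate-variability model is reduced to its
operational core: spectral synthesis of a Gaussian series with a
$1/f^{\beta}$ spectrum ($\beta = 1$), scaled to SDNN 30 ms. AV-block PQ
draws are reflected above the 200 ms floor.

# What the generator emulates — and what it does not

The synthetic cohort reproduces: mechanistically labeled pathologies with
exact ground-truth fiducials; anatomical variability through bounded
shape coefficients (axis perturbations up to ±15 % at the coefficient
bounds, a declared surrogate for statistical-shape-model eigenmodes);
physiological lead relationships (the Einthoven and Goldberger identities
hold to machine precision); clinically coupled amplitude/interval
statistics; and realistic composite noise. It does **not** reproduce:
real torso inhomogeneities (lungs, blood pools enter only as recorded
conductivities), the full atrial ionic model (an MS-parameterized
surrogate with atrial voltage bounds replaces it; fibrotic remodeling is
expressed as template amplitude/APD modification), Purkinje network
trees, rate-dependent APD restitution, or partial conduction blocks.
Consequently, passing tests demonstrate internal consistency and
correct mechanistic coupling, not equivalence to any clinical cohort.

# Problem sizes

Default meshes resolve the ventricles at 2 mm (about 20,000 elements,
six elements across the LV wall) and the atria at 1.5 mm (two elements
across the 3 mm wall); one full labeled record takes a few seconds on one
core after the per-anatomy bundle (meshes, template banks, forward
operator) is built. The test suite exercises batches of 50 AV-block and
100 sinus records and a 26-record mini dataset; the acceptance script
regenerates 70 records plus the slab, infarct and fibrosis analyses.

# Known limitations

* The idealized ellipsoid/spheroid anatomies place the septum, free walls
  and atrial structures by geometric convention; sector boundaries in
  $\varphi$ are exact by construction rather than anatomically fuzzy.
* Ground-truth QRS offset is the last myocardial activation time; the
  surface deflection of late-activating tissue is weak, so delineation
  systematically reads the offset a few milliseconds early. The
  delineator's accuracy contract (median error ≤ 10 ms per fiducial on
  noise-free records) is the honest summary of this gap.
* The infarct radius parameter is treated as a dimensionless fraction of
  the LV long axis; its printed unit in the source material is
  inconsistent, and the package documents its own convention.
* Single-beat morphology within a record is one simulated beat warped
  per RR interval; beat-to-beat morphology variation beyond the QT warp
  is not modeled.
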