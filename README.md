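# ecgsynth

Mechanistic synthesis of labeled 12-lead ECGs from cardiac
electrophysiology simulations.

Machine-learning tools for ECG interpretation need large labeled
databases, but clinical collections carry labeling uncertainty, cohort
bias and no access to the underlying disease mechanism. `ecgsynth`
addresses this by generating 10 s, 500 Hz, 12-lead ECG records whose
pathology labels and wave fiducials are exact by construction, because
every record is produced by a forward electrophysiology simulation:

* **P waves** from an anisotropic Eikonal activation of a two-shell
  atrial geometry (sinoatrial-node initiation, regional conduction
  velocities and anisotropy ratios per structure);
* **QRST complexes** from a five-fascicle His–Purkinje surrogate on a
  fast-conducting endocardium of a two-chamber ventricular geometry,
  with rule-based fibers (60°/−60° helix), the Mitchell–Schaeffer
  two-current myocyte model, and a coordinate-weighted APD map
  mapped onto [APD_min, APD_max] that creates the repolarization
  gradients behind the T wave;
* **electrode potentials** from the infinite-volume-conductor dipole
  sum `phi(y) = -sigma_i/(4 pi sigma_m) * sum_e grad(Vm) . r / |r|^3 Ve`
  and the standard Einthoven/Goldberger/Wilson lead combinations;
* **full records** by conditional-Gaussian coupling of amplitudes and
  intervals around published clinical lead-II statistics, a `1/f`
  heart-rate-variability RR series, beat-wise QT warping, sigmoid
  connectors and TP segments, composite noise at 15–20 dB SNR, and a
  3rd-order 0.5–150 Hz Butterworth bandpass. Each record is written as a
  `raw` / `noise` / `filtered` CSV triple (12 rows × 5000 samples, mV)
  plus two key=value parameter files that regenerate it exactly.

Eight classes are produced — healthy sinus control plus seven
pathologies (myocardial infarction with six artery/transmurality
sub-classes, left and right bundle branch block, fibrotic atrial
cardiomyopathy, interatrial conduction block, left atrial enlargement,
first-degree AV block) — 13 labeled cases in all, with anatomy-disjoint
train/validation/test splits.

## Worked example

```r
library(ecgsynth)

## one anatomy bundle (meshes, fibers, template banks, forward operator)
bundle <- build_anatomy_bundle()

## one healthy record
row <- sample_case(1, seed = 11)
rec <- generate_record(make_case_config("sinus", row[1, ]), bundle)
rec
#> <ecg_record: sinus, 12 x 5000 @ 500 Hz, 16 beats, SNR 15.3 dB>

## ground-truth fiducials of the first beat (ms in record time)
round(unlist(rec$fiducials[1, c("P_on", "P_off", "QRS_on", "QRS_off", "T_off")]), 1)
#>    P_on   P_off  QRS_on QRS_off   T_off
#>     0.0   103.3   126.0   211.4   419.4

## delineate and extract the 11-feature x 12-lead table
ft <- extract_features(rec)
round(subset(ft, lead == "II", c(Pdur, QRSdur, PQint, QTint, RRint, Ramp)), 2)
#>   Pdur QRSdur PQint  QTint  RRint Ramp
#> 2   92     78   114 292.86 689.14 0.46
```

The first beat's ground-truth PQ interval (QRS_on − P_on = 126.0 ms) is
the record's sampled conditional draw `PQ | P_dur`; the delineated
lead-II intervals recover the generator's ground truth (here QRS
duration 78 vs 85.4 ms truth, QT 292.9 vs 293.4 ms) and the R amplitude
sits at its conditional draw given the P amplitude.
`generate_records("avblock", 50, seed = 1)` produces a batch in which
every beat's PQ exceeds 200 ms; `generate_dataset(dir, n_per_case = 2,
seed = 1)` writes the full 13-case folder tree and
`validate_dataset(dir)` checks it against the CSV dialect.

A thin command-line front end is installed with the package
(`system.file("cli/ecgsynth", package = "ecgsynth")`) with subcommands
`generate`, `manifest`, `features`, `validate` and `demo`.

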