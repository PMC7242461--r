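# uteqmri

Quantitative multi-echo MRI simulation and relaxometry for iron-oxide cell
tracking in joints.

## What this is for

Mesenchymal stem cells injected into a joint can be tracked with MRI when
they are labelled with superparamagnetic iron-oxide (SPIO) nanoparticles:
the label accelerates transverse relaxation, raising R2 and especially
R2* (= 1/T2*). But both bone and concentrated SPIO decay so fast that
conventional Cartesian gradient-echo images (first echo ≥ 7 ms) lose them
entirely, and the depot's dipole field blooms into a signal void much
larger than the source. Ultrashort-echo-time (UTE) acquisitions sample the
k-space center ~0.03 ms after excitation and keep that signal.

`uteqmri` reproduces the full computational chain of such a study on
synthetic data, for methodologists who want to exercise or extend the
quantification without scanner access:

- **Digital joint phantom** — parametric sagittal slice with the five
  standard ROIs (joint space, fat pad, tibial bone, dorsal muscle,
  8 mm defect region) and an optional focal SPIO depot in the fat pad.
- **Forward model** — per voxel
  `S(TE) = PD·[f·e^(−R_fast·TE) + (1−f)·e^(−R_slow·TE)]·A(TE)` with
  `R_slow = R2* + r·c` under gradient echo (SPIO relaxivity `r`,
  concentration `c`), spectral dipole-field computation
  (`D(k) = 1/3 − kz²/|k|²`), subvoxel dephasing attenuation `A(TE)`, and
  Rician magnitude noise. Three protocol presets: five-echo UTE
  (TE 0.03–16.1 ms), six-echo Cartesian mGE (7.0–35.8 ms), four-echo FSE
  for R2 (2.8–112 ms).
- **Relaxometry** — per-voxel log-linear least squares
  (`rate = −slope of ln S vs TE`, in s⁻¹), echo-ratio statistics
  `R12 = (S1−S2)/S1`, `R15 = (S1−S5)/S1`, `R25 = (S2−S5)/S2`, the two-point
  estimate `−ln(1−R)/ΔTE`, and echo-subtraction images.
- **Statistics** — ROI mean ± SD over valid voxels, Welch t-tests at the
  study's permissive α = 0.15, and `replicate_study()`, which regenerates
  the two-group design (joint-space R2* 64 ± 6 s⁻¹ with SPIOs vs
  70 ± 7 s⁻¹ without, 7 joints per group) end to end.
- **Acquisition layer** — center-out radial vs Cartesian k-space sampling
  of the time-decaying object with Kaiser-Bessel gridding reconstruction,
  demonstrating why the UTE first echo keeps bone and depot signal that
  the Cartesian first echo loses.

Everything reads/writes NIfTI with JSON sidecars (the sidecar is
authoritative for echo times), YAML run configs and tidy CSV reports. A
thin CLI lives at `inst/cli/uteqmri.R`.

## Worked example

```r
library(uteqmri)

# Phantom with the SPIO-group joint-space rate; noisy five-echo UTE series.
ph <- generate_phantom(
  phantom_config(grid_size = c(64, 64), joint_space_tissue = "joint_space_spio"),
  seed = 1)
series <- simulate_series(ph, protocol_preset("cones_ute"),
                          noise_sigma = 1.8, seed = 1)
fit <- fit_loglinear(series)
roi_summary(fit, ph)
#>   roi           n_voxels  mean    sd
#> 1 joint_space        144  64.0  3.32
#> 2 fat_pad            162  49.8  2.39
#> 3 tibial_bone        794 288.  60.7
#> 4 dorsal_muscle      728  39.9  2.59
#> 5 defect_region      160  55.1  3.46
```

The fitted joint-space mean recovers the configured 64 s⁻¹ within the
noise; bone, fat, muscle and defect recover their table rates likewise.
The full two-group replicate study:

```r
report <- replicate_study(n_per_group = 7, seed = 1)
report$comparisons
#>   roi         metric           t    df     p significant
#> 1 joint_space r2star_cones -1.49  11.0 0.163 FALSE
#> 2 joint_space R12          -1.45  11.6 0.173 FALSE
#> 3 joint_space R15          -1.43  11.0 0.181 FALSE
#> 4 joint_space R25          -1.46  10.7 0.174 FALSE
```

Seven joints per group with between-joint spreads of 6–7 s⁻¹ around means
6 s⁻¹ apart give a small, weakly significant R2* decrease in the
SPIO-injected group — the same qualitative outcome as the in-vivo
comparison this design mirrors (p ≈ 0.1–0.18 depending on the draw).
`plot_roi_report(report)` draws the per-metric group bar chart, and
`run_reproduce(seed, n_per_group, out_dir)` writes the CSVs and figure in
one call.

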