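---
title: "Simulating and quantifying SPIO-induced transverse relaxation in a digital joint phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and quantifying SPIO-induced transverse relaxation in a digital joint phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Tracking superparamagnetic iron-oxide (SPIO) labelled mesenchymal stem cells
in a joint with MRI relies on the label's effect on transverse relaxation:
SPIOs raise R2 and, much more strongly, R2* (= 1/T2*, which includes the
reversible dephasing contribution R2'). Around a concentrated depot the
induced dipole field extends well beyond the source, so conventional
Cartesian gradient-echo images show a signal void far larger than the depot
itself ("blooming"), while ultrashort-echo-time (UTE) acquisitions that
sample the k-space center fractions of a millisecond after excitation retain
signal from bone and SPIO-laden tissue.

`uteqmri` provides the complete computational chain of such a study without
scanner data: a parametric digital stifle-joint phantom, a multi-echo
forward signal model with SPIO relaxivity, dipole-field dephasing and Rician
noise, an optional center-out versus Cartesian k-space layer, log-linear
R2*/R2 mapping with echo-ratio statistics, and ROI-level group comparison
across replicate phantoms.

## Signal model and assumptions

Per voxel the noiseless magnitude signal at echo time $TE$ is

$$S(TE) = PD \cdot \left[f\,e^{-R_\text{fast} TE} + (1-f)\,e^{-R_\text{slow} TE}\right] \cdot A(TE)$$

with, in gradient-echo (`r2star`) mode,
$R_\text{slow} = R_2^* + r \cdot c$, where $c$ is the SPIO concentration and
$r$ the relaxivity (1/s per unit concentration); $f$ and $R_\text{fast}$
come from the optional bi-exponential tissue fields (cartilage-like tissues
have multiple R2* components, which a mono-exponential fit over all echoes
cannot capture — the fitted rate then falls between the component rates).
$A(TE)$ is the intravoxel dephasing attenuation computed from the dipole
field of the susceptibility map. In spin-echo (`r2`) mode the static
dephasing is refocused: $R_\text{slow} = R_2$ and $A \equiv 1$.

Assumptions worth stating explicitly:

* **T1 is folded into the proton density.** All echoes of a protocol share
  one excitation, so steady-state T1 weighting is a per-voxel scale factor
  that cancels in every ratio and every log-linear slope. No T1 map exists
  in the model.
* **SPIO enters linearly** (static-dephasing regime): an additive rate
  inside the depot plus the dipole field outside. The study this mirrors
  published no relaxivity calibration for its label, so the relaxivity is a
  free parameter; its default (2000 1/s per unit concentration) makes the
  depot non-fittable by the first Cartesian echo (7 ms), matching the
  practice of not quantifying regions of heavy blooming.
* **Noise is Rician**, the magnitude of a complex Gaussian:
  $\sqrt{(S+\sigma g_1)^2 + (\sigma g_2)^2}$. Background voxels are
  Rayleigh-distributed with mean $\sigma\sqrt{\pi/2}$.

## The dipole field and blooming

The field perturbation is the convolution of the susceptibility distribution
with the unit dipole kernel, evaluated spectrally as
$D(k) = 1/3 - k_z^2/|k|^2$ with $D(0) = 0$, on a zero-padded grid
(default 2x, 4x in the validation tests) to suppress wrap-around. In the 2D
phantom the main-field axis is taken in-plane (the row axis), for which the
real-space counterpart is $\cos(2\theta)/(2\pi r^2)$; the package's tests
verify the spectral result against a brute-force real-space dipole summation
to within 5% beyond three source radii, including the sign change across the
magic angle.

Intravoxel dephasing is computed by linear interpolation of the field onto
an $m \times m$ subvoxel grid ($m = 4$ by default; 8-16 in tests needing
the analytic sinc limit) and averaging the complex phase factors. For a
linear gradient the attenuation is $|\mathrm{sinc}(\Delta\phi/2)|$ with
$\Delta\phi$ the phase spread across the voxel — the classic closed form
used as the oracle in the unit tests. Because $|\mathrm{sinc}|$ has side
lobes, magnitude signal around a strong depot can locally *rebound* between
echoes; consequently the echo-ratio bounds below are guaranteed only for
monotonically decaying (depot-free or in-depot) signals. This is a physical
feature of magnitude MRI, not an implementation artifact.

## The phantom

The phantom is a single sagittal slice (2D by default; a thin-3D mode
exists) of simple parametric shapes: a dorsal muscle slab, a supra-patellar
fat-pad ellipse, a thin synovial joint-space band, a tibial bone slab, an
8 mm-diameter defect disc carved from the bone, and an optional SPIO depot
disc at the fat-pad center (emulating a focal supra-patellar injection).
The five regions of interest are exactly the standard set: joint space, fat
pad, tibial bone, dorsal muscle, defect region. Geometry is a pure function
of the configuration; the seed only drives optional proton-density texture,
so labelled volume is conserved across seeds. The original study gives no
ROI sizes or placement rules, so placement here is parametric and makes no
claim of matching the study's ROIs.

The default tissue table anchors the two joint-space variants at the
group-mean rates the study reports (64 1/s SPIO-injected, 70 1/s control).
Every other parameter is a documented free default: bone at 300 1/s (chosen
so bone is invisible at TE >= 7 ms but bright at 0.03 ms), muscle 40, fat
50, defect 55 1/s, with R2 set below R2* throughout. Proton densities are
arbitrary signal units (joint space 90, fat 100, muscle 80, bone 30).

## Quantification

* **Log-linear fit**: unweighted ordinary least squares of $\ln S$ on TE
  (the study states linear least-squares regression and no weighting), per
  voxel, over the echoes whose signal exceeds a floor. The floor defaults to
  $3\sigma$ — a conventional guard against fitting log-noise; the study
  excluded non-fittable blooming regions without stating a rule. At least
  two usable echoes are required; otherwise the voxel is invalid, and an
  image with no fittable voxel yields an all-false mask rather than an
  error. Negative fitted rates are kept (clipping would bias ROI means
  under noise). Echo times are converted ms to s centrally; all rates are
  1/s externally.
* **Echo ratios**: $R_{12} = (S_1 - S_2)/S_1$, $R_{15} = (S_1 - S_5)/S_1$,
  $R_{25} = (S_2 - S_5)/S_2$ — zero when no signal is lost, approaching one
  at complete loss, increasing with the local rate. For any common signal
  the identity $1 - R_{15} = (1 - R_{12})(1 - R_{25})$ holds exactly.
* **Two-point estimate**: the rate is recovered from a single ratio as
  $-\ln(1 - R)/\Delta TE$. The source description of this estimator ("the
  negative logarithm of these values minus one") is ambiguous; the literal
  parses ($-\ln R - 1$, $-\ln(R-1)$) are dimensionally or analytically
  inconsistent with a quantity that correlates positively with R2*, while
  $-\ln(1-R)/\Delta TE$ inverts the mono-exponential model exactly. The
  package implements the latter and unit-tests it against the forward
  model and the full log-linear fit.
* **Subtraction images**: $S(TE_i) - S(TE_j)$, unclipped, highlighting
  fast-decaying tissue as hyperintense.

## ROI statistics and the replicate study

ROI summaries are means and population SDs over valid voxels; an ROI with
no valid voxel is reported as missing, never as zero. Group comparison is a
two-sided t-test at $\alpha = 0.15$, the permissive threshold the study
used, with no multiple-testing correction (six metrics, five regions,
uncorrected — reproduced faithfully, not recommended). The study does not
say whether its t-tests were paired across contralateral joints or pooled;
Welch's unequal-variance test is the default, with `student` and `paired`
switches. The replicate unit is the phantom ("joint"); voxels within an ROI
are never treated as independent samples.

`replicate_study()` regenerates the study design at desk scale: 7 joints
per group (seven animals, labelled cells in one stifle, unlabelled in the
contralateral), joint-space R2* drawn per replicate from
$\mathcal{N}(64, 6^2)$ and $\mathcal{N}(70, 7^2)$, UTE simulation at
first-echo SNR ~ 50 (noise sigma 1.8 against joint-space proton density
90), log-linear fit, joint-space summary, Welch comparison. With 7 per
group and these spreads the design's power at $\alpha = 0.15$ is modest,
which is consistent with the weak significance the original comparison
reported; the acceptance script recomputes the group means and p-value
from scratch at exactly this scale.

## The k-space layer

A 2D center-out radial trajectory stands in for the study's 3D cones
readout: the cones waveform mathematics were never published, and the
property under test — center-out sampling acquires $k = 0$ at
TE 0.03 ms and therefore preserves short-T2* signal that a 7 ms Cartesian
echo has lost — is generic to the trajectory family. This is deliberately
documented to avoid over-claiming: nothing here reproduces cones interleave
design, density or timing.

Sampling evaluates the exact non-uniform DFT of the object *at each
sample's own acquisition time* (decay and dephasing applied per shell);
Cartesian echoes, fully encoded at one TE, use a plain FFT.
Reconstruction is adjoint gridding: analytic annulus-area density
compensation, Kaiser-Bessel interpolation (width 4, Beatty beta) onto a 2x
oversampled grid, inverse FFT, crop, deapodization. Numerical choices that
matter:

* **Readout duration** (unpublished in the source study) defaults to
  0.5 ms: long readouts let short-T2* tissue decay across the spoke, which
  blurs exactly the tissue UTE exists to capture.
* **Radial readout oversampling**: 2-n samples per spoke (4x the Nyquist
  radial step). The gridding error against the FFT oracle falls from ~7%
  RMSE at Nyquist-step sampling to under 1% at this density.
* Radial coverage is the inscribed disc of the Cartesian square; all test
  objects are smooth enough that the spectrum beyond the disc is
  negligible.

## Problem sizes and determinism

Defaults are sized for interactive work: 64-128 voxel grids, 5-6 echoes,
replicate sweeps on 64 x 64 phantoms. Every stochastic step takes an
explicit integer seed and restores the caller's RNG state, so identical
inputs give byte-identical outputs, including the CSV reports. NIfTI files
carry a JSON sidecar that is authoritative for echo times and protocol
metadata; NIfTI time-axis metadata is not trusted across tools.

## What the synthetic data do and do not show

The generator emulates the contrast mechanisms (multi-echo decay at the
three protocols' echo times, SPIO relaxivity, blooming, Rician noise) on
deliberately simple geometry. It does not emulate anatomically realistic
ovine joints, B0/B1 inhomogeneity beyond the SPIO dipole field, chemical
shift of fat, slice profiles, coil sensitivity, partial-Fourier or
parallel-imaging artifacts, or physiological variation beyond the
between-replicate rate spread. Passing tests therefore demonstrate the
correctness of the quantification chain and the qualitative
acquisition-contrast mechanisms, not in-vivo performance.

## Known limitations

* Echo-ratio values can leave $[0, 1)$ in voxels where dephasing causes a
  magnitude rebound between echoes (sinc side lobes near a strong depot);
  the bounds are guaranteed only for monotone decay.
* The mono-exponential fit is biased for genuinely multi-exponential
  tissue; the bi-exponential phantom option exists precisely to demonstrate
  this (the fitted rate lies strictly between the component rates).
* The 2D in-plane dipole kernel is a stand-in; quantitative 3D blooming
  geometry requires the thin-3D mode with the 3D kernel.
* No multi-component (NNLS-type) T2* spectrum fitting: more intermediate
  echo times than these protocols provide would be required.
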