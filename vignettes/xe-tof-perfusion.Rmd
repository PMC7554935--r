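---
title: "Modeling and mapping perfusion with hyperpolarized 129Xe time-of-flight MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and mapping perfusion with hyperpolarized 129Xe time-of-flight MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xetof)
```

## The method

Hyperpolarized (HP) xenon-129 carries a non-equilibrium nuclear polarization
up to ~10^5 times thermal. Once a radiofrequency pulse tips that
magnetization, spin–lattice relaxation does *not* restore it, which turns a
saturation pulse into a perfect "eraser": after a 90° pulse over the imaging
volume, any dissolved-xenon signal observed a delay $\tau$ later must have
been *carried in* by arterial blood. Repeating saturation → delay → gradient-echo
readout at several time-of-flight (TOF) delays and fitting the
signal-versus-delay slope pixel by pixel therefore yields maps proportional
to tissue perfusion, and subtracting a baseline slope map from a task slope
map localizes stimulus-driven blood-flow changes (a hemodynamic-response,
HDR, map).

This package implements the complete desk-side counterpart of that
experiment: the kinetic signal model, digital brain and tube-flow phantoms
with a forward k-space acquisition model, the reconstruction chain
(zero-padding, FFT, SNR maps), and the parametric-map estimators.

## The kinetic model

A voxel is modeled as one (or a sum of) well-mixed tissue compartment(s).
After saturation at $t = 0$, fresh HP xenon arrives with arterial inflow at
perfusion rate $f$ (mL blood · mL tissue$^{-1}$ · min$^{-1}$), decaying in
blood with $T_{1b}$; in the voxel it is cleared by venous outflow and tissue
relaxation:

$$\frac{dM}{dt} = \frac{f}{60}\, m_{a0}\, e^{-t/T_{1b}} - kM,
\qquad k = \frac{f}{60\,\lambda} + \frac{1}{T_{1t}},$$

with $\lambda$ the blood–tissue partition coefficient of dissolved xenon
and $m_{a0}$ the arterial magnetization scale. With $M(0) = 0$,

$$M(\tau') = \frac{f}{60}\, m_{a0}\,
  \frac{e^{-\tau'/T_{1b}} - e^{-k\tau'}}{k - 1/T_{1b}},
\qquad \tau' = \max(\tau - \Delta_t, 0),$$

where $\Delta_t$ is the arterial transit delay (default 0 s; no published
value exists for this protocol, so it is exposed as a parameter rather than
guessed). At the removable singularity $k = 1/T_{1b}$ the implementation
switches to the limit form $(f/60)\,m_{a0}\,\tau' e^{-\tau'/T_{1b}}$ when
$|k - 1/T_{1b}| < 10^{-10}\,\mathrm{s}^{-1}$; continuity there is tested
explicitly. The solution is verified against an independent 4th-order
Runge–Kutta integration of the ODE (1 ms steps, 100 random parameter draws,
agreement required to 0.1%).

Two assumptions motivate the working approximation: relaxation in blood
dominates the polarization decay during wash-in, and the clearance rate $k$
is small. Then the signal is linear in the delay,

$$M_{lin}(\tau) = \frac{\sum f}{60}\, m_{a0}\, \tau',$$

so the fitted slope estimates the *sum* of the compartment perfusions. The
linear form is an upper bound on the analytic solution and its relative
error grows roughly as $(1/T_{1b} + k)\,\tau$: under gray-matter-like
parameters ($T_{1b} = 8$ s) it is below 10% for $\tau \le 0.7$ s but the
slope of a straight-line fit through delays of several seconds
underestimates perfusion severely (at the in vivo triplet 2.5/6.7/7.1 s the
secant slope is only ~35% of the true initial slope). This is why the
quantitative simulations below use delays inside the linear regime, while
the long in vivo triplets are shipped as presets for protocol emulation.

### Units and calibration

Perfusion is stored in mL·mL$^{-1}$·min$^{-1}$ throughout; all internal
kinetics run in seconds with a single explicit ÷60 conversion, made once
and tested once. The slope→perfusion conversion is
$F = 60\,\mathrm{slope}/s_{arterial}$, where $s_{arterial}$ — the SNR a
voxel completely replaced by fresh arterial blood would have — is the one
calibration scalar of the method. With real data it must be measured or
assumed; for simulated data `arterial_reference()` computes it exactly from
the known gains (arterial magnetization × flip-angle depletion of the DC
k-space line × the unitary-DFT zero-padding amplitude factor ÷ background
noise sd). Because the same measured noise sd enters both the SNR maps and
the calibration, the Rayleigh bias of the background noise estimate cancels
in the perfusion values.

### Default tissue parameters

`kinetics_preset()` ships literature-conventional values — gray matter
$f = 0.55$, white matter $f = 0.22$ mL/mL/min, $\lambda = 0.9$,
$T_{1b} = 8$ s, $T_{1t} = 16$ s — clearly as defaults for simulation, not
measured constants of any specific experiment.

## The flow phantom

The in vitro system is a 3.175 mm inner-diameter tube fed by a syringe pump
at 5–10 mL/min, with xenon-laden saline refilling a coil-sensitive length
$L$ after each saturation. The signal is the replenished fraction of the
sensitive volume $V = \pi R^2 L$:

* **plug** profile — a sharp front, $S(\tau)/s_{max} = \min(Q\tau/V, 1)$,
  exactly linear until the fill time;
* **laminar** (Poiseuille) profile — $v(r) = 2\bar v (1 - (r/R)^2)$, giving
  the closed form $u/2$ for $u \le 1$ and $1 - 1/(2u)$ for $u > 1$ with
  $u = 2\bar v \tau / L$. It coincides with plug flow early (before the
  fastest axial spins exit) and bends smoothly toward the plateau.

The laminar branch is validated against a $10^4$-point radial trapezoid
quadrature. The sensitive length has no published value; the default,
$L = 20$ mm, was chosen so the simulated curves reproduce the reported
qualitative features of the experiment within the 0.2–2 s delay range — a
quasilinear rise to ~0.7 s, a nonlinear transition, earlier saturation at
10 mL/min and only slight saturation at 5 mL/min. A pleasant consequence,
not a tuning target: with this geometry the *noiseless* laminar curves give
a flow-rate/slope Pearson correlation of 0.989 over the 200–700 ms window —
the mild curvature of the fastest curve, not noise, keeps it below 1 —
essentially the correlation observed experimentally. Curve noise defaults
to 2% of the plateau signal; with only four flow rates and six points per
window fit, the sampled correlation is then intrinsically volatile (median
≈ 0.97 across seeds), so tests assert the exact plug identity and the clean
laminar bound, and treat the noisy correlation as a distributional check.

## The forward acquisition model

`simulate_tof_series()` generates, per delay: the noiseless per-pixel
magnetization from the phantom's compartments → forward unitary 2-D DFT →
per-line depletion weighting → additive complex Gaussian noise (seeded).
Key conventions, each pinned by a test:

* **Depletion.** HP magnetization is consumed, not recovered: the $j$-th
  excitation of a dynamic carries $\sin\alpha\,\cos^{j-1}\alpha$ of the
  magnetization available at that delay. The saturation pulse resets
  between dynamics, so weighting restarts each dynamic; residual
  cross-dynamic depletion is ignored (each dynamic starts from the kinetics
  value at its own delay). Phase-encode ordering is linear by default,
  centric optionally (the DC line then gets the freshest magnetization).
* **DFT.** Unitary ($1/\sqrt N$ per transform), DC sample at 0-based index
  $\lfloor N/2\rfloor$ on both the 20 and 32 grids; Parseval
  ($\sum|I|^2 = \sum|K|^2$) pins the normalization.
* **Zero-padding.** Symmetric insertion of exact zeros around the centered
  spectrum (any odd remainder on the high-frequency side); pad-then-crop is
  exactly the identity, and the padded reconstruction interpolates the
  original samples (checked against a naive direct-DFT oracle).
* **Noise.** Complex Gaussian in k-space; magnitude backgrounds are
  therefore Rayleigh with $\sigma_{mag} = \sigma_c\sqrt{2 - \pi/2}$. The
  noise sd used for SNR maps is the *plain* standard deviation of the
  magnitude background — matching the stated processing of the source
  protocol — with the Rayleigh correction available as an option, and the
  choice is immaterial for perfusion values (it cancels, see above).

## Fitting and mapping choices

* The pixel-wise fit includes an intercept by default: the in vivo delay
  triplets do not start at zero and saturation is never perfect, so forcing
  the line through the origin is unsafe. A through-origin option exists.
* No per-pixel weighting (three points leave nothing to estimate weights
  from); the slope standard error from the residual ($n-2$ dof) is carried
  as a quality layer.
* Negative slopes are retained, not clipped — clipping would bias HDR
  subtraction — and flagged in the perfusion map's quality layer.
* Default fitting mask: pixels whose maximum SNR across dynamics exceeds 3
  (the protocol states no rule; this is a conventional choice).
* HDR thresholding (`threshold_hdr()`, a display utility that is an
  addition of this package, not part of the source protocol) measures
  deviations from the in-mask *median*: two separately normalized series
  carry independent noise-sd estimates, which offsets the whole difference
  map by a few percent of the slope scale; median centering removes that
  common mode while staying robust to a minority of activated pixels.

## Study designs used by the tests and the acceptance script

All simulations run on the 20 × 20 acquisition grid over a 250 × 250 mm
field of view, zero-padded to 32 × 32, flip angle 20°, with the
two-compartment head phantom (gray shell 0.55, white core 0.22 mL/mL/min).
Compartment means on reconstructed maps use masks eroded by 1.5
reconstruction pixels, which keeps Gibbs/partial-volume edge effects out of
the evaluation.

* **Delay presets.** The in vivo protocols are shipped verbatim (axial
  2.5/6.7/7.1 s, sagittal 1/6.5/7.1 s, visual 1/6.5/8 s, motor
  2.5/6.8/7.1 s — the published triplets differ slightly between protocol
  descriptions, so all variants are provided and none is canonical). The
  `"linear"` preset, 0.1/0.2/0.3 s, lies inside the regime where the
  linearized estimator is nearly unbiased: the noiseless end-to-end
  pipeline recovers compartment perfusion within ~2% there (bias grows with
  the mean delay, reaching tens of percent at the in vivo triplets — a
  documented property of the linear model, not a defect of the fit).
* **Perfusion recovery.** k-space noise is calibrated by
  `noise_for_target_snr()` so the mean brain image SNR is ≈10, matching the
  SNR regime of the real perfusion maps; 20 seeds are simulated and the
  *ensemble* compartment means are required to land within 15% of truth.
  Single-seed white-matter means fluctuate by up to ~20% at this SNR — with
  three fit points and a 56-pixel compartment that spread is expected.
* **HDR localization.** A +20% perfusion blob at map SNR 10 has per-pixel
  contrast-to-noise ≈1 for a three-point fit — undetectable at a 2σ
  threshold by any estimator. The localization study therefore runs at map
  SNR 60, chosen by power analysis (blob contrast-to-noise ≈3 after
  partial-volume dilution), where the thresholded HDR map overlaps the true
  blob with Dice ≈ 0.7–0.9. The real experiment detects activation at much
  lower map SNR because real hemodynamic responses are larger than 20% and
  are judged over anatomically contiguous regions, not single pixels.

## What the synthetic data does and does not emulate

The generator reproduces the acquisition geometry, the HP depletion
physics, Rician magnitude statistics, and the tracer-kinetic time courses.
It does **not** emulate: $B_0$/$B_1$ inhomogeneity, chemical-shift-resolved
dissolved-phase structure, motion or breath-hold variability, gas-phase
contamination artifacts (visible in real images), coil sensitivity
profiles, or anatomical heterogeneity beyond two elliptical compartments.
Passing the recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to everything a scanner
can produce.

Also out of scope by design: wash-out-phase modeling, multi-exponential
spectroscopic (CSSR) fitting, chemical-shift-selective phase separation,
BOLD fMRI processing, image registration between xenon and proton scans,
and any multiple-comparison control on HDR maps (the display threshold is
labeled as a convenience).

## Reproducing the numbers

`scripts/acceptance.R --seed <int> --out <path>` reruns everything above
from scratch — closed-form RF values, clean and noisy flow-phantom
correlations (20 replicates), 20-seed perfusion recovery at map SNR ≈ 10,
and 5-replicate HDR localization at map SNR 60 — and writes the results as
JSON. The whole run takes well under a minute on one CPU.
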