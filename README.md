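# xetof — hyperpolarized ¹²⁹Xe time-of-flight perfusion mapping

`xetof` is an R package for simulating and reconstructing hyperpolarized
(HP) xenon-129 **time-of-flight (TOF) depolarization–recovery MRI** of
tissue perfusion. It is aimed at MR physicists and image-analysis
developers who want a fully tested, deterministic desk-side model of the
experiment: the tracer-kinetic signal model, digital brain and tube-flow
phantoms with a forward gradient-echo k-space acquisition model, the
reconstruction chain (k-space zero-padding, FFT magnitude images, SNR
maps), and the parametric-map estimators (pixel-wise slope fits, perfusion
maps, hemodynamic-response maps).

## The idea

Hyperpolarized magnetization is a non-equilibrium resource: once tipped by
an RF pulse it is *not* restored by relaxation. A 90° saturation pulse over
the head therefore erases all dissolved-xenon signal, and anything measured
a recovery delay τ later was carried in by arterial blood. The voxel signal
follows a one-compartment uptake model,

    dM/dt = (f/60) · m_a0 · exp(−t/T1b) − k·M,      k = f/(60λ) + 1/T1t

whose solution, for short delays, is linear in τ with slope proportional to
the **summed perfusion f** of the voxel (mL blood · mL tissue⁻¹ · min⁻¹).
Fitting signal-vs-delay pixel by pixel and rescaling by the arterial
reference SNR,

    F = 60 · slope / s_arterial,

yields quantitative perfusion maps; subtracting a baseline slope map from a
task slope map yields a hemodynamic-response (HDR) map that localizes
stimulus-driven blood-flow changes.

## Worked example

Simulate a dynamic TOF series of the two-compartment digital head phantom
(gray matter 0.55, white matter 0.22 mL/mL/min) at the map SNR of a typical
in vivo acquisition, reconstruct it, and fit perfusion maps:

```r
library(xetof)

spec  <- brain_phantom_spec()                        # GM shell + WM core
acq   <- acquisition_params(
  tof_delays = tof_delay_preset("linear"),           # 0.1/0.2/0.3 s
  noise_sd   = noise_for_target_snr(spec,
                 acquisition_params(tof_delays = tof_delay_preset("linear")),
                 target_snr = 10),
  seed = 1)

series <- simulate_tof_series(spec, acq)             # 20x20 k-space x 3
rec    <- reconstruct_series(series)                 # pad to 32x32, FFT, SNR
slopes <- fit_slope_map(rec, mask = default_fit_mask(rec))
slopes
#> <slope_map> 32 x 32 pixels, 3 dynamics (tau = 0.1, 0.2, 0.3 s)
#>   slope range: -23.91 .. 94.8 per s

perf <- make_perfusion_map(slopes,
          arterial_reference(acq, m_a0 = 100, sigma_hat = rec$sigma_hat))
round(compartment_means(perf$f_sum,
        phantom_masks(spec, dims = c(32, 32), erode_px = 1.5)), 3)
#>  gray white
#> 0.530 0.209
```

The recovered compartment means (0.530 and 0.209) sit within a few percent
of the ground truth (0.55 and 0.22); the residual deficit is the documented
short-time linearization bias plus map noise.

The in vitro counterpart — TOF recovery curves from a tube flow phantom at
the four pump rates — and their flow-rate/slope correlation:

```r
flows  <- c(5, 6, 7, 10)                              # mL/min
curves <- lapply(flows, function(q)
  simulate_flow_curve(flow_phantom_spec(q, noise_sd = 0)))
flow_slope_correlation(flows, curves)
#> <flow_correlation> r = 0.9891  (p = 0.0109 ) over window [ 0.2 , 0.7 ] s
#>   flows (mL/min): 5, 6, 7, 10
#>   slopes (1/s):   0.5263, 0.6315, 0.7361, 0.92
```

The slight departure from r = 1 is physics, not noise: the laminar
(Poiseuille) velocity profile bends the fastest curve within the fit
window. A plug-flow profile gives exactly r = 1.

A command-line front end wrapping the same functions (verbs `simulate`,
`flowsim`, `correlate`, `map`, `hdr`) is installed at
`system.file("cli", "xetof.R", package = "xetof")`; series and maps travel
as NIfTI volumes with JSON sidecars, flow curves as CSV.

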