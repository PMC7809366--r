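# massrhythm

Detection of short-period (ultradian) rhythms in single-cell **dry mass**
measured by lens-free inline holographic microscopy — as a tested, simulated
end-to-end pipeline.

Quantitative phase imaging converts the optical phase delay of a cell into
its dry mass: the optical path difference per pixel is
OPD(x,y) = λ·φ(x,y)/2π, its integral over the cell's projected area is the
optical volume difference (OVD, µm³), and CDM = OVD/α with the specific
refractive increment α = 0.18 µm³ pg⁻¹ gives the cell dry mass in picograms.
Followed every 5 minutes over days, single-cell dry mass grows roughly
linearly through interphase — and carries a small pulsatile component
(~30 min wide, ~100 pg, every ~4.2 h, i.e. 0.004 min⁻¹) that is invisible in
any one trace: the pulse is only ~3× the 35 pg measurement precision and sits
on 1/f noise. Detecting it is a cohort statistic: average the sine-windowed
Fourier amplitude spectra of hundreds of unsynchronized cells, reject the 1/f
background, and test for a sharp line with harmonics.

The package is for people building or validating this kind of analysis:
it provides the full measurement chain **and** a ground-truthed synthetic
generator, so every stage can be checked against known truth.

* **Synthetic data** — dry-mass trajectories (linear growth + pulse train +
  1/f + white noise, divisions, heterogeneous cycle lengths) and optical
  cell phantoms rendered into intensity holograms by Fresnel propagation
  (λ = 647 nm, Z ≈ 1.5 mm).
* **Phase retrieval** — total-variation regularized inversion of
  intensity-only holograms by preconditioned Hestenes–Stiefel nonlinear
  conjugate gradients (15 iterations, ε = 10⁻⁴), plus the negative-region
  unwrapping rule.
* **Cells** — Laplacian-of-Gaussian spot detection, seeded region-growing
  segmentation with geodesic splitting of touching cells, LAP-style
  frame-to-frame linking with gap closing, division detection (mass drop +
  daughter-track birth).
* **Rhythm statistics** — per-cell spectra on the oversampled grid
  df(j) = 1/(T(j)·M) with M = 25, cohort bins of width n_f/(T_max·M),
  power-law-plus-floor background fit, fundamental detection with
  harmonic-comb refinement, inverse-Fourier waveform reconstruction (two
  sign solutions), negative controls, cohort-size scans, and an
  oscillator-strength (AF) comparison between conditions.

The central interface is one fitting function returning a classed object:

```r
fit <- rhythm_fit(traces)   # print, summary, coef, plot, predict, simulate
```

## Worked example

```r
library(massrhythm)

coh <- generate_cohort(cohort_config(n_cells = 300, seed = 1))
fit <- rhythm_fit(coh)
fit
#> Cohort rhythm fit
#>   300 traces (0 excluded), bins of 1.62e-05 min^-1
#>   fundamental: 0.0039922 min^-1 (period 4.17 h), AF = 4.33 pg, significance 7.7

inverse_reconstruct(fit$peak)
#> <rhythm_waveform> 6 harmonics, period 250.5 min; spikes: interval 4.17 h,
#>   FWHM 27 min, height 78 pg
```

Read: the cohort spectrum of 300 simulated cells recovers the injected
fundamental at 0.0040 min⁻¹ (period 4.17 h) with significance 7.7 standard
errors above the fitted 1/f background; the inverse-Fourier reconstruction
(six harmonics, both sign solutions) shows spikes every 4.17 h, ~27 min wide
at half maximum, ~78 pg peak-to-baseline — the ~20% height deficit against
the injected 100 pg is the deterministic six-harmonic truncation loss (see
the methods vignette). Shuffling each trace's residuals kills the signal:

```r
rhythm_fit(negative_control_cohort(coh, "shuffle", seed = 2))
#> Cohort rhythm fit
#>   300 traces (0 excluded), bins of 1.62e-05 min^-1
#>   no significant peak (best bin significance 2.79)
```

The full imaging chain (render holograms → retrieve phase → track → segment
→ dry mass → spectrum) runs through `run_pipeline(pipeline_config(mode =
"full-imaging"))`; `vignettes/rhythm-detection.Rmd` documents the models,
parameter choices and limitations.

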