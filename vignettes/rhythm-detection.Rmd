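---
title: "Detecting an ultradian dry-mass rhythm: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting an ultradian dry-mass rhythm: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Lens-free inline holographic microscopy follows the dry mass of thousands of
individual adherent cells at 5-minute resolution over several days. In such
records, single-cell dry mass grows roughly linearly through interphase, and
superimposed on that growth is a small pulsatile component: symmetric pulses
roughly 30 min wide and ~100 pg high, repeating about every 4.2 h
(0.004 min^-1). A single cell's trace is too noisy to show this directly —
the pulse height is only about three times the ~35 pg single-sample
measurement precision, and slow 1/f fluctuations dominate the low
frequencies — so detection is a cohort-level statistical operation: average
the Fourier amplitude spectra of hundreds of unsynchronized cells, reject the
1/f background, and test whether a sharp spectral line with harmonics stands
out.

`massrhythm` implements this chain end to end, together with a
ground-truthed synthetic-data generator so that every stage can be validated
against known truth:

1. **Synthetic data** (`generate_trace`, `generate_cohort`,
   `render_hologram`, `render_scene`): dry-mass trajectories with a known
   injected rhythm, and optical phantoms rendered into intensity-only
   holograms.
2. **Holographic reconstruction** (`propagate`, `retrieve_phase`,
   `unwrap_phase`): Fresnel propagation and total-variation regularized
   phase retrieval by nonlinear conjugate gradients.
3. **Segmentation and tracking** (`detect_spots`, `segment_cells`,
   `link_tracks`, `detect_divisions`): blob detection, seeded region
   growing, optimal frame-to-frame assignment with gap closing, and
   division-event detection.
4. **Dry mass** (`phase_to_opd`, `integrate_ovd`, `ovd_to_cdm`,
   `build_traces`): phase to optical path difference (OPD) to optical volume
   difference (OVD) to picograms.
5. **Spectral statistics** (`rhythm_fit` and friends): sine-windowed
   per-cell spectra, cohort averaging, background fitting, fundamental-peak
   detection, inverse-Fourier waveform reconstruction.

The central user-facing entry point is the model-fitting function:

```{r}
library(massrhythm)
coh <- generate_cohort(cohort_config(n_cells = 300, seed = 1))
fit <- rhythm_fit(coh)
summary(fit)
plot(fit)                   # cohort spectrum, background fit, peak
predict(fit)                # reconstructed waveform (both sign solutions)
```

# The signal model

A synthetic interphase trace sampled every $dt$ minutes over $T$ minutes is

$$ m(t) = m_0 + g\,t \;+\; s\,A\,p(t - \theta) \;+\; \eta_{1/f}(t) \;+\;
   \varepsilon(t), $$

where $m_0$ is the initial mass, $g$ the linear growth rate, $p$ a periodic
train of unit pulses (raised-cosine by default, triangular available) of
full width $W$ repeating every $P$ minutes, $A$ the pulse amplitude, $s = \pm
1$ the pulse sign, $\theta$ a per-cell uniform phase offset (asynchronous
culture), $\eta_{1/f}$ pink noise whose amplitude spectrum falls as
$f^{-\beta/2}$ (power $\propto f^{-\beta}$, $\beta = 1$ by default), and
$\varepsilon$ white measurement noise.

Defaults and their origin:

| parameter | default | unit | rationale |
|---|---|---|---|
| `period` | 250 | min | the rhythm class under study (0.004 min^-1) |
| `pulse_width` | 30 | min | pulse full width |
| `pulse_amplitude` | 100 | pg | pulse height in fibroblast-like cells |
| `pulse_shape` | raised-cosine | — | symmetric and band-limited |
| `measurement_noise_sd` | 35 | pg | instrument single-sample precision |
| `initial_mass` | 300 | pg | small adherent cell after division |
| `growth_rate` | 0.25 | pg/min | mass roughly doubles over a 1200-min cycle |
| `pink_noise_rms` | 30 | pg | slow biological drift comparable to the measurement floor |
| `sampling_interval` | 5 | min | acquisition cadence |
| cycle length | lognormal, median 1200, sdlog 0.25 | min | heterogeneous interphase durations |

The last four are calibration choices of this package (no published values
exist for them); they were fixed once, before any acceptance statistics were
frozen, and are exposed in `growth_noise_params()` / `cohort_config()`.

Divisions drop the mass abruptly to a fraction $u \sim U(0.45, 0.55)$ of its
pre-division value and spawn a daughter track on the next frame, 13–15 px
away. The returned per-cell analysis trace is the first full interphase, so
each cell contributes one record of its own duration $T(j)$.

## What the generator emulates, and what it does not

The generator reproduces the *statistical* structure the spectral analysis
relies on — linear growth, an asynchronous pulse train, 1/f plus white
noise, heterogeneous trace lengths, division discontinuities — and, for the
imaging chain, cells as radially symmetric OPD phantoms (cosine dome or
uniform disc) performing confined random walks, plated with a minimum
separation and respreading apart after division. It does **not** emulate
real cell morphology and its fluctuations, motility beyond a random walk,
cell–cell contact mechanics, illumination partial coherence, or sensor
artifacts. Passing tests therefore demonstrate that the *algorithms* recover
known truth under the stated noise model, not that real data will be as
well-behaved; in particular the tracking and division statistics are upper
bounds on what morphologically variable cells would give.

Three scene-realism choices deserve explicit mention because the tracking
stage depends on them. (i) Cells are plated with a minimum separation
(dart-throwing): with uniform plating, unrelated simulated walkers
interpenetrate freely — something adherent cells do not do — and every such
crossing forges a division-like segmentation event. (ii) After division the
two cells drift apart by 0.5 px/frame each (saturating at 8 px) on top of
their random walks: freshly divided cells respread away from the cleavage
plane within minutes, and without this the blob detector cannot separate the
pair for tens of frames (the Laplacian-of-Gaussian kernel's negative annulus
suppresses a neighbor closer than ~20 px). (iii) The daughter is born 13–15
px from the mother — two ~10 px cells side by side — which is also the
closest separation the detector can resolve at the configured blob diameter.

# Holographic reconstruction

Light is a scalar complex field; propagation over a distance $Z$ multiplies
the angular spectrum by the unitary Fresnel transfer function
$H_Z(f) = \exp(-i\pi\lambda Z |f|^2)$ (the constant piston phase
$e^{i2\pi Z/\lambda}$ is dropped: an intensity-only sensor destroys it, and
keeping it would put an arbitrary global phase on every reconstruction).
`propagate(field, -Z)` exactly inverts `propagate(field, Z)`, and
$h_{-Z} = \overline{h_Z}$.

The sensor records only $I_Z = |A_Z|^2$. For *any* sensor-plane phase
$\varphi_Z$, the object field
$A_0(\varphi_Z) = (\sqrt{I_Z}\,e^{i\varphi_Z}) * h_{-Z}$ reproduces the data
exactly, so retrieval reduces to choosing $\varphi_Z$. We pick the
$\varphi_Z$ minimizing a total-variation criterion of $A_0$:

$$ \varepsilon(\varphi_Z) \;=\; \sum_{\text{pixels}}
   \sqrt{\epsilon + |\partial_x A_0|^2 + |\partial_y A_0|^2},
   \qquad \epsilon = 10^{-4}, $$

with forward differences and periodic wrap (consistent with the FFT
propagation). Two variants are provided by `tv_criterion`: this smoothed
isotropic form (the default — here $\epsilon$ genuinely keeps the gradient
finite everywhere) and an L1 form
$\sum\sqrt{\epsilon + |\partial_x A_0| + |\partial_y A_0|}$, whose
derivative stays singular wherever a difference vanishes no matter the
$\epsilon$; in our experiments nonlinear conjugate gradients on the L1 form
stalls at a twin-image local minimum (phase error ratio ~1.0 vs plain
back-propagation even after hundreds of iterations), while the smoothed form
converges. Both reduce to $N\sqrt{\epsilon}$ on a constant field.

`retrieve_phase` runs 15 iterations (the standard budget for this
reconstruction) of Hestenes–Stiefel nonlinear conjugate gradients from
$\varphi_Z = 0$, with:

* an analytic gradient through the unitary back-propagation (verified
  against central finite differences in the tests);
* a **Fourier-space preconditioner** $1/(\mathrm{lap}(k) + c_0)$,
  $c_0 = 0.05$, where $\mathrm{lap}(k)$ is the discrete Laplacian
  eigenvalue: in the small-residual regime the criterion's Hessian
  approaches $\mathrm{Laplacian}/(2\sqrt{\epsilon})$, and without the
  preconditioner the low-spatial-frequency content (the cell body and its
  twin image) converges far too slowly for a 15-iteration budget (phase
  error ratio 0.72 instead of ~0.26 on the reference scene);
* a second-order line search: the step minimizes the quadratic development
  of the criterion along the direction (directional curvature from a
  differenced gradient), with backtracking halving as a safeguard, so the
  criterion never increases across accepted iterations;
* $\beta_{HS}$ clamped at zero (restart) to guarantee descent.

On a noiseless 256×256 single-cell scene this halves (in fact roughly
quarters) the object-phase RMSE of plain back-propagation within the 15
iterations, and recovers ~96% of the integrated OPD; the residual few
percent is the flattening the sparsity prior exerts on extended objects. A
multiplicative correction for such retrieval losses is available in
`ovd_to_cdm(apply_correction = TRUE)` (factor 1/0.65, the value appropriate
for reconstructions that lose ~35% of signal) but is **off** by default:
this implementation's measured loss on phantoms is only a few percent, and
the honest thing is to expose the measured loss rather than assume a fixed
one.

Phase images whose shift exceeds $+\pi$ wrap to negative values;
`unwrap_phase` sets every (4-connected) region of pixels below a threshold
to $+\pi$. The literal rule (threshold 0) presumes a clean nonnegative
background; on reconstructions whose background ripples around zero it would
flip half the background, so the pipeline applies a floor of $-0.5$ rad —
genuinely wrapped pixels sit far below zero.

# Segmentation, tracking, divisions

`detect_spots` computes a scale-normalized Laplacian-of-Gaussian response at
$\sigma = d/(2\sqrt2)$ for blob diameter $d$ (default 15 px), normalizes it
to the image maximum, keeps local maxima above the quality threshold
(default 0.7) and refines them to sub-pixel precision by quadratic fits.
Note the normalization makes the threshold *relative to the brightest cell
in the frame*: 0.7 is appropriate when cells are of comparable mass; scenes
whose cells span the full division/growth range (a factor ~2.5) need a
proportionally lower threshold, which is why the rendered-scene tests use
0.25–0.35.

`segment_cells` grows all seeds jointly over 4-connected pixels above the
phase threshold; each pixel goes to the seed that reaches it first, so
touching cells split along the geodesic midline (watershed-fashion) and
masks are disjoint. `integrate_ovd` then sums OPD over the mask
(OVD, µm³) and `ovd_to_cdm` divides by the specific refractive increment
$\alpha = 0.18\ \mu m^3/pg$ to give dry mass.

`link_tracks` is a two-pass LAP-style tracker: optimal frame-to-frame
bipartite assignment (an O(n³) shortest-augmenting-path solver written
in-package, unit-tested against exhaustive search) with a hard 15 px cutoff
and birth/death alternatives, then greedy gap closing (distance, then frame
gap) for up to 5 missed frames within 15 px, then a 10-spot minimum track
length. Linking is invariant to detection order.

`detect_divisions` declares a division at frame $f$ when the track's mass
drops by ≥30% between $f$ and $f+2$ **and** a new track is born within 15 px
of the track during $[f, f+2]$ (distance taken as the minimum over the
window: at the split frame the merged blob centroid lies between the two
cells). The 30%/2-frame rule separates true halving (~50%) from measurement
noise (35 pg on 300–1000 pg cells); it is a calibration choice surfaced in
the arguments. Interphase intervals tile each track's lifetime between
divisions.

# Cohort spectral statistics

Each trace is linearly detrended (removing growth) and multiplied by the
half-period sine window $w(t) = \sin(\pi (t-t_0)/T)$, which vanishes at both
record ends. `cell_ft` evaluates absolute Fourier amplitudes on the
oversampled grid $f_k = k\,df(j)$, $df(j) = 1/(T(j)\,M)$ with $M = 25$, up
to Nyquist, normalized by the sample count so a unit sinusoid contributes
the same peak amplitude whatever the trace length (implemented by
zero-padding to $M$ times the record length). `average_spectra` accumulates
all cells into common bins of width $n_f/(T_{max} M)$ ($n_f = 1$ or 2);
every per-cell frequency lands in exactly one bin, and per-bin mean,
standard deviation and contribution count are kept.

## Background model

The mean-amplitude background is fitted as a power law plus a white floor
added in quadrature,

$$ A(f) = \sqrt{(c f^{-\beta})^2 + w^2}, $$

by Nelder–Mead least squares on log amplitudes, iteratively masking bins
more than 3 standard errors above the fit and refitting. The floor term
matters: incoherent noise components add in power, not amplitude, so a
single log-log line through a 1/f-plus-white mixture is convexity-biased —
it dips below the data at both band edges, manufacturing spurious
"significant" excess exactly where the fundamental search looks.

## Finding the fundamental

Significant bins (excess > 3 standard errors of the bin mean) are grouped
into contiguous clusters; a genuine peak spans about one window main lobe,
i.e. many cohort bins. Candidate clusters are examined in frequency order,
and the fundamental is the **first cluster that survives validation**:

1. an initial excess-weighted centroid over the top half of the cluster
   lobe;
2. an iterated **harmonic-comb refinement**: the $m$-th harmonic lobe sits
   at $m f_0$, so its centroid locates $f_0$ with $m$-fold leverage; within
   each harmonic window the excess is locally detrended by a line through
   the window flanks (smooth leakage tilt would otherwise drag the
   centroid), the top-half centroid taken, and the per-harmonic estimates
   combined with weights $(m \cdot \text{lobe height})^2$;
3. the refined bin must remain >3 SE above the background **and** at least
   two higher-harmonic lobes must have been found. A rhythm peak appears
   together with its harmonics; a background bump mimics a single lobe but
   not a harmonic stack. This harmonic-support requirement is what holds
   the false-positive rate of the negative controls below 5%, and skipping
   failed candidates prevents a low-frequency bump from masking the true
   fundamental.

The reported significance is $(\text{mean} - \text{background}) /
(\mathrm{sd}/\sqrt{\text{count}})$ at the fundamental bin. The
standard-error scale is deliberate: cohort averaging reduces the background
fluctuations of the mean spectrum as $1/\sqrt{n}$ while the coherent peak
persists, which is precisely why the rhythm only emerges once enough cells
are pooled (`cohort_size_scan` shows the significance growing roughly as
$\sqrt{n}$, with detection typically requiring on the order of a hundred
cells at default noise).

## Waveform reconstruction and its calibration

Cohort averaging keeps only absolute amplitudes, so all harmonics are
cosine-aligned at $t = 0$ and the waveform sign is undetermined:
`inverse_reconstruct` returns both solutions
$\pm\sum_m \hat a_m \cos(2\pi m f_0 t)$ (mass-gain pulses vs mass-loss
pulses). Per harmonic ($m \le 6$ by default):

* the measured amplitude is the count-weighted mean over the flat top of
  the harmonic lobe ($|f - m f_0| \le 0.2/T_{med}$, where the window
  response still exceeds 0.95) — single bins can be sparsely populated by
  the beating of per-cell grids against the cohort bins, and single-bin
  reads made the reconstructed spike height scatter several-fold more;
* the coherent amplitude is recovered by inverting the **Rician mean**: the
  observed mean is the expectation of $|s + \text{noise}|$ with the noise
  scale set by the fitted background (its Rayleigh mean). Linear background
  subtraction underestimates the signal by ~30% at the default
  signal-to-background ratio because amplitudes of signal and incoherent
  noise do not add linearly; quadrature subtraction is the first-order form
  of the inversion and still ~6% low;
* the physical cosine amplitude divides out the sine-window gain
  ($\bar w = 2/\pi$) and the 1/2 cosine split.

With six harmonics, a noiseless 30 min/250 min raised-cosine train
reconstructs with peak-to-baseline height 80% of the injected amplitude and
FWHM ~27 min: the truncation to six harmonics is the dominant, fully
deterministic loss, and reconstructed spike heights should be read with
that in mind. `spike_metrics` reports the mean inter-spike interval, the
FWHM of the spike nearest the record midpoint (linear interpolation between
samples), and the peak-to-baseline height.

## Negative controls and condition comparison

`negative_control` implements the two classical controls: residual
shuffling (destroys temporal structure, preserves the value multiset and
trend) and constant mass plus measurement noise (the fixed-cell analogue).
Both must — and in 100 seeded runs do — yield "no significant peak".

`compare_conditions` quantifies a treatment as the ratio of
background-corrected fundamental amplitudes (Rician-inverted, pooled over
the lobe top) of treated over reference cohorts, both read at the
*reference* fit's fundamental frequency — the treatment may suppress the
peak below detectability, which is exactly the effect being measured — with
a bootstrap-over-cells confidence interval. The raw cohort amplitude `AF`
responds linearly to the injected pulse amplitude over 25–200 pg
(R² > 0.95), which is what makes it usable as a dose–response readout.

# Numerical and degenerate-input choices

* Ties in gap closing: smallest distance, then smallest frame gap.
* A seed below the segmentation threshold returns an empty mask flagged
  `empty = TRUE` (distinct from a zero-area cell).
* Traces shorter than 16 samples are excluded from fitting, with the count
  reported in the fit object.
* Bins with a single contribution have undefined SD and are given infinite
  standard error (they can never claim significance).
* The background optimizer is box-guarded: on a white spectrum the power-law
  and floor components are degenerate and unguarded parameters overflow.
* All randomness flows from one master seed; per-cell substreams are derived
  deterministically, so cohorts are bitwise reproducible.
* 32-bit TIFF stacks store samples rescaled to [0,1] with the affine scale
  in a JSON sidecar (`<path>.scale.json`).

# Problem sizes used in the tests

The test suite exercises the chain at desk scale, chosen as the smallest
sizes at which each claim is statistically meaningful: 300-cell cohorts for
fundamental recovery and waveform metrics (10 replicates for amplitude),
100-cell cohorts × 100 seeded runs for the negative controls, 150-cell
cohorts for dose–response linearity, 256×256 noiseless scenes for the
optics contracts, and six 6-cell rendered scenes (280 frames, 400 px field)
pooled for tracking/division recovery. The full-imaging smoke test runs
5 cells × 40 frames end to end, holograms included.

# Known limitations

* The six-harmonic reconstruction under-reports spike height by ~20% by
  construction; increasing `n_harmonics` trades this against noise
  admitted from weaker harmonics.
* The retrieval is single-height, single-wavelength; no autofocus over $Z$
  ($Z$ is assumed known).
* Division detection presumes the daughter becomes resolvable within a few
  frames; densely packed or slowly respreading cells will be missed (the
  track-length filter also makes divisions in the last ~10 frames of a
  recording undetectable by construction).
* The phase-offset distribution across cells is assumed uniform
  (asynchronous culture); partially synchronized cohorts would bias the
  cohort spectrum in ways the generator can emulate but the detector does
  not model.
* No per-cell phase estimation, synchrony analysis, wavelet or
  Lomb–Scargle alternatives; no circadian-scale (24 h) analysis.
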