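---
title: "Methods: how epiwound measures epithelial wound healing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how epiwound measures epithelial wound healing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

epiwound quantifies wound-healing experiments in squamous epithelia of large
(~50 µm) cells: cortical-actin accumulation around small wounds, dye uptake
through ligand-gated channels, nuclear transcription activity, and the
kinetics of wound closure. This vignette explains the measurement models,
the tunable parameters and why their defaults are what they are, what the
synthetic-data generators do and do not emulate, and the numerical choices
that matter.

## The actin line-profile model

The substrate is a 1-D intensity profile sampled along a line drawn from the
wound edge into the cell field, perpendicular to the wound margin. In this
tissue the cortical F-actin of every cell outlines its boundary, so a
perpendicular line crosses one fluorescence peak per cell edge, roughly one
cell diameter (~50 µm) apart. The analysis makes three assumptions:

* the line starts at (or inside) the wound, so the first genuine peak is the
  wound-margin cell's edge;
* cell edges appear as peaks whose width at half prominence falls between
  20 and 40 µm — narrower structures are debris or noise, wider ones are
  out-of-focus or oblique crossings;
* intensity is only meaningful relative to the margin peak of the same line
  (staining efficiency varies across animals), which is why the reported
  statistic is the ratio vector [1, r1, r2, r3].

The pipeline is `smooth_profile()` → `correct_baseline()` →
`detect_peaks()` → `assign_cell_edges()` → `aggregate_ratios()`, and
`analyze_profile()` chains them.

**Smoothing** (default σ = 2 µm) removes pixel-level noise before maxima
finding; without it, the detected local maximum rides the upward noise
excursions and amplitudes are biased high by roughly the noise sd. The
kernel is renormalised at the profile ends rather than padded.

**Baseline adjustment** subtracts a morphological opening — a rolling
minimum followed by a rolling maximum over a flat window, default 80 µm.
The opening is anti-extensive (never exceeds the signal), exactly preserves
the amplitude of isolated peaks narrower than the window, removes any
additive offset, and follows linear drifts with a bias proportional to the
drift slope times the half-window. The window must exceed the widest
acceptable peak (40 µm); 80 µm leaves a factor-two margin while still
descending into the valleys between 50-µm-spaced edges. Degenerate inputs
(window under 3 samples) error.

**Peak detection** computes, for every interior local maximum (plateaus
resolve to their centre sample), its prominence — height above the higher of
the two base minima, each base being the lowest point before the nearest
strictly-higher sample — and its width at half prominence by linear
interpolation. Peaks are kept when prominence ≥ `min_prominence` and width
lies in [20, 40] µm. The width band is treated as an acceptance filter on
width-at-half-prominence; whether the original in-house analysis meant a
detection window or an acceptance band is not recorded anywhere public, so
the band interpretation was chosen because it is parameter-free and
testable against an exhaustive oracle. The default prominence floor is five
times a robust noise estimate (median absolute first difference scaled to
sd); `analyze_profile()` estimates that noise on the *raw* profile and
multiplies by the smoothing kernel's ‖k‖₂/‖k‖₁ — difference-based
estimators collapse on correlated post-smoothing noise, which otherwise
admits broad low-amplitude ripples as spurious "edges".

**Rank assignment** takes the first retained peak as the margin cell (it is
nearest the wound by construction, not necessarily the global maximum), the
next three as submarginal cells 1–3, and marks missing ranks as `NA` —
never imputed. If more than four peaks survive, the first four by position
win. Ratios from lines are averaged as ratios (not amplitudes averaged
before ratioing): each line has its own margin reference, so ratio-space
averaging cancels per-line illumination differences; this is the
within-line-normalised reading of the ratio definition. Aggregation is
line → wound → animal with pairwise exclusion of missing ranks; expected
design ranges (4–8 lines per wound, 1–5 wounds per animal) warn when
violated but never fail.

## Spot assays

**Particles.** The particle detector is intentionally transparent rather
than a reimplementation of any plugin: a difference-of-Gaussians band-pass
(σ₁ = min diameter/2.355, σ₂ = 2 × max diameter/2.355, in pixels), one
global threshold on the filtered response, connected components, and an
equivalent-diameter gate (2√(area/π) within [min, max] µm). Both knobs the
procedure depends on — the size constraint and the intensity threshold —
are exposed in `spot_params()` (defaults 1–4 µm, threshold 20 a.u.).
Because the band-pass is linear, scaling image and threshold together
leaves counts unchanged. Counts are normalized per nucleus and averaged
over each animal's four images with equal weight.

**Nuclei.** Global Otsu threshold on the nuclear stain, connected
components, and an area gate (default 20 µm²). Watershed splitting of
touching nuclei is available but off by default: over-splitting inflates
the denominator of particles-per-nucleus, and in this tissue nuclei are
sparse enough that fusions are rare.

**Transcription positivity.** Nuclear masks come from the nuclear channel;
the mean intensity of the paired channel inside each mask is thresholded by
a 1-D Otsu split of the per-nucleus means (default) or an absolute value.
Otsu was chosen because it is invariant to affine intensity transforms as
long as the two modes remain separable; the absolute override exists for
sensitivity analyses. Thresholding is per image pair rather than global
across animals — with bimodal, well-separated modes the two agree, and the
per-image rule needs no cross-image intensity calibration. Zero nuclei is
an error (the fraction is undefined), not a zero.

## Closure kinetics

Areas are measured on every 10th frame of an 11-s-interval time-lapse
(`closure_config()`), and each wound's curve is expressed as
100 · Aₜ/A₀ with A₀ the first measured frame. Values above 100% (transient
expansion) are kept. The percent computation is exactly invariant to area
rescaling, and on a noiseless exponential series it reproduces
100·exp(−kt) to floating-point accuracy (the ratio is computed before the
×100). The curves are the primary output; a single-number "rate" is
defined, when wanted, as the least-squares slope of percent versus time
over the first 10 minutes — the window in which treatment effects on
closure concentrate in this system.

Group summaries align wounds on a common grid (nearest-time matching within
half an interval), report mean ± SEM (sd/√n, n = wounds in independent
animals — one wound = one animal = one experimental unit), and test each
timepoint with the unpaired two-tailed t test (two groups) or ordinary
one-way ANOVA (more). Per-timepoint p-values are reported unadjusted,
matching how such curves are conventionally annotated; a Holm option
exists but is off by default.

## Classical statistics

`unpaired_t_test()` (pooled variance by default, Welch behind a flag —
commercial packages offer both and the convention in this assay's reporting
is the plain unpaired test), `one_way_anova()`, `tukey_hsd()`
(Tukey–Kramer standard errors, studentized-range p-values via `ptukey`,
family-wise error at the nominal level) and `summarize_group()` are
computed from their textbook definitions. Base-R `t.test`/`aov`/`TukeyHSD`
appear only as independent oracles in the test suite, which checks
agreement to 1e-8 on 100 random fixtures and empirical type-I error within
±1.5 percentage points of α = 0.05 over thousands of null replicates.
Degenerate inputs are defined, not errors: zero variance everywhere gives
statistic 0 and p = 1; between-group differences over zero within-group
variance give p = 0.

## What the generators emulate — and what they do not

`make_sheet_image()` renders the epithelium as the Voronoi tessellation of
a jittered hexagonal lattice (jitter ±12% of the 50-µm cell diameter),
which guarantees near-constant cell size, unlike a Voronoi of uniform
random points. The wound removes *whole cells* — every cell whose centre
falls inside the nominal disk — because a pixel-level disk would leave
sliver margin cells a few µm deep, a geometry the tissue does not produce.
Each boundary carries a cortical band whose amplitude is set by the rank of
the farther cell (wound-facing margin edge first), 25 µm thick so that,
after the 3-µm PSF blur, measured widths sit comfortably inside the
20–40 µm acceptance band. Ground truth includes suggested line ROIs built
by walking outward along chains of adjacent cell centres and keeping only
chains whose fitted line crosses every boundary near-perpendicular and
near mid-edge (every tessellation edge is the perpendicular bisector of a
centre pair) — the in-silico analogue of an experimenter skipping regions
where a clean perpendicular line cannot be drawn. Treatments are emulated
purely as amplitude changes (e.g. scaling submarginal amplitudes by 0.5);
no signalling, lamellipodia, or pharmacokinetics are modelled, and the
renderer is not photorealistic. Passing recovery tests therefore shows the
*measurement chain* is unbiased on known geometry — not that real tissue
meets the model's assumptions.

`make_profile()` is the 1-D surrogate: Gaussian peaks at 50-µm spacing on a
linear baseline with additive noise. The default FWHM of 22 µm keeps
adjacent-peak tail overlap below 3% of amplitude at 50-µm spacing; wider
peaks would couple neighbouring amplitudes through the shared valley floor
and bias ratios noticeably (the residual ~0.02–0.04 bias in recovered
ratios is exactly this valley-floor effect and is documented by the
recovery tests' ±0.05 envelope).

`make_uptake_images()` places nuclei (5-µm discs) and diffraction-limited
particles (Gaussian σ 0.75 µm; "particle size" means FWHM = 2.355σ) by
rejection sampling with a minimum separation, defaulting to 15 µm, and
renders a third channel with bimodal per-nucleus means
(negative ~30 ± 8, positive ~120 ± 8 a.u.). A requested positive count of
`round(fraction × n)` makes exact-fraction recovery testable — e.g. 77
nuclei with 70 positive yields 90.9%. Particles never overlap nuclei
semantics (channels are independent); real uptake imagery has cytoplasmic
texture and uneven illumination that are not modelled.

`make_closure_series()` offers exponential area decay (default) and a
constant-front-speed model; the measured curves in this assay family are
monotone but fit no published functional form, so the generator only
promises a known monotone truth. Noise is multiplicative lognormal with
unit mean (areas are positive and their error scales with size); images
and profiles use additive Gaussian noise. All generators consume a single
integer seed and restore the caller's RNG state, and identical
(parameters, seed) give bit-identical output.

Imaging bit depth and magnification are not dictated by the assay; defaults
are 16-bit and 0.5 µm/px, both configurable, and no function ever guesses a
pixel size — a missing calibration is an error.

## Problem sizes and runtime

The test-suite simulations are sized to establish each property without
waste: 200 random profiles (≤ 2000 samples) for exact oracle equivalence of
the peak detector; 50 seeds for ratio recovery at 5% noise plus 4 rendered
sheets; 40 simulated animals (2 wounds × 6 lines each) for the
submarginal-depletion contrast; 50 spot fields for exact count recovery;
2000–3000 null replicates per test for empirical size. The acceptance
script re-runs the same computations from scratch in under a few minutes on
one CPU.

## Known limitations

* The per-line ratio estimator carries a small deterministic bias from
  baseline coupling between adjacent peaks (bounded by the ±0.05 recovery
  envelope at default geometry); it shrinks with narrower cortical bands
  and vanishes for isolated peaks.
* Rank assignment is positional; a missed intermediate peak shifts later
  ranks. The width band plus the noise-scaled prominence floor make this
  rare on clean data, but heavily degraded lines should be excluded
  upstream, as they would be in manual QC.
* Nuclei segmentation is global-Otsu based and assumes a reasonably uniform
  background; strongly vignetted fields need prior flat-field correction,
  which is out of scope.
* Closure analysis consumes area series; segmenting wound area from movies
  (and movie registration) is upstream of this package.
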