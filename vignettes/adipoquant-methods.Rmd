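---
title: "Methods: Dixon decomposition, snake segmentation and cohort statistics in adipoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Dixon decomposition, snake segmentation and cohort statistics in adipoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`adipoquant` quantifies body composition — visceral adipose tissue (VAT),
subcutaneous adipose tissue (SCAT) and lean tissue water (LTW) — from
whole-body chemical-shift (Dixon) MRI, for longitudinal monitoring of
cachexia in small animals and in patients. This vignette is the package's
account of the underlying science: the signal model and its assumptions,
the segmentation procedure, the statistics, the tunable parameters, what
the digital phantoms do and do not emulate, and the numerical choices made
where the design was genuinely open.

## The chemical-shift signal model

Each voxel's complex signal at echo time $TE_k$ (seconds) is modeled as

$$s_k = \bigl(W + F\,e^{i 2\pi \Delta f TE_k}\bigr)
        e^{i(\phi_0 + 2\pi \psi TE_k)} + n_k,$$

with non-negative real water and fat amplitudes $W$, $F$; a single fat
resonance at $\Delta f = \delta \cdot \gamma \cdot B_0$ Hz
($\delta = -3.4$ ppm, $\gamma = 42.58$ MHz/T); local B0 off-resonance
$\psi$ in Hz; a constant phase $\phi_0$ (zero throughout); and
independent complex Gaussian noise on the real and imaginary channels.

**Assumptions.** One spectral fat peak (the multi-peak fat spectrum is
out of scope); no $T_2^*$ decay across the echo train (echo spacings are
well under a millisecond at these protocols); a spatially smooth B0 field;
and a fixed global phase. Each assumption holds exactly in the phantoms
and approximately in real tissue — fat-fraction estimates in vivo would
carry the usual single-peak bias of a few percent.

### Three-point decomposition

For fixed $\psi$ the amplitudes enter linearly: demodulating
$d_k = s_k e^{-i2\pi\psi TE_k}$ leaves a two-parameter non-negative least
squares problem whose normal-equation matrix depends only on the echo
times. The residual profile

$$R(\psi) = \min_{W,F \ge 0} \textstyle\sum_k
  |s_k - (W + F e^{i2\pi\Delta f TE_k}) e^{i2\pi\psi TE_k}|^2$$

generically has two local minima: the true field and a fat/water-swapped
alias. Candidates are found by a coarse scan of $R$ (97 grid points over
the search window, i.e. roughly 30 Hz resolution at the mouse protocol)
followed by vectorized golden-section refinement of the two lowest local
minima; the refinement brackets one coarse step around each minimum and
converges far below 0.01 Hz.

Two numerical subtleties deserve a record:

* **The search window is an interval, not a circle.** With $\phi_0$ fixed,
  $R(\psi)$ is *not* periodic in $1/\Delta TE$, because the echo times are
  not integer multiples of the echo spacing. The window
  $[-1/(2\Delta TE), +1/(2\Delta TE)]$ is therefore scanned as an
  interval, and a minimum at either endpoint is a legitimate candidate.
  Treating the window as circular (the usual intuition from phase-only
  models) silently loses basins that sit at the window edge.
* **Swap symmetry is exact only for pure voxels.** A water-only voxel at
  field $\psi_0$ is *exactly* explained as fat-only at $\psi_0 - \Delta f$
  (and a fat-only voxel as water-only at $\psi_0 + \Delta f$). For mixed
  voxels the aliased minimum is approximate: it does not sit exactly one
  $\Delta f$ away and its residual is nonzero, though the dominant
  amplitude still moves to the other species. The tests assert the exact
  pure-voxel identities and the dominance exchange, not a blanket
  invariance that the fixed-phase model does not possess.
* When both non-negativity constraints activate, $R(\psi)$ develops wide,
  nearly flat plateaus; floating-point texture on these plateaus can mimic
  local minima. The grid/refine machinery is robust to this because
  genuine basins are strictly lower, but it is the reason candidate
  extraction validates against a 1 Hz brute-force oracle in the tests.

The per-voxel ambiguity is resolved by region growing (C++): per slice,
growth starts at the highest-magnitude voxel — taking its water-dominant
candidate, the standard anchor given that the highest-signal voxel in
these images is water-dominant — and visits the frontier in descending
magnitude order, each voxel adopting the candidate whose phasor
$e^{i2\pi\psi\Delta TE}$ is closest in angle to the mean phasor of its
already-resolved 3×3 neighbors. In-mask voxels disconnected from the seed
fall back to their lower-residual candidate.

### Two-point decomposition

The dual-echo protocol acquires a nominally opposed-phase echo (1.32 ms)
and a nominally in-phase echo (2.46 ms) at 3 T. The error-phasor field is
estimated from the squared inter-echo phasor $(s_2 \bar{s}_1)^2$ —
squaring removes the sign flip of the opposed-phase magnitude — smoothed
per slice with a Gaussian ($\sigma$ = 6 voxels by default), phase-halved,
and converted to $\psi$. After demodulation, $W = (IP + OP)/2$ and
$F = (IP - OP)/2$, clamped at zero. Two caveats are deliberate: the echo
times are not exactly in/opposed phase at 3 T, so fat-fraction estimates
carry a small bias (about 0.015 at FF = 0.9) that is characterized in the
tests rather than corrected — a flexible-angle variant is out of scope;
and phase-halving leaves a $1/(2\Delta TE)$ ambiguity, acceptable for the
smooth sub-200 Hz fields simulated. Magnitude-only input falls back to
$W = (|s_2|+|s_1|)/2$, $F = (|s_2|-|s_1|)/2$ clamped, under which
fat-dominant voxels are unresolvable (swapped); the result is flagged.

## Segmentation

Processing is strictly per 2D slice, per connected body component:

1. **Body mask** — Otsu threshold on the total signal $W+F$, closing with
   a disk of radius 2, hole filling, and removal of components below
   `min_area` (64 voxels). Components are processed largest-first.
2. **Initial contour** — the outer skin boundary, resampled to
   `n_vertices` equidistant vertices (120 mouse-scale, 200 human-scale).
   Resampling iterates to its fixed point so that it is idempotent.
3. **Snake evolution** — semi-implicit evolution of the closed polygon
   minimizing tension ($\alpha = 0.1$) + stiffness ($\beta = 0.05$)
   internal energy plus the external energy
   $-|\nabla (G_\sigma * I_{fat})|$ ($\sigma = 2$ voxels, gain
   `edge_weight` = 2), with a constant inward balloon pressure
   ($\kappa = 0.3$ voxels/step, step $\gamma = 1$). The contour starts on
   the skin and is pushed inward until it locks onto the sharp fat-signal
   edge at the SCAT/fascia boundary. Convergence: mean vertex
   displacement below `tol` = 0.05 voxels for `patience` = 5 consecutive
   iterations, capped at 500; collapse below 4 voxels² aborts with a flag.
4. **Labelling** — fat voxels (FF ≥ 0.5) between the skin and the
   converged contour are SCAT, fat voxels inside it VAT, water-dominant
   body voxels LTW; user-supplied exclusion masks (tumor, metal artifact)
   override to the excluded label and are honored across all timepoints.

One design choice needs justification: the gradient-magnitude external
energy attracts the contour to *any* edge, and the skin→SCAT edge at the
start position is as strong as the target SCAT/fascia edge. The edge map
is therefore zeroed within `edge_margin` (4 voxels) of the body-mask
boundary, so only the deep edge attracts. The margin must stay below the
skin + SCAT thickness in voxels (≈ 8 at both protocol scales) and above
the blurred width of the outer edge; 4 satisfies both with slack. All
snake parameters were tuned once on the analytic annulus and the phantoms
(inner-radius recovery within 1 voxel) and are exposed in
`snake_params()`.

`ff_threshold = 0.5` classifies adipose voxels, and LTW is defined as the
*count* of water-dominant voxels times the voxel volume, not the
integrated water fraction — the simpler convention, adopted uniformly;
with body voxels nearly binary in fat fraction the two differ by well
under a percent in the phantoms.

## Quantification and statistics

Volumes are voxel counts × voxel volume (mouse: 38/162 × 45/192 × 2 mm ≈
0.110 µl; human: 2.6 × 2.6 × 3.1 mm = 20.96 µl), reported in µl at mouse
scale and ml at human scale. Follow-ups are expressed as percent change
from baseline (the first timepoint), per subject; group-level changes
average the per-subject changes rather than forming ratios of group
means. Reporting rounds half away from zero, integer percent for
litre-scale volumes and one decimal otherwise; raw values are always
retained.

Cohort statistics follow the conventional toolkit: sample SD with the
$n-1$ denominator; classical one-way ANOVA; pooled-variance unpaired t
tests; Pearson correlation with the t-transform p value; Shapiro–Wilk
normality (delegated to `stats::shapiro.test`). Bonferroni correction
multiplies each raw pairwise p by the number of comparisons (capped at 1),
and the pairwise confidence intervals are computed at level
$1 - 0.05/m$ so that an interval excludes zero exactly when the adjusted
p falls below the 0.05 significance constant. CIT-filtered analyses keep
therapy ∈ {PD-1-mAb, CTLA-4-mAb}; BRAF rows remain in the table but are
excluded by the filter.

The packaged `table1.csv` transcribes the 18-patient cohort summary
(weights, BMI, compartment changes, therapy, response). The CIT-filtered
LTW summaries for the MIXED and PD groups reproduce from it exactly at
two decimals; the RTT summary and the associated ANOVA F printed alongside
the original table do **not** recompute from the tabulated per-patient
values (the recomputed RTT mean is −1.80, not −3.02). The fixture is kept
faithful to the table rather than adjusted, and those two numbers are not
used for validation anywhere in the package.

## The phantom generator

`phantom_spec()`/`build_phantom()` rasterize a layered elliptical anatomy:
skin, a closed SCAT annulus, a muscle/fascia layer, and a visceral cavity
with water-dominant organ tissue and circular VAT blobs that run through
all slices as cylinders. Lean tissue gets fat fraction 0.05, adipose 0.9;
water + fat density is 1 inside the body. Defaults mirror the two
acquisition regimes: mouse scale (11 × 14 mm body semi-axes, 1.5 mm SCAT,
five blobs of 1.5–2.2 mm radius, 10 slices of 2 mm) and human scale
(110 × 160 mm, 15 mm SCAT, blobs of 15–25 mm, 8 slices of 3.1 mm). The
B0 map is a fixed low-order polynomial per slice scaled to a peak
amplitude — the smooth regime Dixon field resolution assumes. Noise is
complex Gaussian with SD expressed as a fraction of the mean in-body
signal (SNR 30 ⇒ 1/30, the working noise level throughout; neither
scanner's SNR is otherwise constrained, so this is a free parameter chosen
as a realistic mid-range value). Magnitude export takes the modulus after
noise, so Rician statistics arise naturally.

Longitudinal series apply per-compartment scale factors: VAT scales blob
radii by $\sqrt{f}$ (cylinder volume scales exactly by $f$ in the
continuum), SCAT solves the annulus-thickness quadratic for its target
area, and LTW rescales the fascia ellipse by a root-finder that accounts
for the VAT area change inside it. Prescribed factors are exact in the
continuum; rasterization contributes the only error, held within ±2% by
blob radii of at least ~6 voxels.

**What the phantoms do not emulate:** realistic organ anatomy, partial
volume at tissue interfaces, coil sensitivity profiles, k-space effects,
motion, multi-peak fat, $T_2^*$. Passing phantom tests therefore
demonstrates correctness of the algorithms under the stated model, not
clinical-grade robustness on patient data; the manual-override hook
(`apply_manual_override()`) exists precisely because real segmentations
need visual validation and occasional correction.

## Problem sizes and determinism

The test suite and the acceptance script run phantoms at the full
in-plane matrices (162 × 192 mouse, 128–192² human) with two slices and
two to three timepoints — enough slices to exercise per-slice independence
and axial profiles while keeping a full run in tens of seconds. Every
stochastic step (blob placement, noise) draws from an explicit seed
through a private RNG scope, and re-running a configuration reproduces
byte-identical reports; the pipeline itself contains no randomness.

## Known limitations

* Two-point decomposition inherits the nominal in/opposed-phase
  approximation and the $1/(2\Delta TE)$ phase-halving ambiguity; large
  fields or magnitude-only input can swap fat-dominant regions.
* Snake evolution is 2D; no volumetric regularization across slices.
* The edge-margin suppression assumes the SCAT layer is thicker than the
  margin; extremely lean subjects (SCAT thinner than ~4 voxels) would
  need a smaller margin and correspondingly gentler smoothing.
* Tissue classification is a hard FF threshold; no partial-volume
  modelling, no brown/white adipose distinction, no muscle/organ
  sub-segmentation.
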