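# adipoquant

Automated MRI-based body-composition analysis for longitudinal cachexia
monitoring, in R.

Cancer cachexia — the involuntary loss of fat and muscle mass that
accompanies tumor progression — is hard to catch early from weight and BMI
alone. Whole-body chemical-shift (Dixon) MRI separates fat and water
signal per voxel, and automated segmentation of the resulting fat images
yields three compartments whose longitudinal changes are far more
informative: visceral adipose tissue (**VAT**), subcutaneous adipose
tissue (**SCAT**), and lean tissue water (**LTW**). `adipoquant`
implements that workflow end to end for two acquisition regimes — a
three-echo 7 T small-animal protocol and a dual-echo 3 T human protocol —
together with a digital phantom generator that provides analytic ground
truth, and the cohort statistics used to compare response groups.

The package is aimed at imaging scientists who want a tested, scriptable
reference implementation of the pipeline: phantom simulation →
decomposition → segmentation → quantification → statistics.

## The model

Each voxel's complex signal at echo time $TE_k$ follows the single-peak
chemical-shift model

$$s_k = \bigl(W + F\,e^{i 2\pi \Delta f\, TE_k}\bigr)\,
        e^{i(\phi_0 + 2\pi \psi\, TE_k)} + n_k,$$

with $W, F \ge 0$ the water and fat amplitudes, $\Delta f =
-3.4\ \mathrm{ppm} \times 42.58\ \mathrm{MHz/T} \times B_0$ the fat–water
frequency offset, $\psi$ the local B0 off-resonance (Hz), and complex
Gaussian noise $n_k$. Three-point decomposition minimizes the residual

$$R(\psi) = \min_{W,F \ge 0} \sum_k
  \bigl|s_k - (W + F e^{i2\pi\Delta f TE_k})\,e^{i2\pi\psi TE_k}\bigr|^2,$$

which has two local minima per voxel — the true field and its
fat/water-swapped alias. The field map is resolved by region growing from
a high-signal water-dominant seed, each voxel taking the candidate closest
in phasor angle to its already-resolved neighbors. Dual-echo data are
decomposed via the nominal in/opposed-phase relations $W = (IP + OP)/2$,
$F = (IP - OP)/2$ after demodulating a smoothed error-phasor field.

Segmentation runs per axial slice: Otsu body masking on $W+F$, the outer
skin contour as the initial snake, and inward balloon-driven active-contour
evolution on the fat image that locks onto the sharp signal edge at the
SCAT/muscle–fascia boundary. Fat voxels outside that contour are SCAT,
inside it VAT; water-dominant voxels are LTW. Volumes are voxel counts ×
voxel volume; follow-ups are expressed as percent change from baseline;
group comparisons use one-way ANOVA with Bonferroni-corrected pairwise
tests, unpaired t tests, Pearson correlation and Shapiro–Wilk normality
checks.

## Worked example

A three-timepoint mouse-scale phantom with a prescribed VAT trajectory
(baseline, −12%, −25%), simulated at SNR 30 with a 40 Hz B0 field,
decomposed and segmented:

```r
library(adipoquant)

spec <- phantom_spec("mouse", n_slices = 2, seed = 17,
                     b0_amplitude = 40, noise_sd = 1/30)
tl  <- make_longitudinal(spec, list(vat = c(1, 0.88, 0.75)))
rep <- run_subject(run_config("b16", "mouse", "3pt",
                              lapply(tl, `[[`, "series"),
                              timepoint_labels = c("d3", "d12", "d17"),
                              seed = 17))
subset(rep$changes, compartment == "VAT",
       c(timepoint, baseline, followup, change_pct))
#> # A tibble: 2 × 4
#>   timepoint baseline followup change_pct
#>   <chr>        <dbl>    <dbl>      <dbl>
#> 1 d12           226.     201.      -10.9
#> 2 d17           226.     169.      -25.0
```

The recovered changes track the prescribed −12%/−25% trajectory to within
the segmentation tolerance of a couple of percentage points. Volumes are
in mm³ (= µl at mouse scale). `autoplot(axial_profile(...))` draws the
caudocranial compartment profile; `run_cohort()` produces group summaries
and tests, e.g. on the packaged 18-patient table:

```r
run_cohort(load_cohort_table(), "ltw_change", therapies = CIT_THERAPIES)
#> <cohort_report> ltw_change by response (therapy: PD-1-mAb, CTLA-4-mAb)
#> # A tibble: 3 × 4
#>   group     n  mean    sd
#>   <chr> <int> <dbl> <dbl>
#> 1 MIXED     5  4.59  3.71
#> 2 PD        6  1.96  2.19
#> 3 RTT       5 -1.80  3.80
#> ANOVA F = 4.905, p = 0.02587
```

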