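# epiwound

Quantification of in-vivo epithelial wound-healing assays from fluorescence
microscopy, built for experiments on squamous epithelial sheets of large
(~50 µm) cells — such as the jellyfish exumbrella epithelium — where small
wounds (0.02–0.125 mm²) heal within tens of minutes and signalling responses
reach several cell ranks beyond the wound margin.

The package covers four measurements and the statistics used to compare
treatment groups, plus seeded synthetic-data generators with exact ground
truth so every stage can be verified end to end:

1. **Cortical actin accumulation** from line intensity profiles drawn
   perpendicular to the wound edge. A profile is smoothed, its baseline is
   removed by subtracting a morphological opening (flat window, default
   80 µm), and cell edges are detected as local maxima with prominence above
   a noise-scaled floor and width at half prominence within 20–40 µm. The
   first retained peak is the wound-margin cell's edge; the next three are
   submarginal cells 1–3, each reported as a ratio
   *rᵢ = aᵢ / a₀* to the margin amplitude. Ratios are averaged over the 4–8
   lines of each wound, then over the 1–5 wounds of each animal.
2. **Dye-uptake scoring** as particles per nucleus: a difference-of-Gaussians
   band-pass sized to the admissible particle diameter band, one intensity
   threshold, connected components gated by equivalent diameter; nuclei from
   an Otsu-thresholded nuclear channel with an area gate (optional watershed
   splitting). Per-image counts are normalized by nuclei and averaged over
   the four images of each animal.
3. **Nuclear transcription positivity**: per-nucleus mean intensity of a
   nascent-RNA channel inside nuclear masks, split into positive/negative by
   a 1-D Otsu threshold (affine-invariant) or an absolute override; reported
   as the positive fraction.
4. **Wound-closure kinetics**: areas sampled every 10th frame of an
   11-s-interval time-lapse, expressed as percent of the first measured area
   (100 · Aₜ / A₀), with mean ± SEM per treatment and an unpaired two-tailed
   t test (2 groups) or ordinary one-way ANOVA (>2) at each timepoint, plus
   Tukey HSD post hoc comparisons. SEM = sd/√n with the animal as the
   experimental unit.

Everything tabular flows as tibbles, so results pipe straight into
dplyr/ggplot2; `tidy()`/`glance()` methods cover the test objects and
`autoplot()`/`plot_*()` functions draw the standard figures.

## Worked example

Simulate a line profile over four cell edges with known amplitudes
200:100:80:60 (5% noise), then run the actin analysis:

```r
library(epiwound)

sim <- make_profile(4, amplitudes = c(200, 100, 80, 60), noise_sd = 10, seed = 42)
analyze_profile(sim$profile)
#> # A tibble: 4 × 5
#>   rank   position_um amplitude ratio qc
#>   <fct>        <dbl>     <dbl> <dbl> <chr>
#> 1 margin        30.5     189.  1     ok
#> 2 cell1         81        89.9 0.476 ok
#> 3 cell2        130.       71.4 0.378 ok
#> 4 cell3        178        52.3 0.277 ok
```

The estimated ratios 0.476/0.378/0.277 recover the generating ratios
0.5/0.4/0.3 to within 0.03; peak positions land on the true 50-µm cell
spacing. The same analysis runs on rendered sheet images
(`make_sheet_image()` + `analyze_actin_image()`) and on profile CSVs
exported from an image viewer (`read_profile_csv()`).

Closure curves from the packaged synthetic demo series (two treatments,
four wounds each):

```r
demo <- system.file("extdata", "demo_closure_synthetic.csv", package = "epiwound")
out <- run_pipeline("closure", list(areas = demo), out_dir = "closure_out")
dplyr::filter(out$summary, time_min == 11)
#>   time_min treatment  mean   sem     n statistic    df p_value method
#> 1       11 control    55.9  2.39     4     -4.14     6 0.00610 Unpaired two-tailed t test …
#> 2       11 treated    71.1  2.81     4     -4.14     6 0.00610 Unpaired two-tailed t test …
```

Eleven minutes in, control wounds are down to 56% of their original area
while treated wounds remain at 71% (p = 0.006 at that timepoint) — the
treated group closes more slowly, as its generating rate constant dictates.
`autoplot(out$summary)` draws the mean ± SEM curves.

The same `run_pipeline()` entry point drives every stage (`simulate`,
`actin`, `uptake`, `eu`, `closure`, `report`) from a flat YAML/list config
with one `--seed`; a thin command-line wrapper lives at
`inst/cli/epiwound.R`.

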