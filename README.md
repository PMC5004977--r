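# glidebuoy

Body tissue density and diving gas volume of breath-hold divers, estimated
from the biomechanics of glides in biologging tag records.

## The problem

When a deep-diving whale stops stroking and glides, its body is driven
only by drag and net buoyancy. Net buoyancy depends on the density of the
non-gas tissue — a direct proxy for lipid-store body condition — and on
the volume of air the animal carried down from the surface, which
compresses with depth by Boyle's law. Fitting the observed speed changes
during many short glides to a hydrodynamic force balance therefore yields
estimates of tissue density (to a fraction of a kg m⁻³), mass-specific
diving gas volume, a combined drag term and even the tissue
compressibility — quantities that are otherwise nearly unmeasurable in
free-ranging cetaceans. The package is aimed at biologging and diving
ecophysiology work: tag data in, posterior distributions out.

## The model

For a 5-s glide segment with mean speed $v$, pitch $p$ (negative
downward), depth $d$ and ambient seawater density $\rho_{sw}$:

$$
a = -\tfrac12 \frac{C_d A}{m}\rho_{sw} v^2
  + g\sin p\,\frac{\rho_{sw}-\rho_{tissue}(d)}{\rho_{tissue}(d)}
  + g\sin p\,\frac{V_{air}(d)}{m}(\rho_{sw}-\rho_{air}(d))
$$

with $\rho_{tissue}(d)=\rho_{tissue}/(1-rP(d))$ (tissue compressibility
$r$, gauge pressure $P$ at one atmosphere per 10 m) and the gas volume and
density following Boyle's law against absolute pressure. The four
unknowns — $(C_dA)/m$, $\rho_{tissue}$, $V_{air}/m$, $r$ — are estimated
by hierarchical Bayesian MCMC (JAGS) from tables of filtered 5-s glide
segments, with model structures compared by DIC. Observed segment
accelerations are weighted by their own regression residual RMS, so
high-quality segments count for more.

The pipeline covers: seawater density/compressibility from CTD casts
(EOS-80), pitch/roll from whale-frame acceleration, stroke/glide detection
on the high-pass-filtered dorso-ventral axis, dive-phase segmentation,
propeller speed calibration, 5-s segment extraction with alternate-drop
and stability/steepness filters, hierarchical model fitting with
convergence diagnostics, and a synthetic tag-data generator with known
ground truth that exercises every stage.

## Worked example

Simulate a small population with known truth, fit the hierarchical model,
and compare structures by DIC:

```r
library(glidebuoy)

truth <- draw_truth(n_individuals = 4, n_dives = 6, seed = 1)
segments <- simulate_glide_table(truth, glides_per_individual = 60, seed = 2)

spec <- gb_model_spec(density = "hierarchical", drag = "global",
                      gas = "hierarchical-dive")
fit <- run_mcmc(build_model(segments, spec),
                n_iter = 6000, n_burn = 3000, thin = 9, seed = 3)
tidy(fit)
#> # A tibble: 34 x 7
#>    parameter         mean     sd     q2.5    q97.5  rhat converged
#>    <chr>            <dbl>  <dbl>    <dbl>    <dbl> <dbl> <lgl>
#>  1 drag6            9.60  0.699     8.20    10.9   0.999 TRUE
#>  2 gas[1]          24.3   7.85      7.14    37.7   1.01  TRUE
#>  # ... gas[2]-gas[24] (per-dive gas volumes) ...
#> 26 gas_mu          26.8   5.81     13.6     36.7   1.01  TRUE
#> 27 gas_sd           7.92  4.19      1.98    18.7   1.01  TRUE
#> 28 r9               0.410 0.0713    0.306    0.566 1.00  TRUE
#> 29 rho_mu        1031.    1.72   1028.    1034.    0.999 TRUE
#> 30 rho_sd           2.87  2.20      0.950    9.57  1.00  TRUE
#> 31 rho_tissue[1] 1030.    0.514  1029.    1031.    1.01  TRUE
#> 32 rho_tissue[2] 1031.    0.506  1030.    1032.    1.00  TRUE
#> 33 rho_tissue[3] 1030.    0.495  1029.    1031.    1.00  TRUE
#> 34 rho_tissue[4] 1034.    0.595  1032.    1035.    1.01  TRUE
```

Reading the output: `rho_tissue[j]` are the per-individual tissue
densities in kg m⁻³ — the generating truths here were 1030.6, 1031.8,
1030.2 and 1033.9, each recovered within its credible interval. `gas[k]`
are the per-dive diving gas volumes in ml kg⁻¹ with population mean
`gas_mu` (26.8 against a generating mean of 27.4), `drag6` the combined
drag term in units of 10⁻⁶ m² kg⁻¹, and `r9` the tissue compressibility
in units of 10⁻⁹ Pa⁻¹ (0.410 against a generating 0.38). `glance(fit)`
reports the DIC (-1112, with pD = 12.8 effective parameters) for model
comparison, and `autoplot(fit)` draws the posterior densities.

Starting instead from a raw (here simulated) tag record:

```r
rec    <- simulate_tag_record(truth, dive_plan(n_dives = 3), seed = 4)
att    <- compute_pitch_roll(rec)
glides <- detect_glides(rec$az, attr(rec, "sample_rate"),
                        highpass_cutoff = 0.2, stroke_threshold = 0.3)
phases <- segment_dives(rec, pitch = att$pitch)
prof   <- density_profile_from_ctd(
            ctd_profile(c(0, 50, 200, 600), c(8, 6, 4, 3), 35))
segs   <- extract_glide_segments(rec, glides, phases, prof, attitude = att)
nrow(segs)
#> [1] 122
glide_time_by_phase(rec, glides, phases, min_depth = 100)
#> # A tibble: 1 x 7
#>   individual_id pct_glide_descent pct_glide_ascent difference sd_descent sd_ascent n_dives
#>   <chr>                     <dbl>            <dbl>      <dbl>      <dbl>     <dbl>   <int>
#> 1 whale01                    77.7             69.9      -7.81       1.17      3.54       3
```

The `difference` column (ascent minus descent gliding percentage) is the
classic external check on the density estimates: negatively buoyant
animals glide more during descent, so denser animals have more negative
values.

A thin command-line wrapper over the same functions ships in
`inst/cli/glidebuoy.R` (`simulate`, `extract`, `fit`, `report`).

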