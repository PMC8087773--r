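# retinasens

Quantitative analysis of retinal light responses and outer-plexiform-layer
(OPL) synaptic staining, for physiologists and cell biologists comparing
wild-type (WT) and knockout (KO) littermates — the setting where a gene
deletion changes the *sensitivity* of ON-bipolar light responses and the
level of a synaptic protein, but not the saturating response amplitude.

The package implements, as tested reusable components:

* **B-wave sensitivity** — the hyperbolic saturation law
  `B/Bmax = S_B·I / (1 + S_B·I)`, with `S_B` the inverse half-saturating
  intensity; exact algebraic inversion from the two-flash protocol,
  least squares for more flashes (`fit_saturation()`).
* **Rising-phase fitting** — the delayed activation model
  `A(I,t)/Amax = 1 − exp(−S_A·I·(t − t_d)²)` fitted jointly over a flash
  family for ERG A-waves (windowed from `t_d` to the peak, 5 ms back-off
  for long rises) and rod photocurrents (fixed 60 ms window)
  (`fit_rising_phase()`).
* **Filtering and oscillatory potentials** — 6th-order Butterworth
  conventions (22.5 Hz / 1 kHz low-pass, 75–300 Hz band-pass), zero-phase
  by default; OP amplitude as the negative-to-positive peak swing of the
  band-passed B-wave rising phase, normalized by `Bmax`
  (`filter_butterworth()`, `op_amplitude()`).
* **Confocal puncta quantification** — ONL-background normalization,
  strict 3-D local-maxima detection on the mGluR6-proxy reference
  channel, dendritic-tip masking, rod/cone classification by mask extent
  (≤ 0.5 µm per side → rod; > 1.1 µm total → cone), and per-punctum
  1.1 × 1.1 µm background-subtracted window sums (`quantify_section()`).
* **Paired-ratio statistics** — two-step slide/pair normalization;
  jackknife bias-corrected KO/WT ratio
  `r_c = n·r − (n−1)/n · Σ r_i` with jackknife SDs; paired Student's t;
  Welch's t (single and double-difference) with the two-sided p computed
  through the regularized incomplete beta `I_{v/(v+t²)}(v/2, ½)`;
  correlations with t-transform p-values (`jackknife_ratio()`,
  `welch_t()`, `welch_double_diff()`, `correlations()`).
* **Synthetic data with ground truth** — ERG cohorts, rising-phase
  families, paired intensities and two-channel confocal stacks
  (`sim_*`), so every stage is verified by generator→analysis closure.

Everything is tibble-in / tibble-out and pipe-friendly; fitted objects
have `tidy()`, `glance()` and `autoplot()` methods. A thin CLI
(`exec/retinasens`) wraps the two end-to-end pipelines.

## Worked example

Simulate a 7-pair littermate ERG cohort in which the knockout has 1.5×
the ON-bipolar sensitivity but the same saturating amplitude, then run
the full analysis:

```r
library(retinasens)

cfg <- sim_config(seed = 1, n_pairs = 7, noise_sd = 4)
rep <- run_erg_pipeline(cfg, sensitivity_factor = 1.5)
rep$tests
#> # A tibble: 2 × 5
#>   parameter n_pairs mean_WT mean_KO  p.value
#>   <chr>       <int>   <dbl>   <dbl>    <dbl>
#> 1 S_B             7   1943.   2843. 0.000114
#> 2 B_max           7    382.    367. 0.0607
```

The paired test finds the sensitivity change (p ≈ 1e-4) and no amplitude
change (p ≈ 0.06) — the dissociation this analysis is designed to
resolve. The oscillatory potential, coupled to sensitivity in the
generator, correlates with it across the 14 mice:

```r
rep$op_correlation
#> # A tibble: 2 × 5
#>   method   estimate statistic   p.value     n
#> 1 pearson     0.887      6.64 0.0000240    14
#> 2 spearman    0.890      6.77 0.0000200    14
```

Imaging side: matched WT/KO stack pairs with a true KO/WT staining ratio
of 1.42 on the target channel, quantified and ratio-estimated:

```r
img <- run_imaging_pipeline(sim_config(seed = 1, n_pairs = 4, effect_ratio = 1.42),
                            n_rod = 6, n_cone = 2, roi_width = 40)
dplyr::filter(img$ratios, quantity == "rod")
#> # A tibble: 2 × 8
#>   channel   quantity     r        s   r_c      s_c     n defined
#> 1 reference rod       1    0         1    0            4 TRUE
#> 2 target    rod       1.42 2.22e-16  1.42 1.54e-15    4 TRUE
```

Noise-free, the bias-corrected ratio `r_c` recovers the configured
effect exactly on the target channel and 1 on the untouched reference
channel. With noisy paired intensities the estimator behaves like its
field use:

```r
glance(jackknife_ratio(sim_paired_samples(14, 1.34, cv = 0.15, seed = 2)))
#> # A tibble: 1 × 5
#>       r      s   r_c    s_c     n
#> 1  1.41 0.0224  1.41 0.0232    14
```

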