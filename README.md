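# phenogreen

Vegetation phenology — the seasonal cycle of leaf-out and senescence —
leaves a signature in the average color of photographs taken outdoors.
`phenogreen` estimates that signal from large, noisy, *crowdsourced*
image corpora (e.g. social-media posts from national parks): collections
never taken for a scientific purpose, where any single image is
unreliable but the monthly mean over hundreds of images tracks the
greenness of the landscape.

The package is for ecologists and environmental data scientists who want
to mine such "ambient" image data, and it implements the full analysis
chain:

* **Greenness index.** For each image, the mean over pixels of the green
  chromatic coordinate `g = G / (R + G + B)` (ratio per pixel first,
  then the mean; black pixels excluded). An achromatic image scores
  exactly 1/3; greener vegetation pushes the index up.
* **Corpus cleaning.** Removal of byte-identical duplicates (MD5, keep
  the earliest) and files under 10,240 bytes — the spam/thumbnail filter
  applied before any color analysis.
* **Aggregation with uncertainty.** Monthly and seasonal (JJA / DJF)
  park-level means with 10,000-replicate percentile-bootstrap 95%
  confidence intervals and coefficients of variation; summer − winter
  contrasts with bootstrap intervals on the difference.
* **Satellite comparison.** Monthly mean NDVI from all grid cells within
  0.5° of each park center, paired with the monthly greenness means and
  pooled across parks into Pearson and Spearman correlations (bootstrap
  CI on Pearson).
* **Synthetic data with known truth.** A generator for image corpora
  (cosine seasonal cycles, Gaussian image noise, duplicate / undersized /
  advertisement contamination) and linearly coupled NDVI grids, so the
  whole pipeline is testable end to end without any external data.

## Worked example

Simulate one park with a seasonal cycle (base greenness 0.304, amplitude
0.04, July peak) plus 2% duplicates and 2% undersized files, then run
the analysis:

```r
library(phenogreen)

prof <- park_profile("Acadia", base_greenness = 0.304,
                     seasonal_amplitude = 0.04, peak_month = 7,
                     monthly_counts = rep(30L, 12),
                     duplicate_rate = 0.02, undersized_rate = 0.02)
corpus <- generate_corpus(prof, out_dir = tempfile(), seed = 1, year_span = 12)

records  <- load_manifest(file.path(corpus$out_dir, "manifest.csv"))
filtered <- filter_corpus(records)
filtered$report
#> <filter_report> 371 records in: 360 retained, 6 duplicates,
#>   5 undersized (< 10240 bytes), 0 unreadable

obs <- corpus_greenness(filtered$retained)
cfg <- bootstrap_config(n_reps = 2000, seed = 1)
seasonal_stats(obs, cfg)
#>     park period      mean   ci_low   ci_high  n         cv degenerate
#> 1 Acadia    JJA 0.3388149 0.332778 0.3446247 90 0.08555389      FALSE
#> 2 Acadia    DJF 0.2629772 0.255944 0.2693085 90 0.12519427      FALSE

season_contrast(obs, cfg)
#>     park  diff_mean diff_ci_low diff_ci_high significant_95 ...
#> 1 Acadia 0.07583767  0.06696788   0.08467066           TRUE
```

The filter caught exactly the 11 injected contaminants (~3% of the
corpus). The summer mean (0.339) sits near the configured summer level,
the winter mean is ≈ 0.07 lower, and the bootstrap interval of the
difference excludes zero — the park's seasonal cycle is recovered as
significant at the 95% level. The monthly CVs (0.09–0.13) show the
image-to-image noise the aggregation has to average over.

The full eight-park study scenario, including the NDVI comparison, runs
through the pipeline interface:

```r
config <- default_config(out_dir = "run1", seed = 1)
run_simulate(config)   # corpus + truth table + NDVI grid under run1/data
run_analyze(config)    # all statistics as CSV under run1/results
run_report(config)     # run1/results/report.md
```

or from a shell via `inst/scripts/phenogreen-cli.R`
(`simulate` / `analyze` / `report` subcommands).

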