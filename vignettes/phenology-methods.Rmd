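---
title: "Estimating vegetation phenology from crowdsourced image greenness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating vegetation phenology from crowdsourced image greenness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenogreen)
```

## The problem

Photographs posted to social media from inside natural areas are "ambient
data": they were never taken for a scientific purpose, but collectively
they carry a signal about the state of the vegetation in front of the
camera. With a large enough sample, the seasonal cycle of leaf-out and
senescence — plant phenology — should be recoverable from the average
color of such images, even though any single image is dominated by
unrelated content (people, rocks, sky, advertisements, filters).

`phenogreen` implements that analysis as a reusable, tested pipeline:

1. **Corpus cleaning** — remove duplicate files and files under a size
   threshold.
2. **Greenness index** — for each image, the mean over pixels of the
   green chromatic coordinate \(G / (R + G + B)\).
3. **Aggregation** — monthly and seasonal park-level means with
   percentile-bootstrap confidence intervals and coefficients of
   variation.
4. **Seasonal contrast** — bootstrap test of the summer (JJA) minus
   winter (DJF) difference per park.
5. **Satellite comparison** — pooled Pearson and Spearman correlation of
   the monthly greenness means against a gridded monthly NDVI product,
   with a bootstrap interval on the Pearson coefficient.

Because real social-media corpora cannot be redistributed, the package
ships a synthetic-data generator that produces image corpora and NDVI
grids with the same statistical structure and a known ground truth, so
every downstream stage can be validated end to end.

## The greenness index

For a pixel with 8-bit channels \((R, G, B)\) the index is
\(g = G / (R + G + B)\); the image-level index is the arithmetic mean of
\(g\) over all pixels with a positive channel sum. Two conventions matter:

* **Ratio-then-mean, not mean-then-ratio.** Each pixel's ratio is formed
  first and then averaged. The alternative (ratio of channel means)
  differs on real images and is deliberately not provided.
* **Black pixels are excluded**, not scored \(1/3\): the ratio is
  undefined at a zero channel sum. The exclusion count is reported with
  each observation.

Channels are used exactly as decoded — no gamma linearization, white
balancing, or exposure correction — because uncurated corpora offer no
calibration target to correct against. Any achromatic image scores
exactly \(1/3\), the index is invariant to swapping R and B and to
rescaling a pixel's channels, and it increases strictly with G at fixed
R + B; the test suite asserts all of these along with exact agreement
with a naive per-pixel loop.

## Corpus cleaning

Two filters are applied before any color analysis, aimed at spam and
low-quality content:

* files smaller than `min_bytes` (default 10,240 bytes, i.e. 10 kB in
  the binary convention; the threshold is configurable and the boundary
  is "strictly smaller is removed"), and
* byte-identical duplicates, detected by MD5 content hash; within each
  duplicate set the earliest-timestamped record is retained, ties broken
  by the smallest record id.

"Duplicate" here means *byte-identical*: it is deterministic, cheap, and
matches the repost behavior of spam accounts. Perceptual near-duplicate
hashing is out of scope. The size filter runs before hashing; with
byte-identity the order cannot change the outcome, but fixing it makes
runs deterministic. A `filter_report` reconciles every removal
(`n_input = n_retained + duplicates + undersized + unreadable`), and
filtering is idempotent.

## Bootstrap intervals

Uncertainty on every aggregate is a **percentile bootstrap**: the
statistic is recomputed on `n_reps` (default 10,000) resamples drawn
with replacement at the original sample size, and the 2.5% and 97.5%
empirical quantiles form the 95% interval. The percentile method was
chosen over BCa as the simplest construction consistent with reporting a
resampled interval; the method name is recorded in the output metadata.
A single-observation pool yields a degenerate interval flagged as such.

Seeding is disciplined: one root seed, with a per-group child seed
derived deterministically from the group labels (`child_seed()`), and
each pool is sorted before resampling — so results are independent of
the order in which groups or rows are processed. Summer-winter contrasts
resample the two season pools independently within each replicate and
are called significant when the 95% interval of the difference excludes
zero; the more conservative "the two seasons' own intervals do not
overlap" reading is reported alongside (`overlap_significant`). December
is pooled with January and February by calendar label across the whole
simulated span, without shifting years. No multiple-testing correction
is applied across parks.

## The synthetic corpus generator

The generator encodes the structure the analysis assumes, with the
simplest model consistent with it:

* **Seasonal cycle**: each park's true monthly mean greenness is a cosine,
  \(\mu(m) = \text{base} + A\cos(2\pi(m - \text{peak})/12)\), peaking in
  July.
* **Image-level noise**: a per-image target drawn from a Gaussian around
  \(\mu(m)\) with `image_noise_sd = 0.034`, chosen so the monthly
  coefficient of variation is near 0.1 at greenness levels near 0.34 —
  the dispersion characteristic of uncurated corpora. The Gaussian is
  truncated *symmetrically* about \(\mu(m)\) at the attainability limit
  of the image construction, which keeps the expected target exactly
  \(\mu(m)\).
* **Pixel construction**: every pixel has a fixed channel sum
  \(S = 300\); the green channel is
  \(G = \mathrm{clip}(\mathrm{round}((t + \varepsilon)S), 0, 255)\) with
  per-pixel noise \(\varepsilon \sim N(0, 0.05)\), rounding half away
  from zero, and the remainder split between R and B with the odd unit
  to R. One parameter then controls the mean greenness exactly, and the
  realized index — recomputed from the finished pixels with the same
  code the analysis uses — is stored as the image's ground truth. PNG
  encoding is lossless for 8-bit data, so file-based and truth-based
  analyses agree bit for bit (a property the tests assert).
* **Contamination**: exact byte-duplicates, undersized files (4×4
  thumbnails, ~120 bytes), and "advertisement" images whose target is
  \(\mu(\text{peak})\) regardless of posting month. Injection counts are
  binomial with a rate correction so each class makes up the configured
  expected fraction of the final manifest; with duplicate and undersized
  rates of 0.015 each, the filter removes about 3% of records.

The default scenario has eight parks calibrated to the reported study
structure: forested parks with summer means near 0.34 and winter means
0.05–0.1 lower; Great Smoky Mountains the greenest (summer above 0.36,
plus an October posting bump from fall-foliage visitors); Grand Canyon
below 0.32 with amplitude exactly 0 (a desert park with no detectable
cycle — the cleaner null condition for the contrast's type-I behavior,
at the cost of not reproducing the slight positive summer excess a real
desert park might show); and Rocky Mountain the strongest cycle
(amplitude 0.05). Posting volume is summer-peaked (10 images per month
in January to 60 in July, per year; two years are simulated), and
Glacier carries a 12% advertisement rate against 2% elsewhere, which
visibly flattens its observed winter trough.

What the generator does **not** emulate: lighting and exposure
variation, post-processing filters, off-topic but full-size images,
non-Gaussian heavy tails, spatially structured image content, or
JPEG-compression color shifts. Passing tests therefore demonstrate that
the pipeline recovers known structure under realistic dispersion and
contamination rates — not that every pathology of real social-media data
is handled.

## The synthetic NDVI product

NDVI cells are laid on a regular lattice (default 11×11 at 0.1°,
centered on each park) and coupled linearly to the park's true monthly
mean: \(v = \mathrm{clip}(a + b\,\mu(m) + \eta,\ -1,\ 1)\) with
independent per-cell noise \(\eta \sim N(0, 0.30)\). Averaging the 81
cells within 0.5° of the center reduces that noise to ≈ 0.033, which
attenuates the pooled correlation over the default scenario's 96
park-months to

\[ r = \frac{b\,\sigma_\mu^2}{\sqrt{\sigma_\mu^2 + \sigma_e^2}\,
     \sqrt{b^2\sigma_\mu^2 + \sigma_\eta^2}} \approx 0.62, \]

where \(\sigma_\mu^2\) is the variance of \(\mu\) across park-months and
\(\sigma_e^2\) the (small) sampling noise of the monthly greenness
means. The acceptance suite uses this closed form as an independent
oracle for the estimated correlation. Cell selection "within 0.5°" is a
Euclidean radius in degree space, boundary-inclusive (with a 10⁻⁹°
tolerance against floating-point jitter on exact lattice boundaries); a
square-box alternative is available because the phrase is ambiguous.
Correlations are computed only on the pooled park-months — per-park
12-point correlations are too unstable to be useful and are deliberately
not emitted. The comparison is correlation-only: greenness and NDVI are
different quantities, so no regression slope is fit.

## Numerical and degenerate-input choices

* Rounding in the image construction is half-away-from-zero (documented,
  unlike `round()`'s half-to-even).
* Empty monthly or seasonal pools are *absent* from outputs (with a
  warning for seasons), never zero-filled; pairing with NDVI skips
  park-months missing either series, with no imputation.
* An all-black image is an error ("no valid pixels"), as is an empty
  bootstrap input, fewer than 3 correlation pairs, or a zero-variance
  series.
* Bootstrap replicates of the correlation that happen to draw a
  zero-variance resample are dropped from the percentile computation.
* Grayscale files are expanded to R = G = B (index exactly 1/3); alpha
  channels are dropped. How non-RGB inputs were handled in the original
  setting is unknown; this is the package's own convention.

## Problem sizes

The default simulated scenario spans two years at roughly 420 clean
images per park-year (≈ 7,300 records in total, ≈ 13 kB each), small
enough to simulate and analyze in about a minute. The test suite scales
further down: Monte-Carlo studies of the statistical stages use the
no-file generator mode (`write_images = FALSE`, identical realized
values by construction) and 16 px images, whose only effect is a
negligible widening (< 0.004) of per-image noise; coverage studies run
1,000 trials at 1,000–2,000 bootstrap replicates. These sizes are the
package's chosen defaults for a desk-scale validation and are all
configurable upward.

## Known limitations

* The cosine seasonal model cannot express asymmetric green-up/senescence
  (a sharp spring rise with a slow autumn decline); recovery tests on
  such shapes would need a different truth curve.
* Duplicate detection is byte-exact only; recompressed or resized
  reposts pass the filter.
* JPEG decoding is supported but not bit-pinned across decoder versions;
  tests use PNG.
* The advertisement contamination biases off-season means upward by
  design and is *not* filtered (matching the analysis this package
  implements, which treats it as irreducible noise).
* `radius_deg` cell selection treats degrees isotropically; at high
  latitudes a degree of longitude is much shorter than a degree of
  latitude.
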