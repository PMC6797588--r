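---
title: "Histogram phenotyping of vegetation-index imagery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram phenotyping of vegetation-index imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavphenome)
```

This vignette is the package's account of its own science: the models it
implements, the parameters that matter, what the synthetic field-season
generator does and does not emulate, the numerical conventions, and the
design choices made where the design was genuinely open.

## 1. From pixels to phenotypes

A plot-date observation starts as a raster of blue-band NDVI values,
`BNDVI = (NIR − Blue)/(NIR + Blue)`, each in [−1, 1]. Two reductions are
offered:

* **Mean canopy BNDVI** (`plot_mean_bndvi`): pixels at or above the canopy
  threshold (default 0.06, the value at which soil and canopy modes
  separate in bimodal plot histograms) are averaged. Simple, interpretable,
  and blind to distribution shape.
* **The histogram phenotype** (`build_histogram`): all values in (0, 1] are
  binned into 999 equal-width, left-open/right-closed bins and normalised
  to relative frequencies. No canopy threshold is applied here — keeping
  the sub-0.06 soil mass is precisely what lets the decomposition read
  canopy closure.

Binning conventions are fixed and deliberate: a value `v` lands in bin
`ceiling(v * 999)`; exactly 0 is out of range and dropped, exactly 1 falls
in the last bin; negative values and missing pixels are dropped but
counted (`n_pixels_dropped`), so mass conservation is checkable. Rows are
normalised to sum to one because plots differ in usable pixel count and a
decomposition of raw counts would load on plot area; a `normalize =
"count"` option exists for sensitivity analysis since the alternative
reading changes PC loadings.

Histograms are stacked into the matrix `X` (n plot-date rows × 999 bins)
in lexicographic (year, flight day, genotype, trial) order, so `X` is
reproducible whatever the ingestion order. Missing plot-dates are simply
absent rows.

## 2. The decomposition and its orientation

`fit_pca` column-centres `X` and takes its singular value decomposition;
the right singular vectors are the eigenvectors of the covariance matrix.
Only centring is applied — bins share units and scaling would inflate
empty-bin noise. Retention defaults to 15 components.

SVD signs are arbitrary, so the package fixes an orientation that makes
the components' field meaning and all downstream correlation signs
deterministic:

* component 1: loadings over the sub-0.06 (soil) bins sum to ≥ 0, so a
  *higher* PC1 score means *more exposed soil* (less canopy closure);
* component 2: `sum(loading × bin centre) ≥ 0`, so a higher PC2 score
  shifts mass toward greater BNDVI (a greener canopy). (A
  "loading-weighted mean bin position" is not well defined when loadings
  sum to ~0, so the package uses this inner-product form of the same
  idea.)
* components ≥ 3: largest-magnitude loading positive.

Interpretation is supported by **back-projection sweeps**
(`back_project_sweep`): five score values spanning the observed range of
one component are back-projected onto its eigenvector and added to the
mean histogram, with other components held at zero, showing the shape
change the component encodes. Degenerate input (all rows identical) is an
error, not a silent zero decomposition.

## 3. Date-resolved correlation analyses

`correlate_by_date` computes, per year × flight date × predictor, the
Pearson correlation across plots between a predictor (component score or
mean canopy BNDVI) and a trait, with the two-sided p-value from the t
distribution on n − 2 degrees of freedom and a flag at p < 0.05.
Observations are plots (genotype × trial), because that is the unit on
which the phenotype is measured; a `by_genotype_mean` switch averages
trials first. **No multiple-testing correction is applied by default** —
the flags deliberately mirror how per-date significance marks are usually
drawn on such series. The statistical consequence is worth stating
plainly: with a 5% per-date false-positive rate, a season of ten dates is
*expected* to show an occasional spurious flag, particularly at early
dates where scores carry almost no canopy signal. A `p_adjust = "BH"`
option is available. Undefined correlations (zero variance, n < 3) are
reported as missing with a reason, never silently skipped.

`compare_yield_groups` ranks genotypes by trial-averaged yield, takes the
6 lowest and 7 highest by default, and contrasts each predictor per date
with Welch's two-sample t-test — chosen as the robust default for small,
possibly unequal-variance groups, since nothing pins down a specific test
for such group marks.

`detect_flowering_dip` operationalises the transient pre-flowering BNDVI
depression: within a window (default mean flowering day −15 to +5), find
the deepest interior local minimum of a genotype's trial-averaged mean
canopy BNDVI series; its depth is the drop below the straight line joining
the two flanking observations; below `min_depth` (default 0.01 BNDVI)
nothing is reported. All parameters are exposed because the phenomenon is
an observation, not an algorithm, and any detector is an
operationalisation.

## 4. PLS-R trait prediction

`fit_plsr` implements univariate-response partial least squares by the
NIPALS recursion: each factor's weight is the normalised covariance
direction `X'y`, its score is the projection of `X` on that weight, and
`X` and `y` are deflated before the next factor. Coefficient vectors are
assembled for every factor count along the path, so hold-out performance
can be traced factor by factor. Two exact identities anchor the
implementation and are enforced in tests: the first weight equals the
normalised `X'y` of the centred data, and the full-factor model reproduces
the ordinary least-squares fit on full-rank data.

`holdout_evaluate` repeats (default) 100 draws holding out 30% of plots,
recording hold-out Pearson r at every factor count. The factor threshold
f_T of a draw is the **first local maximum** of its r curve — the smallest
k with r(k) ≥ r(k+1), the last count if the curve rises throughout; a flat
stretch counts as diminishing returns. This is the simplest deterministic
reading of "the point where predictive power begins to diminish" and
matches a minimum-factors phrasing; a one-standard-error alternative is
selectable. The report averages, over draws, the hold-out r *at each
draw's own f_T* (less biased than re-evaluating all draws at the average
threshold) and reports f_A, the mean of f_T.

Two feature sources are supported — per-date retained component scores, or
per-date raw histogram bins — and `compare_feature_sources` compares their
per-draw r distributions with a two-sided Mann–Whitney test (no test is
canonical here; rank-based is the conservative choice for bounded,
non-normal correlation values).

**Replicate leakage.** With replicated trials and unrestricted hold-out
sampling, a model can partially recover a held-out plot's trait from its
genotype's *other* replicate in the training set, so hold-out r for any
genotype-level trait is a blend of out-of-genotype prediction and
genotype repeatability. The package's tests demonstrate this directly: a
trait that is pure genotype-level noise, with no canopy coupling at all,
reaches substantial unrestricted hold-out r, which collapses under
genotype-grouped splits (`plsr_config(grouped_split = TRUE)`). Unrestricted
sampling remains the default because it matches how such hold-outs are
commonly drawn, but reports based on it should be read with this in mind —
it plausibly inflates kernel-width "predictions", for instance, which have
no mechanistic canopy link in the simulator.

Missing plot-date feature blocks are imputed by the column mean over
available plots (keeping feature rows aligned with the trait table's 2g
rows), with every imputation counted and messaged.

## 5. The synthetic field season

`simulate_season` generates the study conditions the analyses assume:
25 genotypes × 2 trial replicates, weekly flights (days 30–93 of season),
20,000 pixels per plot. Each plot-date's pixels are a two-component
Gaussian mixture:

| parameter | default | meaning |
|---|---|---|
| `soil_mean`, `soil_sd` | 0.00, 0.025 | bare-soil BNDVI; mean + 2 sd ≤ 0.06 keeps the modes separable |
| `canopy_sd` | 0.08 | within-plot canopy spread |
| `closure_day_mean`, `closure_day_sd`, `closure_rate` | 42, 2, 0.3/day | logistic ground-cover curve; fraction of pixels that are canopy |
| `green0`, `peak_base`, `peak_range` | 0.45, 0.62, 0.04 | canopy-pixel greenness: seedling baseline and genotype peak |
| `greenup_lead_days`, `greenup_rate` | 8, 0.45/day | fast greening of plant pixels, ahead of closure |
| `late_green_share`, `late_green_rate`, `late_green_lead_days` | 0.15, 0.2/day, 5 | slow greening anchored just before flowering; carries greenness to its peak in the flowering period |
| `dip_depth`, `dip_lead_days`, `dip_sd_days` | 0.04, 3, 2 | Gaussian-in-time greenness dip preceding flowering (tassel material) |
| `senescence_rate`, `stay_green_gain`, `peak_offset_days` | 0.012/day, 0.6, 2 | linear post-peak decline; reduced up to 60% by the stay-green latent |
| `plot_effect_sd` | 0.02 | season-constant plot-level greenness offset (field position) |
| `flowering_window` | days 58–66 | genotype flowering dates spread over a contiguous ~8-day window |

Two independent uniform latents per genotype drive the trait structure:
`latent_green` sets peak greenness and contributes weakly to yield
(0.5 kg/plot per unit); `latent_staygreen` slows senescence and
contributes strongly to yield (7.5 kg/plot per unit), and couples kernel
length positively and kernel thickness negatively. Grain yield is
19 kg/plot at centre with genotype-level noise of 1 kg and *plot-level*
noise of 4.5 kg — single-plot combine weights and field heterogeneity
dominate yield error, which (i) caps yield predictability around r ≈ 0.7,
below precisely-scored flowering dates, and (ii) keeps plot-level
correlation tests honestly calibrated (genotype-clustered noise would make
them anticonservative). Flowering dates are scored with 0.4-day plot-level
noise; silking follows tasselling by 1–3 days.

Dip depth and duration are free parameters of this package, documented
here as modelling choices, not as claims about maize; nothing public
quantifies them. Yield is modelled directly rather than as kernel number ×
kernel weight; kernel traits couple to yield only through the shared
stay-green latent.

Three design points deserve emphasis because they were learned the hard
way and are now module contracts:

1. **Green-up precedes closure.** If canopy pixels stayed near-soil-dark
   for weeks, the canopy mode's location would vary while carrying almost
   no histogram mass — and a linear decomposition, which weighs modes by
   mass, could never recover it. Plant pixels therefore green up quickly;
   the seasonal rise of *plot-mean* BNDVI is a ground-cover effect. This
   is also the more realistic reading of early-season field imagery.
2. **Replicate plots differ.** A season-constant plot-level greenness
   offset (`plot_effect_sd`) represents field-position effects — the very
   reason trials are replicated. Without it, replicates are identical up
   to pixel noise, which both understates real variability and makes
   plot-level significance tests anticonservative for genotype-level
   predictors.
3. **A flowering-locked greening component.** A small share of the
   greenness rise is anchored to each genotype's flowering date, so
   score trajectories carry a flowering-time signature beyond the dip.

**Reproducibility.** All randomness flows from one master seed through a
counter-based sub-seeding scheme (a polynomial hash of stage tags reduced
modulo 2^31 − 1), so any plot-date can be regenerated bit-identically in
isolation, outside a full season run. Pixel values are clipped (not
rejection-sampled) to [−1, 1]; at the default parameters the affected mass
is negligible and clipping keeps draws cheap and reproducible.

**What the generator does not emulate:** heavier-than-Gaussian pixel
tails, spatial autocorrelation within plots, radiometric/illumination
drift between flights, compression artefacts, orthomosaic seams, weather
and management effects, and kernel number vs kernel weight composition of
yield. Tests passing on this generator show the *pipeline* is correct and
that its inferences recover known generative structure; they do not show
that real maize data satisfy the generative assumptions.

## 6. Numerical and interface conventions

* BNDVI is computed in double precision after promoting integer channels;
  pixels with NIR + Blue = 0 are missing, excluded everywhere, and
  counted. The boundary pixel exactly at threshold is canopy ("plant"),
  making the partition deterministic.
* The NGB image convention is NIR, green, blue in channels 1–3; such files
  look like RGB with vegetation rendered red, and nothing in the file
  marks the substitution — it is a contract of the acquisition pipeline.
  Synthetic NGB TIFFs invert the BNDVI definition (NIR = (1+v)/2,
  Blue = (1−v)/2) at 16-bit depth, reproducing v to < 4e−5.
* Histogram matrices and decompositions serialise to CSV with 17
  significant digits, a lossless double round-trip.
* Eigenvector orthonormality is maintained to 1e−8; PLS factor scores are
  mutually orthogonal to the same tolerance; reconstruction with all
  components restores `X` to 1e−8.
* Rank-deficient PLS inputs truncate the factor path with a warning;
  zero-variance responses are errors; degenerate hold-out splits (constant
  response) are re-drawn and counted.
* The problem sizes used by the test-suite recovery checks — a
  25 × 2 × 10-date season at 20,000 px/plot, a dense 22-date season for
  dip recovery and prediction, 100 hold-out draws — were chosen as the
  smallest sizes at which the generative signals are clearly resolvable;
  smaller fixtures are used where only bookkeeping is under test.

## 7. Known limitations

* The 0.06 canopy threshold was established for camera-processed imagery;
  whether it transfers to linear sensor data is unknown, so it is a
  parameter everywhere it appears.
* Per-date significance flags are raw; families of dates/components need
  the BH option if used for formal inference.
* Unrestricted hold-out r overstates out-of-genotype predictive power in
  replicated designs (Section 4); use grouped splits for that question.
* PCA is linear: a moving canopy mode is encoded as a mass gradient along
  its eigenvector, so component scores are only locally linear in the
  underlying location parameter, and components beyond the first three mix
  interpretations.
* The dip detector assumes flights dense enough to bracket the dip
  (≈ every 3 days for a ~4-day-wide dip); weekly flights miss shallow
  dips, which is a property of the sampling, not the detector.
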