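---
title: "DAPI-gated quantification of nuclear biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DAPI-gated quantification of nuclear biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleogate)
```

## The measurement problem

Immunofluorescence on formalin-fixed paraffin-embedded (FFPE) tissue —
the standard clinical preparation — is plagued by autofluorescence.
Erythrocytes, fixation adducts and some brain cells all emit in the
red/orange range where secondary antibodies such as Alexa-594 are
read, and this intrinsic emission is routinely *brighter* than true
antibody signal.  A global intensity threshold therefore cannot
separate signal from artifact: the artifact is on the wrong side of
it.  At the same time, the DAPI excitation range is essentially free
of tissue background, so the nuclear counterstain can be trusted.

`nucleogate` turns this asymmetry into the measurement principle.  For
a nuclear biomarker, all legitimate signal lives inside DAPI-positive
regions.  The pipeline segments nuclei from the DAPI channel, then
measures biomarker brightness *only inside those regions*.  An
erythrocyte, however bright, overlaps no nucleus and consequently
contributes exactly nothing to any reported number.  This is a
structural guarantee, not a statistical tendency, and the test suite
checks it as an exact identity on twin scenes that differ only by
planted artifacts.

## The per-field workflow

For each two-channel field the pipeline computes three metrics: the
number of nuclei positive in the merged DAPI/biomarker image, the
number of nuclei positive in the biomarker image alone, and the mean
biomarker intensity over positive nuclei.

1. **DAPI branch.**  The DAPI channel is percentile-normalized
   (defaults 1st to 99th percentile mapped to [0, 1]), median-denoised
   (radius 1), and clustered into `dapi_k = 2` intensity classes.
   Everything above the dimmest class is nuclear; 8-connected
   components of at least `min_area = 50` px become nuclei.  Two
   classes suffice precisely because the DAPI channel is
   background-clean — its histogram is bimodal (background vs
   chromatin).  A larger `dapi_k` is counterproductive: with six
   classes the broad background-noise mode is subdivided and "above
   the dimmest cluster" would sweep in background.
2. **Biomarker branch.**  The biomarker channel is
   percentile-normalized with the percentiles computed **over nuclear
   pixels only**, then median-denoised.  Anchoring the stretch inside
   the gate has two consequences worth stating plainly: a global
   illumination factor cancels exactly (the stretch is linear in the
   percentiles), and extranuclear content — however bright — cannot
   move the normalization.  Whole-image percentiles would violate both
   exactness properties, because adding artifact pixels shifts the
   empirical order statistics.
3. **Merged image.**  The pixelwise maximum of the two processed
   channels.  The maximum preserves [0, 1] without rescaling and
   dominates the biomarker channel everywhere.
4. **Positivity.**  The nuclear-gated biomarker image (extranuclear
   pixels zeroed) is clustered into `k_clusters = 6` intensity
   classes; the lower boundary of the brightest class — the midpoint
   between the top two centroids — is the positivity threshold.  A
   nucleus is positive if its mean intensity reaches the threshold
   (the boundary itself counts as positive).  Classifying on the
   region mean rather than per-pixel membership is deliberately
   robust to the speckled morphology of nucleoplasmic biomarkers: a
   nucleus densely dusted with bright speckles should be positive even
   though its dimmest pixels are not.

### Why the 1-D clustering is solved exactly

Six-class intensity clustering is a one-dimensional k-means problem,
and in one dimension k-means is solvable to global optimality by
dynamic programming over the sorted values (clusters of an optimal
solution are intervals).  `cluster_intensities()` implements the
weighted divide-and-conquer DP and then runs Lloyd iterations from the
optimal centroids — a fixed point, so the iterations serve as
verification and materialize the nearest-centroid label map with a
deterministic tie rule (ties go to the lower cluster).

The obvious cheaper alternative — Lloyd's algorithm seeded at evenly
spaced quantiles — was implemented first and rejected on evidence.
Fluorescence histograms are strongly gapped: background, nucleoplasm
and speckle brightness form separated modes with empty intensity
ranges between them, and Lloyd centroids cannot cross an empty gap.
On gated biomarker images the quantile seeding regularly placed two
centroids inside the tight speckle mode, splitting it between classes
five and six and pushing the "sixth cluster" threshold above every
nucleus mean — zero positive calls on scenes that are 40% positive by
construction.  The exact solver assigns the speckle mode one class and
the threshold falls into the gap between nucleoplasmic and speckle
brightness, where it belongs.  Determinism is retained (no random
initialization anywhere), and the within-cluster sum of squares is
verified against an independent naive DP oracle in the tests.

### One threshold for both counts

The merged image dominates the biomarker image pixelwise, so with a
*common* threshold every biomarker-positive nucleus is also
merged-positive: the count ordering
`n_biomarker_positive <= n_merged_positive <= n_nuclei` is a theorem.
The default (`shared_threshold = TRUE`) therefore applies the
biomarker clustering's sixth-class threshold to both images.  Under
per-image thresholds (available as `shared_threshold = FALSE`) the
merged clustering may place its own threshold higher than the
biomarker one, and marginal nuclei can then be biomarker-positive but
merged-negative — the ordering becomes a strong tendency rather than
a guarantee.  Because the ordering is a stated property of the
method, the guaranteed variant is the default.

With nuclei bright in DAPI, the merged count behaves in practice as a
cellularity-weighted count: nearly every detected nucleus clears the
shared threshold in the merged image.  That is the intended reading —
differences in the merged metric between diagnostic groups are driven
chiefly by cellular density, while the biomarker-only count isolates
expression.

### What "mean intensity" means here

The paper-style mean intensity is computed over biomarker-positive
nuclei by default (`intensity_over = "positive"`); averaging over all
nuclei is available behind the flag, since either reading of "mean
signal intensity in cells" is defensible.  Note that per-field
normalization pins the intensity scale within each field, so this
metric measures *relative within-field* brightness; systematic
between-group brightness differences express themselves in the counts
(more nuclei reach the sixth cluster), not in this mean.  Zero
positive nuclei yield a mean intensity of 0 with a warning.

## Noise handling

Denoising is a median filter (radius 1 by default, square window,
replicate padding) — edge-preserving and suited to impulsive shot
noise.  It is lossless by construction: the signed residual
`input - denoised` is returned alongside and `reconstruct()` recovers
the input bit for bit, so the residual can be rendered in HSV to
confirm by eye that only noise was removed.  Exactness needs one
numerical subtlety: a single double-precision residual cannot always
restore a pixel that is orders of magnitude dimmer than its window
median (the subtraction rounds away the pixel's lowest bits — no
double added to the median can bring them back), so the rounding
remainder, zero almost everywhere and below one unit in the last
place elsewhere, is carried in a second compensation term
(`residual_lsb`), and `(denoised + residual) + residual_lsb` is exact
by the standard error-free-transformation argument.  Background from
no-primary-antibody controls is *characterized* (mean, sd, 99th
percentile of the denoised control) and reported as QC, never
subtracted: the autofluorescence defense is spatial gating, and the
control profile's role is to document that artifact brightness
exceeds the signal range — the very fact that makes intensity
thresholding inadmissible.

## The synthetic scene generator

No public image set accompanies this class of assay, so the package
ships a generator whose defaults encode the imaging conditions the
method is designed for, with full ground truth.  Defaults: 256 x 256
px fields; 20 nuclei as rotated ellipses with semi-axes 5–9 px
(glial scale at 20x); nuclear DAPI level 0.7; biomarker speckles at
0.55 covering 70% of positive-nucleus area over a 0.08 nucleoplasmic
base; one 3-px perinucleolar punctum per positive nucleus; 40% of
nuclei positive; four extranuclear erythrocyte-like blobs at 0.9 —
brighter than any true signal, present only in the red channel; a
multiplicative illumination factor on the biomarker channel; additive
Gaussian sensor noise (sd 0.01) on both channels; and within-nucleus
texture (sd 0.06), because chromatin and nucleoplasm are never flat
and continuous histograms are what real intensity distributions look
like.  Images are quantized to the 16-bit grid, so TIFF round-trips
are bit-identical.

Random draws are ordered so that nuclei, positivity, texture,
speckles and noise are all generated *before* artifacts: two specs
differing only in `n_artifacts` produce pixel-identical images outside
the artifact blobs.  Artifacts keep a 3-px margin from every nucleus,
so a radius-1 median window centred on a nuclear pixel never touches
one.  These two guarantees make the artifact-immunity property
testable as exact equality.

The default cohort (`cohort_groups()`) mirrors a realistic archival
series: 4 reactive-gliosis, 4 recurrent-glioblastoma, 5 de novo
glioblastoma and 16 pilocytic-astrocytoma specimens, 7 randomized
fields each.  Recurrent and de novo glioblastoma carry elevated
cellularity (Poisson mean 32 vs 18 nuclei per field) and positive
fraction (0.45 vs 0.15), while *staining intensity levels are
identical across groups* — so count metrics separate reactive from
recurrent tissue strongly, and the intensity metric does not
distinguish recurrent from de novo disease.  That is the qualitative
signature the statistics layer is expected to recover, and the test
suite requires it in at least 18 of 20 seeded replicates.

What the generator does **not** emulate: touching or overlapping
nuclei (no watershed is implemented, so the simulator respects the
segmenter's stated scope), out-of-focus blur, vignetting, necrosis or
hemorrhage geometry beyond elliptical blobs, and spatially correlated
texture.  Passing tests on synthetic scenes therefore demonstrate the
correctness of the algorithms under the stated physics — clean DAPI,
artifact brightness above signal, speckled nuclear signal — not
performance on adversarial real-world tissue.

## Statistics layer

Rater agreement uses weighted Cohen kappa with squared weights
`(i - j)^2` over the full category range of the scale, the convention
of standard agreement toolkits for ordinal scores; the z statistic
uses the Fleiss–Cohen–Everitt large-sample null standard error and a
two-sided normal p-value.  Verbal interpretation follows Landis–Koch
bands with intervals closed at the upper end (0.60 is still
"Moderate").  Concordance between two raters is the literal
"difference < 1 point" rule — for integer scores only exact agreement
qualifies, which is flagged in the documentation; scale-level
discordance is compared by Pearson chi-square without continuity
correction (switchable).  Group comparisons pool per-image metrics
within each diagnostic group and run one-way ANOVA with Tukey HSD
adjusted p-values from the studentized range (Tukey–Kramer for the
unbalanced group sizes); the two-sample case uses the pooled-variance
t-test.  All of these go through base R (`aov`, `TukeyHSD`,
`chisq.test`, `t.test`); the kappa machinery is implemented here and
cross-checked in the tests against a definitional summation oracle
and frozen external reference values.

## Numerical conventions, edge cases, problem sizes

* Intensities are doubles in [0, 1] immediately after load; bit depth
  is metadata.  Images below 16 x 16 px are rejected.
* Cluster assignment ties (a value exactly midway between centroids)
  go to the lower cluster; a nucleus mean exactly at threshold is
  positive; Landis–Koch bands close at the upper end; concordance is
  strict (`< 1`).
* Constant images cannot be normalized (zero dynamic range) and the
  error names the offending channel.  Fields with no detectable
  nuclei, or no biomarker dynamic range inside nuclei, return zero
  metrics with a warning rather than failing a whole run; the
  pipeline log counts such fields.
* Lloyd polish stops at a centroid shift below 1e-7 or 300
  iterations; with the DP initialization it converges immediately.
* Test and acceptance simulations use 256 x 256 scenes, 91-field
  cohorts (4/4/5 specimens x 7 fields) and 20 replicates — sizes
  chosen so the full property suite exercises thousands of fields
  while remaining comfortable on a single desktop core.

## Known limitations

Touching nuclei are merged (no watershed); the mean-intensity metric
is relative to the within-field normalization, not an absolute
expression level; kappa's null SE is a large-sample approximation;
and the merged-count metric intentionally tracks cellularity, so it
should be interpreted jointly with the biomarker-only count, never in
isolation.
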