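# nucleogate

DAPI-gated quantification of nuclear biomarkers in two-channel
fluorescence micrographs of FFPE tissue.

## The problem

Immunofluorescence on formalin-fixed paraffin-embedded (FFPE) tissue
is confounded by autofluorescence: erythrocytes and fixation products
emit brightly in the red channel where antibody signal is read, and
this artifact emission is routinely *brighter* than true signal, so no
intensity threshold can remove it.  The DAPI excitation range, in
contrast, is essentially background-free in FFPE material.
`nucleogate` exploits that asymmetry: nuclei are segmented from the
clean DAPI channel, and biomarker brightness is measured **only inside
nuclei**, so extranuclear autofluorescence — however bright — has
exactly zero influence on the results.  The package is aimed at
quantitative digital-pathology workflows for nuclear biomarkers (the
motivating application is an RNA-binding protein elevated in
glioblastoma, scored on second-resection biopsies to separate reactive
gliosis from recurrent tumor), and at anyone who needs a tested,
deterministic reference implementation of this style of analysis.

## Method

For each field (one DAPI image `D`, one biomarker image `B`):

1. **Normalize** — percentile stretch mapping the (1st, 99th)
   percentiles to [0, 1]; for `B` the percentiles are computed over
   nuclear pixels only.  A global illumination factor *c* cancels
   exactly: `norm(cI) = norm(I)`.
2. **Denoise** — median filter (radius 1) with exact residual
   accounting: `denoised + residual == input`.
3. **Segment** — 1-D intensity k-means on `D` (k = 2); everything
   above the dimmest cluster is nuclear; 8-connected components with
   area ≥ 50 px are nuclei.
4. **Merge** — `M = max(D, B)` pixelwise.
5. **Classify** — the nuclear-gated `B` is clustered into k = 6
   intensity classes; with ascending centroids `c₁ < … < c₆`, the
   positivity threshold is `t = (c₅ + c₆)/2`, the lower boundary of
   the brightest ("sixth") cluster.  A nucleus with mean intensity
   ≥ t is positive.  The 1-D k-means is solved *exactly* (dynamic
   programming over sorted values, as in `Ckmeans.1d.dp`), so the
   clustering is deterministic and globally WCSS-optimal.

Per-field outputs: `n_merged_positive` (nuclei positive in `M`),
`n_biomarker_positive` (nuclei positive in `B`), and `mean_intensity`
(mean normalized biomarker intensity over positive nuclei), plus
`n_nuclei`.  By construction
`n_biomarker_positive ≤ n_merged_positive ≤ n_nuclei`.

On top sit the study-level statistics: squared-weight Cohen kappa
(κ_w = 1 − Σw·O / Σw·E with w_ij = (i−j)², Fleiss–Cohen–Everitt null
SE, Landis–Koch interpretation bands), the strict "<1 point"
concordance rule with a Pearson chi-square comparison of discordance
between scales, one-way ANOVA with Tukey HSD (studentized range,
Tukey–Kramer) across diagnostic groups, and the pooled-variance
t-test.  A synthetic scene generator produces two-channel fields with
full ground truth (elliptical nuclei, speckled nuclear signal dimmer
than erythrocyte-like artifacts, illumination decay, sensor noise)
and multi-group cohorts with planted effects.

## Worked example

```r
library(nucleogate)

scn <- generate_scene(scene_spec(seed = 42))   # 20 nuclei, 40% positive
m <- compute_field_metrics(scn$field)
m
#>   specimen_id group_label field_index n_nuclei n_merged_positive
#> 1        SYN1    REACTIVE           1       20                20
#>   n_biomarker_positive mean_intensity
#> 1                    8      0.7816664
```

The planted scene contains 20 nuclei of which 8 are biomarker-positive;
the pipeline recovers all 20 nuclei and exactly the 8 positives, with
the sixth-cluster threshold at 0.653 — between the nucleoplasmic
background of negative nuclei (≈0.12) and the speckle-driven means of
positive nuclei (≈0.78, reported as `mean_intensity`).  All 20 nuclei
clear the threshold in the merged image (`n_merged_positive = 20`)
because nuclei are DAPI-bright: the merged count tracks cellularity.

```r
rt <- rating_table(
  case_id = sprintf("case%02d", 1:6),
  group_label = "PILOCYTIC", scale = "THREE_POINT",
  rater_a = c(0, 1, 2, 3, 2, 1),
  rater_b = c(0, 1, 2, 2, 2, 0))
weighted_kappa(rt)
#> Weighted kappa = 0.818 (Almost Perfect Agreement), z = 2.138, p = 0.0325, n = 6
```

An end-to-end run over an image directory (manifest-driven) is
`run_pipeline(run_config(input_dir, output_dir))`, or from a shell:

```sh
exec/nucleogate simulate --out cohort/ --seed 1
exec/nucleogate quantify --input cohort/ --out results/
```

which writes `field_metrics.csv`, `pairwise_comparisons.csv`
(ANOVA/Tukey per metric) and a structured `run_log.json`.

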