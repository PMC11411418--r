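---
title: "Methods: colorimetric sensor-array analysis with chromanose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colorimetric sensor-array analysis with chromanose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromanose)
library(dplyr)
```

## The measurement model

A paper-based optoelectronic nose carries 12 sensing elements
(S1–S12), each a spot of dopamine-capped Cu/Ag bimetallic nanozyme
mixed with one organic dye (alizarin red S, indigo carmine, toluidine
blue, malachite green, Congo red, phenol red, pararosaniline,
bromopyrogallol red, erythrosine, murexide, Chrome Azurol S, eriochrome
black T for S1–S12). Volatile analytes are catalytically transformed at
the nanozyme; the products shift the hydronium concentration or bind the
dye, and the spot color changes. The raw signal of one exposure is the
per-spot, per-channel RGB difference between a scan taken before and one
taken after exposure,
$\Delta = (\Delta R, \Delta G, \Delta B)$ per element.

Two blank corrections define the final signal:

* **VOC mode** (pure compound in the reaction container):
  $x = \Delta_{\text{full}} - \Delta_{\text{empty}}$, removing the
  drift the device shows in an empty container.
* **Urine mode**:
  $x = \Delta_{\text{urine}} - \Delta_{\text{water}} - \Delta_{\text{empty}}$,
  additionally removing the response to water vapor, which dominates
  urine headspace.

The corrected values of the 12 elements are assembled element-major
(S1\_R, S1\_G, S1\_B, …, S12\_B) into a 36-feature response vector
$x_1, \dots, x_{36}$. Negative values are retained — the difference
equations permit them and the sign carries pattern information. A single
scalar summary, used wherever the assay needs "one number per sample",
is the Euclidean norm $\lVert x \rVert = \sqrt{\sum_i x_i^2}$.

## Condition optimization: the discriminant ability function

Assay conditions (dye loading, exposure time, temperature) are chosen to
maximize group separation, quantified by the discriminant ability
function (DAF): the ratio of between-group to within-group variance of
the per-sample norms. `compute_daf()` uses the one-way ANOVA mean-square
convention,
$\mathrm{DAF} = \frac{\sum_g n_g(\bar{x}_g - \bar{x})^2 / (G-1)}
                     {\sum_{g,i} (x_{gi} - \bar{x}_g)^2 / (N-G)},$
which is zero when group means coincide and grows without bound as the
groups separate. Zero within-group spread with separated means is
reported as `Inf` rather than an error. A multivariate alternative
(`method = "wilks"`, scored as $(1-\Lambda)/\Lambda$ from a one-way
MANOVA on the full 36-feature vectors) is provided but is not the
default, because the assay's condition scans summarize each sample by
its norm before comparing groups.

Operating points are not taken at the literal DAF argmax.
`select_operating_point()` returns the smallest grid value whose DAF is
within `plateau_tol` (default 5%) of the maximum — the "earliest
plateau". On saturating scans this picks the point where the response
has effectively equilibrated instead of chasing noise on the plateau;
with `plateau_tol = 0` it reduces to the first argmax, and a flat curve
yields the smallest grid value. The 5% default reproduces the
earliest-plateau reading on saturating synthetic scans while being wide
enough that plateau-level DAF sampling noise (which is substantial at a
few dozen samples per grid point, the realistic batch size) does not
push the selection to the scan end.

## Discrimination layer

* **PCA** (`run_pca()`): mean-centered, optionally autoscaled.
  Centering without autoscaling is the default because all 36 features
  share the same 8-bit color units; autoscaling would inflate
  low-response channels.
* **HCA** (`run_hca()`): agglomerative clustering with Ward's criterion
  on Euclidean distances (`hclust`, `ward.D2`), cut at a chosen number
  of clusters. "Total accuracy" of a clustering is made well-defined by
  optimal assignment: the best one-to-one cluster-to-class pairing is
  found by exact search (clusterings here have at most a handful of
  clusters) and accuracy is the fraction of samples in their class's
  cluster. This is invariant to cluster relabeling, unlike majority
  voting.
* **PCA–LDA** (`pca_lda_classify()`): principal components are fitted
  inside each cross-validation fold, linear discriminant analysis is
  trained on the retained scores, and the held-out sample is projected
  and predicted. Leave-one-out is the default because cohort sizes in
  this kind of study are small; a resubstitution mode exists for
  comparison but is optimistic. The number of retained components
  defaults to those explaining ≥ 95% of training variance, capped at
  $n - \#\text{classes} - 1$ so the LDA stays well-posed.
  `report_metrics()` computes accuracy (trace/total), per-class
  sensitivity (recall) and specificity (true-negative rate); for two
  classes the sensitivity of one class equals the specificity of the
  other.

## Clinical layer

`grade_spirometry()` grades injury severity from percent-predicted
spirometry: control when FEV1 > 80 and FEV1/FVC > 70; mild when
FEV1 > 80 and the ratio is below 70; moderate for FEV1 in [50, 80];
severe for FEV1 in [30, 50). The printed rules leave the exact
boundaries open; the conventions adopted here (closed moderate band,
ratio of exactly 70 counted as control, FEV1 below 30 graded severe
with an `out_of_range` flag) are isolated in this one function.
Severity is encoded ordinally (control 0, mild 1, moderate 2,
severe 3) for `severity_regression()`, an ordinary least-squares fit of
a response norm on grade with $R^2$ reported. Age effects are tested by
`pearson_with_p()` (Pearson r with the two-sided t-transform p-value on
$n-2$ degrees of freedom), and replicate reproducibility by `rsd()`
(sample standard deviation over mean, as a percentage). Since the
severity plots are attributed to "sensing elements S3 and S7" without
stating whether they were fitted individually or jointly,
`clinical_summary()` reports each per-element fit and a combined fit.

## What the synthetic data emulates

The package ships no measured data; `generate_voc_dataset()` and
`generate_cohort_dataset()` simulate response matrices with the
structure the analysis assumes, and `render_array_scan()` draws scan
images for the imaging path. Defaults are fixed once to mirror the
study design:

* **Panel and shape.** Nine compounds — ethanol, butanol, hexanol;
  acetaldehyde, butyraldehyde, hexanaldehyde; ethyl acetate, ethyl
  butyrate, ethyl hexanoate — with three replicates each, giving the
  canonical 27 × 36 matrix. Three replicates per compound is an
  inference from 27 = 9 × 3, not a printed fact.
* **Selectivity structure** (`default_profiles()`). S1 and S3 respond
  mainly to alcohols, S6/S7/S8 to aldehydes, S4 to esters, S12 strongly
  to all three classes, and every element at least weakly to every
  vapor; ester patterns share features with both other classes, which
  places them between alcohols and aldehydes in PCA score space. The
  quantitative means are free parameters of this package: the source
  figures are qualitative, so values were chosen once so that every
  in-text selectivity statement holds with class separations well above
  the replicate noise, and they are user-replaceable.
* **Carbon-chain trends.** Aldehyde homologues scale the selective
  elements multiplicatively per carbon beyond the class minimum
  (S6 strengthens, `chain_slope` 0.15; S7 and S8 fade, −0.08).
* **Urine cohorts.** S4 and S8 (plus weak S12) respond in both cohorts;
  S3 and S7 are silent in controls and respond in injured subjects
  proportionally to severity grade (`urine_injured +
  severity_slope · grade · urine_severity` per element). This makes
  `severity_slope = 0` an exact null and noiseless severity norms
  exactly collinear with grade. Cohort sizes default to 36 controls and
  114 injured; the injured split (38/38/38 over mild/moderate/severe)
  is this package's choice, as the study does not print one. Ages are
  drawn uniformly in 50–75 (war veterans of the 1980s surveyed in
  2021–23), independently of response, so the age effect is null by
  construction. Spirometry values are drawn strictly inside each
  grade's diagnostic band so grading round-trips without boundary
  ambiguity.
* **Noise.** Per-channel i.i.d. Gaussian noise with standard deviation
  `noise_rsd × ‖mean vector‖`. For small relative noise the replicate
  Euclidean norms then have relative standard deviation ≈ `noise_rsd`
  (the component of the noise along the mean direction dominates), so
  the generator's noise knob is calibrated in the same units as the
  assay's reproducibility metric. Default `noise_rsd = 0.05`, the
  reproducibility scale of the real assay (~5% RSD).
* **Condition scans** (`generate_condition_scan()`). Responses approach
  equilibrium as `1 − exp(−p/midpoint)` along the scanned parameter
  while the scanner noise floor stays constant, so the DAF rises and
  plateaus; the earliest-plateau rule then lands where the response has
  saturated.

What the generator does **not** emulate: correlated channel noise
within a spot, scanner color management, drift between before/after
scans beyond the blank terms, inter-subject biological variance within
a severity grade (subjects of one grade share one mean response, which
is what makes within-grade RSD a pure replicate-noise readout), and any
chemistry of the dye–analyte mechanisms. Passing tests therefore show
that the pipeline's statistics behave correctly under the assumed
response structure — not that the real assay attains any particular
accuracy. In particular, the measured clinical figures (78% PCA–LDA
accuracy, $R^2$ of 0.928/0.959, RSD of 4.67%/5.62%) depend on the real
cohort and are treated as qualitative references only; on the clean
synthetic cohorts the classifier is essentially perfect.

## Numerical and design choices

* ROI geometry for spot extraction: a circle at 80% of the nominal spot
  radius, arithmetic mean per channel (the ImageJ "mean gray value"
  convention); the source workflow used manual ROIs of unstated shape.
* Images are 8-bit RGB with no color management, matching consumer
  scanner output.
* A 180°-rotated scan of the default layout would be indistinguishable
  from an upright one (the 4 × 3 spot grid is symmetric), so rendered
  scans carry a small white fiducial square in the rectangle's top-left
  corner; `register_array()` auto-corrects the placement when the
  fiducial is found at the opposite corner and otherwise assumes the
  scan is upright. Real upright scans without a fiducial register
  unchanged.
* Feature order is fixed element-major (RGB within element) and is part
  of the package contract (`response_cols()`).
* Exact-search assignment for cluster accuracy is limited to 8 clusters;
  beyond that the factorial search is replaced by an error, since the
  assay never cuts deeper than a handful of classes.
* Problem sizes in the shipped tests: 27-sample VOC matrices,
  150-subject cohorts, 200-replicate convergence checks, 240-pixel-wide
  rendered scans — the scale at which the statistics stabilize while
  test runs stay fast.

## Known limitations

* The generator's class means are stylized; real dye responses are
  correlated across channels and drift with sensor age (the physical
  sensor is valid for ~75 days, which this package models only as a
  metadata concern, not at all chemically).
* `register_array()` assumes scanner-like geometry: one dark rectangle,
  axis-aligned, on a light background. Perspective or rotation other
  than 180° is out of scope.
* DAF values at realistic batch sizes are noisy (between-group degrees
  of freedom are small); operating-point selection on measured curves
  inherits that noise. The plateau rule is deliberately tolerant, but
  on a nearly flat measured curve adjacent grid points are genuinely
  exchangeable.
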