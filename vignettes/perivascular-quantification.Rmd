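---
title: "Quantifying perivascular amyloid plaque topography: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying perivascular amyloid plaque topography: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periplaque)
```

This vignette is the package's account of its own methods: the model each
stage implements, the assumptions behind it, the parameters that matter,
and the design choices made where the underlying convention was genuinely
open. Nothing here reports an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The measurement model

A subject contributes one fundus fluorescence image of the supero-temporal
quadrant and one manual vessel annotation: centerline polylines with
arteriole/venule labels, parent links, and the optic-disc position.
Hyperfluorescent amyloid plaques are counted inside *perivascular zones* —
bands one vessel diameter wide on either side of each traced vessel — and
stratified by vessel type and branch order. The package deliberately does
not segment or trace vessels automatically, nor classify artery versus
vein from appearance: those labels come from the annotation (in practice
assigned by trained observers from caliber, location and morphology; in
the synthetic data, from ground truth).

### Diameter measurement

The vessel diameter is the arithmetic mean of width samples taken at
pre-set intervals along the centerline, with the most proximal and most
distal positions always included. Width comes either from a per-vertex
width profile in the annotation (linearly interpolated in arc length) or
from perpendicular chords through a binary vessel mask, marched at
quarter-pixel steps. The sampling interval defaults to 20 px; no interval
is dictated by the measurement convention itself, and 20 px gives 5–10
samples on typical synthetic branch lengths (45–150 px) while keeping the
endpoint rule visible. A zero chord at any sample aborts with an error
rather than silently averaging over a broken mask.

### Branch-order taxonomy

Orders advance at *main bifurcations* only. The rules, applied
breadth-first from the roots:

* root segments (proximal end within `root_radius` of the optic disc) are
  primary main;
* at a split of a main branch of order *k* ≤ 2, daughters with diameter
  below `small_ratio_threshold` × parent mean diameter are *small*
  branches of order *k*; if ≥ 2 daughters are of comparable caliber the
  split is a bifurcation and those daughters take order *k* + 1; exactly
  one comparable daughter means a continuation at order *k*;
* order 3 and beyond, and every descendant of a small branch, is
  *tertiary* — tertiary vessels are not subdivided further because their
  calibers are nearly equal and order bookkeeping past the second
  bifurcation adds nothing the reporting taxonomy uses.

The small-vs-main criterion is the one genuinely open choice: the
underlying convention distinguishes "bifurcation" daughters from
"protruding small vessels" visually, without a number. We use a diameter
ratio threshold, default 0.6, exposed as `small_ratio_threshold`. The
synthetic generator draws main daughters at ratios 0.72–0.85 and small
twigs at 0.30–0.45, placing both populations well clear of the threshold;
the classifier-vs-oracle agreement the tests demonstrate is therefore a
check of rule *implementation*, not of threshold robustness on ambiguous
real calibers — real tracings with daughters near 0.6 will be sensitive
to this parameter. A split where *every* daughter falls below the
threshold counts no bifurcation event (all daughters become small
branches of the parent's order); a trifurcation is treated as a single
bifurcation event advancing all comparable daughters, with a logged note.

For reporting, main + small combine into `primary_total` and
`secondary_total`; the seven categories per vessel type are the five leaf
classes plus these two unions.

### Perivascular zones

The zone of a segment with mean diameter *d* is the set of pixels whose
center lies within 1.5 *d* of the centerline polyline: a stroke of total
width 3 *d*. Design choices:

* **Lumen included.** The stroke covers the vessel itself; a plaque
  overlying the lumen is perivascular. The construction draws one wide
  stroke and counts everything inside its boundary, so subtracting the
  lumen would mismeasure.
* **Flat caps.** No disk extends beyond the endpoints (configurable to
  round caps). Joints between polyline edges are filled with vertex
  disks, clipped by the two end-cap planes; this assumes a
  forward-progressing centerline, which traced vessels satisfy.
* **Raster authority.** The zone is authoritative as a raster mask at
  pixel resolution (pixel centers at half-integer coordinates, which
  makes integer-coordinate annotations rasterize without half-pixel
  bias); the GeoJSON export is an analytic offset polygon for
  interoperability only.
* **Overlaps kept.** Overlapping arteriolar and venular strokes are both
  kept intact; per-type total areas count union pixels once.

### Plaque detection and assignment

The reference image-enhancement chain is proprietary, so detection here is
a deliberately transparent operator: white top-hat with a disc of radius
`background_radius` (default 9 px, chosen above the largest rendered spot
radius), threshold at median + `threshold_k` × MAD (default k = 6),
connected components filtered to areas 4–400 px². All parameters are
exposed, and externally detected plaque lists can be supplied instead, so
the downstream pipeline is independent of this choice. Detection is
deterministic for fixed input.

Assignment implements the border-touch rule: a plaque is a member of a
zone when footprint and zone share at least one pixel, so spots straddling
the boundary count as perivascular. A plaque may belong to several zones.
Counting then resolves multiplicity:

* within one scope and order, a plaque touching both a main and a small
  zone is attributed to *main*, so main + small = total holds exactly;
* a plaque touching both vessel types increments both peri-arteriolar and
  peri-venular scopes but the combined perivascular scope once — which is
  why type totals may sum to more than the combined total;
* `non_perivascular` = all analyzed plaques minus distinct perivascular
  plaques, so the partition `total = perivascular + non_perivascular` is
  an invariant.

Plaques outside the supplied analysis-quadrant polygon are ignored
entirely, including for the non-perivascular count.

## 2. The statistics layer

Test selection follows a normality gate: a sample is Gaussian when it
passes *at least one* of the D'Agostino–Pearson omnibus test and the
Shapiro–Wilk test at α = 0.05. The omnibus K² statistic is implemented
from the standard transformed-skewness (D'Agostino) and transformed-
kurtosis (Anscombe–Glynn) formulas and requires n ≥ 8; below that the
gate rests on Shapiro–Wilk alone. Two-group contrasts use the
pooled-variance Student t (not Welch — recomputing the reference
secondary-branch contrast from its printed summaries reproduces the
printed p only under pooled df), or the two-tailed Mann–Whitney when the
gate fails. `group_comparison_summary()` accepts (mean, SD, n) pairs
directly so printed table cells can be recomputed without raw data.

Fold changes are ratios of group means. The CI construction was not
specified by the reference convention; we default to Fieller's interval
for a ratio of independent means (t quantile at pooled df, unbounded
intervals flagged when the denominator mean is compatible with zero).
Fieller CIs are reported, never used as decision gates, and differ
numerically from the reference tables' printed intervals, whose method is
unknown.

CDR severity strata (0.5 / 1 / 2) are compared by one-way ANOVA with
Tukey HSD adjusted pairs; levels with fewer than two observations are
dropped with a warning. Correlation grids use Pearson's r on
pairwise-complete observations (n per cell therefore varies, matching how
such tables are reported), with cells of n < 3 or zero variance flagged
rather than computed. Holm–Bonferroni flags are applied within families;
the family definition is ambiguous in the reference convention, so it is
configurable: default is one clinical variable's column across all
vascular categories, with a whole-grid alternative. Display rounding
follows the reporting convention (FC to 1 decimal, r to 2, p to 2
significant figures) and applies only to display columns.

Degenerate-input conventions: identical paired samples give t = 0, p = 1;
an exactly constant nonzero paired shift is reported as the t → ∞ limit
with the smallest positive double as p, keeping p in (0, 1].

## 3. What the synthetic data emulates — and what it does not

**Trees** (`generate_vessel_network`): one venule and one arteriole
rooted at the optic disc (vein root 14 px, artery 11 px, preserving the
vein > artery caliber cue), tortuous centerlines, main bifurcations to
depth 3 with small protruding twigs, diameters tapering within and across
segments. Every segment carries its construction-time label, the oracle
for the classifier. The 560 × 768 px field and 45–150 px branch lengths
are geometry choices that keep default trees inside the frame;
infeasible draws retry, then shorten with a warning, then error.

**Images** (`place_plaques_and_render`): plaque centers from an
inhomogeneous Poisson process — background rate `lambda_bg` per 10⁴ px²
and per-category multiplied rates inside zones (defaults enrich secondary
branches, arteriolar above venular, echoing the planted group contrast) —
rendered as Gaussian spots (σ 1.3–1.9 px, amplitude 0.30–0.55) on a flat
background with faint vessel strokes and Gaussian noise (SD 0.02, so
minimum spot SNR = 15). A minimum center separation of 9 px keeps planted
spots resolvable, which is what makes exact count-recovery testable; real
images contain confluent spots the detector would merge. Ground-truth
zone memberships are computed by an independent brute-force disc-vs-mask
test inside the generator, giving the dual route the assignment tests
rely on. The renderer does not attempt photorealism: no vignetting, no
focal blur gradients, no curcumin-uptake variability — so passing
recovery tests demonstrates correctness of the pipeline's bookkeeping at
favorable SNR, not detector performance on clinical images.

**Cohorts** (`generate_cohort`): per-subject counts for the ten base
cells (type × main/small/tertiary) drawn from group-specific (mean, SD)
pairs — defaults are the reference cohort's printed values — as
left-censored rounded normals (negative-binomial alternative, since
counts are discrete); all totals are *derived*, so the count-record
invariants hold by construction and derived-total summaries approximate
rather than equal the printed total-row summaries (cells are drawn
independently; real main/small counts covary). The combined perivascular
scope is the exact sum of the two type scopes, consistent with the
reference summaries, i.e. no cross-type dedup is simulated. The
non-perivascular cell's mean/SD are synthetic (60 ± 25 vs 78 ± 28,
preserving the reported 1.3-fold impaired-cognition excess) because only
its fold change and p were published. Clinical variables with planted
associations (e.g. hippocampal volume at ρ = −0.5 against peri-venular
tertiary counts) are built from the standardized realized count through a
Gaussian copula, so the planted ρ is the *marginal* cohort-level
correlation; remaining metadata are independent draws. CDR is assigned
14:3 mild:moderate within the impaired group (minimum two at the top
level so severity contrasts stay estimable) rather than independently,
trading a little realism for estimability.

## 4. Problem sizes and numerical choices

The test and acceptance workloads use 48–300 px frames for
pixel-exhaustive oracles, 100 trees for classification agreement, 20
rendered 560 × 768 images for detection recovery, and 500 replicate
cohorts (n = 9 + 19) for planted-effect recovery — sizes at which the
Monte-Carlo error of each check is far below its tolerance. Acceptance of
the planted group effect is judged by sign recovery of the fold change
across replicates; the significance-detection (power) rate is reported
alongside. Rasterization tolerance for band areas is 2%, which
half-integer pixel centers comfortably meet (the straight-band identity
is exact). Ties in the Mann–Whitney statistic follow the half-count
convention and are cross-checked against a brute-force pairwise oracle.

## 5. Known limitations

Automatic vessel tracing, artery/vein classification, far-peripheral and
capillary analysis are out of scope by design. Physical units are not
modeled: all geometry is scale-relative in pixels. The detection operator
is a stand-in with exposed parameters, not a reproduction of any
proprietary enhancement chain. The small-branch threshold is a convention
(see §1) and should be calibrated against grader judgment before use on
real tracings. Printed-summary recomputation can verify t-based cells
only; cells compared by Mann–Whitney in the reference tables cannot be
recomputed from (mean, SD, n) and are carried as reference values, not
checks.
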