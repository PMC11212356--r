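# periplaque

Quantification of perivascular amyloid-plaque topography in retinal fundus
fluorescence images, with the cohort statistics used to relate that
topography to cognition and neuroimaging markers of neurodegeneration.

## The problem

Retinal amyloid-β deposits imaged by curcumin-fluorescence scanning laser
ophthalmoscopy appear as discrete hyperfluorescent spots, many of them
hugging the retinal vessels. Whether those plaques sit preferentially
beside arterioles or venules, and whether they concentrate near the optic
disc or out along higher-order branches, carries diagnostic information:
peri-arteriolar deposition mirrors cerebral amyloid angiopathy, and a
shift of plaque burden into secondary branches accompanies cognitive
impairment. Turning that observation into numbers requires a reproducible
chain from traced vasculature to stratified counts to group statistics —
the chain this package implements, for imaging scientists and
neuro-ophthalmology researchers working with traced fundus images or with
per-subject count tables.

## What it computes

**Branch taxonomy.** Traced centerlines form optic-disc-rooted arteriolar
and venular trees. Vessels leaving the disc are the primary (1°) main
branch; each bifurcation into comparable-caliber daughters advances the
order (2° main, then tertiary); thin protruding vessels are "small"
branches of their parent's order (daughter is small when its diameter is
below `small_ratio_threshold` × parent diameter, default 0.6); everything
beyond the second main bifurcation is grouped as tertiary. For reporting,
main and small branches combine into primary and secondary totals.

**Perivascular zones.** Vessel diameter d is the arithmetic mean of widths
sampled at pre-set intervals along the centerline, endpoints always
included. The perivascular zone is the stroke of total width 3d centered
on the centerline — one vessel diameter on either side of the vessel —
with flat end caps, clipped to the frame.

**Counting.** Spots are detected by white top-hat filtering, a robust
threshold (median + k·MAD), and area-filtered connected components — or
supplied as an external list. A plaque belongs to a zone if its footprint
touches the zone by even a single pixel. Counts are tabulated per scope
(perivascular, peri-venular, peri-arteriolar) × branch category, plus the
non-perivascular remainder.

**Statistics.** Samples passing at least one of the D'Agostino–Pearson and
Shapiro–Wilk tests (α = 0.05) count as Gaussian; group contrasts then use
the pooled-variance two-tailed t, otherwise the two-tailed Mann–Whitney.
Fold changes FC = mean₂/mean₁ carry Fieller 95% CIs. CDR strata are
compared by one-way ANOVA with Tukey HSD. Count-vs-clinical associations
use Pearson's r with pairwise deletion and Holm–Bonferroni flags per
clinical-variable family.

Seeded generators (`generate_vessel_network`, `place_plaques_and_render`,
`generate_cohort`) produce labeled trees, rendered images with planted
plaques, and cohort tables with planted effects, so every stage is
testable without data downloads.

## Worked example

```r
library(periplaque)
g <- generate_vessel_network(seed = 7)          # synthetic quadrant
r <- place_plaques_and_render(g, seed = 7)      # image + planted truth
res <- run_quantify(r$image, g$network, subject_id = "sim007")
print(res$network)
#> <vessel_network> 24 segments (11 arteriolar, 13 venular), 2 roots, optic disc at (48, 280)
#>                  vessel_type
#> branch_class      artery vein
#>   primary_main         1    2
#>   primary_small        1    2
#>   secondary_main       2    2
#>   secondary_small      2    2
#>   tertiary             5    5
res$counts[, c("total_AP", "perivascular_total", "periA_total",
               "periV_total", "non_perivascular")]
#>   total_AP perivascular_total periA_total periV_total non_perivascular
#> 1       80                 18           9          11               62
```

80 spots were detected; 18 touch a perivascular band (9 peri-arteriolar,
11 peri-venular — a plaque touching both types counts once in the
combined scope), 62 lie outside every band. Group contrasts can be run
from raw columns or directly from printed summary statistics:

```r
group_comparison_summary(19.78, 10.47, 9, 35.79, 13.18, 19,
                         variable = "secondary branch AP count",
                         groups = c("NC", "IC"))
#> <stat_result> secondary branch AP count: NC vs IC
#>   test = unpaired_t, statistic = 3.188, df = 26, P (two-tailed) = 0.0037
#>   FC = 1.8 [1.3, 2.9], n = 9/19
```

The impaired-cognition group shows a 1.8-fold secondary-branch excess,
p = 0.0037 on the pooled t with 26 df.

A thin CLI over these functions lives at
`inst/scripts/periplaque-cli.R` (`simulate` / `quantify` / `stats`
subcommands).

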