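---
title: "Structural phenotype discovery: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural phenotype discovery: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbmclust)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters, what the synthetic-cohort generator does and
does not emulate, and the choices made where several reasonable designs
exist. Everything stated here is implemented and exercised by the test
suite; no empirical claim below goes beyond what the tests and the
acceptance script compute.

## The problem

Neurodegenerative disease does not atrophy every brain the same way. Given a
cohort of spatially normalized gray-matter (GM) density volumes — one scalar
per voxel per subject, comparable across subjects thanks to prior
segmentation and registration — we want to find subgroups of subjects with
*similar whole-brain atrophy patterns*, describe those subgroups clinically,
and localize the anatomical differences between them. The intended users are
neuroimaging analysts with a table of subjects (baseline diagnosis coded
NC = 1 / MCI = 2 / AD = 3, demographics, APOE ε4 genotype, longitudinal
ADAS-cog scores) and a stack of co-registered NIfTI volumes.

## Pipeline model

### 1. Confound removal

GM density varies with age, sex, scanner field strength and education in
ways that have nothing to do with the disease axis of interest. At each
masked voxel $x$ we fit, by ordinary least squares *on normal controls
only*,

$$ v_i(x) = \beta_0(x) + \beta_a(x)\,\mathrm{age}_i +
  \beta_s(x)\,\mathrm{sex}_i + \beta_f(x)\,\mathrm{field}_i +
  \beta_e(x)\,\mathrm{edu}_i + \varepsilon_i(x), $$

and take residuals $r_i(x) = v_i(x) - \hat v_i(x)$ for **every** subject,
patients and controls alike. Fitting on controls prevents the disease
effect (which is correlated with age) from being regressed away; applying
the model to all rows puts all subjects on one scale, which is necessary
because controls enter the clustering too. All voxels share one design
matrix, so the fit is a single QR solve; the tests verify it equals
independent per-voxel `lm()` fits.

Assumptions: confound effects are linear and additive in the covariates;
no site/batch structure beyond field strength; no intensity
standardization beyond residualization. Residuals are deliberately *not*
z-scored per voxel — raw residuals preserve each voxel's GM-density units
so that distances weight tissue loss by its physical magnitude rather than
by its local noise level; a z-scored variant would up-weight
low-variance voxels and is easy to add upstream of
`manhattan_distance_matrix()` if wanted.

### 2. Distances and complete-linkage clustering

The imaging phenotypic distance between subjects $i$ and $j$ is the
Manhattan (L1) distance over the brain mask,
$d_{ij} = \sum_x |r_i(x) - r_j(x)|$, in GM-density-sum units. L1 grows
linearly with the amount of differing tissue, making it a direct "total
tissue difference" measure. Metric axioms (including the triangle
inequality) are asserted when the matrix is built.

Clustering is agglomerative with the **farthest-neighbor (complete
linkage)** rule: starting from singletons, repeatedly fuse the pair of
clusters $A, B$ minimizing $\max_{a \in A, b \in B} d_{ab}$. Complete
linkage caps within-cluster diameter, so clusters are compact — appropriate
when "same structural phenotype" should mean *every* pair of members looks
alike. The agglomeration is implemented from scratch against the
max-pairwise definition (the Lance–Williams update
$d(A{+}B, C) = \max(d(A,C), d(B,C))$ realizes it exactly, by induction);
the test suite checks equivalence with an exhaustive per-step minimization
oracle on hundreds of random instances, including tie cases.

Two determinism choices the definition leaves open:

* **Tie-break.** When several fusions share the minimal height, we fuse the
  pair whose smallest original member index is lowest, then compare the
  other cluster's smallest index. Any fixed rule would do; this one makes
  trees reproducible across runs and platforms and is mirrored in the test
  oracle.
* **Cluster numbering.** After cutting, clusters are numbered by increasing
  smallest member index. Permuting subject order permutes labels but never
  the partition (property-tested).

### 3. Choosing the cluster count

Complete-linkage heights are monotone non-decreasing, so the merge-height
curve (`merge_metric_curve()`, plotted by `autoplot()` on the tree) falls
flat while coherent clusters merge and rises when mergers become forced.
The cut level is an **analyst's choice** informed by that curve; `k` is
therefore a required parameter of `cut_clusters()` and of the pipeline.
`suggest_k()` offers a labeled heuristic: the number of clusters remaining
just before the largest height jump (the standard "biggest gap in the
dendrogram" reading). An earlier sketch used a chord-distance (kneedle
style) rule, but on clean planted-cluster curves it lands mid-slope rather
than at the corner, so the gap rule was kept.

Clusters smaller than `min_cluster_size` (default 7 subjects) are flagged
non-reportable rather than dropped: below that size the characterization
statistics (percentages, slope SDs) are not meaningful, but the
assignments are still written so nothing silently disappears.

### 4. Cluster characterization

Per cluster we compute the row a reader of subtype-discovery reports
expects: size, sex and baseline-diagnosis counts, **average diagnosis**
$(1 n_{NC} + 2 n_{MCI} + 3 n_{AD})/n \in [1,3]$, APOE ε4 prevalence
(at least one allele, %), declining-status rate (% of subjects whose
follow-up diagnosis code exceeds baseline — only NC→MCI/AD and MCI→AD can
count on this scale), mean education / baseline ADAS / age, and the mean
and SD of per-subject **ADAS slopes** (OLS of score on month over visits at
months 0/12/24/36; subjects with fewer than two usable visits are excluded
from slope statistics but stay in the cluster).

Categorization splits $[1,3]$ into three equal bands. Printed descriptions
of such bands often round the boundaries (1.666 / 1.667 / 2.333) in ways
that conflict at the edges; we use exact fractions with ties going up:
NC if $\bar d < 5/3$, MCI if $5/3 \le \bar d < 7/3$, AD if
$\bar d \ge 7/3$. Boundary behavior is unit-tested.

Category-level progression is summarized by a two-sided 95% **t interval
over the reportable clusters' mean slopes** (unweighted, df = #clusters −
1). Alternatives — pooling subject-level slopes, or size-weighting cluster
means — are defensible; the unweighted cluster-level interval treats each
discovered phenotype as one observation about the category, which matches
how the clusters are interpreted. The method string is recorded in the
output so downstream readers see which convention produced the interval.
With fewer than two reportable clusters in a category the interval is
omitted with a warning, never fabricated.

The association between baseline diagnosis and APOE ε4 allele count is
tested by Pearson's chi-squared on the 3×3 contingency table (df = 4, no
continuity correction), via `stats::chisq.test()`.

### 5. Voxel-wise t-maps and FDR at a threshold

Anatomical differences between any two cluster unions are mapped by a
two-sample t statistic per voxel on the residualized data (the clusters
were formed on residuals; a flag allows raw-density maps for sensitivity
analysis). The default is the pooled-variance Student form
(df $= n_A + n_B - 2$), the classical VBM choice; Welch is available
behind `var_equal = FALSE` and the variance model is recorded in the
sidecar. Sign convention: positive $t$ = higher density in group A.
Voxels with zero variance in both groups get $t = 0$ and are counted, not
silently dropped.

The FDR at threshold $\theta$ (default $|t| > 3$) is the plug-in estimate

$$ \widehat{\mathrm{FDR}}(\theta) = \min\!\left(1,
   \frac{m \cdot P(|T_{df}| > \theta)}{\#\{|t| > \theta\}}\right), $$

with $m$ the masked voxel count. This bounds the expected false-positive
count by treating all $m$ voxels as null, so it is conservative
(upward-biased when many voxels carry signal). With no exceedances the
estimate is reported as not-applicable (`NA`), not zero. Voxel-wise
dependence makes the numerator an expectation only, not a guarantee; no
random-field or permutation correction is attempted.

## The synthetic-cohort generator

`simulate_cohort()` exists so that every stage is testable with known
ground truth. Each subject's volume is

$$ v(x) = \mathrm{baseline}(x) + \beta_a \mathrm{age} + \beta_s
  \mathrm{sex} + \beta_e \mathrm{edu} + \beta_f \mathrm{field} -
  \mathrm{severity} \cdot \mathbf{1}[x \in \text{atrophy region}] +
  \varepsilon(x), $$

clipped to $[0,1]$, with $\varepsilon \sim N(0, \sigma_v^2)$ i.i.d. across
voxels by default (an optional Gaussian smoothing flag induces spatial
correlation). The baseline map is a smooth radial profile spanning
0.3–0.7 so clipping is negligible at realistic noise (tested: < 1% of
in-mask values at $\sigma_v \le 0.05$). Defaults, all configurable:

| parameter | default | unit | rationale |
|---|---|---|---|
| grid | 24×24×24, ellipsoidal mask | voxels | desk-scale stand-in for ~256³ clinical grids |
| age | N(73, 7²) truncated to [55, 90] | years | elderly memory-clinic cohort |
| sex, field strength | Bernoulli(0.5) | — | balanced |
| education | N(16, 2²) | years | typical research cohort |
| APOE carrier rate | 27.3 / 49.3 / 66.7 by NC/MCI/AD | % | published per-diagnosis prevalences |
| confound slopes | age −0.002, sex −0.01, edu +0.001, field +0.005 | GM density per unit | small relative to baseline, recoverable |
| voxel noise σ | 0.02 | GM density | ~5% of baseline range |
| ADAS visit noise σ | 2 | points | test–retest scale |
| visits | months 0, 12, 24, 36 | — | standard follow-up schedule |

ADAS trajectories are linear per subject (slope drawn per subject from the
template's Normal, scores floored at 0); follow-up diagnoses progress one
stage at a time under a per-month conversion hazard. Demographics are drawn
independently of subtype — the joint distribution of age and subtype in
real cohorts (e.g. young early-onset clusters) is deliberately not modeled,
and is configurable instead.

**What passing tests do and do not show.** The generator produces additive,
linearly confounded, regionally coherent atrophy with independent voxel
noise. Real GM maps have spatially correlated noise, registration error,
nonlinear age effects, site effects beyond field strength, and subtypes
that differ in texture rather than region. Recovery results on this
generator validate the *machinery* (the pipeline finds what its model says
should be findable); they are not evidence about recoverability of subtypes
in clinical data.

### Reference study designs

Two frozen configurations back the validation suite and the acceptance
script:

* `example_subtype_config()` — three templates (NC-like, MCI-like,
  AD-like) on a 16³ grid: atrophy balls of radius 3.5 voxels (~180 voxels,
  ~13% of the mask), severity 0.12 = 6× the voxel noise SD, n = 120. The
  planted whole-map L1 separation must dominate the spread that
  confound-fit prediction error adds to within-template distances; smaller
  regions (an early sketch used radius 2.5, ~65 voxels) are *not*
  well-separated in this sense and complete linkage then merges templates
  before finishing them. The frozen geometry recovers the planted labels
  with ARI = 1 across 20 fresh seeds (checked once, before freezing).
* `example_category_config()` — twelve templates, four per diagnosis
  category, n = 240, atrophy balls (radius 2.8) on a symmetric
  non-overlapping lattice. Planted cluster-mean ADAS slopes sit near 0
  (NC), 0.19 (MCI) and 0.5 (AD) points/month with within-category spread
  kept small relative to those gaps, emulating the ordered,
  non-overlapping category intervals reported for elderly memory cohorts.
  Diagnosis mixtures are decisive — (0.85, 0.15, 0), (0.1, 0.85, 0.05),
  (0.02, 0.18, 0.8) — so each cluster's average diagnosis lies more than
  3σ inside its band at the design cluster size of ~20; with fuzzier
  mixtures a cluster occasionally straddles a band boundary, which is a
  genuine behavior of the categorization rule but not the regime this
  fixture is meant to probe.

## Numerical and degenerate-input choices

* Distances and linkage in double precision; no subsampling or
  approximation (an $n^2$ matrix is cheap at cohort scale).
* Tie-breaks as above; exact floating-point equality defines a tie (the
  Lance–Williams update takes maxima of the same doubles the definition
  does, so implementation and oracle see identical ties).
* Empty masks, mismatched grids, missing covariates, rank-deficient
  designs, overlapping t-map groups, out-of-range cuts and empty clusters
  all raise immediate errors naming the offender.
* `adjusted_rand_index()` returns 1 (not NaN) when both partitions are
  degenerate and identical (all singletons or a single cluster), where the
  chance-correction denominator vanishes.
* The triangle-inequality assertion is $O(n^3)$ and is skipped by
  `run_pipeline()` above 500 subjects; the other axioms are always checked.

## Validation problem sizes

The suite validates recovery at the sizes the reference designs state:
confound recovery on n = 200 controls over a 24³ grid (~7,000 masked
voxels, all five coefficients within 3 SE of truth at ≥ 95% of voxels),
subtype recovery at n = 120 (ARI ≥ 0.9 required, = 1 observed), category
CI ordering at n = 240 / 12 clusters, t-map calibration on 40 subjects
over a 32³ grid (~11,300 masked voxels, null |t|>3 rate within 3 binomial
SEs of the analytic tail), and byte-level reproducibility of a full run at
n = 60. These sizes were chosen as the smallest at which the respective
statistical claims are comfortably testable.

## Known limitations

* Complete linkage is sensitive to outlier subjects (they inflate cluster
  diameters and can delay or distort merges); the non-reportable flag
  absorbs the resulting singletons/doubletons rather than hiding them.
* The L1 whole-brain distance weights regions by voxel count: cortical
  atrophy moves distances more than hippocampal atrophy of equal severity
  simply because the cortex has more voxels.
* The FDR estimate is a conservative plug-in, not an error-controlling
  procedure under dependence.
* No nonlinear confounds, no site harmonization, no intracranial-volume
  correction, no segmentation/registration: the package consumes
  already-preprocessed, co-registered GM density maps.
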