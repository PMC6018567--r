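---
title: "Iterative voxel-based lesion-deficit mapping: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative voxel-based lesion-deficit mapping: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `iterlesion`, the
choices that were genuinely open when the package was designed and how they
were resolved, the design of the synthetic-cohort generator, and what the
package's tests do and do not establish about real data.

## The mass-univariate model

Each patient contributes a 3D lesion image on a shared grid — either a
*fuzzy* map of structural abnormality in $[0,1]$ or its binarized
counterpart (voxel lesioned iff fuzzy value $> 0.3$, strict inequality) —
and six behavioural T-scores. At every voxel $v$ in the analysis mask the
package fits, by ordinary least squares,

$$y_v = X\beta + \varepsilon,$$

where $y_v$ is the vector of lesion values across patients and the design
$X$ has seven columns in fixed order: the composite naming score (mean of
spoken and written picture naming — the regressor of interest), four
nuisance task scores (nonword repetition, semantic associations, spoken
word comprehension, writing copy), lesion volume in cm³, and an intercept.
Predictors are mean-centered by default; centering only relocates the
intercept and leaves every contrast t unchanged. The test statistic is
$t_v = c^\top\hat\beta / \widehat{se}(c^\top\hat\beta)$ with
$c = (-1, 0, \dots, 0)$ and $df = n - \operatorname{rank}(X)$: one-sided in
the damage-impairs direction, so a positive $t$ means more abnormality
accompanies worse naming. Z-equivalents for reporting are
$z = \Phi^{-1}(1 - p_{unc})$, computed on the log scale so extreme p-values
keep precision.

The analysis mask is always derived from *binary* lesion indicators — a
voxel enters the search volume iff at least `min_overlap = 5` patients are
lesioned there — even when the regression itself uses fuzzy values. Voxels
damaged in fewer than five patients cannot support a stable estimate and
would only pay multiple-comparisons cost.

Why regress the lesion on behaviour rather than the reverse? With the
behavioural scores in the design, a *single* model per voxel factors out
speech production, semantics, comprehension, motor writing and lesion size
simultaneously, and the composite's partial slope isolates word retrieval.
The t-statistic is symmetric in the two formulations given the same
conditioning set, so no information is lost.

### Assumptions

* All images share one grid and affine; assembly rejects mismatches rather
  than resampling (resampling would silently change damage fractions).
* Scores are complete: no imputation is attempted, a missing score is an
  error. The behavioural model has no principled fill-in value.
* The OLS noise model is only a working model for bounded lesion values;
  inference never relies on it (next section).

## Permutation inference

Parametric p-values are untrustworthy here: the response is bounded,
zero-inflated and spatially structured, so the uncorrected parametric
$p_{unc}$ is reported for reference only. All significance decisions use
the permutation distribution of the **maximum** statistic over the mask
(maxT), which controls family-wise error exactly under exchangeability and
adapts automatically to the spatial correlation of lesion data.

Permutation follows the Freedman–Lane scheme: the nuisance-only model
$y = Z\gamma + e$ (all design columns with zero contrast weight, including
the intercept) is fitted, its residuals are row-permuted, and the full
model is refitted on the permuted residuals. The classical scheme adds
$Z\hat\gamma$ back before refitting; the package omits this because the
full-model contrast t is algebraically invariant to adding any vector in
the column span of $Z$ — the identity permutation therefore reproduces the
observed statistic exactly, a property the tests assert.

Corrected p-values are exceedance ranks:
$p_{fwe}(v) = (1 + \#\{\max T^{(b)} \ge t_v\})/(B+1)$ for $B$ Monte-Carlo
permutations, guaranteeing $p > 0$. When the number of distinct
permutations is at most `n_perm` (in practice $n \le 8$ at the default
5000), all $n!$ permutations are enumerated and $p = \#\{\cdot\}/n!$ is
exact; the tests compare this against an independent enumeration oracle.
Cluster-level inference shares the *same* permutation stream: per
permutation the maximum supra-threshold cluster extent is recorded
(forming threshold $p < 0.001$ uncorrected one-sided, i.e.
$t > t_{0.999,df}$), giving corrected p-values for observed cluster sizes.

Numerical conventions:

* **Ties.** A permutation statistic equal to the observed one counts as an
  exceedance, with equality assessed at a $10^{-8}$ relative tolerance.
  Structural ties are real — a permutation can reproduce the observed
  statistic exactly — and two floating-point paths to the same value must
  not flip the count.
* **Degenerate voxels.** Zero residual variance with a nonzero contrast
  estimate yields $t = \pm\infty$ (p of 0 or 1); the fully constant $0/0$
  case yields $t = 0$ (no evidence either way). Both are counted and
  reported via a message rather than an error: in-mask voxels are nearly
  never constant, but permuted refits can be.
* **Connectivity.** Clusters use 26-neighbourhood connectivity by default
  (configurable to 6 or 18), the common choice for volumetric cluster
  inference; components are found on the voxel adjacency graph and verified
  in tests against a breadth-first-search oracle.

## The iterative procedure

`iterative_mapping()` loops: run one full analysis; extract significant
regions (voxel-level rule by default: connected components of voxels with
$p_{fwe} \le 0.05$; a cluster-level rule is available because the reference
procedure does not pin down which set defined the exclusion regions);
exclude every patient whose damage fraction *strictly exceeds*
`exclusion_fraction = 0.25` on **any** region found in **any** iteration so
far (fractions of exactly 0.25 are retained — the boundary convention
matches the "0–25% damage" description of the retained subsample); repeat.
Damage fractions use the configured image kind: lesioned proportion of the
region for binary images, mean abnormality for fuzzy — the continuous
analogue, chosen because the reference procedure ran separate fuzzy and
binary pipelines without stating the fuzzy rule.

Regions accumulate across iterations because the reference procedure's
third pass excluded damage to the regions of *both* previous analyses; a
patient who slips past iteration 1 but damages its regions above threshold
can therefore never re-enter later analyses.

Stopping: the loop ends when an analysis finds no significant voxels, when
the mask is empty, when the cohort would fall below `min_cohort_size = 30`,
or when significant regions exist but nobody exceeds the exclusion fraction
(without this fourth reason the loop would re-run an identical analysis
forever). The floor exists because the procedure as described stops only on
non-significance, but permutation inference on a handful of patients is
vacuous; 30 keeps the smallest analysis meaningful while letting the
simulated traces reach a third iteration.

Reproducibility: every iteration draws an independent child seed from the
master seed, so a trace is bit-reproducible, and permutation streams do not
repeat across iterations.

## Post-hoc analyses

* **Five-way grouping** by damage to two regions: Group 1 ($\ge 75\%$
  frontal-slot, $\le 25\%$ temporal-slot), Group 2 (the converse), Group 3
  (both $\ge 75\%$), Group 5 (both $\le 25\%$), and Group 4 defined as the
  complement of the other four. The complement definition is deliberate:
  enumerating "26–74%" bands literally leaves fraction combinations
  unassigned, while the complement provably partitions every cohort.
* **Incidence tables** report integer-rounded percentages; comparisons use
  Pearson $\chi^2$ *without* continuity correction — the convention that
  reproduces the reference worked examples (13.95, 23.3, 81.4) exactly,
  which Yates-corrected values do not.
* **Severity ANCOVA**: `lm(composite ~ volume + group)` with the group F
  from the sequential ANOVA (group entered after volume), and all pairwise
  group differences tested from the coefficient covariance with Bonferroni
  multiplication by the number of pairs.
* **Power maps**: a voxel lesioned in $k$ of $n$ patients is "powered" iff
  the best-case two-sample pooled t — obtained by assigning the $k$ lowest
  observed composite scores to the lesioned group, which provably maximizes
  the statistic over all assignments — reaches the corrected critical
  value. This is an operationalisation built for this package; it is
  documented behaviour, not a re-implementation of any external tool.
* **Smallest-lesion reports**: among impaired patients with more than 25%
  damage to a region, the minimum lesion volume and whether that lesion
  extends beyond the region — probing whether focal damage is ever actually
  observed.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts whose statistical structure contains
exactly the phenomenon the iterative procedure exists to fix; it is the
package's test bed, not an anatomical simulation.

**Geometry.** A $32^3$ grid of 2 mm voxels carries three disjoint
ground-truth regions: two $8^3$ "cortical" boxes T (posterior) and F
(anterior) and one $4^3$ "deep" box P between them. Lesions are ellipsoids
with jittered centres, log-normal radii and mild (10%) anisotropy; fuzzy
values are $\operatorname{logistic}(-d/w)$ of the signed distance $d$ to
the ellipsoid surface with border width $w = 1$ voxel — a gradual rather
than categorical lesion border, as automated lesion identification
produces.

**Territories.** Each patient draws one of four lesion classes:
posterior (weight 0.30, centred on T), anterior (0.30, centred on F),
deep (0.15, centred on P, small radii — rarely reaching T or F), and large
(0.25, radii spanning all three regions). The large class is what couples
deep damage to cortical damage in the pooled cohort: deep-region damage
*without* cortical damage occurs in only $\sim$9% of patients, so the
pooled analysis sees the deep region's effect mostly in patients whose
cortical damage already explains their deficit.

**Behaviour.** The latent deficit is the OR rule $D = 1$ iff any true
region's binary damage fraction exceeds $\theta = 0.5$. Both naming scores
are $70 - 12\,D - 0.002\,n_{vox} + \mathcal N(0, 3^2)$; the four nuisance
scores couple mildly to the region each nominally probes (e.g. repetition
to the F fraction at $-3$) plus noise. Scores are not truncated to
$[0,100]$: T-scores are unbounded in principle. Null cohorts keep the
identical lesion model but draw every score as baseline plus noise,
independent of the lesions.

**Calibration.** The free parameters (radius distributions, centre jitter,
the volume slope of $0.002$ per lesioned voxel, nuisance couplings) were
set once against structural targets: pooled deficit-of-interest incidence
of roughly a third of the cohort, deep-only damage in 5–15% of patients,
deep draws damaging P in about half of cases, and — the point of the
design — a pooled analysis whose deep-region association falls short of the
corrected threshold while the cortical associations exceed it. Two
sensitivities discovered during design are worth recording: (i) nuisance
tasks must couple only weakly to the critical regions, because a nuisance
regressor strongly coupled to a region's damage absorbs that region's
composite association — with strong couplings the cortical regions
disappear before the deep one does; (ii) the deep class must cause the
deficit unreliably (small, jittered lesions), because a deep class that
always produces the deficit makes the deep region the *strongest* voxelwise
association rather than a masked one. Real cohorts show the same asymmetry:
deep lesion-deficit couplings reported in the reference setting are weak
(3 impaired of 13 deep-damaged patients).

**What the generator does not emulate**: anatomy (no vascular atlas, no
white matter), registration error, scanner effects, lesion-identification
artefacts, score floors/ceilings, or missing data. Passing tests on this
generator therefore demonstrate the *statistical* behaviour of the
procedure — calibrated false positives, recovery of OR-masked regions —
not performance on any particular clinical dataset.

## Problem sizes used by the tests

Unit tests run on grids up to $7^3$ with $n \le 12$ and enumerate
permutations exhaustively where exactness is asserted ($n = 5$, 120
permutations). The end-to-end checks use the sizes the package treats as
its standard desk-scale study: the recovery demonstration on the default
cohort ($n = 300$, 500 permutations per iteration), and the null
calibration over 50 replicates ($n = 150$, 250 permutations each) — with
250 permutations the finest attainable corrected p is $1/251 \approx
0.004$, ample resolution for a 0.05 threshold. The full suite completes in
a few minutes on one CPU.

## Known limitations

* Exchangeability is assumed across patients; there is no block or
  covariate-restricted permutation.
* The procedure inherits mass-univariate blind spots it does not try to
  fix: effects driven by small patient subsets, significant regions smaller
  than any causative lesion, and AND-structured causes (two regions jointly
  required) remain invisible; multivariate modelling is out of scope.
* The voxel-level ROI rule with maxT correction is conservative for broad,
  weak effects; the cluster-level rule trades localisation power the other
  way.
* Damage fractions for fuzzy images use mean abnormality; a thresholded
  count is defensible too and can be had by binarizing the cohort before
  exclusion.
* With Monte-Carlo permutations, corrected p-values carry sampling noise of
  order $1/\sqrt{B}$; exact enumeration is automatic only for tiny $n$.
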