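---
title: "Methods: multimodal cortical structure analysis with cortexpls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal cortical structure analysis with cortexpls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexpls)
```

# What the package models

`cortexpls` analyses three structural brain metrics — cortical thickness
(CT, mm), surface area (SA, mm²), and quantitative T1 relaxation time
(T1, ms) — measured in 76 cortical AAL regions (38 per hemisphere), in
cohorts of adolescents grouped as cisgender boys (CB), gender-dysphoric
adolescents assigned female at birth (GD), and cisgender girls (CG).
Alongside the brain data it scores two psychosexual instruments and ties
everything together with mean-centered Task and Behavior partial least
squares (PLS).

The package starts from *tabular* data: a participant table and a wide
ROI table (and, optionally, per-region voxel samples for the T1 stage).
Image acquisition, registration, segmentation, and surface extraction are
upstream of this package and out of its scope; gray-matter probabilities
are consumed as given.

# Psychosexual scoring

Questionnaire scale scores are item means, computed only when a
respondent answered at least 75% of a scale's items (`scale_mean()`; the
rule is inclusive, so 6 of 8 items qualifies). Internal consistency is
Cronbach's α.

The two EROS subscale means — androphilia $a$ and gynephilia $g$, each in
$[1, 5]$ — are treated as a vector in the plane. Its length and angle
summarise two distinct aspects of sexual orientation:

$$\text{strength} = \sqrt{a^2 + g^2}, \qquad
  \theta = \arccos\!\left(\frac{a}{\sqrt{a^2+g^2}}\right)\cdot\frac{180}{\pi}.$$

Strength ranges over $[\sqrt 2, \sqrt{50}] \approx [1.41, 7.07]$. The
phase θ ranges over $[11.31°, 78.69°]$: 45° means equal attraction (or
none), smaller angles mean androphilic preference, larger gynephilic,
symmetric ±34° (after rounding to whole degrees) around 45°. Phase is
stored at full precision; 11°/79° are display roundings. The GIDYQ-AA
"caseness" flag is inclusive at a mean score of ≤ 3.00.

# Quantitative T1 stages

**Forward model.** The spoiled gradient-recalled echo (SPGR) signal at
flip angle α, repetition time TR, and B1 factor $b_1$ (true/nominal angle
ratio) is

$$S = M_0 \sin(b_1\alpha)\,\frac{1 - E_1}{1 - E_1\cos(b_1\alpha)},
  \qquad E_1 = e^{-TR/T_1}.$$

**Two-point variable flip angle fit.** With exactly two acquisitions
(nominal 3° and 14°, TR = 10.6 ms) the linearisation
$y = S/\sin(b_1\alpha)$ vs $x = S/\tan(b_1\alpha)$ makes $E_1$ the exact
two-point slope and $T_1 = -TR/\ln E_1$. No least squares is involved —
two points determine the line — and an implied $E_1 \notin (0,1)$ flags a
non-physical voxel as `NA` rather than erroring over an array.

**B1 by the method of slopes.** Near the 180° signal null the SPGR
signal falls approximately linearly in flip angle, so extrapolating the
line through the two calibration signals (nominal 130° and 150°,
TR ≈ 55 ms) to zero signal locates the nominal angle α₀ at which the true
angle is 180°, giving $b_1 = 180/\alpha_0$. The linearisation carries a
small bias (the signal is not exactly linear); the test suite bounds it
at under 3% against a root-finding oracle on the full signal model. More
elaborate calibration refinements are deliberately out of scope.

**Regional T1 mode.** Regional gray-matter T1 distributions are
generally unimodal but positively skewed (gray-matter/CSF partial
volumes) and sometimes carry a low-T1 white-matter shoulder, so the mode
— not the mean — represents a region. `roi_t1_mode()`:

1. keeps voxels with gray-matter probability strictly greater than 0.40;
2. clips T1 inclusively to the 500–5000 ms window and bins at 30 ms with
   the left edge fixed at 500 ms;
3. fits a smoothing spline to the (bin center, √count) pairs, smoothing
   chosen by generalized cross-validation, falling back to cubic
   interpolation when fewer than 8 bins span the occupied range;
4. reports the argmax of the fitted curve on a 1 ms grid, ties broken
   toward lower T1.

Two numerical choices deserve comment. The spline is fit over the
*occupied* bin span only, because the long empty tails of a 500–5000 ms
window carry no shape information and drag a GCV smoother toward a flat
line. And the counts enter through a square-root transform: bin counts
are Poisson-like, so their variance grows with the mean, while GCV
assumes homoscedastic noise; the transform restores that assumption and,
being monotone, cannot move the argmax of the underlying shape. In
repeated 20,000-voxel simulations this choice keeps the maximum mode
error well inside one bin width, where a raw-count fit occasionally
exceeds it. Fewer than 50 retained voxels (configurable) marks the region
missing with a reason instead of producing a meaningless spline.

# Partial least squares

All brain columns are first z-scored across participants
(`zscore_columns()`, n−1 denominator), putting CT, SA and T1 on one scale.

**Task PLS.** Let $M$ be the groups × columns matrix of group means of
the z-scored data and $M_c$ its column-centered version. The SVD
$M_c = V\,\mathrm{diag}(s)\,U^\top$ yields latent variables: group
contrasts $v$, brain saliences $u$, strengths $s$. Covariance explained
by LV $i$ is $s_i^2/\sum_j s_j^2$; brain scores are $Z u$. Centering
removes the *unweighted* mean of group means by default — the classical
mean-centered variant, appropriate when group sizes are near-equal — with
a participant-weighted option as a switch.

**Behavior PLS.** For each group, each behavior (attraction strength,
phase, age) is Pearson-correlated with every brain column; the group
blocks are stacked group-major and the stack decomposed by SVD.
Correlations are computed on raw behavior values against the globally
z-scored brain columns — correlation is scale-invariant, so no extra
within-group normalisation is imposed. For reporting, the correlations of
brain scores with each behavior within each group are also computed;
these reflect the observed contrast.

**Sign convention.** SVD signs are arbitrary, so each LV is flipped so
that the largest-magnitude element of $v$ is positive. This makes
repeated runs and tests deterministic; interpretation is unchanged.

**Permutation test.** Under the null, participants are reassigned to
groups (Task) or the behavior rows are permuted against the brain rows
with groups fixed (Behavior); the cross-block construction and SVD are
recomputed in full. The p-value of LV $i$ is the fraction of permutations
whose $i$-th singular value meets or exceeds the observed one —
position-wise, with no rotation and no add-one smoothing, so a
never-exceeded LV reports p = 0. The reference analysis size is 1000
permutations.

**Bootstrap stability.** Participants are resampled with replacement
*within group*. Each replicate's SVD is aligned to the original by an
orthogonal Procrustes rotation of $v$ (with three or more latent
variables, replicate axes rotate, and a bare sign-flip alignment inflates
standard errors), and the rotation is applied to the scaled saliences
$u\,\mathrm{diag}(s)$. A column's bootstrap ratio is its observed scaled
salience over the standard deviation of the aligned replicate values;
|ratio| ≥ 3 (≈ a z-score) marks the column stable. 95% percentile
confidence intervals are formed for the contrast-level quantities: group
mean brain scores (Task) and per-group brain-score/behavior correlations
(Behavior). Behavior replicates that produce a zero within-group variance
are redrawn and counted. A single integer seed drives a distinct
substream for each resampling stage.

# Univariate battery

Group descriptives pass through the classical one-way ANOVA, with
Levene's test (mean-centered — the convention of the common commercial
implementations) deciding heterogeneity at 0.05. When Levene fires, the
Welch and Brown–Forsythe robust tests are reported and post hoc pairwise
comparisons switch from Fisher's LSD (pooled MSE, N−k df) to
Games–Howell (per-pair variances, Welch–Satterthwaite df, studentized
range p-values). Pearson correlation tables are produced overall and
within groups, and Benjamini–Hochberg is the default multiplicity
correction for screening-style correlation tables (Bonferroni-style
usage remains possible by adjusting externally; BH is the least-assuming
default where no method is mandated).

One practical note encoded in the tests: statistics that weight by
within-group *variances* (Welch, Brown–Forsythe, Games–Howell standard
errors) are sensitive to rounding of the inputs — reconstructing a
cohort from group moments printed at two decimals reproduces an F of
several hundred only to about 2%.

# The synthetic cohort generator

`simulate_cohort()` exists so every pipeline stage — scoring, z-scoring,
both PLS analyses, and their inference — can be exercised end-to-end on
data with known ground truth. Its defaults describe the cohort the
analyses are designed around:

* group sizes 14 (CB) / 16 (GD) / 17 (CG), ages uniform over 144–215
  months;
* per-group EROS phase moments (64.60°, 9.29) / (46.38°, 15.23) /
  (30.94°, 13.18) and strength moments (3.25, 1.28) / (3.00, 1.30) /
  (2.83, 0.76), drawn as (phase, strength) pairs and inverted to raw
  scores $a = m\cos\theta$, $g = m\sin\theta$ with redraw on range
  violation — redraw, not clipping, so the marginals carry no boundary
  atoms that would distort variance-test calibration. The inversion
  truncates the joint distribution (a high-phase draw needs enough
  magnitude to keep $a \ge 1$), which pulls realized group phase means a
  few degrees toward 45°; the generator refuses configurations whose
  rejection rate exceeds 20%;
* GIDYQ-AA scores from truncated normals at (4.91, 0.12) / (2.21, 0.35) /
  (4.90, 0.15), keeping cisgender participants above the 3.00 caseness
  threshold and GD participants at or below 3.04;
* a standardized +0.8 shift on 20 designated SA columns and +0.5 on 5 CT
  columns in CB rows (the planted sex-assigned-at-birth difference);
* 33 designated T1 columns generated, within CB and GD rows only, as
  $\rho z_{\text{age}} + \rho z_{\text{phase}} + \sqrt{1-2\rho^2}\,
  \varepsilon$ with ρ = −0.5, where the $z$'s are Gaussian-copula scores
  of the group's realized age and phase — hitting the target correlations
  without distorting marginals; CG rows stay pure noise.

A truth record lists the planted columns and parameters; the same seed
reproduces the dataset bit for bit.

**What the generator does not emulate.** ROI columns are independent
apart from the planted structure — real cortical metrics are spatially
correlated, left/right homologues strongly so — and all noise is
Gaussian. Passing recovery tests therefore demonstrate that the
machinery finds the structure it is pointed at, not that real cohorts of
this size yield comparable stability.

# What the recovery experiments show — and their limits

The test suite includes a 50-seed recovery experiment (500 permutations
and 500 bootstrap replicates per seed; sizes chosen to keep a full run
on one CPU within a few minutes). Two quantitative lessons from it are
worth recording, because they are properties of the method at these
sample sizes rather than implementation artifacts:

* **Per-column stability demands large effects.** A planted column's
  bootstrap ratio behaves like the t-statistic of its group contrast, on
  the order of $d \times 3$ for a standardized shift $d$ at these group
  sizes — about 2.3 for $d = 0.8$. The ±3 threshold therefore marks only
  a minority of columns carrying a 0.8-SD effect as stable, even when the
  latent variable itself is unambiguous (the CB-vs-{GD, CG} contrast with
  a significant permutation test is recovered in essentially every
  seed). Region-level stability at |BSR| ≥ 3 with 14–17 participants per
  group implies underlying effects well above one standard deviation.
* **Null groups inherit optimism in Behavior PLS.** The first latent
  variable maximises cross-block covariance over *all* group-by-behavior
  rows, including those of a group with no true correlations. At these
  dimensions a null group's correlation rows carry as much Frobenius
  mass as the planted rows, so the LV partially aligns with the null
  group's sampling noise, its observed brain-score correlations are
  biased away from zero, and the within-group bootstrap — which re-fits
  each replicate — reproduces the bias. Percentile intervals for a null
  group's correlations therefore exclude zero far more often than the
  nominal 5%. Interpreting "no stable correlation in group X" from such
  intervals deserves caution at this scale.

# Degenerate inputs and numerical tolerances

Zero-variance brain columns stop z-scoring with the column named;
all-constant ANOVAs error; a constant variable in a correlation table
yields a missing entry with a reason rather than an error. SVD
reconstruction is verified to 1e-8, covariance fractions sum to one to
1e-10, and the noiseless VFA round trip holds to 1e-6 relative. Bootstrap
replicates with degenerate within-group behavior variance are redrawn and
the count reported.

# Reproducing archived cohort results

`run_full()` is also the reproduction path for an archived cohort: it
accepts the participant and ROI tables as files, adapts foreign column
headers through a user-supplied mapping file
(`read_roi_matrix(header_map=)`) rather than code edits, and emits
summary tables plus a manifest (all switches, seed, versions) from which
a run can be regenerated bit-identically. The pipeline never fetches
data itself; archived inputs are downloaded manually and treated as
read-only.
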