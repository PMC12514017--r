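---
title: "Methods: linking sex differences in cortical atrophy to regional gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking sex differences in cortical atrophy to regional gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

In prodromal synucleinopathies, cortical thinning is markedly less
widespread in female than in male patients despite similar age and clinical
severity. `protectomap` implements the analysis chain that asks *which
genes' regional expression patterns track this apparent female protection*:

1. parcellated cortical thickness from a multi-site cohort is harmonized
   across scanners (ComBat);
2. each patient's regional thickness is converted to a **W-score** — the
   standardized deviation from the value a control-fitted regression on age
   and sex predicts;
3. a per-region **sex-interaction beta** is estimated among patients
   (female indicator, male = 0 / female = 1), so positive beta = females
   less atrophied than males;
4. the beta map is related to a regions-by-genes expression matrix by
   **partial least squares (PLS)**, with component significance from
   spatial-autocorrelation-preserving **spin permutations** and per-gene
   **bootstrap ratios**;
5. ratio-ranked genes feed a preranked **gene-set enrichment analysis**
   (permutation NES/FDR, weighted set-cover redundancy reduction);
6. candidate genes are checked for **brain-vs-peripheral expression** in a
   genes-by-tissues TPM table via a median-split overexpression call.

The original study's MRI and donor microarray data are access-restricted,
so a synthetic-data module generates every input with the statistical
structure the analysis assumes, and the whole chain is validated on planted
ground truth.

# Site harmonization (ComBat)

Per region, thickness is standardized using a full-rank design of site
indicators plus protected covariates (group, age, sex); per-site additive
(gamma) and multiplicative (delta) effects are estimated in standardized
units and shrunk by parametric empirical Bayes — a normal prior on gamma,
an inverse-gamma prior on delta, hyperparameters by moments across regions,
solved by fixed-point iteration (relative tolerance 1e-6, at most 500
iterations, gamma updated before delta). Fitting (`combat_fit()`) is
separated from application (`combat_apply()`) so the model can be audited,
dumped to JSON, and re-applied.

Numerical choices worth knowing:

* `delta_hat` uses denominator `n_s` (matching the pooled variance), so a
  single-site fit is an exact identity (gamma* = 0, delta* = 1 to machine
  precision) rather than an `n/(n-1)` near-identity.
* Degenerate hyperpriors (variance of the region-wise estimates below
  1e-12, e.g. one site) skip shrinkage rather than divide by zero.
* Zero-variance regions and rank-deficient designs raise errors naming the
  offender; they are never silently passed through.
* The model is fitted jointly on patients and controls with group, age and
  sex protected. Whether the original analysis fitted jointly or per group
  is not documented; joint fitting is the package's choice and keeps the
  group contrast out of the removed variance.

A caution on effect sizes: removing a *multiplicative* site effect changes
pooled SDs, so Cohen's d computed across sites is not expected to be
invariant under harmonization — the mean difference is. Tests therefore
check d-preservation on shift-only configurations (against a matched
no-site-effect counterfactual) and mean-difference preservation generally.

# W-scores and the sex-interaction map

`fit_normative()` fits, per region, OLS `thickness ~ 1 + age + sex` on
controls only, with residual SD on denominator `n - 3` (three fitted
parameters; the convention is not stated in the source literature).
`compute_wscores()` returns `(observed - predicted) / residual SD`;
negative W = thinner than expected for that age and sex.

`sex_interaction_estimates()` regresses patient W-scores on the female
indicator. The slope *equals* the female-minus-male mean W difference
(asserted to 1e-12 in tests); p-values come from the OLS t-test and
q-values from Benjamini-Hochberg across regions. Sex coding male = 0 /
female = 1 was chosen so a positive beta means female protection.

`regional_atrophy_test()` runs one-sample t-tests of W against 0 per
region (optionally within one sex) with BH-FDR across the tested regions —
correction is applied within the hemisphere/subset being tested, matching
how counts are usually reported per hemisphere.

A property users should expect with large patient samples: the W-score
formalism does not propagate the control model's estimation error, which
acts as a fixed per-region offset of order `1/sqrt(n_controls)` W units.
With hundreds of patients, one-sample tests detect these offsets too, so
the number of significant regions exceeds the planted set. This mirrors the
method's behavior on real data and is visible in the synthetic runs.

# PLS, spin permutations, bootstrap ratios

`pls_fit()` implements univariate-response PLS by iterative deflation
(NIPALS-equivalent): on the deflated matrices, `w_k` is proportional to
`X'y` with unit norm, region scores are `t_k = X w_k`, and the per-component
statistic is the **fraction of outcome variance explained** by regressing
`y` on `t_k` — the quantity the significance rule compares against nulls.
Columns of X are z-scored across regions (required for weights to be
comparable across genes); y is centered; signs are fixed so
`corr(t_k, y) >= 0`. Scores are mutually orthogonal and the fractions sum
to the OLS R-squared of y on the score space (tested against `lm()`).

`spin_permutations()` draws uniform random 3-D rotations (QR of a Gaussian
matrix, determinant +1), rotates the spherical centroids, and reassigns
each original region to the nearest rotated centroid. Duplicates are
allowed; a greedy distance-ordered one-to-one matching is available via
`unique_assign = TRUE` (a Hungarian solver is deliberately not a
dependency). `lv_significance()` refits the model with y permuted by each
spin row and reports the add-one tail
`p = (1 + #{null >= empirical}) / (1 + n_perm)`; p is never exactly zero.

`bootstrap_gene_weights()` resamples regions with replacement (jointly for
X rows and y), refits, aligns each replicate component's sign to the
empirical region scores, and reports `ratio = weight / bootstrap SE`.
Replicates with a constant resampled outcome are redrawn and counted.
Two properties established during validation:

* **Ratios are z-like only under signal.** Under a global null the
  unit-norm constraint on `w` doubles the resampling variance of each
  weight, so null ratios are approximately N(0, sqrt(2)) and
  `P(|ratio| > 3)` is about 3.4%, not the 0.27% a standard normal would
  give. Ratio thresholds should be read as rankings, not exact z cutoffs.
* **Weight recovery is limited by `n/(n+p)`.** The first weight vector is
  `X'y`; with 499 regions and 1000 genes, even a noise-free outcome gives
  `corr(w1, w*) ~ sqrt(n/(n+p)) ~ 0.58` against an arbitrary dense
  generating weight vector, because `X'X` is far from the identity.
  The meaningful recovery statement — tested in the acceptance suite — is
  that the weights obtained from a *noisy* outcome map (signal-to-noise 4)
  match the weights the noise-free map would give (correlation > 0.9; about
  0.997 at the default coupling).

# Preranked enrichment

`gsea_preranked()` uses the weighted Kolmogorov-Smirnov running sum with
weight exponent 1: hits advance by `|score| / sum over hit |score|`, misses
retreat by `1/(N - n_set)`; the ES is the extremum by absolute value (an
exact tie between the two sides resolves positive — ties are possible
because miss decrements are rational). The size filter (default 5-2000,
inclusive) applies to the intersection with the ranked universe. Nulls are
gene-label permutations per term; `NES = ES / mean(|null ES| of matching
sign)`; the permutation p is the add-one tail of `|ES|` over **all** nulls
— a sign-conditional tail chosen by the observed direction would double the
type-I rate, while the |ES| tail is calibrated (verified by simulation) and
keeps the attainable floor at `1/(1 + n_perm)`. BH q-values are computed
separately within the positive and negative NES strata. Score ties are
broken by gene id so ranks are deterministic.

`weighted_set_cover()` greedily selects up to k terms maximizing the
covered-gene objective `f(S) = sum over covered leading-edge genes of the
largest -log10(p) among covering terms` (monotone submodular; ties by raw
marginal coverage, then lexical term id). It is a redundancy-reduction
convention, not a reimplementation of any specific web service.

# Tissue enrichment

A tissue overexpresses a gene when its TPM strictly exceeds the gene's
across-tissue median (even-length medians average the two central order
statistics; ties at the median do not count, so 54 distinct values give
exactly 27 overexpressing tissues, and the call is invariant to monotone
transforms). Two genes are compared by a 2x2 chi-squared on brain vs
non-brain membership among their overexpressing tissues, Yates-corrected by
default; the correction is a flag because published 2x2 statistics mix both
conventions (the demographic sex-distribution statistic matches the
uncorrected formula, while the tissue and MCI statistics match the
corrected one).

# What the synthetic generator emulates — and what it does not

`generate_cohort()` produces thickness as
`baseline(region) + age_slope (age - midpoint) + site_shift + site_scale *
noise + atrophy`, with ages uniform on 55-80 years, sites round-robin, a
male-skewed patient group (294 M / 49 F) and sex-imbalanced controls
(213 M / 131 F), matching the cohort structure of the motivating study.
Default effect magnitudes are the package's calibration choices, not
estimates of real data: atrophy -0.3 mm (male patients) vs -0.1 mm
(female), `noise_sd` 0.25 mm — chosen by power analysis so the female
effect (d = 0.4 at n = 49) sits at the edge of FDR detectability while the
male effect (d = 1.2 at n = 294) is overwhelming, reproducing the reported
qualitative asymmetry (widespread male atrophy, sparse female atrophy).

The planted atrophy patch defaults to the 60 highest region ids, which form
a compact polar cap on the Fibonacci hemisphere. The low-id band was
rejected because it forms a thin annulus at the hemisphere rim: under
hemispheric spin nulls its rotations fold into compact blobs that smooth
gene maps fit *better* than the original annulus, inverting the spin test.
A compact cap is also the realistic stand-in for focal atrophy.

`generate_expression()` builds spatially autocorrelated gene maps
(exponential kernel in angular distance, default scale 0.3 rad) and plants
a 20-gene set tracking the interaction map at correlation 0.8. Donor
microarray bundles add 1-3 probes per gene (one high-fidelity, optional
noisy and background-failing probes), coordinate jitter, and deliberately
unassignable samples. The tissue table plants elevated TPM for chosen genes
in 13 of 54 tissues.

Not emulated: surface meshes, volumetric images, realistic MRI noise
spectra, hemispheric asymmetries, donor-specific expression biology, or
gene-gene co-expression beyond shared spatial smoothness. Passing tests
demonstrate that the *pipeline machinery* recovers planted structure under
the stated conditions; they say nothing about effect sizes in real cohorts.

# Problem sizes and runtimes

Default end-to-end runs use 499 regions, 687 participants, 1000 genes,
1000 spin permutations, 1000 bootstrap replicates, and 50 random gene sets
plus the planted one — sizes chosen so a full run completes in about a
minute and the validation suite (including 50-seed and 100-seed recovery
loops and a 200-replicate spin calibration at 500 permutations) stays
within a quarter hour on one CPU. The function defaults for a production
analysis are 10,000 spins and 5000 bootstrap replicates, as used in the
motivating study; `default_pipeline_config()` documents where the two
differ.

# Known limitations

* W-scores do not propagate control-model uncertainty (see above).
* The spin test assumes region centroids live on a sphere and that
  nearest-neighbour reassignment preserves the map's autocorrelation;
  maps concentrated at the hemisphere rim violate this in spirit (fold-over)
  and should be interpreted cautiously.
* Bootstrap SEs of unit-norm weights are conditional on the observed
  regions; ratios are rankings, not calibrated z-scores.
* BH-FDR is assumed wherever the source methods say only "FDR"; the
  enrichment FDR is BH over permutation p-values, not the sample-based
  GSEA variant.
* The one-vs-rest tissue chi-squared is provided for completeness but has
  no published anchor value.
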