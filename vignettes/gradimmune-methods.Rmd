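---
title: "Models and methods in gradimmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gradimmune}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradimmune)
```

# The problem

Cohorts sampled along an urbanization gradient — rural and urban subjects from
one region plus a Western-European reference cohort — differ systematically in
gut microbiome composition, in ex vivo cytokine responses of whole blood, and
in circulating plasma metabolites. gradimmune implements the statistical
machinery to connect these three layers:

1. a **gradient screen** for species whose relative abundance changes
   monotonically across the three cohorts,
2. a **pooled log-linear model** linking each microbe's abundance to cytokine
   responses, with a positive/negative/neutral classification of
   immunomodulatory species,
3. a **pathway copy-number enrichment model** asking which metabolic pathways
   are over- or under-encoded in immunomodulatory genomes,
4. **metabolome integration**: species-metabolite and metabolite-cytokine
   Spearman screens with FDR control, pathway-level tallies, and k-means
   clustering of metabolite peaks with the cluster count chosen by adjusted
   Rand index (ARI) against molecular-class labels, and
5. **compositional statistics**: Jensen-Shannon divergence (JSD) distances, a
   deterministic merge-height rule for the cluster count, one-factor
   PERMANOVA, and metadata association screens.

Every stage runs end-to-end on seeded synthetic cohorts with planted ground
truth, so each estimator can be scored against the parameters that generated
its input.

# The double-Wilcoxon gradient screen

For an ordering of the three groups (e.g. rural → urban → external, "RUN"),
each species is tested with two two-sided Wilcoxon rank-sum tests on the
consecutive group pairs. The combined p-value is the **larger** of the two —
a species only counts as changing along the gradient if *both* steps move —
and a direction is assigned only when both pairwise shifts share a sign;
otherwise the species is flagged inconsistent and counted as non-significant.
Species detected (abundance > 0) in at most 20% of samples are excluded before
testing (strict `prevalence > 0.20`). Benjamini-Hochberg correction is applied
to the combined p-values within each ordering separately, because the
per-ordering significant counts are the screen's readout. Two-sided tests with
a post-hoc consistency flag were chosen over one-sided tests: they are
agnostic about each species' direction while preserving the "simultaneous
change" semantics.

# The pooled cytokine model

Concentrations (pg/mL) of five cytokines after stimulation with nine microbial
stimuli (a tenth, the viral TLR3 ligand Poly:IC, is excluded because its
responses do not correlate with the rest of the panel) are pooled into one
model per microbe $m$:

$$\log y_{c,s,i} = \beta_0 + \beta_{c,s} + \beta_a\,\mathrm{age}_i +
  \beta_s\,\mathrm{sex}_i + \beta_m\,\mathrm{mic}_{m,i} + \varepsilon_{c,s,i}$$

where $\beta_{c,s}$ is a full cytokine-by-stimulus interaction (one reference
level absorbed by the intercept), sex is coded female = 0 / male = 1, and
$\mathrm{mic}_{m,i}$ is the species' relative abundance converted to
**zero-anchored ranks**: all zeros map to rank 0 and the nonzero values get
ranks $n_\mathrm{zero}, \dots, n-1$ (mid-ranks for ties), so with 299 subjects
the maximum receives rank 298. All logarithms are natural. The model is fit
once per microbe by ordinary least squares; $\beta_m$ carries a two-sided
t-test. Species are classified *positive*/*negative* when the
Bonferroni-adjusted p (over the number of species passing the prevalence
filter) is below 0.005 and prevalence exceeds 20%, with the sign taken from
$\hat\beta_m$; otherwise *neutral*.

`fit_species_effects()` fits all microbes by QR-factorizing the shared
covariate block once and residualizing each microbe's rank vector against it
(Frisch-Waugh-Lovell); this is algebraically identical to the one-microbe-at-a-
time fit (verified to 1e-10 in the tests) and roughly two orders of magnitude
faster.

## Repeated measures and the subject-clustered diagnostic

The pooled model deliberately treats the ~45 observations of one subject as
independent. That choice is part of the method, but it has a measurable
consequence that the synthetic cohorts expose precisely: any *subject-level*
signal omitted from the model — in a planted cohort, the other
immunomodulatory species; in real data, any latent host factor — acts as
clustered noise. For a subject-level covariate with $J$ observations per
subject, clustered noise of variance $\sigma_c^2$ against observation noise
$s$ inflates the OLS t-statistic's spread by
$\sqrt{(J\sigma_c^2+s)/(\sigma_c^2+s)}$. Under a *global* null
($\sigma_c^2 = 0$, the type-I experiment) the t-tests are exactly calibrated.
But in a cohort with several strong planted effects, the null species'
t-statistics widen, and no effect size escapes the trade-off: making planted
effects stronger inflates the nulls proportionally. Exact sign-correct
recovery with zero false positives under the primary OLS inference therefore
caps well below certainty regardless of the generator's effect size — this is
a property of the method, not a bug in the implementation, and it is the same
inflation visible in the method's real-data p-value distributions.

As a diagnostic, `fit_species_effects(..., se = "cluster")` provides
subject-clustered (CR0 sandwich) standard errors with $G-1$ degrees of
freedom. Coefficients are unchanged; only the inference accounts for the
repeated-measures structure. With clustered inference, the planted
classification experiment recovers all planted signs with rare false
positives. The primary inference remains plain OLS, matching the original
method; the acceptance script reports recovery under both.

# The pathway enrichment model

Species-stratified pathway copy numbers (complete "copies" of a pathway
encoded by one species in one sample, length-normalized) are modeled per
pathway $p$ over all (species, sample) rows with positive copies:

$$\log y_{p,m,i} = \beta_0 + \beta_d \log(\mathrm{reads}_i) +
  \beta_m\,\mathrm{mic}_{m,i} + \beta_e\,\mathrm{eff}_m + \varepsilon_{p,m,i}$$

with $\mathrm{eff}_m$ the microbe's immunomodulatory class (neutral as
reference, so $\beta_e$ splits into a positive-class and a negative-class
dummy) and $\mathrm{mic}_{m,i}$ the **raw relative abundance** (the rank
conversion is specific to the cytokine model). Sequencing depth enters as one
coefficient on the natural log of total reads. Missing classes leave their
coefficient NA rather than failing. Per-dummy two-sided t-tests are reported
with raw-p significance stars (\*p < 0.1, \*\*p < 0.01, \*\*\*p < 0.001); BH
across pathways is available but off by default, since the raw-p stars are the
primary readout.

# Metabolome integration

**Species-metabolome effects.** Every species × peak pair gets a Spearman
correlation over the shared samples; BH runs globally over the full grid (one
significance line for the whole experiment, not per species). A species'
metabolome effect $E_s$ is the maximum absolute correlation, and its
significance is its best pair's adjusted p. Effect distributions of
positive/negative vs neutral species are compared with one-sided
(greater) rank-sum tests.

**Metabolite-cytokine screen.** Spearman per (peak, cytokine × stimulus
response) over the subjects with both measured (pairs with < 3 complete
observations are skipped), BH across all pairs, with per-peak summaries.

**Pathway tallies.** For pathways with at least 10 detected microbial enzymes,
significant metabolite-cytokine correlations among the pathway's peaks are
counted by the sign of rho; separately, pathways with at least 3 peaks
significantly correlated with an immunomodulatory species are flagged.

**Peak clustering.** Peaks are z-scored across samples and clustered by
k-means (peaks as points, 25 seeded restarts per candidate k, best
within-cluster sum of squares kept). The cluster count maximizes
ARI(partition, molecular class), ties broken toward smaller k; each cluster is
annotated with its most prevalent molecular class. The ARI is computed from
the pair-counting formula and cross-checked against an established
implementation in the tests.

# Compositional statistics

JSD between renormalized sample compositions uses natural logs with
$0\log 0 = 0$, giving distances in $[0, \ln 2]$; it is used directly (not its
square root) as the distance, which is configurable. Sample trees use average
linkage (robust for divergence matrices; the linkage is likewise
configurable). The cluster count scans the merge heights from the top: cut at
the first consecutive pair of heights whose ratio drops below 2, i.e.
$k = j+1$ for the smallest $j$ with $h_j/h_{j+1} < 2$, with $k = n$ when no
such step exists. PERMANOVA is computed from distance-based sums of squares
($SS_\mathrm{total} = \sum_{i<j} d_{ij}^2/n$, within-group terms scaled by
group size), with the p-value from full enumeration of label permutations when
$n! \le 10{,}000$ and seeded random permutations (with the +1 convention)
otherwise. Metadata screens send categorical variables to the chi-square test
(Yates correction only for 2×2), ordinal weekly-consumption variables to
Kruskal-Wallis, and convert age to three equal-frequency bins first.

# The synthetic cohort generator

Defaults mirror the study conditions: 70 rural + 253 urban subjects with a
471-subject external cohort; 100 species; five cytokines, nine modeled stimuli
plus the excluded one; 8.23% of cytokine records deleted at random (so a full
5 × 9 × 299 grid of 13,455 possible rows loses about 1,100); ages uniform on
18-65; cytokine responses decreasing with age (-0.02/year) and male sex
(-0.1), consistent with the reported directions.

* **Abundances** are zero-inflated log-normals: per-species Bernoulli
  detection (default probability 0.7) times a log-normal draw around a
  per-species base mean, then per-sample renormalization (closure). Species 1
  is a core commensal detected everywhere so no sample is empty.
* **Gradient species** get monotone group-mean steps of 2.0 on the log scale
  (~7.4-fold per stage — a large, unambiguous shift). Two structural choices
  keep non-planted species honest nulls under closure: planted step signs
  alternate across species, and gradient taxa are assigned low base abundance
  (log-mean -2), mirroring the low-abundance taxa that shift along real
  urbanization gradients. A high-mass planted shift would otherwise dilute
  every other species monotonically — a real compositional effect that the
  screen would correctly, but unhelpfully, flag.
* **Cytokine responses** follow the pooled model's generative form exactly,
  with planted per-rank-unit effects of ±0.004 for 4 positive and 3 negative
  species (matching the effect scale used in the power analysis of the
  per-microbe fit).
* **Metabolites** are exponentiated class-specific latent factors (5 classes)
  plus noise (SD 0.5), so k-means clusters align with molecular classes by
  construction; at zero noise the alignment is exact. Planted
  species-metabolite couplings use a Gaussian copula on Blom normal scores of
  the abundance ranks, which controls the target Spearman correlation to
  within a few hundredths.
* **Pathway copies** follow the enrichment model's generative form with a
  depth coefficient of 0.5, an abundance coefficient of 2, noise SD 0.5, and
  planted class offsets of +0.8/-0.8 on three of the pathways; each pathway is
  encoded by a species subset that always includes planted positive and
  negative species so both contrasts are estimable.

All stages derive independent RNG streams from one master seed with a pinned
generator, so outputs are byte-identical across runs and platforms.

**What the generator does not emulate:** phylogenetic correlation among
species, strain-level variation, realistic cytokine-cytokine correlation
beyond the shared linear predictor, LC-MS artifacts (adducts, isotopes,
batch effects), and fungal taxa. Passing recovery tests therefore demonstrate
correctness of the estimators under the assumed generative structure, not
robustness to everything real data can do.

# Numerical choices

* Rank statistics use mid-ranks for ties throughout.
* The rank-sum p-value is exact (full enumeration) for combined n ≤ 20
  without ties, otherwise a tie-corrected normal approximation with continuity
  correction; fully degenerate inputs (all values identical) return p = 1.
* Spearman p-values use the t approximation (exact permutation enumeration is
  available for n ≤ 8 and used as a test oracle); at the cohort sizes involved
  the two agree to well past the decision thresholds.
* The chi-square test applies the Yates correction to 2×2 tables by default.
* Kruskal-Wallis on all-identical data returns H = 0, p = 1 by convention.
* Least squares is QR-based; rank-deficient designs are flagged and aliased
  coefficients are NA rather than errors.
* Equal-frequency binning resolves ties by stable rank order; bin sizes differ
  by at most one.
* k-means ARI ties break toward smaller k; infeasible k (more centers than
  distinct points) are skipped.

# Problem sizes in the test suite

The recovery and calibration experiments run at the study's cohort sizes
(299-323 modeled subjects, 100-200 species) with seed counts chosen per
experiment: 10 null cohorts × 200 microbes for t-test calibration, 50 seeds
for immunomodulator recovery, 50 planted + 100 null seeds for the gradient
screen, 100 seeds for pathway enrichment, and 20 for the metabolome stage.
Unit tests use miniature cohorts (20/40/60 subjects, 30 species) where only
the algebra, not the power, is at stake.

# Limitations

* The primary cytokine-model inference inherits the original method's
  independence assumption; use the subject-clustered diagnostic when judging
  borderline species.
* BH control for the species-metabolite grid treats the grid's tests as
  sufficiently independent; strongly co-abundant species share best peaks.
* The merge-height rule is deterministic but sensitive to the linkage choice;
  bootstrap consensus clustering is out of scope.
* Compositional closure means "one species up" is indistinguishable from
  "everything else down"; the gradient screen reports what changed in relative
  terms, not absolute loads.
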