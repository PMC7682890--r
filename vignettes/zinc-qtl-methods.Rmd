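---
title: "Methods: mapping natural variation in zinc responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping natural variation in zinc responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zincmap)
```

zincmap reimplements, end to end, the quantitative-genetics analysis used
to dissect natural variation in *C. elegans* zinc responses: processing of
large-particle-sorter phenotype data, broad-sense heritability, linkage
mapping on a recombinant inbred advanced intercross (RIAIL) panel,
expression-mediation analysis, mixed-model genome-wide association (GWA)
on wild isolates, and region-level population genetics. This vignette
explains each model, its assumptions, the tunable parameters, and the
design choices made where the procedure was genuinely open.

## Sorter phenotypes

A large-particle flow sorter reports, per animal, a time-of-flight (TOF,
a length proxy) and an extinction (EXT, an optical-density proxy). Wells
are summarized by four traits: `median.TOF`, `median.EXT`,
`median.norm.EXT` and `norm.n` (animals per well over parents sorted, an
approximate brood size). `median.norm.EXT` is computed as the **median of
per-animal EXT/TOF ratios**, not the ratio of the two medians: the
per-animal ratio is the quantity with biological meaning (density per
unit length), and its median is robust to within-well size spread. The
two definitions differ in general; the choice is fixed here and in the
tests.

Traits then pass through four ordered stages, tracked on the table
itself and enforced at each transition:

1. **Assay regression** (`regress_assay`): traits are replaced by the
   residuals of a fixed-effect model on the assay label, removing
   day-to-day differences among assay runs. With one level this is mean
   centering; single-well levels get residual zero.
2. **Outlier pruning** (`prune_wells`). Two policies, both single-pass
   (bounds computed once from the full group, then applied; no
   re-estimation after removal, which makes the `sd` policy idempotent on
   its output):
   * `sd`, for highly replicated designs: within each
     (condition, strain) group, wells beyond two standard deviations of
     the group mean are removed. The grouping is per strain because the
     group mean is meant to be the strain's own expectation; groups with
     fewer than 3 wells are skipped.
   * `bamf`, for low-replication designs: within each condition, fences
     at `Q1 - 2 IQR` and `Q3 + 2 IQR` (type-7 quantiles, the convention
     of this package's quantile calls throughout), with an escape hatch:
     if at least 5% of the distinct strains have any well outside the
     fences, the spread is treated as genuine strain variation and
     nothing is removed for that trait/condition. The strain-fraction
     exemption is evaluated per trait per condition.
   A well flagged on any trait is dropped as a whole row, so pruning only
   removes rows and never edits values.
3. **Control regression** (`regress_control`): for each trait, the drug
   wells are regressed on their strain's mean control (water) value with
   one joint linear model across all strains; the residuals are the
   drug-response phenotype for everything downstream. This isolates
   differences caused by the treatment from standing differences in the
   control condition.
4. **Unit normalization** (`normalize_unit`): an affine map of the
   residuals to [0, 1], used for presentation-style comparisons only.

`select_dose` picks the treatment concentration by a one-way variance
decomposition at each candidate dose: the dose maximizing the mean (over
the four traits) of between-strain to within-strain mean squares. A dose
with zero within-strain variance is treated as infinitely favorable with
a warning.

## Heritability and strain comparisons

Broad-sense heritability comes from the random-intercept model
`value = mu + strain + e` fit by REML (`lme4::lmer`):
`H2 = sigma2_strain / (sigma2_strain + sigma2_resid)`. The confidence
interval is a nonparametric bootstrap over strains (default 1000
resamples, percentile interval); a strain-level bootstrap respects the
unit of replication, and a required seed makes every interval
reproducible. H2 is invariant to affine transformation of the trait.

Worth knowing: with very few strains the plug-in ratio is biased low.
At the dose-response design of four divergent strains, simulations
planted at H2 = 0.48 average an estimate near 0.42 (the strain variance
carries 3 degrees of freedom); at 50 strains x 10 replicates the mean
estimate is 0.47-0.49. The acceptance script therefore demonstrates
recovery on the many-strain design.

Pairwise strain comparisons use `aov` + `TukeyHSD`, with conventional
stars at 0.05/0.01/0.001/0.0001 and `ns` above 0.05.
Bonferroni-adjusted pairwise t-tests are reported alongside; stars
default to the Tukey adjustment.

## Linkage mapping

Genotypes are a strains-by-markers 0/1 matrix (N2 allele = 0, CB4856
allele = 1) with a physical map. The scan statistic is the
correlation LOD

$$\mathrm{LOD} = \frac{-n \ln(1 - r^2)}{2 \ln 10},$$

with `r` the Pearson correlation between genotype code and phenotype.
This equals the likelihood-ratio LOD of the single-marker linear
regression, `(n/2) log10(RSS0/RSS1)` — the equality is this module's
core oracle and is asserted to 1e-10 on random instances in the tests.
Markers with zero variance score 0; a perfect correlation is capped at
`(n/2) log10(1/1e-12)` with a warning. Missing genotypes use
pairwise-complete correlations.

The genome-wide threshold is by permutation: the phenotype vector is
permuted as a whole against the genotype matrix (preserving marker-marker
linkage), the genome-wide maximum LOD recorded, and the `1 - alpha`
quantile taken (defaults 1000 permutations, alpha 0.05).

`forward_search` iterates: scan, and if the maximum LOD clears the
threshold, add that marker (leftmost on ties) as a cofactor — implemented
as least-squares residualization of the phenotype on the cofactor
genotype columns — and rescan; stop otherwise, with a hard cap of 20
iterations. The threshold is computed once per trait from the
unconditioned phenotype: recomputing it per iteration would control a
different (conditional) error rate per step, while a single threshold
keeps the familiar genome-wide interpretation; with phenotypes
residualized on cofactors the null max-LOD distribution is close to the
unconditioned one.

`annotate_peaks` rescans for each peak with all other peaks as cofactors
and takes, on the peak's chromosome only, the outermost contiguous run of
markers whose conditional LOD stays within 1.5 of the peak (the
`chromosomal` cutoff convention). Per-QTL `variance_explained` is the
squared partial correlation of the peak marker given the other peaks;
the marginal R^2 is reported alongside (the two differ under
multi-QTL conditioning — the partial is the model-based attribution, the
marginal matches a planted marginal variance share), and the joint
additive model's R^2 is attached as the total.

`scan_two` fits, for every marker pair on a thinned grid (default at
most 1000 markers, every k-th), the full model `y ~ gA + gB + gA:gB` and
the additive model `y ~ gA + gB`, each scored against the intercept-only
null as `(n/2) log10(RSS0/RSS)`; the interaction LOD is the difference,
nonnegative because the models are nested. Closed-form sufficient
statistics make the pair sweep feasible without per-pair model objects;
collinear pairs are skipped. The interaction threshold is the 95th
percentile of the permuted genome-wide maximum interaction LOD.
`interaction_anova` is the direct F-test of the `gA:gB` term for two
chosen markers.

## Mediation

For a QTL peak marker `g`, an expression trait `m` and a phenotype `y`,
two linear models — mediator `m ~ g` (slope `a`) and outcome
`y ~ g + m` (slopes: direct effect, and `b`) — give the average causal
mediation effect `ACME = a * b`. With linear models and no
treatment-mediator interaction, `total = ACME + ADE` holds exactly at
the point estimates. Uncertainty is a nonparametric strain bootstrap
(default 1000 resamples): percentile CI and a two-sided sign-based
p-value. `prop_mediated = ACME/total` is clipped to [0, 1] and flagged
`NA` when the total effect is near zero (the ratio is then
uninterpretable). `mediation_screen` runs every probe at the same marker
and flags those above the 95th percentile of the ACME distribution —
by construction about 5% of pure-noise probes get flagged, which is the
intended reading of the cutoff. eQTL discovery for probe selection is
the same `forward_search` applied to expression traits; no separate
machinery.

## Mixed-model GWA

Wild-isolate dosages (homozygous inbred, 0/1) are filtered strictly —
any missing call drops the variant, then minor allele frequency < 5% —
and optionally LD-pruned with a greedy sliding window (defaults: window
50 variants, step 10, r^2 > 0.8 removes the lower-MAF member, rightmost
on ties; the window/step/r^2 are conventional, exposed, and matched
exactly by a brute-force oracle in the tests). Kinship is VanRaden-style
for inbred dosage coding: columns centered at allele frequency,
`A = Z Z' / sum p(1-p)`, so the expected diagonal is 1.

The association model is `y = mu + x b + u + e`, `u ~ N(0, sg^2 K)`,
solved through one eigendecomposition of `K`: REML estimates the
variance ratio on the null model only and reuses it for every marker
(the P3D shortcut — per-marker REML would cost an optimization per
variant for little gain at these panel sizes), and each marker then gets
a rotated GLS Wald t-test reported as `-log10 p`. With `K = I` the scan
reduces exactly to per-marker OLS. A single global kinship is used (no
leave-one-chromosome-out).

Multiple testing uses two thresholds: strict Bonferroni over all
variants, and the more lenient effective-number-of-tests threshold from
eigendecomposition of the variant correlation matrix with the Li & Ji
estimator (each eigenvalue contributes `I(lambda >= 1)` plus its
fractional part; eigenvalues are rounded at 1e-9 so exactly-orthogonal
designs sitting numerically at integer eigenvalues are not undercounted).
Significant variants are padded by 150 variants each side, overlapping
stretches merged, and emitted as regions. A one-way ANOVA
(`variance_explained_by_class`) quantifies how much phenotypic variance
a haplotype class (e.g. functional vs deletion alleles at a locus)
explains.

## Population genetics

Sliding-window Tajima's D uses physical windows (default 10 kb sliding
by 1 kb), left-aligned at the region start and right-truncated at its
end: `D = (pi - S/a1) / sqrt(e1 S + e2 S (S-1))` with the standard
constants from the sample size. Windows with no segregating sites give a
missing D, never 0. Sites with missing calls are excluded.

Neighbor-joining trees are built from Hamming-proportion distances over
shared non-missing sites (for equal-length variant strings this equals
an alignment-based p-distance, so no multiple alignment step is needed),
agglomerated with `ape::nj` and midpoint rooted. NJ can produce slightly
negative internal edges; they are clamped to zero with the deficit
transferred to the sibling edge, preserving the path length through
their parent.

## Synthetic data

Every input class has a seeded generator, so each stage is testable
against known truth with no downloads. All generators are pure functions
of their arguments and a seed.

* `simulate_cross`: chromosome-wise two-state Markov mosaics of parental
  alleles; the adjacent-marker switch rate is the Haldane recombination
  fraction of the map distance scaled by an intercross map-expansion
  factor (default 2). Defaults scale the study down to desk size: 6
  chromosomes, ~1000 markers, 250 strains (vs 13,003 SNPs and 253
  RIAILs), 0.5 Morgans per chromosome.
* `simulate_phenotypes`: additive QTL with effects calibrated so each
  planted marginal variance fraction is met in expectation
  (`beta = sign * sqrt(frac / p(1-p))` on a unit-variance scale).
* `simulate_sorter_records`: lognormal per-animal TOF/EXT around
  strain-and-condition means (strain effects act only in the drug
  condition), multiplicative assay offsets, Poisson animal counts, and
  optional outlier wells shifted by ±1.5 log units with truth labels.
  Under the defaults (noise SD 0.15, ~30 animals/well) the injected
  outliers are far outside the bamf fences, and the pruner recovers them
  with mean sensitivity ~1 and specificity > 0.99 over replicate assays;
  in individual control-condition draws the 5% strain exemption can
  legitimately veto removal, which is the rule working as designed.
* `simulate_expression`: one mediator probe `m = a g + e`, phenotype
  `y = b m + c g + e'`, independent-noise decoys.
* `simulate_wild_panel`: Balding-Nichols subpopulation divergence,
  Bernoulli inbred dosages, a causal haplotype class calibrated to a
  target variance fraction (default 0.115, the *sqst-5* design point),
  and a polygenic background over centered dosages. When a causal class
  is planted the background is orthogonalized against the causal
  genotype — in a structured panel the background lies largely along the
  subpopulation axis, and without orthogonalization the realized class
  fraction would be confounded rather than equal to its specification.
* `simulate_neutral_haplotypes`: Kingman coalescent with
  `Poisson(theta/2 x branch length)` infinite-sites mutations, for
  Tajima's D calibration.

What these generators do **not** emulate: genotyping error, segregation
distortion, selfing-rate variation, linked selection, hyper-divergent
regions where alignment-based statistics degrade, batch structure in
expression data, and contamination in sorter wells. Passing tests
therefore show the estimators are correct under their stated models, not
that real data meet those models.

## Numerical choices and calibrations

* Quantiles are type 7 (linear interpolation) everywhere.
* Tie-breaks: equal max LOD goes to the leftmost marker in map order;
  LD-prune r^2 ties drop the rightmost variant; midpoint-rooting ties
  break by lexicographic leaf order (via the underlying tree tools).
* Degenerate inputs error loudly: constant phenotypes (unit scaling,
  heritability), zero-variance mediators, empty genotype cells,
  non-segregating markers in a cross.
* The neutral mean of Tajima's D is not exactly zero in finite samples:
  at n = 20, theta = 10 it is about -0.09 (a property of the statistic's
  variance normalization). The calibration check that the mean lies
  within 0.1 of zero therefore runs 3000 coalescent replicates
  (Monte-Carlo SE ~0.016) so the estimate is stable rather than a draw
  near the band edge.
* Desk-scale problem sizes used by the tests and the acceptance script:
  null-calibration panels of 250 strains x 1002 markers with 200
  permutations (200 replicates); recovery panels of 250 strains x 504
  markers (50 replicates); mediation screens of 17 probes x 120 strains
  (25 replicates); wild panels of 81 strains x 2000 variants; scantwo on
  a 120-marker grid with 100 permutations.

## Known limitations

* Marker regression only: no hidden-genotype interval mapping or
  imputation between markers, matching the mapping statistic
  reimplemented here.
* The permutation threshold is computed once per trait, not per
  forward-search iteration.
* The quasi-Bayesian mediation variant is not implemented (the interface
  reserves a method flag); bootstrap only.
* The GWA effective-test count depends on the panel and the pruning
  parameters; no attempt is made to reproduce any particular published
  count.
* Wild panels use a single global kinship; no leave-one-chromosome-out.
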