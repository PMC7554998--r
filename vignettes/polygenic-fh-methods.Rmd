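---
title: "Weighted LDL-c gene scores and polygenic FH classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted LDL-c gene scores and polygenic FH classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Familial hypercholesterolemia (FH) is clinically diagnosed by point systems
such as the Dutch Lipid Clinic Network (DLCN) score, but a pathogenic variant
in *LDLR*, *APOB* or *PCSK9* is found in only a minority of clinically
diagnosed patients. One candidate explanation for the mutation-negative
remainder is a *polygenic* burden of common LDL-cholesterol-raising alleles.
`polyfh` implements the analysis that question requires: score a small SNP
panel, ask which SNPs actually separate patients from controls, derive a
"high score" cutoff from a control population, and combine the monogenic and
polygenic yields into a single percentage of patients with an identified
genetic cause.

## The score

For a panel $P$ of SNPs with per-allele effects $\beta_i$ (mmol/L per copy,
signed) and effect-allele dosages $c_i \in \{0,1,2\}$, the weighted gene
score of a sample is

$$\mathrm{wGS} = \sum_{i \in P} c_i \, \beta_i .$$

Three nested panels are built in: `wGS11` (the full 11-SNP assay), `wGS8`
(the association-refined panel plus rs429358 so APOE &epsilon; genotypes stay
representable), and `wGS6` (the classical six-SNP refinement). The two APOE
sites deserve care: rs429358-C defines &epsilon;4 and rs7412-T defines
&epsilon;2, so the package carries rs7412 on its &epsilon;2 allele with a
*negative* beta — an &epsilon;2/&epsilon;2 homozygote with no other risk
alleles scores below zero, which is the behaviour reported for such patients.
Two APOE modes exist because the literature is split: the default
`additive` mode scores both sites like any other SNP; `diplotype` mode
replaces them with a joint &epsilon;-genotype weight
(`default_apoe_diplotype_weights()`), with the double heterozygote phased as
&epsilon;2/&epsilon;4 under the no-recombinant assumption (configurable off
by supplying your own table).

Missing dosages follow the `exclude` policy by default: the sample's score
is `NA` and every downstream denominator drops it. This matches how cohort
denominators shrink in practice when a few samples fail genotyping for one
assay. `renormalize` (scale by panel size over SNPs used) is provided purely
for sensitivity analysis.

**Weights are configuration, not constants.** The shipped
`glgc_weights_synthetic.tsv` is a clearly labelled synthetic approximation of
the published GLGC orientations and magnitudes, good enough for simulation
and testing; for real cohorts, supply the exact published betas via
`read_weights()`.

## The synthetic cohort generator

`simulate_study()` produces the three-group structure the analysis assumes:

* **Controls (`EUR`, default n = 503):** genotypes drawn per SNP as
  Binomial(2, p) — Hardy-Weinberg by construction, so the generator
  satisfies the condition the analysis later tests.
* **Mutation-negative patients (`FH_Mneg`, n = 420):** two mechanisms.
  `frequency-shift` (default) draws HWE genotypes at enriched group-specific
  frequencies from `group_freqs_synthetic.tsv`; those defaults were chosen
  once so the simulated wGS8 case-control mean gap is about 0.10 on a
  within-group SD near 0.2 — i.e. a binormal AUC around 0.65, the
  discrimination scale small LDL-c panels achieve in practice.
  `liability-threshold` draws candidates at *control* frequencies, forms a
  latent LDL-c liability $\mathrm{wGS} + N(0, \sigma_r)$ and keeps the top
  tail (default: top 5%, $\sigma_r = 0.9$ mmol/L, a plausible residual SD
  for LDL-c), so enrichment emerges from selection rather than being
  hard-coded — this is the mode that tests whether the pipeline *detects*
  enrichment it was not handed.
* **Mutation-positive patients (`FH_Mpos`, n = 250):** mutation genes are
  allocated 231:19 LDLR:APOB by largest-remainder rounding and shuffled;
  their allele-frequency shift is roughly 40% of the mutation-negative one,
  reproducing the usual pattern that carriers sit between controls and
  polygenic cases on the score scale.

DLCN components are drawn *independently* per component from group-specific
margins, and the DLCN total score from a group-typical normal distribution,
so component flags and the total are not internally consistent the way a
real chart review would be — only the margins are faithful. That is a
deliberate simplification (no joint distribution is available to emulate),
and it means passing tests say nothing about correlations between clinical
items on real data. Likewise the generator has no linkage disequilibrium
(the panel uses one SNP per locus by design) and no family structure.

## The statistical battery

* **HWE:** chi-square goodness of fit (1 df) against expectations from the
  observed allele frequency; the exact conditional test takes over whenever
  an expected genotype count is below 5.
* **Allele-frequency tests:** Pearson chi-square on the 2×2 allele-count
  table without continuity correction (standard association practice);
  Fisher's exact test whenever an expected cell is ≤ 5.
* **Panel refinement:** bidirectional stepwise logistic regression on
  additive dosages. The p-based rule (enter 0.05, remove 0.10) is the
  default because refined panels are usually reported with per-term Wald
  p-values; an AIC mode is available since the selection rule is a genuinely
  open choice. Complete separation is flagged (by the glm warning *and* by a
  runaway-coefficient check, since glm can converge quietly under
  separation).
* **Group comparisons:** Shapiro-Wilk at α = 0.05 per group gates
  t-test/ANOVA versus Wilcoxon/Kruskal-Wallis; degenerate all-tied groups
  take the rank path with p = 1. No multiplicity correction is applied —
  raw p-values are reported, as is conventional for this kind of
  confirmatory panel.
* **Trend:** the Cochran-Armitage statistic with integer scores (invariant
  to affine re-scoring), two-sided normal p.
* **Adjusted associations:** `component ~ wGS + age + sex` logistic fits,
  reporting the score term as an OR per score unit.

## Cutoffs and classification

Percentile cutoffs use the type-7 (linear interpolation) empirical quantile —
the convention is declared in every report because "the 75th percentile" is
otherwise ambiguous by up to one order statistic; a test covers that
sensitivity. "Above the cutoff" is strict (`>`), the conservative reading,
and configurable.

The ROC sweep places thresholds at midpoints between adjacent distinct
scores. The AUC is computed by the trapezoid rule and must agree with the
tie-corrected Mann-Whitney identity $U/(n_1 n_0)$ to $10^{-10}$ — the two
are computed independently and a disagreement aborts rather than returning a
number. Because mathematically equal beta sums can differ by ~1e-16
depending on summation order, scores are snapped to 10 decimals on entry so
ties are treated as ties by both routes. Youden's J = sens + spec − 1 is
maximized by exhaustive scan over the swept thresholds with ties broken
toward the higher threshold (higher specificity). AUC comparison between
panels scored on the same samples uses the DeLong placement-value
covariance; the method choice is an assumption documented here, not a claim
about any particular study's software.

## The combined estimator

With monogenic percentage $M$ and polygenic rate $r$ (percentage of
mutation-negative patients above the cutoff, missing-score samples excluded
from the denominator),

$$\text{combined} = M + (100 - M)\, \frac{r}{100}.$$

Percentages are carried at full precision and rounded to one decimal only at
report time. In integer-count mode the per-stratum combined counts
(`n_mpos + n_above`) recompose exactly to the whole-cohort count when the
strata partition the cohort; a test asserts this.

## Numerical and design choices, in brief

* Strand flips (A/T, C/G pairs included) are never guessed: the panel is a
  fixed assay, so any REF/ALT or allele-pair mismatch against the weight
  table is a data error.
* Matching is by rsid only; coordinates and genome build are ignored.
* Determinism: every simulation entry point takes a seed, and the full
  pipeline writes byte-identical JSON under a fixed seed and config.
* Problem sizes used by the test suite were chosen to make the statistical
  properties decisive at modest cost: the distributional checks run 10-50
  seeds at the study's group sizes (403/503), liability-mode enrichment uses
  250 cases against 300 controls per seed, and stepwise recovery uses
  n = 2000 with ten candidate SNPs over 20 seeds.

## Limitations

The simulator reproduces marginal structure (allele frequencies, HWE, DLCN
margins, group sizes), not the joint structure of real referral cohorts;
cohort-dependent quantities such as specific refined-panel ORs, AUC values
near 0.65, or threshold values are exercised as shapes and distributional
properties, not as value targets, because they depend on unpublished exact
betas and on the original genotypes. The combined estimator itself carries
no uncertainty interval; a bootstrap over `fraction_table()` is the natural
extension point.

## A worked run

```r
library(polyfh)
report <- run_pipeline(sim_config(seed = 1))
report$fractions
tidy(group_compare(
  dplyr::inner_join(score_panels(simulate_study(sim_config(seed = 1))$genotypes,
                                 default_weights()),
                    simulate_study(sim_config(seed = 1))$cohort[, c("sample_id", "group")],
                    by = "sample_id") |>
    dplyr::filter(panel == "wGS8", !is.na(wgs))
))
```
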