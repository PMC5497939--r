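---
title: "Methods: measuring polygenic score portability on synthetic multi-population data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring polygenic score portability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsport)
```

## The model

A polygenic risk score is the linear predictor
$\mathrm{PRS}_j = \sum_{i=1}^{n} w_i X_{ij}$, where $X_{ij} \in \{0,1,2\}$
counts copies of SNP $i$'s effect allele in sample $j$. Weights are either
the GWAS effect sizes themselves ($w_i = \beta_i$, single weighting) or
shrunken per SNP ($w_i = \beta_i \pi_i$ with $\pi_i \in [0,1]$, double
weighting, which damps the winner's-curse overestimation of effects
selected for significance in the discovery scan).

Under Hardy–Weinberg equilibrium and linkage equilibrium, a population
with effect-allele frequencies $p_i$ has analytic score moments

$$\mathbb{E}[\mathrm{PRS}] = \sum_i 2 w_i p_i, \qquad
\mathrm{Var}[\mathrm{PRS}] = \sum_i 2 w_i^2 p_i (1 - p_i).$$

These two formulas are the package's central oracle
(`expected_prs_moments()`): every distribution-shift claim made by the
pipeline is checkable against them. The mean formula makes the portability
problem immediate: two populations that differ in allele frequencies by
$\Delta p_i$ differ in expected score by $\sum_i 2 w_i \Delta p_i$, which
for thousands of SNPs accumulates into shifts that dwarf the
within-population standard deviation, even when every individual effect
$w_i$ transfers perfectly.

Scores are reported on the pooled z-scale: `scale_scores()` standardizes
over **all** samples across populations (standard deviation with the
$n-1$ denominator; the choice is distribution-visible at small $n$ and is
therefore fixed and documented). Per-population scaling would erase
exactly the shifts the analysis is about.

## The synthetic cohort generator

`simulate_frequencies()` draws ancestral effect-allele frequencies
uniformly on a range bounded away from fixation (default $[0.1, 0.9]$)
and diverges each population under the Balding–Nichols model:
$p_{\mathrm{pop}} \sim \mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,
(1-p)\tfrac{1-F}{F}\big)$, with mean $p$ and variance $F\,p(1-p)$, so $F$
plays the role of $F_{ST}$ against the ancestral pool. Effect sizes are
normal with both signs (default sd 0.05, the small-effect regime of
genome-wide models); an optional uniform $\pi$ range produces
double-weighted models.

A population can additionally receive a deterministic, directional shift
$\delta$: its risk-allele frequency (the effect allele where $w_i > 0$,
the other allele where $w_i < 0$) is moved toward the risk allele by
$\delta$ and clipped to $[0.01, 0.99]$. Applying $\delta$ after the
Balding–Nichols draw keeps the induced between-population mean difference
analytic — $2\delta \sum_i |w_i|$ up to clipping — which is what lets the
shift-mechanism checks compare simulation against a closed form. The
clipping bounds also keep every SNP polymorphic, which the genotype-PCA
normalization requires. Genotypes are then $\mathrm{Binomial}(2,
p_{\mathrm{pop}})$ per SNP per sample.

What the generator deliberately does **not** emulate: linkage
disequilibrium (the portability mechanism studied here is
frequency-driven, and independent SNPs keep the analytic oracles exact —
LD-induced effect-size misestimation across ancestries is a separate,
real phenomenon that this simulator cannot exhibit), realistic
site-frequency spectra, admixture within individuals, and genotyping
error. Passing tests therefore demonstrate the frequency-shift arithmetic
and the pipeline's correctness, not that any particular real pair of
cohorts differs by a given amount.

`write_fixture()` materializes a simulated cohort as VCF 4.2 + TSVs and
deliberately perturbs configurable, disjoint fractions of SNPs: rewritten
as palindromic A/T–C/G pairs, written with the effect allele as VCF REF
(so the ALT dosage is the complement), or omitted from the VCF. Counts
are exact by construction, which is what makes the harmonization
bookkeeping testable to equality rather than approximately.

## Harmonization and scoring choices

- **Matching is by SNP ID only** (with an optional user-supplied static
  alias map), never by position; no liftover, no live annotation-service
  queries, for reproducibility.
- **Palindromic SNPs** (allele pairs A/T or C/G) are strand-ambiguous and
  are dropped when the filter is on. The filter is a per-model flag
  because published score pipelines differ in whether the source model
  was already filtered.
- **No strand flipping is guessed** for other mismatches: a record whose
  REF/ALT pair does not equal the model's allele pair as a set is
  excluded and logged `allele_mismatch`. Multiallelic records are
  excluded with their own reason code — the conservative reading of
  ID-based extraction. Duplicate VCF records resolving to one model SNP
  keep the first occurrence, with a warning.
- **Absent SNPs are dropped, never imputed**; the exclusion log is a
  first-class output.
- **Missing dosages** pass through harmonization and are resolved at
  scoring time. The default `mean_dosage` policy substitutes the SNP's
  pooled mean dosage, matching the default behaviour of the standard
  command-line scoring tools; `zero` and `drop_snp_for_sample` are
  explicit alternatives (numerically identical sums, distinct intent).
  `n_snps_used` records per-sample completeness.

## Stratification conventions

Quintile thresholds are the 20/40/60/80% quantiles of each population's
scaled scores, computed with the linear-interpolation empirical estimator
(`stats::quantile` type 7, the default of mainstream statistical
environments) — fixed because threshold values are the headline output.
The 95% CI on the mean is the normal approximation
$\bar{x} \pm 1.96\, s/\sqrt{n}$. A score exactly at a threshold falls in
the **lower** quintile; the convention is arbitrary but must be fixed for
determinism, and it makes "quintile 5" mean *strictly above* the
reference q80. `cross_population_shift()` is then a pure counting
operation, verified in the tests against a direct count oracle.

The logistic validation (`fit_prs_logistic`) regresses a binary phenotype
on the scaled score, so the odds ratio is per scaled-PRS unit — i.e. per
pooled standard deviation — which is the natural reading of a model fit
on standardized scores. Complete or quasi-complete separation is detected
(non-convergence, |slope| > 15, or an exploded standard error) and
reported as an error rather than a spurious estimate.

## PCA and ancestry conventions

Genotype PCA uses the standard normalization — center by $2\hat p$, scale
by $\sqrt{2\hat p (1-\hat p)}$ — after mean-substituting missing dosages
(scoring keeps its own policy; the two imputations serve different
purposes). Monomorphic SNPs are dropped; an all-constant matrix is a hard
error. Each component's sign is fixed by a non-negative loading sum;
since any eigen-solver's sign is arbitrary, the PRS–PC1 correlation is
reported signed but should be interpreted through $|r|$.

Per-population correlations recompute the PCA **within** that population
only: the question is whether residual structure inside a cohort leaks
into the score, not whether global ancestry does (it does, trivially).

Top-SNP selection ranks by $|w_i|$ with lexicographic tie-breaks. This is
a proxy for "most contributing" — discovery-GWAS z-scores are not part of
a weight file and need not order SNPs identically. Frequency comparisons
expect a risk-increasing-oriented subset so that "effect-allele
frequency" means "frequency of the score-raising allele" in both
populations; the implementation additionally checks each subset record
against the allele actually counted by the genotype column and
complements the frequency if the orientation differs, so the estimate is
invariant to the orientation convention.

## Null design for the PRS–PC1 calibration check

Computing both the score and the PCA from the *same* SNP panel is not a
true null even in a homogeneous population: PC1 is by construction the
panel's maximum-variance direction, so a random weighted sum of the same
columns has slightly elevated expected correlation with it, and the
0.05-level test over-rejects. Under linkage equilibrium and no structure,
a score computed on one panel is exactly independent of a PCA computed on
a disjoint panel — which mirrors practice, where scoring SNPs and
ancestry-informative panels need not coincide. The calibration check
therefore draws two independent panels per replicate (scores from one,
PC1 from the other) and recovers the nominal ≈5% rejection rate over 200
replicates.

## Study conditions and problem sizes

The test and acceptance workloads use sizes chosen so each property is
measured with adequate power while the whole suite stays desk-scale:
scoring-oracle equivalence on 100 random instances (≤50 samples × ≤200
SNPs, tolerance 1e-12); moment recovery on 5 populations × 5000 SNPs ×
2000 samples (4-standard-error bands against the analytic moments); the
shift mechanism at $\delta = 0.05$ with $F = 10^{-3}$ for both
populations, so Balding–Nichols between-population noise stays small
against the analytic $2\delta\sum|w_i|$ shift being verified; null
checks at $F = 10^{-4}$ (the no-structure condition); PCA separation at
$F = 0.2$, 2000 SNPs, 100 samples per population; OR recovery at a true
OR of 1.76 per scaled unit, $n = 5000$, 100 phenotype replicates. The
demonstration model (`demo_model()`) uses six populations — two
undifferentiated European-like cohorts and four with increasing $F$
(0.005–0.05) and $\delta$ (0.01–0.10) — at 1500 SNPs, chosen to produce
clearly ordered shifts whose spacing exceeds the Balding–Nichols
between-population noise ($\mathrm{sd} \approx s\sqrt{2(F_1+F_2)}$ for a
population pair with within-population score sd $s$).

## Known limitations

- Linkage equilibrium means the simulator cannot reproduce LD-driven
  effect-size non-transferability; observed shifts are purely
  frequency-driven.
- Quantile thresholds at small $n$ depend on the estimator; only type 7
  is implemented.
- The Wald CI and normal-approximation mean CI are asymptotic; at very
  small cohort sizes exact methods would differ.
- Alias resolution is static; stale alias maps will log resolvable SNPs
  as `not_in_vcf`.
- Admixed individuals are outside the simulator's scope: every sample
  belongs to exactly one population.

```{r demo, eval = FALSE}
# end-to-end demonstration (writes fixture + results under `out`)
bundle <- demo_simulation(out <- tempfile(), seed = 1)
bundle$quantiles
```
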