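---
title: "Summary-statistic TWAS with multi-tissue exclusivity: methods and design"
author: "xtwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-statistic TWAS with multi-tissue exclusivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtwas)
```

## The problem

A transcriptome-wide association study (TWAS) asks whether the
*genetically-regulated* component of a gene's expression (GReX) is
associated with a trait.  When only summary statistics are available —
per-variant GWAS effects on one side, per-variant cis-eQTL effects on the
other — the association can still be computed, provided a reference
genotype panel supplies the linkage disequilibrium (LD) structure.  This
package implements that pipeline for the setting where the tissue of
interest (for example, placenta) has its own eQTL resource and the
question is whether a gene's trait association is *exclusive* to that
tissue when compared against models from many other tissues.

## Prediction models from eQTL summary statistics

Models are built from marginal cis-eQTL regressions in four stages
(`buildModels()`):

1. **Within-gene FDR filter.**  Each gene's cis p-values are
   Benjamini–Hochberg adjusted and records with adjusted q-value of 0.1 or
   more are dropped.  The adjustment is within-gene by default; a
   transcriptome-wide adjustment is available via `fdrScope = "global"`,
   because with summary data both readings of "FDR within each gene" are
   defensible.  Within-gene is the default because eQTL significance is
   conventionally assessed per gene, and the filter's purpose here is to
   pick each gene's credible cis signals, not to control a study-wide
   error rate.
2. **LD clumping.**  Survivors are greedily pruned: the smallest-p variant
   is retained and every remaining variant within ±250 kb with squared
   Pearson dosage correlation r² ≥ 0.1 in the reference panel is
   discarded; repeat.  Ties in p are broken by ascending position then
   variant ID, so the result is invariant to input row order.  r² is
   computed on panel dosages (panels ship as genotypes, not haplotypes).
3. **Weights and variance accounting.**  Each retained variant's weight is
   its marginal eQTL beta (SD of expression per effect allele) — no
   re-fitting or shrinkage, since the procedure is defined on filtered
   marginal effects.  The expression variance a variant explains under
   Hardy–Weinberg equilibrium is 2pqβ² (`snpVariance()`), with p its
   effect-allele frequency from the eQTL file; the gene total is the sum
   over retained variants.
4. **Gene-level variance filter.**  Genes whose total is strictly greater
   than 2 or strictly less than 0.01 are excluded: totals below 0.01
   indicate no substantial genetic regulation, totals above 2 (an
   impossible variance for standardized expression) indicate redundant,
   correlated weights surviving the clump.  Boundary values are retained
   because the exclusion rule is strict.

## The association statistic

For a gene with weights $w_l$, GWAS z-scores $z_l$, reference dosage
variances $\sigma_l^2$ and predicted-expression variance
$\sigma_g^2 = w^\top \Gamma w$ (with $\Gamma$ the reference dosage
covariance over the model variants):

$$Z_g = \frac{\sum_l w_l\,\sigma_l\,z_l}{\sigma_g},\qquad
\hat\gamma_g = \frac{\sum_l w_l\,\sigma_l^2\,\beta_l}{\sigma_g},\qquad
\mathrm{se}_g = \left|\hat\gamma_g / Z_g\right|,$$

with a two-sided p-value from the standard normal.  $\hat\gamma_g$ is in
trait units per SD of predicted expression: dividing the weighted
covariance $\sum_l w_l \sigma_l^2 \beta_l$ (the covariance between trait
and unstandardized GReX implied by the marginal GWAS effects) by one power
of $\sigma_g$ yields the per-SD slope, which is the scale on which a
single-SNP model reduces to $\beta_l \sigma_l$ and on which a planted
trait effect per SD of GReX is recovered as itself.  $\sigma_l$ is taken
from the diagonal of $\Gamma$, so numerator and denominator always use
the same LD source; $\Gamma$ comes from the model covariance file when it
covers the usable variants and from the panel otherwise.

Numerical choices:

* $\sigma_g^2 \le 10^{-12}$ marks a degenerate (fully pruned or
  monomorphic) model; the gene is skipped with reason `"degenerate"`
  rather than divided through.
* Genes with no model variant present in the GWAS are reported as
  untested (`"no_gwas_overlap"`), never as zero associations.
* Under the per-variant identity $\beta_l = z_l\,\mathrm{se}_l$ the
  numerators of $Z_g$ and $\hat\gamma_g$ share their sign; with
  finite-sample standard errors a *near-zero* effect can come out on the
  other side of zero from $Z_g$ by cancellation.  In that case the effect
  is sign-aligned to the z-score, which carries the inference.
* P-values are floored at the smallest positive double so that the
  p ∈ (0, 1] invariant survives extreme z-scores.

## Multi-tissue pooling and exclusivity

All gene×tissue results for a phenotype are pooled
(`classifyResults()`); the Bonferroni threshold is α divided by the
*total* pooled test count — the study-wide accounting under which
published percentages of significant results are quoted — and
comparisons are strict (`p < threshold`, `p < α`).  A gene significant in
the focal tissue is *exclusive* iff it is not Bonferroni-significant in
any other tissue where it carries a model (`findExclusive()`).  A gene
with no model elsewhere counts as exclusive but carries
`tested_in_n_tissues = 1`, keeping "tested elsewhere and null"
distinguishable from "untestable elsewhere".  Gene identity across
tissues is by version-stripped stable ID, so distinct genes sharing a
symbol stay distinct.

## Gene-set over-representation

`hypergeometricEnrichment()` computes the upper-tail hypergeometric
p-value $P(X \ge k)$ per set with BH adjustment across tested sets.  The
recommended background is the genes carrying a model in the focal tissue
— the universe the query was drawn from; any other background biases the
test.  Published adjusted enrichment p-values cannot be recomputed
without knowing the original background size, so none is asserted.

## The synthetic study

The generator replaces external GWAS/eQTL downloads with a fully seeded
population model (`simScenario()`, `simulateStudy()`):

* **Genotypes.**  One gene per chromosome, `mPerGene = 30` cis variants at
  5 kb spacing, haplotype blocks of `blockSize = 10`.  Within a block,
  haplotypes follow a copy model — each variant copies its left
  neighbour's allele with probability ρ (default 0.7), else redraws
  Bernoulli(f) — giving allele correlation exactly $\rho^d$ at distance
  d; blocks are independent.  The block frequency f is drawn once per
  block from U[0.05, 0.5]: equal margins are what make the adjacent
  correlation exactly ρ (two Bernoullis with different means cannot reach
  arbitrary correlation), at the cost of no frequency variation inside a
  block.
* **Cohorts.**  Reference panel (default 500), eQTL cohort (default 150,
  the size of the placental eQTL study this pipeline is modelled on) and
  GWAS cohort (default 10,000) are independent draws from the same
  population, matching the use of an external LD reference.
* **Expression.**  Per gene and tissue, `nCausal = 2` causal cis variants
  with effects b ~ N(0, 1); Gaussian noise is scaled so the cis-genotype
  fraction of expression variance is `eqtlH2 = 0.2` in the population.
  Across the 5 tissues, half of each gene's causal set is shared (same
  variant, same effect) and half tissue-specific; genes designated
  *exclusive* trait genes instead receive causal sets disjoint across
  tissues.
* **Trait.**  The phenotype is $\sum_g \alpha_g \cdot$ (standardized
  focal-tissue GReX) plus Gaussian noise with SD
  $\sqrt{1 - \sum \alpha_g^2}$, then standardized — a trait z-score.  The
  default plants five trait genes (α between 0.2 and 0.3, three
  exclusive), leaving ~95 cis-regulated but trait-null genes.
* **Ground truth** (`simulateTruth()`) records causal sets, effects, α,
  and each variant's expected marginal GWAS effect computed from the
  closed-form block covariance $2f(1-f)\rho^{|i-j|}$.

What the generator does *not* emulate: realistic human LD maps and allele
frequency spectra, imputation error, sample overlap between cohorts,
population stratification, and trait effects not mediated by expression.
Passing tests therefore demonstrate the statistical machinery — not
robustness to those real-data complications.

## What the checks compute, and at what size

The package's validation suite (run by `testthat`) checks, among others:

* clumping against a brute-force greedy oracle on 20-variant instances;
* BH and hypergeometric p-values against direct step-up / combinatorial
  enumeration (e.g. N = 100, K = 10, n = 10, k = 5 gives 6.716 × 10⁻⁴);
* the summary-statistic $Z_g$ against individual-level regression of the
  trait on the weighted dosage score, on a 50-gene scenario with
  n\_gwas = 5,000 and the cohort itself as panel.  The summary identity
  replaces each variant's residual variance by the trait variance, an
  approximation with error of order $|Z|^3/n$; the check therefore plants
  effects in the moderate regime (|Z| ≲ 10), where agreement to
  |ΔZ| < 0.2 is informative about correctness rather than about the
  approximation's large-Z behaviour;
* type-I error and p-value uniformity on ~460 trait-null genes;
* recovery of a planted α = 0.3 (mean over 50 seeded replicates of the
  per-SD effect at n\_eqtl = 5,000, n\_gwas = 20,000).  Replicates in
  which 2pqb² falls outside the variance-filter bounds carry no model and
  are excluded — the filter doing its job;
* exclusivity classification on a 5-tissue scenario with three
  placenta-only trait genes.  A truth gene detected in the focal tissue
  may legitimately be called non-exclusive when another tissue's model is
  *linked* (r² ≥ 0.1, the pipeline's own linkage notion) to the focal
  causal set: disjoint causal variants in one LD block still tag each
  other's signal.  The check verifies every non-exclusive call is
  explained that way.

These sizes keep the full suite within a few minutes on one CPU while
leaving each check's Monte-Carlo error well inside its assertion margin.

## A small worked example

```{r example, eval = FALSE}
sc <- simScenario(seed = 1)
st <- simulateStudy(sc)
fits <- lapply(sc@tissues, function(t)
  buildModels(st$eqtl[[t]], st$panel, tissue = t))
names(fits) <- sc@tissues
resl <- lapply(sc@tissues, function(t)
  runAssociation(st$gwas, fits[[t]]$models, st$panel))
summ <- classifyResults(resl, phenotype = "trait")
summ
findExclusive(summ, "placenta")
```

## Known limitations

* Weights are unshrunken marginal betas; penalized multi-variant models
  (elastic net, BSLMM) usually predict better and are out of scope.
* The exclusivity call inherits the power of every non-focal tissue:
  low-powered models elsewhere bias genes *toward* exclusivity.  The
  `tested_in_n_tissues` flag is the only guard offered.
* With the eQTL cohort at its default size (150), model building is
  low-powered, as in the real resource it mirrors; many genuinely
  cis-regulated genes carry no model.
* Harmonization resolves strand ambiguity by dropping palindromic
  variants; frequency-based strand inference is deliberately not
  attempted.
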