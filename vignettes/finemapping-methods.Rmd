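---
title: "Multiethnic fine-mapping with finemapSNV: models, assumptions and design"
author: "finemapSNV authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiethnic fine-mapping with finemapSNV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finemapSNV)
library(SummarizedExperiment)
```

# The problem

Genome-wide association studies localize disease risk only to regions of
correlated variants. Deep targeted sequencing of such regions in a
case-control sample, ideally across several ancestral populations whose
linkage-disequilibrium (LD) patterns differ, makes it possible to (i) test
every observed SNV rather than a tagging subset, (ii) shrink the list of
candidate causal variants with a single-causal Bayesian argument, and (iii)
aggregate the abundant rare variation into gene-level tests. `finemapSNV`
implements that full analysis as reusable, tested components around a single
container, the `GenotypeExperiment` (a `RangedSummarizedExperiment` whose
assays are the dosage matrix and the per-genotype read-depth and quality
side-channels), together with a synthetic multiethnic cohort generator that
provides ground truth for every downstream stage.

The intended cohort shape is four populations (African American n=937,
Japanese American n=1256, Hispanic n=907, European n=1511; 2288 cases and
2323 controls in total; `defaultPopulations()`), roughly a dozen sequenced
regions, and a variant spectrum in which ~87% of SNVs are rare
(MAF < 0.005), most observed in a single population.

# The synthetic cohort generator

The generator is first-class, tested code; its defaults define the study
conditions everywhere else in the package.

**Allele frequencies.** Each variant's ancestral frequency is drawn from a
mixture: with probability `common_fraction` (default 0.128, tuned to
reproduce the ~87.2% rare fraction) uniform on the common range
[0.005, 0.5]; otherwise from a density proportional to 1/x — the neutral
spectrum shape — on [1/(4K), 0.005], where K is the founder-pool size. Only
the rare *fraction* is targeted; no empirical site-frequency spectrum is
fitted. Population frequencies then diverge by the Balding–Nichols model,
`Beta(p(1-F)/F, (1-p)(1-F)/F)`, with per-population divergence F (defaults
0.15/0.12/0.08/0.05, ordered by expected drift from a shared ancestral
pool; the scale of F is a realism choice, not a fitted quantity).

**LD.** Each population gets K founder haplotypes drawn sitewise
independently at the population frequencies; sampled haplotypes copy a
founder and switch, at each adjacent-variant step with probability
`switch_prob`, to a uniformly chosen founder. This one-knob mosaic produces
block-like LD without a coalescent simulator. An important structural
consequence, verified empirically: because founder alleles at different
sites are independent, the *expected* pairwise r² is bounded near 1/(K-1).
Large pools (K = 200 default) therefore give realistic-looking weak LD, and
near-perfect proxies (r² > 0.8) only arise with small pools (K ≲ 6). Tests
that need strong proxies — conditional-scan signal absorption, credible-set
competition — deliberately use small founder pools; this is a property of
the generator's design, not of the analysis code.

**Disease model.** An individual pairs two random haplotypes from its
population pool (regions are unlinked, i.e. independent pools). Disease is
Bernoulli with `plogis(alpha + sum(beta * g))` over the configured causal
SNVs. The intercept is calibrated by bisection on a fixed simulated pool of
50,000 individuals so the pool prevalence matches `baseline_prevalence`
(default 0.1, a lifetime-risk-scale figure) within 0.002; a closed form is
unavailable once several causal SNVs contribute. Cases and controls are then
rejection-sampled to exact per-population targets, with an explicit
diagnostic failure if the quota is unreachable. ER status is assigned to
cases independently of genotype (probability `er_neg_fraction`, default
393/2288); ER-specific genetic effects can be layered with a second
`DiseaseModel` if needed.

**Side-channels and annotations.** Read depth (negative binomial, mean 30)
and genotype quality (Poisson around 60, capped at 99) feed the QC module
and are switchable off for pure statistics studies. Impact classes are
multinomial with default proportions (81, 1983, 1374, 134092)/137530
(disruptive / nonsynonymous / synonymous / noncoding), genes come from
interval containment, and nonsynonymous variants get a damaging flag with
configurable probability (default 0.5: roughly half of scored
nonsynonymous variants being called possibly or probably damaging is
typical of PolyPhen-2 output).

**Reproducibility.** All randomness flows from one master seed through
deterministic stream-splitting (`childSeed`) keyed by region and population
labels, so enlarging a design never perturbs existing streams, and
simulation is bit-reproducible.

# Quality control

The cascade mirrors a deep targeted-sequencing workflow, with thresholds
collected in `QcThresholds`:

* genotype level: mask calls with DP < 5 or GQ < 10 (exclusive thresholds:
  DP = 5 passes);
* variant level, in a fixed attribution order (nodata → total depth →
  missingness → HWE): drop variants with >10% of samples without reads,
  total depth < 20,000 reads, >10% missing calls, or exact Hardy–Weinberg
  p < 1e-6 in any ancestry group;
* sample level: call rate < 90%, concordance < 90% against an external
  genotype table (when supplied), and one of each near-duplicate pair
  (concordance > 0.99; the deterministic tie-break drops the
  lexicographically larger id — the duplicate criterion itself is a design
  choice, as only the existence of a duplicate filter is documented for the
  workflow being modeled).

The HWE test is the exact conditional test (heterozygote counts no more
probable than observed, given allele counts), not the chi-square: rare
variants dominate and the asymptotic test is invalid at low counts. Whether
the original workflow computed HWE in all samples or controls only is not
documented; the default here uses all samples of each ancestry group
(matching the "any ancestry group" phrasing), with
`controls_only_hwe = TRUE` available. A `QcReport` reconciles every removal
count with the input/output dimensions, and the variant cascade is
idempotent.

# Association and meta-analysis

Single-SNV association is a logistic regression of case status on the
additive dosage (0/1/2; per-allele odds ratios, no dominance terms),
adjusted for the top three within-population principal components. The IRLS
core iterates to a relative log-likelihood change below 1e-10 (at most 50
iterations, with step-halving); monomorphic dosages, non-convergence and
quasi-complete separation (|log-OR| > 15, SE > 100, or fitted probabilities
at the boundary) are flagged not-evaluable and excluded from meta-analysis
and posterior sums. Wald statistics are reported because the downstream
tables are OR-with-CI shaped; the maximized and covariates-only
log-likelihoods are recorded on each variant's exact sample subset for the
Bayesian module.

PCs are computed within each population from variants with MAF > 0.05,
mean-imputed, centered and scaled by `sqrt(2f(1-f))`, with signs fixed so
each component's largest-magnitude loading is positive.

Cross-population combination uses inverse-variance fixed-effect
meta-analysis of the per-population log-ORs; populations where a variant is
not evaluable are skipped silently but recorded. No heterogeneity statistic
is computed (out of scope). A pooled single-model analysis (all populations
in one regression) is available simply by scanning without a population
filter, but stratified meta-analysis is the default convention.

Conditional scans add the index/top SNV dosage (mean-imputed at missing
genotypes — deterministic and innocuous at post-QC missingness levels) as a
covariate, refuse collinear conditioning variants by name, and report the
conditioned variants themselves as not-evaluable.

Multiplicity uses the simpleM construction per region: the effective number
of tests is the smallest k such that the top-k eigenvalues of the
(mean-imputed, pairwise-complete) dosage correlation matrix reach C = 0.995
of the total variance — 0.995 being that method's published default, since
the workflow being modeled cites the method without parameters. The
region-wise Meff values sum to a study-wide effective test count and an
adjusted threshold `alpha / total`.

# Single-causal posteriors and the credible set

Assuming exactly one causal SNV per region and a uniform prior over which
SNV it is, the posterior for SNV i is the ratio of its maximized likelihood
to the region sum, computed by a log-sum-exp stabilized softmax of the
per-SNV log-likelihoods. Every per-SNV model has the same dimension
(intercept + covariates + one SNV), so maximized-likelihood ratios are used
directly with no complexity penalty; a per-variant penalty argument exists
for BIC-style weighting but an equal penalty cancels exactly. Not-evaluable
variants get posterior zero (the sum runs over tested SNVs only, matching
the construction being reproduced, rather than granting them prior mass).

The credible (posterior probability) set sorts posteriors descending (ties
broken by variant id) and takes the shortest prefix whose cumulative mass
*strictly* exceeds the target (default 0.90), with a 1e-12 float guard: ten
equal posteriors of 0.1 yield a set of size ten, because nine reach exactly
0.9, not more.

For the cross-population analysis the per-SNV log-likelihood is the sum of
stratified population log-likelihoods, substituting a population's
covariates-only log-likelihood where the variant is not evaluable there —
this keeps all variants on a common likelihood scale when, say, a variant is
monomorphic in one ethnicity. How the original cross-ethnicity analysis
combined likelihoods is not documented; summed stratified likelihoods are
this package's convention, and the pooled-model route is available.

## Calibration, and when coverage exceeds the mass

`ppsCoverageStudy()` measures frequentist coverage: the fraction of
simulated single-causal regions whose credible set contains the truth. Two
regimes matter:

* **Competition regime** (near-perfect proxies, moderate power): the
  posterior spreads over a proxy class, the set boundary bites, and coverage
  sits at or modestly above the nominal mass (the strict ">" rule includes
  whole tied proxy classes, which can only push coverage up). The test suite
  verifies this with a 4-founder generator.
* **Strong-signal / weak-LD regime**: when the causal SNV's Wald z is large
  (e.g. OR 1.5 at MAF 0.2 with 2000 cases / 2000 controls gives z ≈ 8) and
  no proxy exceeds r² ≈ 0.3 (the 30-founder mosaic bound discussed above),
  the posterior concentrates entirely on the causal SNV, sets have size 1,
  and empirical coverage is ~100% — conservative relative to the 90% mass.
  This is a property of the construction itself ("at least 90%" coverage),
  not an implementation artifact, and it is exactly what the calibration
  study in `scripts/acceptance.R` reports under its stated conditions.

# Gene-based rare-variant tests

Sets are a gene's nonsynonymous (moderate-impact) SNVs with pooled-sample
MAF strictly below 0.005, optionally restricted to predicted-damaging ones
("p2" sets). Pooled MAF governs eligibility — matching the pooled phrasing
of the rarity rule — while per-population polymorphic member counts are
reported. Missing dosages in a set are imputed to homozygous reference: at
MAF < 0.005 the reference call is overwhelmingly likely, with a small
conservative bias toward the null, noted here deliberately.

The **burden** statistic is the per-subject summed minor-allele count,
tested in a logistic model with the same covariate machinery as the
single-SNV scan; this yields the per-gene OR with CI that result tables
report. A carrier-indicator burden is available as an option. The **SKAT**
statistic is `Q = sum_j w_j^2 S_j^2` with scores `S = G'(y - mu)` under the
covariates-only null fit and Beta(1, 25)-density weights at the pooled MAF
(the method's published default, since no parameters are documented for the
workflow being modeled). Its null law, a weighted sum of 1-df chi-squares
with weights the eigenvalues of `W^(1/2) G' P G W^(1/2)`, is evaluated by
numerical inversion of the characteristic function (Imhof integral via
adaptive quadrature, eigenvalues truncated below 1e-10 of the maximum) with
a Liu moment-matching fallback whenever the inversion fails, strays outside
[0, 1], or hits its ~1e-12 resolution floor.

Across populations, burden results combine by inverse-variance fixed
effects; SKAT combines under the homogeneous-effect assumption
(Hom-Meta-SKAT): scores and projected information matrices are summed over
cohorts, with variants absent from a cohort contributing zero score and
zero information, and weights recomputed at the across-cohort pooled MAF.
A single-cohort meta-analysis reproduces the plain SKAT p-value exactly,
and splitting one cohort at random recombines to within numerical
approximation error of the unsplit analysis.

Gene-level significance uses Bonferroni at `alpha / (number of meta-level
gene tests actually evaluated)`.

# Numerical and testing choices

Problem sizes in the test suite are chosen to make each statistical check
informative yet quick: the calibration study uses 500 regions of 200 SNVs
at 2000/2000 cases/controls; type-I error rates use 2000 null variants and
2000 null genes at n = 1000; oracle equivalences run full enumeration (all
HWE count triples to n = 50), 10,000-label permutations, and coarse-to-fine
grid likelihood maximization; the Marchenko–Pastur-style PC null check uses
a 50-sample × 500-variant aspect ratio so the null top eigenvalue stays
below twice the mean. The private-polymorphism property is measured on a
common-variant spectrum with well-sampled pools: under the 87%-rare
spectrum with small pools, rare-variant sampling sparsity saturates the
private fraction at any divergence and the trend reflects denominator
composition rather than drift.

# What passing tests do and do not show

The generator emulates cohort sizes, the rare/private variant spectrum,
population divergence, block-LD shape and a logistic disease model. It does
not emulate sequencing error processes correlated with genotype, batch
effects in variant calling, indels and multi-nucleotide variants, realistic
coalescent LD decay, admixture within labeled populations, or
genotype-dependent ER status. Consequently the suite demonstrates
correctness and calibration of the statistical machinery under a
well-specified generative model — not robustness to the artifacts of real
sequencing data, for which the QC cascade is the first but not sufficient
line of defense.

# Known limitations

* The founder-mosaic LD model cannot produce sustained r² ≈ 1 blocks at
  large founder-pool sizes (see above); realistic haplotype panels would
  require a coalescent or copying model, deliberately out of scope.
* The single-causal posterior is exactly that: with multiple causal SNVs in
  a region, posteriors and sets remain interpretable only as single-signal
  summaries; conditional scans are the provided tool for multi-signal
  regions.
* Wald inference for very sparse burdens (a handful of carriers) can be
  conservative; score or exact alternatives are not implemented.
* The duplicate-sample filter is O(n²) in samples over the indicator
  cross-products; it is intended for cohort-scale (thousands), not
  biobank-scale, inputs.
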