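---
title: "Methods: competitive gene-set enrichment for quantitative-trait GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: competitive gene-set enrichment for quantitative-trait GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gwaset asks a single scientific question of genome-wide association data for
a quantitative phenotype: is an a-priori set of genes *more* associated with
the phenotype than comparable genes elsewhere in the genome? The package
implements the full chain of analyses needed to answer it — phenotype
derivation, quality control, single-marker association, gene-based testing,
LD clumping into genomic intervals, and a competitive interval-overlap
permutation test with a bootstrap correction for testing many correlated
gene sets — together with a synthetic cohort generator so that every stage
can be validated without access to any genotype data.

## The analysis chain and its models

### Phenotypes

Cognitive batteries mix tests on arbitrary scales, so the general ability
phenotype is the score on the **first unrotated principal component** of the
column-standardised test matrix (`first_unrotated_pc()`). Standardising
before the decomposition (correlation-matrix PCA) is deliberate: raw-scale
PCA would let a test with a large score range dominate the component. One
consequence, exercised in the tests, is that component scores are exactly
invariant only under variance-preserving rotations of the battery (signed
permutations); a generic orthogonal rotation re-mixes columns before they
are re-standardised and preserves the scores only approximately. The
component is oriented so that higher scores mean better mean performance —
the sign of a principal component is otherwise arbitrary.

Age and sex effects are removed afterwards by ordinary least squares
(`residualize()`), returning standardised residuals (mean 0, SD 1, exactly
uncorrelated with both covariates); the composition of the two steps is the
standard derivation for the Scottish-cohort style of battery. A
`mean_composite()` of two adjusted phenotypes (fluid and crystallised) is
provided for the variant in which the general factor is the re-standardised
mean of the two; with inputs correlating at r the composite correlates with
each at √((1+r)/2). Rows with any missing test are dropped listwise —
model-based score imputation is a deliberate non-goal.

### Quality control and association

Marker filters use the conventional chip thresholds as strict inequalities:
call rate > 0.98, 1-df chi-square Hardy–Weinberg p > 0.001, MAF > 0.01;
individuals with call rate < 0.95 are removed first. The rules are marginal,
so the retained set does not depend on the order in which they are applied;
only the logged first-failing reason does (order: call rate, HWE, MAF). The
chi-square test (not the exact test) is used for HWE: at these thresholds
and sample sizes it is the field convention, and the threshold is a
tunable in `qc_thresholds()`.

Population structure is captured by the first k = 4 principal components of
the standardised dosage matrix (`genotype_pcs()`), standing in for classical
multidimensional scaling of an identity-by-state distance — the two are
near-equivalent, and PCA avoids a bespoke distance implementation without
changing the covariate contract.

`run_gwas()` fits, per SNP, ordinary least squares of the residualised
phenotype on intercept + dosage + ancestry PCs. Computation uses the
Frisch–Waugh–Lovell projection: the phenotype and all complete dosage
columns are residualised against the covariate block once, reducing the
genome scan to vectorised simple regressions; SNPs with missing calls fall
back to a per-SNP `lm()` on complete observations, and both routes are
checked against each other in the tests. P-values are clamped at 1e-300 so
downstream −log10 and chi-square conversions stay finite.

### Gene-based testing

The gene statistic is the **sum of the member SNPs' 1-df chi-square
statistics**, members being every QC-passing SNP within ±50 kb of the gene
body (inclusive bounds; membership is not exclusive between overlapping
windows). Direction of effect is discarded — the two-sided p is pushed
through the χ²(1) upper-tail quantile. Because members are in LD the sum is
not χ²(k); its null is obtained by simulation: draw z ~ N(0, R) with R the
member LD (dosage correlation) matrix, sum the squared components, and take
the empirical exceedance probability with the permutation convention
(count + 1)/(n + 1), which keeps p in (0, 1] at zero exceedances. Sample
correlation matrices from finite panels are routinely indefinite, so R is
repaired by clipping eigenvalues at 1e-10, reconstructing, and rescaling to
unit diagonal — the rescaling keeps the marginal null statistics exactly
χ²(1). Adaptive mode escalates the simulation size 10³ → 10⁴ → 10⁵ → 10⁶
until at least 10 exceedances are seen, bounding the relative Monte-Carlo
error of small p-values. The LD reference defaults to the analysis cohort
itself; any reference panel with the member SNPs can be supplied, and the
tests verify that an independent panel from the same generative process
moves gene p-values by less than Monte-Carlo noise.

### Clumping and genomic intervals

`clump()` reduces the scan to LD-independent association signals with
greedy PLINK-style semantics: the smallest-p unclaimed SNP with
p < 0.0005 seeds an index (ties break to the lower chromosome, then
position); every unclaimed, nominally significant (p < 0.05) SNP within
250 kb and with dosage r² > 0.5 against the index is claimed; the interval
spans the claimed SNPs' positions (not index ± window — intervals are
usually much narrower than the search window). "Below 0.0005" and
"r² > 0.5" are read as strict, "within 250 kb" as inclusive; all three
boundaries are pinned by tests. Intervals further than 20 kb from every
gene are discarded, and overlapping survivors are merged by sweep-line
union, the merged index SNP being the member with the smallest p. The three
counts (raw → gene-overlapping → merged) are reported for every run.

### The competitive set test

The observed statistic for a gene set is the number of merged intervals
lying within 20 kb of at least one set gene — an interval counts once no
matter how many set genes it covers. Significance is judged against
**matched permuted interval sets**: for each observed interval, a random
placement on the SNP-covered genome with the same overlapped-gene count
(exact for 1,000 attempts, then ±1 for another 1,000, then a hard error
naming the interval) and a member-SNP count within ±20% of observed,
placements spanning runs of consecutive panel SNPs so they inherit the
panel's SNP density. "Same LD structure" cannot be matched literally — the
notion is not well defined for an arbitrary placement — so the package
operationalises it two ways: the SNP-count band above, and **rigid cluster
placement**: observed intervals within 250 kb of each other on one
chromosome are relocated jointly with their SNP-index offsets preserved.
The second part matters. Clumped intervals cluster — neighbouring signals
whose r² falls below the 0.5 threshold stay separate yet often sit within
20 kb of the same gene — and a null that places intervals independently
underestimates the variance of the overlap statistic. In our null
simulations, independent placement produced a type-I error of ~0.085 at
α = 0.05; rigid cluster placement restores validity (the test becomes
slightly conservative, the expected direction for a tie-inclusive
exceedance count).

The empirical set p is the proportion of permuted statistics ≥ observed
(ties included, exactly as the estimator is defined); a zero count is
reported censored at the resolution floor 1/n_perm.

### Bootstrap correction across correlated gene sets

Keyword-derived gene-set collections overlap heavily, so Bonferroni or FDR
across sets would be badly conservative. The correction instead reuses the
permutation null: in each of B rounds one permuted interval set is promoted
to pseudo-observed (drawn with replacement — the source text does not say;
with replacement is the standard bootstrap and is the logged choice), its
empirical p against the remaining n−1 permutations is computed for every
set (its own permutation excluded to avoid self-comparison), and the
minimum over sets is recorded. The corrected p for a set is the proportion
of rounds whose minimum is at most that set's empirical p. Three limiting
behaviours pin the construction down, and all three are tested at
B = 1,000: a single set keeps its empirical p; duplicated (perfectly
correlated) sets do not inflate; K independent sets approach the Šidák
limit 1 − (1 − p*)^K.

## The synthetic cohort generator

`sim_config()` defaults describe the study conditions the pipeline targets:
3,500 unrelated older adults (ages 64–80), a biallelic SNP panel with MAF
drawn uniformly (0.05–0.5 by default, range configurable down to the 0.01
QC boundary), six cognitive tests loading 0.5–0.8 on one latent factor,
a mild negative age trend (−0.03 SD/year) and a small sex effect (0.1 SD) —
magnitudes chosen once as typical for ageing-cohort cognitive data. LD is
generated by a latent-Gaussian threshold model: each haplotype's latent
vector follows an AR(1) process with correlation ρ (default 0.8) inside
blocks of 10 SNPs and is independent across blocks; an allele is minor when
its latent value falls below the MAF quantile, and two independent
haplotypes per individual guarantee Hardy–Weinberg marginals. Dosage
correlation rises monotonically with ρ but is attenuated by thresholding
(ρ = 0.8 gives adjacent-dosage r² around 0.4) — so, deliberately, the
synthetic panel contains substantial sub-threshold LD, the regime in which
interval clustering stresses the permutation null. Causal effects are
specified per SNP in phenotype-SD-per-allele units; no effect size is
calibrated to any published estimate, since none exists for these
phenotypes — positive controls use planted effects sized for the simulated
cohort. What the generator does **not** emulate: realistic human LD maps
and recombination hotspots, imputation dosages, related individuals,
ancestry admixture gradients (populations are homogeneous unless two are
simulated explicitly), and X-chromosome genetics. Passing calibration here
shows the machinery is correct under the stated model, not that any given
real cohort satisfies that model.

Gene bodies are placed without overlap (1-based inclusive coordinates,
matching the fixture tables; BED export is the only 0-based surface), and
gene sets are sampled without replacement, optionally forcing causal genes
into one designated set.

## Numerical and design choices

* Empirical p conventions differ by level on purpose: the gene test uses
  (count+1)/(n+1) so its p is never 0; the set test uses count/n with
  explicit censoring at 1/n, following the estimator's printed definition.
* PSD repair clips eigenvalues at 1e-10; zero-variance or missing LD
  entries enter as 0 correlation.
* A monomorphic SNP has HWE p defined as 1 (nothing to test); its MAF of 0
  then fails the frequency filter.
* Residualisation treats an outcome that is an exact linear function of
  the covariates as an error (`gwaset_degenerate_residual`) rather than
  returning zero-variance noise.
* All randomness flows through per-operation integer seeds derived from
  the configuration seed; no function consults global RNG state, and
  identical configuration implies bit-identical output (tested).

## Problem sizes used by the test suite

Calibration properties are exercised at sizes chosen to make the
statistical assertions sharp: identity-LD gene-test calibration at 10⁵
simulations for k ∈ {1, 2, 5, 20}; null-GWAS gene-level uniformity on ten
cohorts of n = 2,000 with 5,000 SNPs and 100 genes; set-test type-I error
from 500 null permutations against 200 replicates; bootstrap limits at
B = 1,000; and end-to-end positive/negative controls on twenty cohorts each
of n = 800 with 2,000 SNPs and 100 genes, with the clumping index threshold
at 0.01 so that a desk-scale panel yields interval counts proportionate to
a full-scale analysis. The positive control plants ten causal SNPs of
0.15 SD/allele — per-SNP non-centrality at n = 800 comparable to an
aggregate ~2% heritability set in a full-size cohort.

## Known limitations

The set test inherits the conservatism of tie-inclusive exceedance counts
when interval counts are small; censored results ("< 1/n_perm") should be
re-run at larger n_perm before being quoted. Gene-count matching widens to
±1 after bounded retries rather than biasing the null silently, and rigid
cluster placement falls back to independent placement only when a genome
cannot host the cluster at all — both events are loud. Imputation,
relatedness handling and text-mining-based set construction are outside the
package's scope; gene sets arrive as GMT files, whatever produced them.
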