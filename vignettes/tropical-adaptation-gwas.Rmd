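---
title: "Admixture-aware GWAS for tropically adapted cattle: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Admixture-aware GWAS for tropically adapted cattle: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tropigwas)
```

`tropigwas` analyses adaptation traits in cattle populations that are
recent admixtures of the taurine (*Bos taurus*) and indicine
(*Bos indicus*) lineages. This vignette explains the statistical models
the package implements, the choices made where the design was genuinely
open, what the synthetic-data generator does and does not emulate, and
the numerical conventions. It states no empirical result beyond what the
package's tests and acceptance script themselves compute.

## The models

### Supervised ancestry

Each animal's genotype at SNP *j* (count of the B allele, 0/1/2) is
modelled as Binomial(2, π<sub>ij</sub>) with
π<sub>ij</sub> = λ<sub>i</sub>f<sub>Bj</sub> + (1−λ<sub>i</sub>)f<sub>Aj</sub>,
where f<sub>Aj</sub>, f<sub>Bj</sub> are the B-allele frequencies in the
taurine and indicine reference panels and λ<sub>i</sub> ∈ [0,1] is the
animal's indicine proportion. With the panels fixed (supervised mode) the
likelihood decouples across animals into independent one-dimensional
problems, so the package maximizes each λ<sub>i</sub> by EM on the
allele-origin posteriors rather than the block relaxation a general
admixture program needs. Convergence is declared at |Δλ| < 10⁻⁸ or 500
iterations; the EM update is monotone in the likelihood. Panel
frequencies from genotype panels get a +0.5/+1 pseudocount so fixed sites
never produce log(0); frequencies are clamped to [10⁻⁴, 1−10⁻⁴]. If the
two panels are identical at every SNP, λ is unidentifiable: the estimate
is returned as 0.5 with a `degenerate` flag rather than an arbitrary
optimum. An LD-pruned SNP set is the recommended input, since the
binomial likelihood treats SNPs as independent.

Only the two-population supervised case is implemented (no K > 2, no
local ancestry). A third ancestry axis, where present in real data, shows
up in the second MDS coordinate but is not modelled.

### Animal-model REML

Heritability uses the standard animal model y = Xb + g + e,
Var(g) = σ²<sub>g</sub>K, Var(e) = σ²<sub>e</sub>I, where K is either the
VanRaden method-1 genomic relationship matrix
(ZZ′/2Σp(1−p), Z the dosage matrix centred by 2p) or the pedigree
numerator relationship matrix from the tabular recursion. Eigendecomposing
K once rotates the model so the covariance is diagonal, reducing REML to
a one-dimensional profile likelihood in δ = σ²<sub>g</sub>/σ²<sub>e</sub>,
searched on log δ ∈ [−12, 12] by Brent's method. This is exact for the
single-random-effect model class and costs one O(n³) decomposition. A
boundary fit (δ → 0) is detected by comparing against the no-genetics
profile value. The SE of h² comes from the finite-difference curvature of
the profile likelihood via the delta method. A non-positive-semi-definite
K (possible after subsetting or with near-duplicate animals) is bent by
lifting its smallest eigenvalues to 10⁻⁶, with a warning.

Heritability is reported as σ²<sub>g</sub>/(σ²<sub>g</sub>+σ²<sub>e</sub>);
fixed-effect variance is excluded, the usual animal-model convention.

The default fixed effects are: contemporary group (sex × year × location,
categorical), age of dam, the ancestry proportion as a linear covariate,
and optionally an AGE12 covariate for the yearling-weight analogue. Age
of dam is linear by default with a categorical option — its functional
form matters little for the variance components and the linear form
keeps the design full-rank in small cohorts. Where field descriptions of
the contemporary group differ (with or without sex), both are available
through `model_spec`; sex × year × location is the default.

### Genetic correlations (a deliberate simplification)

Full bivariate REML is replaced by the sum-trait identity: after
adjusting both traits for their fixed effects and standardizing,
rg = [Vg(x+y) − Vg(x) − Vg(y)] / (2√(Vg(x)Vg(y))), with each genetic
variance from the univariate maximizer above and the result clamped to
[−1, 1]. This reuses one well-tested estimator three times instead of
introducing a multivariate optimizer; its sampling error is larger than
a true bivariate fit, which is why correlation estimates are treated as
descriptive here and compared between cohorts only through the paired
t-test on the 45 trait pairs (`compare_correlation_sets`). Phenotypic
correlations are Pearson correlations of the fixed-effect-adjusted
residuals.

### Mixed-model association

The scan adds each SNP's dosage to the fixed effects while holding the
polygenic covariance at the null-model REML estimates — variance
components are fitted once without any SNP and reused for every SNP.
Refitting per SNP changes results negligibly when any single SNP explains
a small share of variance, and the single-fit form lets the whole scan
reuse one rotation of the genotype matrix: after rotating, each test is
a weighted least-squares residual regression, and a 10-trait × 20,000-SNP
scan is a few matrix products (`gwas_scan_multitrait` shares the rotation
across traits). Two-sided P-values use the normal approximation to the
GLS t-ratio, appropriate at the cohort sizes the package targets
(hundreds to thousands). Monomorphic SNPs, SNPs below the call-rate
threshold (default 0.9) and SNPs collinear with the covariates are
flagged, not tested. Missing dosages are mean-imputed within SNP for the
scan and the GRM; r² uses pairwise-complete observations.

The share of genetic variance attributed to a SNP is
%Vg = 100·2p(1−p)a²/σ²<sub>g</sub> with the cohort's own allele
frequency; it is allele-flip invariant, not capped at 100, and flagged
when it exceeds 100 (an effect estimate larger than the whole genetic
variance, a sign of overfitting or tiny σ²<sub>g</sub>).

### FDR and significance accounting

The explicit estimator fdr = P(1−S/T)/((S/T)(1−P)) converts a count S of
SNPs significant at threshold P out of T tested into an expected
false-discovery proportion; S = 0 leaves it undefined (reported as 1 with
a flag) and values are capped at 1. Downstream thresholds are used
exactly as stated in the analysis constants: 0.001 for the per-trait
tables, 0.0001 for chromosome heat-map counts, 5×10⁻⁸ for genome-wide
claims. No correction is applied inside the scan itself.

### Multi-trait pleiotropy

For SNP *i*, the studentized effects across the k traits form
t<sub>i</sub>; under the null of no effect on any trait,
Q = t<sub>i</sub>′V⁻¹t<sub>i</sub> is approximately χ²<sub>k</sub>, where
V is the correlation matrix of SNP effects across traits, estimated from
all SNPs (an option restricts estimation to null-like SNPs with all
|t| < 2, default off, since genome-wide the signal fraction is small). V
near-singularity — e.g. duplicated traits — is repaired by flooring
eigenvalues at 10⁻⁶ and renormalizing to unit diagonal, with a warning.
The significance cut-off for ten traits at α = 0.001 is the χ²₁₀ quantile
29.588; because the test is applied to SNPs already vetted by the
single-trait scans, no further multiplicity correction is layered on.
Antagonistic loci are reported where two traits' studentized effects have
opposite signs with both |t| ≥ 2.

### Divergent alleles and candidate genes

A SNP is "divergent" when one allele has frequency strictly above 0.95 in
the taurine panel and strictly below 0.05 in the indicine panel; that
allele is the taurine allele, and per-animal scores sum its dosage over a
SNP set (missing calls are excluded and the score rescaled to the full
set size, then rounded). Score-trait association contrasts a target
region's score against scores from random same-size selections of
divergent SNPs drawn outside excluded chromosomes.

Positional candidate genes require a SNP within 3,000 bp of the gene
interval (nearest-edge distance, 0 inside) associated at P < 0.01 in both
cohorts with the same effect sign under a shared allele coding. Sign
agreement is used as the coding-independent core of "same favourable
allele", since trait polarity (whether low or high values are favourable)
is metadata the genotype file does not carry. The gene-interval distance
test uses GenomicRanges. The differential-expression join marks genes
present in the supplied DE table at P < 0.05; the DE analysis itself is
an input, never recomputed.

## The synthetic-data generator

The generator exists so every stage can be validated against known truth
at desk scale, emulating the crossbred study design the package targets:

- **Ancestral panels**: a Balding–Nichols model; per SNP a common
  ancestral frequency f ~ Uniform(0.05, 0.95) and population frequencies
  Beta(f(1−d)/d, (1−f)(1−d)/d), so d is an Fst-like divergence (the
  package's tests confirm Hudson-style Fst ≈ d on sampled panels; d = 0.2
  is the default working value for the taurine/indicine split). A chosen
  number of SNPs is made highly divergent by construction to exercise the
  divergent-allele machinery.
- **Cohort**: sires drawn from a Beta-mixture ancestry distribution with
  modes 0.30 and 0.95 (the two modes observed in composite and
  near-purebred tropical cattle), offspring assigned to sires
  multinomially into paternal half-sib families, dams unique. Each
  offspring receives one allele transmitted from its sire's genotype and
  one maternal allele drawn at the dam's λ-mixed frequency; marginally
  every allele is Bernoulli at the λ-mixed frequency, while the shared
  paternal genotypes create the half-sib blocks visible in the
  relationship matrix. Dams share the sire's mixture component
  (assortative by population), which keeps the offspring ancestry
  distribution bimodal at the configured modes instead of blurring into
  a three-mode convolution. Global ancestry is applied uniformly across
  SNPs — no local-ancestry tracts, no recombination map — because all
  downstream analyses use only global λ.
- **Traits**: trait = contemporary-group effect + age-of-dam slope +
  ancestry slope (optionally piecewise around a threshold, to generate
  subgroup sign flips) + QTL effects + polygenic value + residual, on a
  unit phenotypic-variance scale with σ²<sub>g</sub> = h² and
  σ²<sub>e</sub> = 1−h². QTL allele-substitution effects are back-solved
  from target variance shares, a = ±√(pct·σ²<sub>g</sub>/(100·2pq)), at
  the cohort's realized allele frequency; a monomorphic QTL is an error
  naming the SNP. The polygenic value assigns every non-QTL SNP a small
  effect, correlated across traits by the configured genetic correlation
  matrix.

Two generator choices deserve emphasis. First, polygenic values are made
orthogonal to λ: in an admixed cohort the relationship matrix has a
dominant ancestry axis, and a polygenic draw aligned with it carries a
single χ²₁-distributed slice of genetic variance, so realized and
parameter variances diverge wildly between replicates. The analysis model
fits λ as a fixed covariate and therefore attributes ancestry-aligned
trait differences to that covariate anyway; the generator mirrors this
decomposition, and mean ancestry effects are injected explicitly through
`ancestry_slope`. Second, the polygenic scale is set so the implied
per-SNP effect variance is σ²<sub>poly</sub>/(2Σpq) — the same scale the
GRM-based REML estimates — rather than forcing the sample variance of
breeding values to the target, which would re-introduce the
realized-vs-parameter mismatch.

What the generator does **not** emulate: linkage and LD decay along the
chromosome (SNPs are exchangeable given ancestry), genotyping error and
missingness patterns, selection, maternal effects, repeated measures, and
local-ancestry structure. Tests passing on this generator therefore
validate the estimators' statistical correctness under the stated model,
not robustness to those real-data features.

## Numerical conventions and edge cases

- Coordinates are 1-based in all file output (PLINK/VCF convention);
  genotypes are counts of the B/ALT allele; a `.bed` round trip is
  bit-exact including missingness.
- LD pruning: windows of 50 currently retained SNPs advanced by 10, per
  chromosome; within a window the highest-r² violating pair loses its
  lower-MAF member (later index on ties); sweeps repeat until a full pass
  removes nothing. The literal one-pass reading of the windowed rule can
  strand islands of perfectly correlated SNPs when a window collapses and
  the 10-SNP step jumps over survivors; running to the fixed point makes
  the output idempotent and guarantees no final window contains a
  violating pair, which is the property downstream analyses rely on.
- r² of a pair monomorphic among jointly observed animals is undefined
  and treated as 0 (no LD) with a flag, so pruning never stalls on
  degenerate pairs.
- The paired comparison of correlation sets distinguishes "no difference
  at all" (all differences zero: t = 0, P = 1) from "constant non-zero
  difference" (zero variance: degenerate flag, no t), both up to a 10⁻¹⁰
  relative tolerance.
- All simulations are seed-deterministic: identical seeds give
  bit-identical genotypes, phenotypes and result tables; the pipeline
  writes the seed into every output header.

## Problem sizes used in the test suite

The suite validates at sizes a desk machine handles in minutes: cohorts
of 300–2,000 animals, 1,000–20,000 SNPs. The pleiotropy type-I
calibration runs the full chain (simulate → 10 REML fits → 10 scans →
V → Q) at 20,000 SNPs × 1,000 animals and checks the exceedance of
29.588 lies in [0.0003, 0.003]; heritability recovery averages five
replicates at n = 2,000 with a 10,000-SNP GRM (a single GREML replicate
at that size has sampling SE ≈ 0.06, so the mean is the meaningful bias
check); ancestry recovery requires RMSE < 0.03 at divergence 0.2; a QTL
at 10% of genetic variance must reach P < 5×10⁻⁸ in ≥ 9 of 10 replicates.
The analysis workflow in `analysis/` uses a 1,000-animal × 6,000-SNP
study as its running example.

## Known limitations

- The genetic-correlation estimator trades efficiency for simplicity;
  its estimates carry wider sampling error than bivariate REML and are
  not intended as reference values.
- The scan's single-fit approximation slightly misstates SEs for SNPs of
  very large effect (where the null variance components are no longer
  those of the SNP-conditional model).
- The EM ancestry estimator treats SNPs as independent; residual LD in
  the pruned set mildly overstates the likelihood's sharpness (point
  estimates are unaffected in practice, as the recovery tests show).
- Pedigree NRM construction is O(n²) dense — adequate for tens of
  thousands of animals, not for national evaluations.
- X-chromosome dosage handling is out of scope; non-autosomal SNPs should
  be excluded before pruning-dependent analyses.
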