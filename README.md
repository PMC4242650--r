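# tropigwas

Quantitative-genetics toolkit for genome-wide association in admixed
taurine × indicine cattle. Tropical beef populations are typically crosses
between *Bos taurus* (taurine) and *Bos indicus* (indicine/zebu) lineages,
recorded for adaptation traits — temperament, rectal temperature, parasite
burdens, coat characters, sheath score, body condition, yearling weight —
in paternal half-sib family designs. Analysing such data requires keeping
three things apart at once: global ancestry (a fixed covariate), family
relatedness (a random polygenic effect), and individual loci of large
effect. `tropigwas` implements that full chain as a tested R package plus
a numbered analysis workflow.

## What the package computes

- **Supervised ancestry (`estimate_ancestry_supervised`)** — per animal,
  the proportion λ attributable to the indicine reference panel, from the
  binomial likelihood g<sub>ij</sub> ~ Bin(2, λ<sub>i</sub>f<sub>Bj</sub> +
  (1−λ<sub>i</sub>)f<sub>Aj</sub>), maximized by EM per individual.
- **Animal-model REML (`reml_fit`)** — y = Xb + g + e with
  Var(g) = σ²<sub>g</sub>K for a genomic (VanRaden) or pedigree (tabular)
  relationship matrix; profile REML over σ²<sub>g</sub>/σ²<sub>e</sub> on
  the eigenbasis of K; h² = σ²<sub>g</sub>/(σ²<sub>g</sub>+σ²<sub>e</sub>).
- **Mixed-model GWAS (`gwas_scan`)** — each SNP's 0/1/2 dosage added to
  the fixed effects with the polygenic covariance held at the null REML
  fit (single-fit approximation); effects, SEs, studentized effects t and
  two-sided P per SNP; genomic-control diagnostics.
- **Per-SNP variance share (`percent_genetic_variance`)** —
  %Vg = 100·2p(1−p)a²/σ²<sub>g</sub>.
- **Explicit FDR (`fdr_at_threshold`)** —
  fdr = P(1−S/T) / ((S/T)(1−P)) for S SNPs significant at threshold P out
  of T tested.
- **Multi-trait pleiotropy (`pleiotropy_scan`)** — Q = t′V⁻¹t over the
  traits' studentized effects, V the SNP-effect correlation matrix,
  compared to the χ² quantile with one df per trait (29.588 for 10 traits
  at α = 0.001).
- **Divergent-allele scores (`identify_divergent_snps`,
  `taurine_allele_score`)** — SNPs with one allele > 0.95 in the taurine
  panel and < 0.05 in the indicine panel; per-animal summed "taurine
  allele" dosages and their association versus random control SNP sets.
- **Synthetic cohorts (`simulate_ancestral_panels`,
  `simulate_admixed_cohort`, `simulate_traits`)** — Balding–Nichols
  diverged panels, bimodal-ancestry half-sib cohorts, and ten correlated
  traits with configurable heritabilities, QTL and fixed effects; every
  analysis above is validated against this generator's known truth.

Genotype I/O covers PLINK 1.x binary (.bed/.bim/.fam) and biallelic VCF;
LD pruning follows the 50-SNP/10-step sliding-window r² > 0.5 rule.

## Worked example

```r
library(tropigwas)

panels <- simulate_ancestral_panels(5000, divergence = 0.2,
                                    n_divergent = 50, seed = 7)
cfg <- simulation_config(n_individuals = 400, n_sires = 20,
                         h2_targets = c(COND = 0.4),
                         qtl_spec = data.frame(snp = 2500, trait = "COND",
                                               pct_vg = 20, sign = 1),
                         seed = 7)
cohort <- simulate_admixed_cohort(panels, cfg)
traits <- simulate_traits(cohort, cfg)

est <- estimate_ancestry_supervised(cohort$genotypes,
                                    panels$freq_A, panels$freq_B)
sqrt(mean((est$lambda_hat - cohort$truth$lambda)^2))
#> [1] 0.01347882

K <- genomic_relationship(cohort$genotypes)
fit <- reml_fit(traits$phenotypes$COND, model_spec("COND"), K,
                phenotypes = traits$phenotypes)
fit
#> reml_fit: sigma2_g = 0.5351, sigma2_e = 0.4447, h2 = 0.546 (SE 0.163)

scan <- gwas_scan(cohort$genotypes, traits$phenotypes, K,
                  model_spec("COND"), null_fit = fit)
scan[scan$snp == "snp002500", c("a", "se", "t", "neglog10p", "pct_vg")]
#>              a        se        t neglog10p   pct_vg
#> 2500 0.6729066 0.1021802 6.585488  10.34352 23.17413
```

The ancestry RMSE (~0.013) shows λ is recovered almost exactly at
divergence 0.2; the REML h² lands within one SE of the simulated 0.4 (a
400-animal cohort leaves h² a wide SE); the planted QTL (20 %Vg) is
genome-wide significant (−log₁₀P ≈ 10.3) with its variance share
re-estimated near the target.

## Analysis workflow

`analysis/01_simulate.R` … `05_pleiotropy.R` run the full narrative on one
simulated study (seed and sizes in `analysis/00_config.R`): cohort
simulation and file export → LD pruning, ancestry, MDS → REML
heritabilities, trait correlations, ancestry effects split at 30%
indicine → ten-trait GWAS with FDR table, chromosome heat-map counts,
sliding allele-frequency profile, divergent-score contrast → pleiotropy
scan, antagonistic loci, positional candidate genes against a synthetic
annotation + differential-expression table. Each stage writes
tab-separated tables with provenance headers under `results/analysis/`.
`run_pipeline()` wraps the same chain as a single call.

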