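#!/usr/bin/env Rscript
# Stage 1: simulate the admixed half-sib cohort, its reference panels and
# ten correlated phenotypes; write genotypes (PLINK and VCF), pedigree and
# phenotype tables under results/analysis/.

source("analysis/00_config.R")

panels <- make_panels()
cfg <- sim_config()
cohort <- simulate_admixed_cohort(panels, cfg)
traits <- simulate_traits(cohort, cfg)

write_genotypes(cohort$genotypes, file.path(OUT, "cohort.bed"), "plink")
refs <- sample_panel_genotypes(panels, 81, 91, seed = SEED)
write_genotypes(refs$A, file.path(OUT, "panel_taurine.vcf"), "vcf")
write_genotypes(refs$B, file.path(OUT, "panel_indicine.vcf"), "vcf")

write_result_table(cohort$pedigree, file.path(OUT, "pedigree.tsv"), SEED)
write_result_table(traits$phenotypes, file.path(OUT, "phenotypes.tsv"),
                   SEED)
write_result_table(
  data.frame(snp = cohort$genotypes$snps$id,
             freq_taurine_panel = panels$freq_A,
             freq_indicine_panel = panels$freq_B),
  file.path(OUT, "panel_frequencies.tsv"), SEED)

lam <- cohort$truth$lambda
cat(sprintf("cohort: %d offspring in %d half-sib families, %d SNPs\n",
            nrow(cohort$genotypes$data), N_SIRES, N_SNPS))
cat(sprintf("true indicine%%: mean %.2f, quartiles %.2f / %.2f / %.2f\n",
            mean(lam), quantile(lam, 0.25), median(lam),
            quantile(lam, 0.75)))
cat(sprintf("realized QTL variance shares:\n"))
print(traits$truth$qtl[, c("snp", "trait", "p", "target_pct_vg")])
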