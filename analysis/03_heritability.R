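#!/usr/bin/env Rscript
# Stage 3: animal-model REML per trait against the genomic relationship
# matrix, pairwise genetic/phenotypic correlations for the first traits,
# and the ancestry-effect linear models with the 30% subgroup split.

source("analysis/00_config.R")

gm <- read_genotypes(file.path(OUT, "cohort.bed"))
pheno <- read_result_table(file.path(OUT, "phenotypes.tsv"))
anc <- read_result_table(file.path(OUT, "ancestry.tsv"))
pheno$lambda_hat <- anc$lambda_hat
pheno$cg <- factor(pheno$cg)

K <- genomic_relationship(gm)
eig <- tropigwas:::relmat_eigen(unclass(K))

traits <- names(H2)
reml_tbl <- do.call(rbind, lapply(traits, function(tr) {
  ms <- model_spec(tr, ancestry = "lambda_hat",
                   age12 = if (tr == "YWT") "age12" else NULL)
  fit <- reml_fit(pheno[[tr]], tropigwas:::design_matrix(pheno, ms),
                  eig = eig)
  data.frame(trait = tr, sigma2_g = fit$sigma2_g,
             sigma2_e = fit$sigma2_e, h2 = fit$h2, se_h2 = fit$se_h2,
             converged = fit$converged)
}))
write_result_table(reml_tbl, file.path(OUT, "heritability.tsv"), SEED)
cat("REML heritabilities (target -> estimate):\n")
for (tr in traits)
  cat(sprintf("  %-7s %.2f -> %.3f (SE %.3f)\n", tr, H2[[tr]],
              reml_tbl$h2[reml_tbl$trait == tr],
              reml_tbl$se_h2[reml_tbl$trait == tr]))

# pairwise correlations among the first four traits
pick <- traits[1:4]
pairs <- t(combn(pick, 2))
cor_tbl <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
  mx <- model_spec(pairs[i, 1], ancestry = "lambda_hat")
  my <- model_spec(pairs[i, 2], ancestry = "lambda_hat")
  data.frame(trait_x = pairs[i, 1], trait_y = pairs[i, 2],
             rg = suppressWarnings(
               genetic_correlation(pheno, K, mx, my))$rg,
             rp = phenotypic_correlation(pheno, mx, my))
}))
write_result_table(cor_tbl, file.path(OUT, "correlations.tsv"), SEED)

# ancestry effects per trait, full sample and split at 30%
anc_tbl <- do.call(rbind, lapply(traits, function(tr) {
  ms <- model_spec(tr, ancestry = "lambda_hat")
  rbind(ancestry_effect(pheno, ms, "all"),
        ancestry_effect(pheno, ms, "below"),
        ancestry_effect(pheno, ms, "at_or_above"))
}))
write_result_table(anc_tbl, file.path(OUT, "ancestry_effects.tsv"), SEED)
epg <- anc_tbl[anc_tbl$trait == "EPG", ]
cat(sprintf("EPG ancestry slope: below 30%% = %.2f, at/above = %.2f\n",
            epg$estimate[epg$subgroup == "below"],
            epg$estimate[epg$subgroup == "at_or_above"]))
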