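#!/usr/bin/env Rscript
# Stage 2: LD-prune the cohort genotypes, estimate supervised indicine%
# against the two reference panels, check robustness to the panel choice,
# and summarize population structure by MDS.

source("analysis/00_config.R")

gm <- read_genotypes(file.path(OUT, "cohort.bed"))
freqs <- read_result_table(file.path(OUT, "panel_frequencies.tsv"))
pheno <- read_result_table(file.path(OUT, "phenotypes.tsv"))

pruned <- ld_prune(gm)
cat(sprintf("LD pruning: %d of %d SNPs retained (r2 <= 0.5, 50/10 window)\n",
            length(pruned), ncol(gm$data)))

est <- estimate_ancestry_supervised(gm[, pruned],
                                    freqs$freq_taurine_panel[pruned],
                                    freqs$freq_indicine_panel[pruned])
write_result_table(est, file.path(OUT, "ancestry.tsv"), SEED,
                   c(n_pruned_snps = length(pruned)))

rmse <- sqrt(mean((est$lambda_hat - pheno$lambda_true)^2))
cat(sprintf("supervised ancestry: RMSE vs generating lambda = %.4f\n",
            rmse))
sp <- split_by_ancestry(est, 0.30)
cat(sprintf("ancestry split at 30%%: %d below, %d at-or-above\n",
            length(sp$below), length(sp$at_or_above)))

# panel sensitivity: two independent taurine panel subsamples
panels <- make_panels()
refs <- sample_panel_genotypes(panels, 80, 91, seed = SEED + 1)
ps <- panel_sensitivity(gm[, pruned],
                        list(half1 = list(A = refs$A[1:40, pruned],
                                          B = refs$B[, pruned]),
                             half2 = list(A = refs$A[41:80, pruned],
                                          B = refs$B[, pruned])))
cat(sprintf("alternative taurine panels: r = %.3f between estimates\n",
            ps$correlations["half1", "half2"]))

fit <- mds(gm[, pruned], k = 2)
write_result_table(
  data.frame(id = gm$ids, mds1 = fit$points[, 1], mds2 = fit$points[, 2],
             lambda_hat = est$lambda_hat),
  file.path(OUT, "mds.tsv"), SEED)
cat(sprintf("MDS axis 1 vs indicine%%: |r| = %.3f\n",
            abs(cor(fit$points[, 1], est$lambda_hat))))
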