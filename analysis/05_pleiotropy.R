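#!/usr/bin/env Rscript
# Stage 5: multi-trait pleiotropy test on the studentized effects from
# stage 4, antagonistic-effect report, and positional candidate genes
# against a synthetic annotation and differential-expression table.

source("analysis/00_config.R")

gm <- read_genotypes(file.path(OUT, "cohort.bed"))
gwas_all <- read_result_table(file.path(OUT, "gwas.tsv"))

t_matrix <- do.call(cbind, lapply(names(H2), function(tr)
  gwas_all$t[gwas_all$trait == tr]))
colnames(t_matrix) <- names(H2)
rownames(t_matrix) <- gwas_all$snp[gwas_all$trait == names(H2)[1]]

pl <- pleiotropy_scan(t_matrix)
write_result_table(
  cbind(snp = rownames(t_matrix), pl$table),
  file.path(OUT, "pleiotropy.tsv"), SEED,
  c(critical = sprintf("%.3f", pl$critical)))
cat(sprintf("pleiotropy: %d of %d SNPs exceed Q = %.3f (fraction %.4f)\n",
            sum(pl$table$significant, na.rm = TRUE), nrow(t_matrix),
            pl$critical, pl$exceedance_fraction))

ant <- antagonism_report(t_matrix, rbind(c("COND", "YWT"),
                                         c("SHEATH", "EPG")))
write_result_table(ant, file.path(OUT, "antagonism.tsv"), SEED)
cat(sprintf("antagonistic SNPs (|t| >= 2, opposite signs): %d rows\n",
            nrow(ant)))

# synthetic annotation: 40 genes tiled around the pleiotropic QTL region,
# plus a synthetic DE table in which half the genes respond
qtl_pos <- gm$snps$pos[QTL$snp[1]]
qtl_chrom <- gm$snps$chrom[QTL$snp[1]]
set.seed(SEED)
genes <- data.frame(gene = sprintf("GENE%02d", 1:40),
                    chrom = qtl_chrom,
                    start = qtl_pos + seq(-2e6, 2e6, length.out = 40),
                    end = qtl_pos + seq(-2e6, 2e6, length.out = 40) + 2e4)
# one gene spans the QTL itself (the positional-candidate case of interest)
genes$start[20] <- qtl_pos - 1e4
genes$end[20] <- qtl_pos + 1e4
genes$start <- as.integer(pmax(genes$start, 1))
genes$end <- as.integer(genes$end)
de <- data.frame(gene = genes$gene,
                 fold_change = rnorm(40, 0, 2),
                 p = ifelse(seq_len(40) %% 2 == 0, 0.01, 0.5))

# two "cohorts": split the sample in half and rescan body condition
pheno <- read_result_table(file.path(OUT, "phenotypes.tsv"))
anc <- read_result_table(file.path(OUT, "ancestry.tsv"))
pheno$lambda_hat <- anc$lambda_hat
pheno$cg <- factor(pheno$cg)
K <- genomic_relationship(gm)
half1 <- seq_len(nrow(pheno)) %% 2 == 1
ms <- model_spec("COND", ancestry = "lambda_hat")
sub_scan <- function(keep) {
  suppressWarnings(gwas_scan(gm[keep, ], pheno[keep, ],
                             unclass(K)[keep, keep], ms))
}
s1 <- sub_scan(half1)
s2 <- sub_scan(!half1)
cand <- candidate_gene_intersection(s1, s2, genes, de)
write_result_table(cand, file.path(OUT, "candidate_genes.tsv"), SEED)
cat(sprintf("candidate genes (P<0.01 both halves, <=3 kb, same sign): %d; %d with DE support\n",
            nrow(cand), sum(cand$de_match)))
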