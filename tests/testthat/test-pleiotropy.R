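test_that("effect correlations are clean for independent traits and
           repaired when singular", {
  set.seed(11)
  Tm <- matrix(rnorm(10000 * 4), ncol = 4,
               dimnames = list(NULL, paste0("T", 1:4)))
  V <- effect_correlation(Tm)
  expect_equal(unname(diag(V)), rep(1, 4))
  expect_lt(max(abs(V[upper.tri(V)])), 0.05)
  expect_false(attr(V, "repaired"))
  # duplicated trait column: perfect correlation, repair kicks in
  Tm2 <- cbind(Tm, T5 = Tm[, 1])
  expect_warning(V2 <- effect_correlation(Tm2), "singular")
  expect_true(attr(V2, "repaired"))
  expect_gt(V2["T1", "T5"], 0.99)
  # repaired matrix is invertible
  expect_no_error(solve(unclass(V2)))
})

test_that("chi-squared critical values match the reference quantiles", {
  expect_equal(round(chi2_critical(10, 0.001), 3), 29.588)
  expect_equal(round(chi2_critical(1, 0.05), 3), 3.841)
  # alpha -> 1 limit: critical value decreases to 0
  alphas <- c(0.5, 0.99, 0.999999, 1 - 1e-12)
  crits <- vapply(alphas, chi2_critical, numeric(1), df = 10)
  expect_true(all(diff(crits) < 0))
  expect_lt(chi2_critical(1, 1 - 1e-12), 1e-9)
  expect_error(chi2_critical(0, 0.05), "df")
})

test_that("the quadratic form matches hand computation and its invariances", {
  # zero vector: Q = 0, not significant
  z <- pleiotropy_statistic(rep(0, 10), diag(10))
  expect_equal(z$Q, 0)
  expect_false(z$significant)
  # identity V, unit effects over 10 traits: Q = sum t^2 = 10
  expect_equal(pleiotropy_statistic(rep(1, 10), diag(10))$Q, 10)
  # V = [[1, .5], [.5, 1]], t = (2, 2): hand inversion gives 16/3
  q <- pleiotropy_statistic(c(2, 2), matrix(c(1, 0.5, 0.5, 1), 2))$Q
  expect_equal(q, 16 / 3, tolerance = 1e-12)
  # congruence: permuting traits in t and V together leaves Q unchanged
  set.seed(4)
  V <- effect_correlation(matrix(rnorm(500 * 5), ncol = 5))
  t5 <- c(1.2, -0.4, 2.5, 0.3, -1.8)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(pleiotropy_statistic(t5[perm],
                                    unclass(V)[perm, perm])$Q,
               pleiotropy_statistic(t5, V)$Q, tolerance = 1e-10)
})

test_that("the pleiotropy scan is calibrated on a synthetic null and
           powered for multi-trait effects", {
  set.seed(12)
  # correlated null studentized effects: MVN with known V
  k <- 10
  V0 <- 0.3 ^ abs(outer(1:k, 1:k, `-`))
  L <- chol(V0)
  Tm <- matrix(rnorm(5000 * k), ncol = k) %*% L
  scan <- pleiotropy_scan(Tm)
  expect_gte(scan$exceedance_fraction, 0.0001)
  expect_lte(scan$exceedance_fraction, 0.003)
  expect_true(all(scan$table$Q >= 0))
  # a SNP affecting 3 of 10 traits at |t| ~ 4 is detected
  hits <- 0L
  for (r in 1:20) {
    t_alt <- drop(rnorm(k) %*% L)
    t_alt[c(1, 4, 7)] <- t_alt[c(1, 4, 7)] + c(4, -4, 4)
    if (pleiotropy_statistic(t_alt, scan$V)$significant) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("antagonistic SNPs are reported only above threshold with
           opposite signs", {
  Tm <- rbind(c(6.3, -5.0), c(1.9, -6.0), c(3.0, 2.5), c(-2.1, 2.0))
  colnames(Tm) <- c("COND", "YWT")
  rownames(Tm) <- paste0("s", 1:4)
  rep <- antagonism_report(Tm, cbind("COND", "YWT"))
  expect_identical(rep$snp, c("s1", "s4"))   # s2 below threshold, s3 same sign
  expect_true(all(sign(rep$t_x) * sign(rep$t_y) < 0))
})

test_that("candidate genes require replication, proximity and sign
           agreement", {
  mk_res <- function(p, a) {
    structure(data.frame(snp = c("s1", "s2", "s3"), chrom = "1",
                         pos = c(10000L, 50000L, 90000L), trait = "C",
                         a = a, se = 1, t = a, p = p,
                         neglog10p = -log10(p), pct_vg = 1,
                         stringsAsFactors = FALSE),
              class = c("assoc_result", "data.frame"))
  }
  ann <- data.frame(gene = c("G1", "G2", "G3"), chrom = "1",
                    start = c(12500L, 53500L, 200000L),
                    end = c(14000L, 55000L, 210000L))
  de <- data.frame(gene = c("G1", "G3"), fold_change = c(2.5, -1.2),
                   p = c(0.01, 0.5))
  r1 <- mk_res(c(0.005, 0.004, 0.5), c(1, 1, 1))
  r2 <- mk_res(c(0.004, 0.008, 0.5), c(2, -1, 2))
  out <- candidate_gene_intersection(r1, r2, ann, de)
  # G1: s1 at 2,500 bp, P < 0.01 both, signs agree -> included, DE match
  expect_identical(out$gene, "G1")
  expect_equal(out$distance, 2500 - 1)  # nearest-edge gap in bp
  expect_true(out$de_match)
  # G2 fails the sign-agreement rule; boundary: move G1 3,500 bp away
  ann2 <- ann
  ann2$start[1] <- 13501L
  out2 <- candidate_gene_intersection(r1, r2, ann2, de)
  expect_false("G1" %in% out2$gene)
})

test_that("a QTL inside a gene is the gene recovered from simulation", {
  hits <- 0L
  for (r in 1:10) {
    panels <- simulate_ancestral_panels(800, 0.2, seed = 900 + r)
    qtl_snp <- 400L
    cfg <- simulation_config(n_individuals = 500, n_sires = 20,
                             h2_targets = c(A = 0.5),
                             qtl_spec = data.frame(snp = qtl_snp,
                                                   trait = "A",
                                                   pct_vg = 40, sign = 1),
                             seed = 900 + r)
    co <- simulate_admixed_cohort(panels, cfg)
    # two independent phenotype draws over the same genotypes = two cohorts
    cfg2 <- cfg; cfg2$seed <- cfg$seed + 5000L
    tr1 <- simulate_traits(co, cfg)
    tr2 <- simulate_traits(co, cfg2)
    K <- genomic_relationship(co$genotypes)
    sub <- (qtl_snp - 30):(qtl_snp + 30)
    s1 <- suppressWarnings(gwas_scan(co$genotypes, tr1$phenotypes, K,
                                     model_spec("A"), snp_subset = sub))
    s2 <- suppressWarnings(gwas_scan(co$genotypes, tr2$phenotypes, K,
                                     model_spec("A"), snp_subset = sub))
    snps <- co$genotypes$snps
    genes <- data.frame(gene = paste0("G", 1:10),
                        chrom = snps$chrom[qtl_snp],
                        start = snps$pos[qtl_snp] + (-5:4) * 50000L - 100L,
                        end = snps$pos[qtl_snp] + (-5:4) * 50000L + 100L)
    genes$start[6] <- snps$pos[qtl_snp] - 100L   # G6 spans the QTL
    genes$end[6] <- snps$pos[qtl_snp] + 100L
    out <- candidate_gene_intersection(s1, s2, genes, NULL)
    if ("G6" %in% out$gene) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
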