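test_that("percent genetic variance follows the closed formula", {
  # p = 0.5, a = 1, sigma2_g = 2: 100 * 2*0.25*1 / 2 = 25
  expect_equal(as.numeric(percent_genetic_variance(0.5, 1, 2)), 25.0)
  # anchored example: a = -0.141, sigma2_g = 0.175, p = 0.468 -> 5.66
  expect_equal(round(as.numeric(
    percent_genetic_variance(0.468, -0.141, 0.175)), 2), 5.66)
  # allele-flip invariance
  expect_equal(as.numeric(percent_genetic_variance(0.3, 0.7, 1.1)),
               as.numeric(percent_genetic_variance(0.7, -0.7, 1.1)))
  # uncapped but flagged above 100
  big <- percent_genetic_variance(0.5, 10, 0.1)
  expect_gt(as.numeric(big), 100)
  expect_true(attr(big, "above_100"))
  expect_error(percent_genetic_variance(0.5, 1, 0), "sigma2_g")
})

test_that("the FDR estimator matches its contract and caps at 1", {
  expect_equal(round(fdr_at_threshold(0.001, 1870, 729068)$fdr, 2), 0.39)
  expect_equal(round(fdr_at_threshold(0.001, 14269, 729068)$fdr, 2), 0.05)
  # observed = expected under the null: fdr = 1
  expect_equal(fdr_at_threshold(0.01, 100, 10000)$fdr, 1.0)
  # S = 0 undefined, reported 1 with flag
  z <- fdr_at_threshold(0.001, 0, 1000)
  expect_equal(z$fdr, 1.0)
  expect_true(z$undefined)
  # more hits than expected never exceeds 1
  expect_lte(fdr_at_threshold(0.5, 1, 1000)$fdr, 1.0)
  expect_error(fdr_at_threshold(1.5, 10, 100), "P must")
})

test_that("significance counting is monotone and localizes the QTL", {
  expect_identical(count_significant(list(), 0.001)$per_trait, integer(0))
  st <- small_study()
  ph <- st$phenotypes
  ms <- model_spec("A")
  scan <- suppressWarnings(gwas_scan(st$cohort$genotypes, ph, st$K, ms))
  s3 <- count_significant(scan, 1e-3)
  s4 <- count_significant(scan, 1e-4)
  expect_lte(s4$per_trait[["A"]], s3$per_trait[["A"]])
  # the QTL chromosome (snp 1500 lives on chrom 3 of 5) holds the max count
  qtl_chrom <- st$cohort$genotypes$snps$chrom[1500]
  heat <- count_significant(scan, 1e-4)$per_chrom
  expect_equal(unname(which.max(heat[, "A"])), qtl_chrom)
})

test_that("the mixed-model scan finds the QTL and stays calibrated", {
  st <- small_study()
  ph <- st$phenotypes
  scan <- suppressWarnings(gwas_scan(st$cohort$genotypes, ph, st$K,
                                     model_spec("A")))
  # t and P mutually consistent under the normal approximation
  ok <- !is.na(scan$t)
  expect_lt(max(abs(abs(qnorm(scan$p[ok] / 2)) - abs(scan$t[ok]))), 1e-6)
  expect_true(all(is.finite(scan$neglog10p[ok])))
  # the simulated QTL (25 %Vg at n=400) reaches genome-wide significance
  expect_lt(scan$p[scan$snp == "snp001500"], 5e-8)
  # null SNPs are calibrated: lambda-GC near 1
  null_rows <- scan[scan$chrom != st$cohort$genotypes$snps$chrom[1500], ]
  expect_gt(genomic_inflation(null_rows), 0.9)
  expect_lt(genomic_inflation(null_rows), 1.1)
  # empirical null P-value calibration at 0.01 and 0.001
  for (x in c(0.01, 0.001)) {
    frac <- mean(null_rows$p < x, na.rm = TRUE)
    se <- sqrt(x * (1 - x) / sum(!is.na(null_rows$p)))
    expect_lt(abs(frac - x), 3 * se + 1e-4)
  }
})

test_that("permuting phenotypes destroys the association signal", {
  st <- small_study()
  ph <- st$phenotypes
  set.seed(9)
  ph_perm <- ph
  idx <- sample.int(nrow(ph))
  ph_perm$A <- ph$A[idx]
  ph_perm$lambda_true <- ph$lambda_true[idx]
  scan <- suppressWarnings(gwas_scan(st$cohort$genotypes, ph_perm, st$K,
                                     model_spec("A")))
  expect_gt(min(scan$p, na.rm = TRUE), 1e-6)
})

test_that("monomorphic SNPs are flagged, not tested", {
  st <- small_study()
  gm <- st$cohort$genotypes
  gm$data[, 7] <- 1L       # constant heterozygote: zero dosage variance
  scan <- suppressWarnings(gwas_scan(gm, st$phenotypes, st$K,
                                     model_spec("B"),
                                     snp_subset = 1:20))
  expect_true(is.na(scan$a[7]))
  expect_false(is.na(scan$a[8]))
})

test_that("effect estimates barely move when ancestry is dropped from an
           unstratified model, and r = 1 for identical models", {
  # unstratified: single-component ancestry, no ancestry effect on traits
  panels <- simulate_ancestral_panels(1000, 0.05, seed = 700)
  cfg <- simulation_config(n_individuals = 300, n_sires = 15,
                           ancestry_mixture = data.frame(
                             mode = 0.5, weight = 1, concentration = 200),
                           h2_targets = c(A = 0.4), seed = 700)
  co <- simulate_admixed_cohort(panels, cfg)
  tr <- simulate_traits(co, cfg)
  K <- genomic_relationship(co$genotypes)
  cs <- suppressWarnings(covariate_sensitivity(
    co$genotypes, tr$phenotypes, K, model_spec("A"), snp_subset = 1:400))
  expect_gt(cs$correlation, 0.99)
  # identical models (no ancestry in either): correlation exactly 1
  ms0 <- model_spec("A", ancestry = NULL)
  s1 <- suppressWarnings(gwas_scan(co$genotypes, tr$phenotypes, K, ms0,
                                   snp_subset = 1:200))
  s2 <- suppressWarnings(gwas_scan(co$genotypes, tr$phenotypes, K, ms0,
                                   snp_subset = 1:200))
  expect_equal(cor(s1$a, s2$a, use = "complete.obs"), 1.0)
  # strong simulated stratification lowers the correlation
  cfg2 <- simulation_config(n_individuals = 300, n_sires = 15,
                            h2_targets = c(A = 0.4),
                            ancestry_slope = list(A = 4),
                            seed = 700)
  panels2 <- simulate_ancestral_panels(1000, 0.3, seed = 700)
  co2 <- simulate_admixed_cohort(panels2, cfg2)
  tr2 <- simulate_traits(co2, cfg2)
  K2 <- genomic_relationship(co2$genotypes)
  cs2 <- suppressWarnings(covariate_sensitivity(
    co2$genotypes, tr2$phenotypes, K2, model_spec("A"),
    snp_subset = 1:400))
  expect_lt(cs2$correlation, cs$correlation)
})

test_that("divergent-score association separates a QTL region from controls", {
  panels <- simulate_ancestral_panels(4000, 0.2, n_divergent = 200,
                                      seed = 800)
  # place a strong QTL at a divergent SNP on chromosome 1
  target <- panels$divergent_idx[panels$chrom[panels$divergent_idx] == 1][5]
  cfg <- simulation_config(
    n_individuals = 800, n_sires = 25, h2_targets = c(A = 0.4, N = 0.4),
    qtl_spec = data.frame(snp = target, trait = "A", pct_vg = 40,
                          sign = 1),
    seed = 800)
  co <- simulate_admixed_cohort(panels, cfg)
  tr <- simulate_traits(co, cfg)
  dset <- identify_divergent_snps(panels$freq_A, panels$freq_B)
  out <- taurine_score_association(co$genotypes, tr$phenotypes, dset,
                                   target_chrom = 1, model_spec("A"),
                                   n_random_sets = 10, seed = 5)
  expect_gt(out$target$neglog10p, max(out$controls$neglog10p))
  # a trait with no QTL anywhere: target within the control range
  out_null <- taurine_score_association(co$genotypes, tr$phenotypes, dset,
                                        target_chrom = 1, model_spec("N"),
                                        n_random_sets = 10, seed = 5)
  expect_lt(out_null$target$neglog10p,
            max(out_null$controls$neglog10p) + 2)
  # identical seed reproduces identical control sets
  rep2 <- taurine_score_association(co$genotypes, tr$phenotypes, dset,
                                    target_chrom = 1, model_spec("A"),
                                    n_random_sets = 10, seed = 5)
  expect_identical(rep2$controls$neglog10p, out$controls$neglog10p)
})
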