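test_that("REML conserves variance and is invariant to reordering", {
  st <- small_study()
  ph <- st$phenotypes
  ms <- model_spec("A")
  fit <- reml_fit(ph$A, ms, st$K, phenotypes = ph)
  expect_true(fit$converged)
  expect_gte(fit$sigma2_g, 0)
  expect_gte(fit$sigma2_e, 0)
  expect_true(fit$h2 >= 0 && fit$h2 <= 1)
  # sigma2_g + sigma2_e close to the variance after fixed-effect projection
  X <- tropigwas:::design_matrix(ph, ms)
  resid_var <- var(qr.resid(qr(X), ph$A))
  expect_lt(abs((fit$sigma2_g + fit$sigma2_e) / resid_var - 1), 0.10)
  # reordering individuals leaves the estimates unchanged
  idx <- rev(seq_len(nrow(ph)))
  fit2 <- reml_fit(ph$A[idx], tropigwas:::design_matrix(ph, ms)[idx, ],
                   unclass(st$K)[idx, idx])
  expect_equal(fit2$h2, fit$h2, tolerance = 1e-6)
})

test_that("REML shrinks to the boundary when heritability is zero", {
  # n = 1000 with 25 half-sib families gives SE(h2-hat) ~ 0.025, so the
  # boundary property is decidable with few replicates
  hits <- 0L
  for (r in 1:8) {
    panels <- simulate_ancestral_panels(1200, 0.2, seed = 400 + r)
    cfg <- simulation_config(n_individuals = 1000, n_sires = 25,
                             h2_targets = c(Z = 0), seed = 400 + r)
    co <- simulate_admixed_cohort(panels, cfg)
    tr <- simulate_traits(co, cfg)
    K <- genomic_relationship(co$genotypes)
    fit <- suppressWarnings(reml_fit(tr$phenotypes$Z, model_spec("Z"), K,
                                     phenotypes = tr$phenotypes))
    if (fit$h2 <= 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 7L)   # ~90% of replicates at the boundary
})

test_that("genetic correlation: identity, symmetry and recovery", {
  panels <- simulate_ancestral_panels(3000, 0.2, seed = 500)
  R <- matrix(c(1, 0.5, 0, 0.5, 1, 0, 0, 0, 1), 3)
  cfg <- simulation_config(n_individuals = 2000, n_sires = 50,
                           h2_targets = c(X = 0.4, Y = 0.4, W = 0.4),
                           genetic_correlation_matrix = R, seed = 500)
  co <- simulate_admixed_cohort(panels, cfg)
  tr <- simulate_traits(co, cfg)
  ph <- tr$phenotypes
  K <- genomic_relationship(co$genotypes)
  mx <- model_spec("X"); my <- model_spec("Y"); mw <- model_spec("W")
  # same trait twice: rg = 1
  expect_equal(suppressWarnings(genetic_correlation(ph, K, mx, mx))$rg,
               1.0, tolerance = 1e-6)
  # correlated pair recovers 0.5
  rg_xy <- suppressWarnings(genetic_correlation(ph, K, mx, my))$rg
  expect_lt(abs(rg_xy - 0.5), 0.15)
  # symmetry in the trait arguments
  expect_equal(suppressWarnings(genetic_correlation(ph, K, my, mx))$rg,
               rg_xy, tolerance = 1e-6)
  # genetically independent pair stays near zero
  expect_lt(abs(suppressWarnings(genetic_correlation(ph, K, mx, mw))$rg),
            0.15)
})

test_that("phenotypic correlation matches its contract", {
  st <- small_study()
  ph <- st$phenotypes
  ma <- model_spec("A"); mb <- model_spec("B")
  expect_equal(phenotypic_correlation(ph, ma, ma), 1.0, tolerance = 1e-12)
  rp <- phenotypic_correlation(ph, ma, mb)
  # affine rescaling of either trait leaves rp unchanged
  ph2 <- ph
  ph2$B <- 3 * ph2$B - 7
  expect_equal(phenotypic_correlation(ph2, ma, mb), rp, tolerance = 1e-12)
})

test_that("the ancestry-effect model recovers slopes and controls type I", {
  panels <- simulate_ancestral_panels(1500, 0.2, seed = 600)
  cfg <- simulation_config(
    n_individuals = 2000, n_sires = 50,
    h2_targets = c(EPG = 0.35, NUL = 0.35),
    ancestry_slope = list(EPG = -5.0),
    seed = 600)
  co <- simulate_admixed_cohort(panels, cfg)
  tr <- simulate_traits(co, cfg)
  ph <- tr$phenotypes
  eff <- ancestry_effect(ph, model_spec("EPG"))
  expect_lt(abs(eff$estimate - (-5.0)) / eff$se, 2)
  expect_true(eff$significant)
  # no simulated slope: flagged non-significant at alpha = 0.005
  eff0 <- ancestry_effect(ph, model_spec("NUL"))
  expect_false(eff0$significant)
})

test_that("subgroup analysis reproduces a piecewise sign flip", {
  panels <- simulate_ancestral_panels(1500, 0.2, seed = 601)
  cfg <- simulation_config(
    n_individuals = 2000, n_sires = 50, h2_targets = c(EPG = 0.35),
    ancestry_slope = list(EPG = list(below = -10, above = 6,
                                     threshold = 0.30)),
    seed = 601)
  co <- simulate_admixed_cohort(panels, cfg)
  tr <- simulate_traits(co, cfg)
  lo <- ancestry_effect(tr$phenotypes, model_spec("EPG"), "below")
  hi <- ancestry_effect(tr$phenotypes, model_spec("EPG"), "at_or_above")
  expect_lt(lo$estimate, 0)
  expect_gt(hi$estimate, 0)
})

test_that("paired comparison of correlation sets handles all regimes", {
  # identical vectors: no difference at all
  out <- compare_correlation_sets(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # constant non-zero difference: degenerate guard
  out2 <- compare_correlation_sets(c(0.1, 0.3, 0.5), c(0.2, 0.4, 0.6))
  expect_true(out2$degenerate)
  # differences (-0.1, 0, 0.1, 0.2): frozen against stats::t.test
  x <- c(0.0, 0.1, 0.2, 0.3)
  y <- x - c(-0.1, 0.0, 0.1, 0.2)
  out3 <- compare_correlation_sets(x, y)
  oracle <- t.test(x, y, paired = TRUE)
  expect_equal(out3$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(out3$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(out3$t, 0.7746, tolerance = 1e-4)
  expect_equal(out3$p, 0.495, tolerance = 1e-3)
  expect_equal(out3$df, 3)
})
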