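test_that("geno_matrix validates its invariants", {
  expect_error(tiny_gm(matrix(3L, 2, 2)), "0, 1, 2")
  expect_error(geno_matrix(matrix(0L, 2, 2), c("a", "b"),
                           data.frame(id = c("s1", "s2"), chrom = 1,
                                      pos = c(10, 10), allele_A = "A",
                                      allele_B = "A")),
               "allele_A and allele_B")
  expect_error(geno_matrix(matrix(0L, 2, 2), c("a", "b"),
                           data.frame(id = c("s1", "s2"), chrom = 1,
                                      pos = c(10, 10), allele_A = "A",
                                      allele_B = "B")),
               "duplicated SNP")
  gm <- tiny_gm(matrix(c(0L, 1L, 2L, NA), 2, 2))
  expect_identical(dim(gm), c(2L, 2L))
})

test_that("allele frequencies handle missing calls and degenerate SNPs", {
  gm <- tiny_gm(cbind(c(0L, 1L, 2L), c(2L, 2L, NA), c(NA, NA, NA)))
  f <- allele_frequencies(gm)
  expect_equal(unname(f[1]), 0.5)
  expect_equal(unname(f[2]), 1.0)       # missing excluded from denominator
  expect_true(is.na(f[3]))
  expect_identical(unname(attr(f, "undefined")), c(FALSE, FALSE, TRUE))
})

test_that("PLINK binary round-trips genotypes, ids and metadata exactly", {
  set.seed(1)
  G <- matrix(sample(c(0:2, NA), 3 * 7, replace = TRUE), 3, 7)
  gm <- tiny_gm(G, chrom = c(1, 1, 1, 1, 2, 2, 2),
                pos = c(5, 10, 20, 30, 7, 9, 40))
  bed <- file.path(tempdir(), "rt.bed")
  write_genotypes(gm, bed, "plink")
  back <- read_genotypes(bed)
  expect_identical(unname(back$data), unname(gm$data))
  expect_identical(back$ids, gm$ids)
  expect_identical(back$snps$pos, gm$snps$pos)
  expect_identical(back$snps$allele_B, gm$snps$allele_B)
})

test_that("a .bed with wrong magic bytes raises a format error", {
  bad <- file.path(tempdir(), "bad.bed")
  writeBin(as.raw(c(0x00, 0x01, 0x02, 0x03)), bad)
  writeLines("1\ts1\t0\t100\tA\tB", sub("bed$", "bim", bad))
  writeLines("f1\ti1\t0\t0\t0\t-9", sub("bed$", "fam", bad))
  expect_error(read_genotypes(bad), "magic")
})

test_that("VCF round-trips and maps 0/1 against ALT to dosage 1", {
  G <- rbind(c(0L, 1L, NA), c(2L, 1L, 0L))
  gm <- tiny_gm(G)
  vcf <- file.path(tempdir(), "rt.vcf")
  write_genotypes(gm, vcf, "vcf")
  back <- read_genotypes(vcf)
  expect_identical(unname(back$data), unname(G))
  # het record maps to ALT count 1
  expect_identical(back$data[1, 2], 1L)
})

test_that("ld_r2 matches direct Pearson computation and its invariances", {
  gm <- tiny_gm(cbind(c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 2L),
                      c(2L, 1L, 0L, 1L)))
  # oracle: base R cor on the dosage vectors
  expect_equal(as.numeric(ld_r2(gm, 1, 2)),
               cor(c(0, 1, 2, 1), c(2, 1, 0, 2))^2)
  expect_equal(as.numeric(ld_r2(gm, 1, 2)), 0.727272727, tolerance = 1e-8)
  # identical columns and 2-complement columns are perfect LD
  expect_equal(as.numeric(ld_r2(gm, 1, 1)), 1.0)
  expect_equal(as.numeric(ld_r2(gm, 1, 3)), 1.0)
  # allele relabeling of either SNP leaves r2 unchanged
  gm_flip <- tiny_gm(cbind(2L - c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 2L)))
  expect_equal(as.numeric(ld_r2(gm_flip, 1, 2)),
               as.numeric(ld_r2(gm, 1, 2)))
})

test_that("monomorphic pairs give r2 = 0 with a flag", {
  gm <- tiny_gm(cbind(c(1L, 1L, 1L), c(0L, 1L, 2L)))
  out <- ld_r2(gm, 1, 2)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "monomorphic"))
})

test_that("pruning keeps independent SNPs and collapses duplicates", {
  set.seed(42)
  # mutually independent SNPs: all retained
  G <- matrix(rbinom(200 * 30, 2, 0.5), 200, 30)
  gm <- tiny_gm(G)
  expect_identical(ld_prune(gm), 1:30)
  # 100 identical copies on one chromosome: exactly 1 retained
  g0 <- rbinom(60, 2, 0.5)
  dup <- tiny_gm(matrix(rep(g0, 100), ncol = 100))
  expect_length(ld_prune(dup), 1L)
})

test_that("pruning is idempotent and leaves no violating pair", {
  set.seed(7)
  n <- 150
  base <- matrix(rbinom(n * 12, 2, 0.5), n, 12)
  # interleave correlated copies (base with a little noise)
  noisy <- pmin(pmax(base + matrix(rbinom(n * 12, 1, 0.15) -
                                     rbinom(n * 12, 1, 0.15), n, 12), 0), 2)
  G <- cbind(base, noisy)[, rep(seq_len(12), each = 2) +
                            c(0, 12) * rep(c(0, 1), 12)]
  G <- matrix(as.integer(G), n)
  gm <- tiny_gm(G)
  kept <- ld_prune(gm)
  pruned <- gm[, kept]
  expect_identical(ld_prune(pruned), seq_along(kept))
  R2 <- suppressWarnings(cor(pruned$data)^2)
  R2[!is.finite(R2)] <- 0
  diag(R2) <- 0
  expect_lte(max(R2), 0.5)
})

test_that("sliding allele-frequency windows behave as a moving average", {
  # constant frequency 0.5: every window 0.5
  G <- matrix(rep(c(0L, 1L, 1L, 2L), 120), 4, 120)
  gm <- tiny_gm(G)
  prof <- sliding_allele_freq(gm, chrom = 1, window = 100)
  expect_true(all(abs(prof$mean_freq - 0.5) < 1e-12))
  expect_equal(nrow(prof), 21)
  # exactly `window` SNPs: one window equal to the grand mean
  gm2 <- small_study()$cohort$genotypes
  idx <- which(gm2$snps$chrom == 1)[1:100]
  one <- sliding_allele_freq(gm2[, idx], chrom = 1, window = 100)
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_freq, mean(allele_frequencies(gm2[, idx])))
  # step in frequency (exact 0.1 then 0.9): window means monotone
  lo <- matrix(rep(c(1L, 1L, rep(0L, 8)), 60), 10)
  hi <- 2L - lo
  step_gm <- tiny_gm(cbind(lo, hi))
  prof3 <- sliding_allele_freq(step_gm, chrom = 1, window = 50)
  expect_true(all(diff(prof3$mean_freq) > -1e-9))
})
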