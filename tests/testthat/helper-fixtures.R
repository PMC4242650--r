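# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# tiny genotype matrix with default metadata
tiny_gm <- function(G, chrom = NULL, pos = NULL) {
  G <- as.matrix(G)
  m <- ncol(G)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  geno_matrix(G, sprintf("i%02d", seq_len(nrow(G))),
              data.frame(id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                         pos = pos, allele_A = "A", allele_B = "B",
                         stringsAsFactors = FALSE))
}

# independent oracle: Hudson-style Fst, ratio of averages, from two
# genotype samples
hudson_fst <- function(gmA, gmB) {
  p1 <- allele_frequencies(gmA); p2 <- allele_frequencies(gmB)
  n1 <- nrow(gmA$data) * 2; n2 <- nrow(gmB$data) * 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  mean(num, na.rm = TRUE) / mean(den, na.rm = TRUE)
}

# small admixed cohort with phenotypes, reused by several test files
small_study <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    panels <- simulate_ancestral_panels(3000, 0.2, n_divergent = 60,
                                        seed = 101)
    cfg <- simulation_config(
      n_individuals = 400, n_sires = 20,
      h2_targets = c(A = 0.4, B = 0.3, C = 0.2),
      qtl_spec = data.frame(snp = 1500, trait = "A", pct_vg = 25,
                            sign = 1),
      seed = 101)
    co <- simulate_admixed_cohort(panels, cfg)
    tr <- simulate_traits(co, cfg)
    cache <<- list(panels = panels, cfg = cfg, cohort = co,
                   phenotypes = tr$phenotypes, truth = tr$truth,
                   K = genomic_relationship(co$genotypes))
    cache
  }
})
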