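#' Simulate two diverged ancestral allele-frequency panels
#'
#' Balding-Nichols-style model: a common ancestral frequency f is drawn
#' Uniform(0.05, 0.95) per SNP and each population's frequency is drawn
#' Beta(f(1-d)/d, (1-f)(1-d)/d), so the between-population variance of
#' frequencies is d*f*(1-f) and the expected Hudson-type Fst between panel
#' samples is d. A requested number of SNPs is overwritten to be "highly
#' divergent" (B-allele frequency > 0.95 in A and < 0.05 in B), spread
#' evenly across the genome, to support divergent-allele analyses.
#'
#' @param n_snps number of SNPs.
#' @param divergence Fst-like scalar in `[0, 1)`.
#' @param n_divergent number of constructed highly divergent SNPs
#'   (default 0).
#' @param n_chrom number of chromosomes the map is spread over (default 5).
#' @param seed RNG seed.
#' @return List of class `ancestral_panels`: `n_snps`, `freq_A`, `freq_B`
#'   (B-allele frequencies), `chrom`, `pos`, `divergence`, `divergent_idx`.
#' @export
simulate_ancestral_panels <- function(n_snps, divergence, n_divergent = 0,
                                      n_chrom = 5, seed = 1) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  set.seed(seed)
  f <- stats::runif(n_snps, 0.05, 0.95)
  if (divergence == 0) {
    freq_A <- freq_B <- f
  } else {
    conc <- (1 - divergence) / divergence
    freq_A <- stats::rbeta(n_snps, f * conc, (1 - f) * conc)
    freq_B <- stats::rbeta(n_snps, f * conc, (1 - f) * conc)
  }
  divergent_idx <- integer(0)
  if (n_divergent > 0) {
    divergent_idx <- round(seq(1, n_snps, length.out = n_divergent))
    freq_A[divergent_idx] <- stats::runif(n_divergent, 0.96, 0.999)
    freq_B[divergent_idx] <- stats::runif(n_divergent, 0.001, 0.04)
  }
  chrom <- sort(rep_len(seq_len(n_chrom), n_snps))
  pos <- unlist(lapply(split(seq_len(n_snps), chrom), function(i)
    sort(sample.int(2e8, length(i)))), use.names = FALSE)
  structure(list(n_snps = n_snps, freq_A = freq_A, freq_B = freq_B,
                 chrom = chrom, pos = pos, divergence = divergence,
                 divergent_idx = divergent_idx),
            class = "ancestral_panels")
}

panel_snp_table <- function(panels) {
  data.frame(id = sprintf("snp%06d", seq_len(panels$n_snps)),
             chrom = panels$chrom, pos = panels$pos,
             allele_A = "A", allele_B = "B", stringsAsFactors = FALSE)
}

#' Draw reference-panel genotype samples
#'
#' Samples individuals from each ancestral population by binomial draws at
#' the panel frequencies, as reference genotypes for supervised ancestry
#' estimation and Fst checks.
#'
#' @param panels an `ancestral_panels` object.
#' @param n_A,n_B sample sizes for populations A and B.
#' @param seed RNG seed.
#' @return List with `A` and `B`, each a [geno_matrix()].
#' @export
sample_panel_genotypes <- function(panels, n_A, n_B, seed = 1) {
  set.seed(seed)
  snps <- panel_snp_table(panels)
  draw <- function(n, freq, prefix) {
    G <- matrix(stats::rbinom(n * length(freq), 2L, rep(freq, each = n)),
                nrow = n)
    geno_matrix(G, sprintf("%s%03d", prefix, seq_len(n)), snps)
  }
  list(A = draw(n_A, panels$freq_A, "refA_"),
       B = draw(n_B, panels$freq_B, "refB_"))
}

#' Simulation configuration for an admixed half-sib cohort
#'
#' Collects the knobs of the cohort generator with defaults emulating the
#' crossbred tropical-cattle design the package targets: ~2,000 animals in
#' paternal half-sib families under 50 sires, a bimodal indicine-ancestry
#' distribution with modes near 0.30 and 0.95, ten correlated traits with
#' heritabilities between 0.09 and 0.54, contemporary-group /
#' age-of-dam / ancestry fixed effects, and optional large-effect QTL over a
#' polygenic background.
#'
#' @param n_individuals cohort size (default 2000).
#' @param n_sires number of paternal half-sib families (default 50).
#' @param ancestry_mixture data.frame with columns `mode`, `weight`,
#'   `concentration` describing a Beta mixture for per-individual ancestry
#'   lambda (proportion from population B). Default: modes 0.30 and 0.95,
#'   equal weight, concentration 30.
#' @param h2_targets named numeric vector of per-trait heritabilities in
#'   `[0, 1]`. Default: ten traits spanning 0.09-0.54.
#' @param genetic_correlation_matrix trait x trait correlation matrix of the
#'   polygenic effects (default: exchangeable 0.1 off-diagonal).
#' @param qtl_spec data.frame with columns `snp` (column index), `trait`
#'   (name), `pct_vg` (target percentage of genetic variance) and `sign`
#'   (+1/-1); default none.
#' @param ancestry_slope named per-trait linear effect of lambda on the
#'   phenotype (units per 100% ancestry); default 0. A piecewise slope may
#'   be given as a list per trait: `list(below=, above=, threshold=)`.
#' @param cg_sd SD of contemporary-group effects (default 0.5).
#' @param age_of_dam_effect per-year slope of age of dam (default 0.05).
#' @param age12_effect slope of the AGE12 covariate, applied to the last
#'   trait (a yearling-weight analogue) only (default 0.1).
#' @param seed RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 2000,
                              n_sires = 50,
                              ancestry_mixture = data.frame(
                                mode = c(0.30, 0.95),
                                weight = c(0.5, 0.5),
                                concentration = c(30, 30)),
                              h2_targets = c(FT = 0.44, TEMP = 0.22,
                                             EPG = 0.39, SHEATH = 0.51,
                                             COLOUR = 0.54, FLY = 0.19,
                                             TICK = 0.09, COAT = 0.41,
                                             COND = 0.45, YWT = 0.38),
                              genetic_correlation_matrix = NULL,
                              qtl_spec = NULL,
                              ancestry_slope = NULL,
                              cg_sd = 0.5,
                              age_of_dam_effect = 0.05,
                              age12_effect = 0.1,
                              seed = 1) {
  if (!nrow(ancestry_mixture)) stop("ancestry_mixture must be non-empty")
  if (any(h2_targets < 0 | h2_targets > 1))
    stop("h2 targets must lie in [0, 1]")
  k <- length(h2_targets)
  if (is.null(genetic_correlation_matrix)) {
    genetic_correlation_matrix <- matrix(0.1, k, k)
    diag(genetic_correlation_matrix) <- 1
  }
  R <- genetic_correlation_matrix
  if (!isSymmetric(unname(R)) || any(abs(diag(R) - 1) > 1e-8))
    stop("genetic correlation matrix must be symmetric with unit diagonal")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("genetic correlation matrix must be positive semi-definite")
  if (!is.null(qtl_spec)) {
    tot <- tapply(qtl_spec$pct_vg, qtl_spec$trait, sum)
    if (any(tot > 100))
      stop("total target %Vg exceeds 100 for trait(s): ",
           paste(names(tot)[tot > 100], collapse = ", "))
  }
  structure(list(n_individuals = n_individuals, n_sires = n_sires,
                 ancestry_mixture = ancestry_mixture,
                 h2_targets = h2_targets,
                 genetic_correlation_matrix = R,
                 qtl_spec = qtl_spec,
                 ancestry_slope = ancestry_slope,
                 cg_sd = cg_sd,
                 age_of_dam_effect = age_of_dam_effect,
                 age12_effect = age12_effect,
                 seed = seed),
            class = "simulation_config")
}

# draw lambdas and the mixture component used, Beta(mode*c, (1-mode)*c)
draw_lambda <- function(n, mixture) {
  comp <- sample.int(nrow(mixture), n, replace = TRUE,
                     prob = mixture$weight)
  m <- mixture$mode[comp]; cc <- mixture$concentration[comp]
  lam <- stats::rbeta(n, m * cc, (1 - m) * cc)
  list(lambda = pmin(pmax(lam, 0), 1), comp = comp)
}

#' Simulate an admixed half-sib cohort
#'
#' Sires are drawn with ancestry lambda from the configured mixture and get
#' binomial genotypes at the lambda-mixed frequencies. Offspring are split
#' into paternal half-sib families (family sizes multinomial with equal sire
#' probabilities, dams unique). Each offspring receives one allele per SNP
#' transmitted from its sire's genotype and one maternal allele drawn at the
#' dam's lambda-mixed frequency; the dam's lambda comes from the same
#' mixture component as the sire's (assortative mating by population), so
#' the offspring lambda distribution keeps the configured modes. Offspring
#' true lambda is the parental mean.
#'
#' @param panels an `ancestral_panels` object.
#' @param config a [simulation_config()].
#' @return List with `genotypes` ([geno_matrix()] of the offspring cohort),
#'   `pedigree` (data.frame id/sire/dam covering parents and offspring),
#'   `truth` (list: `lambda` per offspring, `sire_lambda`, `sire_of`),
#'   and `sire_genotypes`.
#' @export
simulate_admixed_cohort <- function(panels, config) {
  set.seed(config$seed)
  n <- config$n_individuals
  ns <- config$n_sires
  m <- panels$n_snps
  snps <- panel_snp_table(panels)
  mix_freq <- function(lam) lam * panels$freq_B + (1 - lam) * panels$freq_A

  sl <- draw_lambda(ns, config$ancestry_mixture)
  sire_G <- matrix(0L, ns, m)
  for (s in seq_len(ns))
    sire_G[s, ] <- stats::rbinom(m, 2L, mix_freq(sl$lambda[s]))
  sire_ids <- sprintf("sire%03d", seq_len(ns))

  sire_of <- sample.int(ns, n, replace = TRUE)   # multinomial, equal probs
  # dams: unique, lambda from the sire's mixture component
  dam_comp <- sl$comp[sire_of]
  mx <- config$ancestry_mixture
  dam_lambda <- stats::rbeta(n, mx$mode[dam_comp] * mx$concentration[dam_comp],
                             (1 - mx$mode[dam_comp]) *
                               mx$concentration[dam_comp])
  G <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    paternal <- stats::rbinom(m, 1L, sire_G[sire_of[i], ] / 2)
    maternal <- stats::rbinom(m, 1L, mix_freq(dam_lambda[i]))
    G[i, ] <- paternal + maternal
  }
  lambda <- (sl$lambda[sire_of] + dam_lambda) / 2
  ids <- sprintf("ind%05d", seq_len(n))
  dam_ids <- sprintf("dam%05d", seq_len(n))
  ped <- rbind(
    data.frame(id = sire_ids, sire = NA_character_, dam = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = dam_ids, sire = NA_character_, dam = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = ids, sire = sire_ids[sire_of], dam = dam_ids,
               stringsAsFactors = FALSE))
  list(genotypes = geno_matrix(G, ids, snps),
       pedigree = ped,
       truth = list(lambda = lambda, sire_lambda = sl$lambda,
                    sire_of = sire_of, dam_lambda = dam_lambda),
       sire_genotypes = geno_matrix(sire_G, sire_ids, snps))
}

#' Simulate correlated phenotypes over a genotyped cohort
#'
#' Builds each trait as mean + contemporary-group effect + age-of-dam slope
#' + ancestry slope + QTL effects + polygenic breeding value + residual.
#' QTL allele-substitution effects are back-solved from the target
#' percentage of genetic variance, a = sign * sqrt(pct * sigma2_g /
#' (100 * 2pq)) at the cohort allele frequency. The polygenic part is a
#' genomic breeding value (small effects at every non-QTL SNP, correlated
#' across traits by the configured matrix) rescaled so the realized genetic
#' variance hits sigma2_g = h2 on a unit phenotypic-variance scale;
#' residuals are independent with variance 1 - h2. Heritability is
#' sigma2_g / (sigma2_g + sigma2_e); fixed-effect variance is excluded, as
#' in animal-model convention.
#'
#' @param cohort output of [simulate_admixed_cohort()].
#' @param config the same [simulation_config()].
#' @return List with `phenotypes` (data.frame: id, one column per trait,
#'   `cg`, `age_of_dam`, `age12`, `sex`, `lambda_true`) and `truth` (list:
#'   `bv` matrix of true breeding values, `qtl` realized per-QTL table,
#'   `sigma2_g`, `sigma2_e`).
#' @export
simulate_traits <- function(cohort, config) {
  set.seed(config$seed + 1L)
  gm <- cohort$genotypes
  n <- nrow(gm$data)
  traits <- names(config$h2_targets)
  k <- length(traits)
  lambda <- cohort$truth$lambda

  sigma2_g <- config$h2_targets           # unit phenotypic variance scale
  sigma2_e <- 1 - config$h2_targets

  # QTL genetic values
  freq <- allele_frequencies(gm)
  qtl_gv <- matrix(0, n, k, dimnames = list(NULL, traits))
  qtl_var <- stats::setNames(numeric(k), traits)
  qtl_real <- NULL
  if (!is.null(config$qtl_spec) && nrow(config$qtl_spec)) {
    qs <- config$qtl_spec
    for (r in seq_len(nrow(qs))) {
      j <- qs$snp[r]; tr <- as.character(qs$trait[r])
      p <- freq[j]; twopq <- 2 * p * (1 - p)
      if (!is.finite(twopq) || twopq == 0)
        stop("QTL at monomorphic SNP ", gm$snps$id[j],
             ": target %Vg unattainable")
      a <- qs$sign[r] * sqrt(qs$pct_vg[r] * sigma2_g[tr] / (100 * twopq))
      g <- gm$data[, j]; g[is.na(g)] <- 2 * p
      qtl_gv[, tr] <- qtl_gv[, tr] + a * (g - 2 * p)
      qtl_var[tr] <- qtl_var[tr] + a^2 * twopq
      qtl_real <- rbind(qtl_real,
                        data.frame(snp = j, trait = tr, a = a, p = p,
                                   target_pct_vg = qs$pct_vg[r]))
    }
  }

  # polygenic breeding values from all non-QTL SNPs, correlated across traits
  qtl_cols <- unique(qtl_real$snp)
  poly_cols <- setdiff(seq_len(ncol(gm$data)), qtl_cols)
  Gc_raw <- impute_mean(gm$data[, poly_cols, drop = FALSE])
  storage.mode(Gc_raw) <- "double"
  Gc <- sweep(Gc_raw, 2, colMeans(Gc_raw))
  L <- chol_psd(config$genetic_correlation_matrix)
  beta <- matrix(stats::rnorm(length(poly_cols) * k), ncol = k) %*% L
  bv_poly <- Gc %*% beta
  # The analysis model carries ancestry-mean trait differences in the fixed
  # ancestry covariate, so the polygenic background is made orthogonal to
  # ancestry; ancestry effects enter through config$ancestry_slope. This
  # also keeps the realized/parameter variance ratio stable: otherwise the
  # dominant ancestry axis of the relationship matrix carries a single
  # chi-squared(1) draw of genetic variance.
  bv_poly <- as.matrix(stats::lm.fit(cbind(1, lambda), bv_poly)$residuals)
  target_poly_var <- pmax(sigma2_g - qtl_var, 0)
  # Scale each trait's background so the implied per-SNP effect variance is
  # sigma2_poly / (2 sum pq): the variance parameter the animal model's
  # relationship matrix is scaled against. The model-implied sample
  # variance of the orthogonalized background is sigma2_beta times the
  # trace of the centred genotype cross-product minus its ancestry-aligned
  # mass, so the realized heritability matches the target in expectation
  # on the same scale REML estimates it.
  pfreq <- colMeans(Gc_raw) / 2
  two_sum_pq <- 2 * sum(pfreq * (1 - pfreq))
  q2 <- lambda - mean(lambda)
  q2 <- q2 / sqrt(sum(q2^2))
  tr_orth <- sum(Gc^2) - sum(as.vector(crossprod(Gc, q2))^2)
  sdv <- apply(bv_poly, 2, stats::sd)
  for (t in seq_len(k)) {
    v_t <- target_poly_var[t] * tr_orth / (nrow(Gc) * two_sum_pq)
    bv_poly[, t] <- if (sdv[t] > 0 && v_t > 0)
      bv_poly[, t] * sqrt(v_t) / sdv[t] else 0
  }
  bv <- bv_poly + qtl_gv
  colnames(bv) <- traits

  # fixed effects
  sex <- sample(c("M", "F"), n, replace = TRUE)
  year <- sample(2009:2011, n, replace = TRUE)
  loc <- sample(c("north", "south"), n, replace = TRUE)
  cg <- interaction(sex, year, loc, drop = TRUE)
  cg_eff <- matrix(stats::rnorm(nlevels(cg) * k, sd = config$cg_sd),
                   nlevels(cg), k)
  age_of_dam <- sample(3:10, n, replace = TRUE)
  age12 <- stats::rnorm(n, 360, 20)

  pheno <- matrix(0, n, k, dimnames = list(NULL, traits))
  for (t in seq_len(k)) {
    tr <- traits[t]
    slope <- ancestry_slope_value(config$ancestry_slope, tr, lambda)
    fixed <- cg_eff[as.integer(cg), t] +
      config$age_of_dam_effect * (age_of_dam - mean(age_of_dam)) +
      slope +
      if (t == k) config$age12_effect * (age12 - mean(age12)) / 20 else 0
    resid <- stats::rnorm(n, sd = sqrt(sigma2_e[t]))
    pheno[, t] <- fixed + bv[, t] + resid
  }

  phenotypes <- data.frame(id = gm$ids, pheno, cg = cg,
                           age_of_dam = age_of_dam, age12 = age12, sex = sex,
                           lambda_true = lambda, stringsAsFactors = FALSE)
  list(phenotypes = phenotypes,
       truth = list(bv = bv, qtl = qtl_real, sigma2_g = sigma2_g,
                    sigma2_e = sigma2_e))
}

# per-individual ancestry contribution; supports scalar and piecewise slopes
ancestry_slope_value <- function(spec, trait, lambda) {
  if (is.null(spec)) return(0)
  s <- spec[[trait]]
  if (is.null(s)) return(0)
  if (is.list(s)) {
    thr <- s$threshold
    ifelse(lambda < thr, s$below * lambda,
           s$below * thr + s$above * (lambda - thr))
  } else {
    s * lambda
  }
}

# Cholesky factor tolerant of semi-definite matrices
chol_psd <- function(R) {
  ev <- eigen(R, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  t(ev$vectors %*% diag(sqrt(vals), length(vals)) %*% t(ev$vectors))
}
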