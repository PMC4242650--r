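#' Single-SNP mixed-model association scan
#'
#' Each SNP in turn is added as a linear 0/1/2 dosage covariate to the
#' animal model's fixed effects, with the polygenic covariance
#' sigma2_g K + sigma2_e I held at the null-model REML estimates (fitted
#' once without any SNP and reused for every SNP, the standard single-fit
#' approximation). The cached eigendecomposition of K diagonalizes the
#' covariance, so each SNP test is a weighted least-squares regression of
#' the rotated phenotype on the rotated, fixed-effect-residualized dosage;
#' the whole scan is a handful of matrix products. Two-sided P-values come
#' from the normal approximation to the GLS t-ratio.
#'
#' @param gm a [geno_matrix()].
#' @param phenotypes phenotype data.frame, rows matching `gm` individuals.
#' @param K relationship matrix over the same individuals.
#' @param model a [model_spec()].
#' @param null_fit optional precomputed [reml_fit()] under the null (no
#'   SNP); computed if absent.
#' @param snp_subset optional SNP column indices to test (default all).
#' @param min_call_rate SNPs below this call rate are flagged and not
#'   tested (default 0.9).
#' @return data.frame of class `assoc_result`: `snp`, `chrom`, `pos`,
#'   `trait`, `a` (allele-substitution effect per B allele), `se`, `t`,
#'   `p`, `neglog10p`, `pct_vg`, `freq`, `note` (NA, "monomorphic",
#'   "low_call_rate" or "collinear").
#' @export
gwas_scan <- function(gm, phenotypes, K, model, null_fit = NULL,
                      snp_subset = NULL, min_call_rate = 0.9,
                      .rotated = NULL) {
  ok <- stats::complete.cases(phenotypes[[model$trait]])
  ph <- phenotypes[ok, , drop = FALSE]
  y <- ph[[model$trait]]
  X <- design_matrix(ph, model)
  if (is.null(null_fit)) {
    if (!is.null(.rotated)) {
      null_fit <- reml_fit(y, X, eig = .rotated$eig)
    } else {
      Ksub <- unclass(K)[ok, ok, drop = FALSE]
      null_fit <- reml_fit(y, X, Ksub)
    }
  }
  eig <- null_fit$eig
  w <- 1 / (null_fit$sigma2_g * eig$values + null_fit$sigma2_e)
  U <- eig$vectors
  yr <- crossprod(U, y)
  Xr <- crossprod(U, X)
  XtWX <- crossprod(Xr, Xr * w)
  XtWX_inv <- solve(XtWX)
  # residualize the rotated phenotype against the fixed effects under W
  beta0 <- XtWX_inv %*% crossprod(Xr, yr * w)
  y_res <- yr - Xr %*% beta0

  if (is.null(snp_subset)) snp_subset <- seq_len(ncol(gm$data))
  if (!is.null(.rotated)) {
    Gr <- .rotated$Gr
    call_rate <- .rotated$call_rate
    freq <- .rotated$freq
  } else {
    G <- gm$data[ok, snp_subset, drop = FALSE]
    call_rate <- colMeans(!is.na(G))
    freq <- colSums(G, na.rm = TRUE) / (2 * pmax(colSums(!is.na(G)), 1L))
    G <- impute_mean(G)
    storage.mode(G) <- "double"
    Gr <- crossprod(U, G)
  }
  # residualize dosages against fixed effects under W
  Gr_res <- Gr - Xr %*% (XtWX_inv %*% crossprod(Xr, Gr * w))
  ss <- colSums(w * Gr_res^2)
  num <- colSums((w * y_res)[, 1] * Gr_res)
  a <- num / ss
  se <- sqrt(1 / ss)

  mono <- freq <= 0 | freq >= 1
  lowcall <- call_rate < min_call_rate
  collinear <- !mono & ss < 1e-10
  bad <- mono | lowcall | collinear
  a[bad] <- NA_real_; se[bad] <- NA_real_
  tval <- a / se
  p <- 2 * stats::pnorm(-abs(tval))
  pct_vg <- percent_genetic_variance(freq, a, null_fit$sigma2_g)
  note <- rep(NA_character_, length(snp_subset))
  note[lowcall] <- "low_call_rate"
  note[mono] <- "monomorphic"
  note[collinear] <- "collinear"
  out <- data.frame(snp = gm$snps$id[snp_subset],
                    chrom = gm$snps$chrom[snp_subset],
                    pos = gm$snps$pos[snp_subset],
                    trait = model$trait,
                    a = a, se = se, t = tval, p = p,
                    neglog10p = -log10(pmax(p, .Machine$double.xmin)),
                    pct_vg = pct_vg, freq = freq, note = note,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "null_fit") <- null_fit
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Multi-trait mixed-model scan with one shared rotation
#'
#' Runs [gwas_scan()] for several traits against the same relationship
#' matrix, individuals and SNPs, eigendecomposing K and rotating the
#' genotype matrix once (the dominant cost of a scan). Individuals must be
#' complete cases for every trait.
#'
#' @param gm a [geno_matrix()].
#' @param phenotypes phenotype data.frame.
#' @param K relationship matrix.
#' @param models list of [model_spec()], one per trait.
#' @param snp_subset optional SNP column indices.
#' @param min_call_rate as in [gwas_scan()].
#' @return List: `scans` (named list of `assoc_result`), `t_matrix`
#'   (SNPs x traits studentized effects), `null_fits`.
#' @export
gwas_scan_multitrait <- function(gm, phenotypes, K, models,
                                 snp_subset = NULL, min_call_rate = 0.9) {
  traits <- vapply(models, `[[`, "", "trait")
  ok <- stats::complete.cases(phenotypes[, traits, drop = FALSE])
  if (!all(ok))
    stop("multi-trait scan needs complete cases for every trait; ",
         "scan incomplete traits individually with gwas_scan()")
  eig <- relmat_eigen(unclass(K))
  if (is.null(snp_subset)) snp_subset <- seq_len(ncol(gm$data))
  G <- gm$data[, snp_subset, drop = FALSE]
  call_rate <- colMeans(!is.na(G))
  freq <- colSums(G, na.rm = TRUE) / (2 * pmax(colSums(!is.na(G)), 1L))
  G <- impute_mean(G)
  storage.mode(G) <- "double"
  Gr <- crossprod(eig$vectors, G)
  rotated <- list(eig = eig, Gr = Gr, call_rate = call_rate, freq = freq)
  scans <- lapply(models, function(ms)
    gwas_scan(gm, phenotypes, K, ms, snp_subset = snp_subset,
              min_call_rate = min_call_rate, .rotated = rotated))
  names(scans) <- traits
  t_matrix <- vapply(scans, function(s) s$t, numeric(length(snp_subset)))
  rownames(t_matrix) <- gm$snps$id[snp_subset]
  list(scans = scans, t_matrix = t_matrix,
       null_fits = lapply(scans, attr, "null_fit"))
}

#' Percentage of genetic variance explained by a SNP
#'
#' 100 * 2 p (1 - p) a^2 / sigma2_g: the additive variance of the SNP in
#' the absence of dominance, as a percentage of the REML polygenic
#' variance. Not capped; values above 100 indicate an effect estimate
#' larger than the trait's whole genetic variance and are flagged via
#' attribute `above_100`.
#'
#' @param p per-SNP B-allele frequency (cohort-specific).
#' @param a estimated additive allele-substitution effect.
#' @param sigma2_g REML estimate of the polygenic variance (> 0).
#' @return Numeric vector of percentages; invariant to allele flips
#'   (p, a) -> (1 - p, -a).
#' @export
percent_genetic_variance <- function(p, a, sigma2_g) {
  if (sigma2_g <= 0) stop("sigma2_g must be > 0")
  out <- 100 * 2 * p * (1 - p) * a^2 / sigma2_g
  attr(out, "above_100") <- !is.na(out) & out > 100
  out
}

#' Explicit false-discovery-rate estimator
#'
#' fdr = P (1 - S/T) / ((S/T) (1 - P)): the expected proportion of false
#' positives among the S SNPs declared significant at the tested P-value
#' threshold, out of T SNPs tested. Capped at 1; S = 0 leaves the rate
#' undefined and is reported as 1 with a flag.
#'
#' @param P P-value threshold tested (0 < P < 1).
#' @param S number of SNPs significant at P.
#' @param T_total total number of SNPs tested.
#' @return data.frame of class `fdr_estimate`: `P`, `S`, `T`, `fdr`,
#'   `undefined`.
#' @export
fdr_at_threshold <- function(P, S, T_total) {
  if (any(P <= 0 | P >= 1)) stop("P must lie in (0, 1)")
  if (any(S < 0) || any(S > T_total)) stop("need 0 <= S <= T")
  prop <- S / T_total
  fdr <- ifelse(S == 0, 1, pmin(P * (1 - prop) / (prop * (1 - P)), 1))
  out <- data.frame(P = P, S = S, T = T_total, fdr = fdr,
                    undefined = S == 0)
  class(out) <- c("fdr_estimate", "data.frame")
  out
}

#' Count significant SNPs per trait and per chromosome
#'
#' Strict `<` threshold counting over one or more association-result
#' tables, giving the per-trait totals (the S of the FDR estimator) and a
#' chromosome x trait count matrix for heat-map style summaries.
#'
#' @param results an `assoc_result` data.frame or a list of them
#'   (multiple traits).
#' @param p_threshold significance threshold (strict `<`).
#' @return List: `per_trait` (named vector S), `per_chrom` (chromosome x
#'   trait matrix), `threshold`.
#' @export
count_significant <- function(results, p_threshold) {
  if (is.data.frame(results)) results <- list(results)
  res <- do.call(rbind, lapply(results, as.data.frame))
  if (is.null(res) || !nrow(res)) {
    return(list(per_trait = integer(0),
                per_chrom = matrix(integer(0), 0, 0),
                threshold = p_threshold))
  }
  sig <- !is.na(res$p) & res$p < p_threshold
  per_trait <- tapply(sig, res$trait, sum)
  per_chrom <- table(factor(res$chrom[sig],
                            levels = sort(unique(res$chrom))),
                     factor(res$trait[sig],
                            levels = sort(unique(res$trait))))
  list(per_trait = c(per_trait), per_chrom = unclass(per_chrom),
       threshold = p_threshold)
}

#' Association of summed divergent-allele scores with a trait
#'
#' Regresses the trait on the per-individual taurine-allele score for a
#' target set of divergent SNPs (e.g. one chromosome's divergent regions),
#' with the model's fixed effects, and contrasts the target's -log10 P
#' against control scores built from random selections of equally many
#' divergent SNPs drawn outside excluded chromosomes.
#'
#' @param gm a [geno_matrix()].
#' @param phenotypes phenotype data.frame.
#' @param dset full `divergent_snp_set` (from
#'   [identify_divergent_snps()]).
#' @param target_chrom chromosome whose divergent SNPs form the target set.
#' @param model a [model_spec()].
#' @param n_random_sets number of random control selections (default 10).
#' @param exclude_chrom chromosomes never sampled for controls (default:
#'   the target chromosome).
#' @param seed RNG seed for the control selections.
#' @return List: `target` (data.frame with estimate, se, p, neglog10p,
#'   n_snps), `controls` (one row per control set), `mean_control_neglog10p`.
#' @export
taurine_score_association <- function(gm, phenotypes, dset, target_chrom,
                                      model, n_random_sets = 10,
                                      exclude_chrom = target_chrom,
                                      seed = 1) {
  set.seed(seed)
  on_target <- dset[gm$snps$chrom[dset$snp] == target_chrom, , drop = FALSE]
  if (!nrow(on_target)) stop("no divergent SNPs on the target chromosome")
  pool <- dset[!(gm$snps$chrom[dset$snp] %in% exclude_chrom), ,
               drop = FALSE]
  if (!nrow(pool)) stop("no divergent SNPs outside the excluded chromosomes")
  k <- nrow(on_target)

  score_fit <- function(sub) {
    sc <- taurine_allele_score(gm, sub)
    ph <- phenotypes
    ph$..score <- sc
    ok <- stats::complete.cases(ph[[model$trait]], ph$..score)
    ph <- ph[ok, , drop = FALSE]
    X <- cbind(design_matrix(ph, model), score = ph$..score)
    fit <- stats::lm.fit(X, ph[[model$trait]])
    df <- nrow(X) - ncol(X)
    rss <- sum(fit$residuals^2)
    XtXinv <- tryCatch(chol2inv(chol(crossprod(X))),
                       error = function(e) NULL)
    if (is.null(XtXinv))
      return(data.frame(estimate = NA, se = NA, p = NA, neglog10p = NA,
                        n_snps = nrow(sub)))
    j <- ncol(X)
    se <- sqrt(rss / df * XtXinv[j, j])
    est <- fit$coefficients[j]
    p <- 2 * stats::pt(-abs(est / se), df)
    data.frame(estimate = est, se = se, p = p,
               neglog10p = -log10(pmax(p, .Machine$double.xmin)),
               n_snps = nrow(sub), row.names = NULL)
  }

  target <- score_fit(on_target)
  controls <- do.call(rbind, lapply(seq_len(n_random_sets), function(i) {
    sub <- pool[sample.int(nrow(pool), min(k, nrow(pool))), , drop = FALSE]
    cbind(set = i, score_fit(sub))
  }))
  list(target = target, controls = controls,
       mean_control_neglog10p = mean(controls$neglog10p, na.rm = TRUE))
}

#' Sensitivity of SNP effects to the ancestry covariate
#'
#' Runs the mixed-model scan twice, with and without the ancestry
#' proportion as fixed covariate, and reports the Pearson correlation of
#' the two allele-effect vectors.
#'
#' @inheritParams gwas_scan
#' @return List: `correlation`, `with_ancestry`, `without_ancestry` (the
#'   two `assoc_result` tables).
#' @export
covariate_sensitivity <- function(gm, phenotypes, K, model,
                                  snp_subset = NULL) {
  model_no <- model
  model_no$ancestry <- NULL
  r_with <- gwas_scan(gm, phenotypes, K, model, snp_subset = snp_subset)
  r_without <- gwas_scan(gm, phenotypes, K, model_no,
                         snp_subset = snp_subset)
  ok <- stats::complete.cases(r_with$a, r_without$a)
  list(correlation = stats::cor(r_with$a[ok], r_without$a[ok]),
       with_ancestry = r_with, without_ancestry = r_without)
}

#' Genomic inflation factor
#'
#' Median chi-squared statistic of a scan over its null expectation
#' (0.4549); a calibration diagnostic for polygenic control.
#'
#' @param results an `assoc_result` data.frame.
#' @return Scalar lambda-GC.
#' @export
genomic_inflation <- function(results) {
  t2 <- results$t[!is.na(results$t)]^2
  stats::median(t2) / stats::qchisq(0.5, 1)
}
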