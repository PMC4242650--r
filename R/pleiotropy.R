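#' Correlation matrix of SNP effects across traits
#'
#' Pearson correlations, computed across SNPs, between the per-trait
#' columns of a studentized-effect matrix. Estimated from all SNPs by
#' default; optionally restricted to null-like SNPs (|t| below a cutoff in
#' every trait) for robustness to large-effect loci. A near-singular
#' matrix is repaired by flooring its eigenvalues at 1e-6 and renormalizing
#' to unit diagonal, with a warning.
#'
#' @param t_matrix SNPs x traits matrix of studentized effects (or raw
#'   effects; correlations are scale-free).
#' @param null_like_only restrict estimation to SNPs with all |t| below
#'   `null_t_max` (default FALSE).
#' @param null_t_max cutoff defining null-like SNPs (default 2).
#' @return traits x traits matrix of class `effect_correlation` with
#'   attributes `n_snps` (rows used) and `repaired` (logical).
#' @export
effect_correlation <- function(t_matrix, null_like_only = FALSE,
                               null_t_max = 2) {
  t_matrix <- as.matrix(t_matrix)
  if (nrow(t_matrix) < ncol(t_matrix) + 1)
    stop("need more SNPs than traits to estimate the effect correlation")
  use <- stats::complete.cases(t_matrix)
  if (null_like_only)
    use <- use & apply(abs(t_matrix) < null_t_max, 1, all)
  V <- stats::cor(t_matrix[use, , drop = FALSE])
  repaired <- FALSE
  ev <- eigen(V, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    warning("effect correlation matrix near-singular; ",
            "flooring eigenvalues at 1e-6")
    vals <- pmax(ev$values, 1e-6)
    V <- ev$vectors %*% diag(vals, length(vals)) %*% t(ev$vectors)
    V <- stats::cov2cor(V)
    repaired <- TRUE
  }
  dimnames(V) <- list(colnames(t_matrix), colnames(t_matrix))
  structure(V, n_snps = sum(use), repaired = repaired,
            class = c("effect_correlation", "matrix", "array"))
}

#' Upper-tail chi-squared critical value
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha upper-tail probability (0 < alpha < 1).
#' @return The value exceeded with probability `alpha` under the
#'   chi-squared distribution with `df` degrees of freedom.
#' @export
chi2_critical <- function(df, alpha) {
  if (df < 1) stop("df must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qchisq(1 - alpha, df)
}

#' Multi-trait pleiotropy quadratic form for one SNP
#'
#' Q = t' V^-1 t, where t is the SNP's vector of studentized effects
#' across traits and V the effect correlation matrix. Under the null of no
#' effect on any trait, Q is approximately chi-squared with one degree of
#' freedom per trait; the SNP is flagged pleiotropically significant when
#' Q exceeds the upper-alpha critical value (29.588 for 10 traits at
#' alpha = 0.001).
#'
#' @param t_vector studentized effects, one per trait.
#' @param V effect correlation matrix (same dimension).
#' @param alpha significance level (default 0.001).
#' @return List: `Q`, `critical`, `significant`.
#' @export
pleiotropy_statistic <- function(t_vector, V, alpha = 0.001) {
  if (length(t_vector) != nrow(V)) stop("dim(t) must match dim(V)")
  Q <- drop(crossprod(t_vector, solve(unclass(V), t_vector)))
  crit <- chi2_critical(length(t_vector), alpha)
  list(Q = Q, critical = crit, significant = Q > crit)
}

#' Pleiotropy scan over all SNPs
#'
#' Computes the quadratic form for every row of the studentized-effect
#' matrix against one shared effect correlation matrix (estimated from the
#' matrix itself when not supplied), flags SNPs exceeding the chi-squared
#' critical value, and reports the empirical exceedance fraction — on a
#' null simulation this is the test's realized type-I error at `alpha`.
#'
#' @param t_matrix SNPs x traits studentized effects.
#' @param V optional precomputed [effect_correlation()] matrix.
#' @param alpha significance level (default 0.001).
#' @return List of class `pleiotropy_result`: `table` (data.frame with
#'   `Q`, `significant` per SNP), `V`, `critical`, `exceedance_fraction`,
#'   `alpha`.
#' @export
pleiotropy_scan <- function(t_matrix, V = NULL, alpha = 0.001) {
  t_matrix <- as.matrix(t_matrix)
  if (is.null(V)) V <- effect_correlation(t_matrix)
  Vinv <- solve(unclass(V))
  ok <- stats::complete.cases(t_matrix)
  Q <- rep(NA_real_, nrow(t_matrix))
  Tm <- t_matrix[ok, , drop = FALSE]
  Q[ok] <- rowSums((Tm %*% Vinv) * Tm)
  crit <- chi2_critical(ncol(t_matrix), alpha)
  sig <- !is.na(Q) & Q > crit
  structure(list(table = data.frame(Q = Q, significant = sig),
                 V = V, critical = crit,
                 exceedance_fraction = mean(sig[ok]),
                 alpha = alpha),
            class = "pleiotropy_result")
}

#' Antagonistic-effect report
#'
#' Lists SNPs whose studentized effects on a pair of traits have opposite
#' signs with both magnitudes at or above a threshold — loci where the
#' favourable allele for one trait is unfavourable for the other.
#'
#' @param t_matrix SNPs x traits studentized effects with trait column
#'   names; rownames (if any) identify SNPs.
#' @param trait_pairs data.frame or 2-column matrix of trait-name pairs.
#' @param threshold minimum |t| on both sides (default 2.0).
#' @return data.frame: `snp`, `trait_x`, `trait_y`, `t_x`, `t_y`.
#' @export
antagonism_report <- function(t_matrix, trait_pairs, threshold = 2.0) {
  t_matrix <- as.matrix(t_matrix)
  trait_pairs <- as.matrix(trait_pairs)
  snp_ids <- rownames(t_matrix)
  if (is.null(snp_ids)) snp_ids <- as.character(seq_len(nrow(t_matrix)))
  out <- NULL
  for (r in seq_len(nrow(trait_pairs))) {
    tx <- t_matrix[, trait_pairs[r, 1]]
    ty <- t_matrix[, trait_pairs[r, 2]]
    hit <- which(!is.na(tx) & !is.na(ty) & sign(tx) * sign(ty) < 0 &
                   abs(tx) >= threshold & abs(ty) >= threshold)
    if (length(hit))
      out <- rbind(out, data.frame(snp = snp_ids[hit],
                                   trait_x = trait_pairs[r, 1],
                                   trait_y = trait_pairs[r, 2],
                                   t_x = tx[hit], t_y = ty[hit],
                                   row.names = NULL,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(snp = character(0), trait_x = character(0),
                      trait_y = character(0), t_x = numeric(0),
                      t_y = numeric(0), stringsAsFactors = FALSE)
  out
}

#' Positional candidate genes replicated across two cohorts
#'
#' A gene qualifies when some SNP within `window` base pairs of its
#' interval (nearest-edge distance; 0 if inside) is associated below
#' `p_threshold` in both cohorts with the same effect sign under a shared
#' allele coding. Qualifying genes are joined against a
#' differential-expression table; a DE match requires the gene present
#' with P below `de_p`.
#'
#' @param results_cohort1,results_cohort2 `assoc_result` tables for the
#'   same SNPs (matched by `snp` id) in the two cohorts.
#' @param annotation data.frame: `gene`, `chrom`, `start`, `end` (bp).
#' @param de_table optional data.frame: `gene`, `fold_change`, `p`.
#' @param p_threshold per-cohort association threshold (default 0.01,
#'   strict `<`).
#' @param window maximum SNP-gene distance in bp (default 3000).
#' @param de_p DE significance threshold (default 0.05).
#' @return data.frame of class `candidate_gene_list`: `gene`, `chrom`,
#'   `start`, `end`, `snp`, `distance`, `p1`, `p2`, `sign`, `de_match`,
#'   `fold_change` (best-supported SNP per gene: smallest p1 * p2).
#' @export
candidate_gene_intersection <- function(results_cohort1, results_cohort2,
                                        annotation, de_table = NULL,
                                        p_threshold = 0.01, window = 3000,
                                        de_p = 0.05) {
  r1 <- as.data.frame(results_cohort1)
  r2 <- as.data.frame(results_cohort2)
  m <- match(r1$snp, r2$snp)
  keep <- !is.na(m) & !is.na(r1$p) & !is.na(r2$p[m]) &
    r1$p < p_threshold & r2$p[m] < p_threshold &
    sign(r1$a) == sign(r2$a[m]) & r1$a != 0
  hits <- r1[keep, , drop = FALSE]
  hits$p2 <- r2$p[m][keep]
  empty <- data.frame(gene = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      snp = character(0), distance = numeric(0),
                      p1 = numeric(0), p2 = numeric(0), sign = numeric(0),
                      de_match = logical(0), fold_change = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("candidate_gene_list", "data.frame")
  if (!nrow(hits)) return(empty)

  snp_gr <- GenomicRanges::GRanges(
    seqnames = as.character(hits$chrom),
    ranges = IRanges::IRanges(start = hits$pos, width = 1))
  gene_gr <- GenomicRanges::GRanges(
    seqnames = as.character(annotation$chrom),
    ranges = IRanges::IRanges(start = annotation$start,
                              end = annotation$end))
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr, maxgap = window)
  if (!length(ov)) return(empty)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  dist <- GenomicRanges::distance(snp_gr[qi], gene_gr[si])
  cand <- data.frame(gene = annotation$gene[si],
                     chrom = as.character(annotation$chrom[si]),
                     start = annotation$start[si],
                     end = annotation$end[si],
                     snp = hits$snp[qi],
                     distance = as.numeric(dist),
                     p1 = hits$p[qi], p2 = hits$p2[qi],
                     sign = sign(hits$a[qi]),
                     stringsAsFactors = FALSE)
  cand <- cand[cand$distance <= window, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  # best-supported SNP per gene
  cand <- cand[order(cand$gene, cand$p1 * cand$p2), , drop = FALSE]
  cand <- cand[!duplicated(cand$gene), , drop = FALSE]
  if (!is.null(de_table)) {
    dm <- match(cand$gene, de_table$gene)
    cand$de_match <- !is.na(dm) & de_table$p[dm] < de_p
    cand$fold_change <- ifelse(cand$de_match, de_table$fold_change[dm],
                               NA_real_)
  } else {
    cand$de_match <- FALSE
    cand$fold_change <- NA_real_
  }
  rownames(cand) <- NULL
  class(cand) <- c("candidate_gene_list", "data.frame")
  cand
}
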