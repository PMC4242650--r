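#' Identify divergent SNPs between two reference panels
#'
#' A SNP is divergent when one of its alleles has frequency strictly above
#' `hi` in panel A (taurine) and strictly below `lo` in panel B (indicine);
#' that allele is recorded as the "taurine" allele. Both allele orientations
#' are checked, so the rule is invariant to which allele the file counts.
#'
#' @param freq_A,freq_B per-SNP B-allele frequencies in the two panels
#'   (equal length, same SNP order). Vectors or the `freq_A`/`freq_B` fields
#'   of [simulate_ancestral_panels()] output.
#' @param hi,lo frequency bounds (defaults 0.95 and 0.05, strict
#'   inequalities).
#' @return data.frame of class `divergent_snp_set` with columns `snp`
#'   (column index) and `taurine_allele` (`"B"` if the counted allele is the
#'   taurine allele, `"A"` otherwise).
#' @export
identify_divergent_snps <- function(freq_A, freq_B, hi = 0.95, lo = 0.05) {
  if (length(freq_A) != length(freq_B))
    stop("panels must cover the same SNPs")
  b_is_taurine <- !is.na(freq_A) & !is.na(freq_B) & freq_A > hi & freq_B < lo
  a_is_taurine <- !is.na(freq_A) & !is.na(freq_B) &
    (1 - freq_A) > hi & (1 - freq_B) < lo
  snp <- which(b_is_taurine | a_is_taurine)
  out <- data.frame(snp = snp,
                    taurine_allele = ifelse(b_is_taurine[snp], "B", "A"),
                    stringsAsFactors = FALSE)
  class(out) <- c("divergent_snp_set", "data.frame")
  out
}

#' Per-individual taurine-allele score
#'
#' Sums the taurine-allele dosage (0/1/2 per SNP) over a divergent SNP set.
#' For SNPs whose taurine allele is the uncounted A allele the dosage is
#' 2 - g. Missing calls are excluded and the score rescaled to the full-set
#' scale (x set size / non-missing count, rounded to the nearest integer),
#' so scores remain comparable across individuals with different call rates.
#'
#' @param gm a [geno_matrix()].
#' @param dset a `divergent_snp_set` from [identify_divergent_snps()].
#' @return Integer vector of scores, one per individual (0..2 x set size).
#' @export
taurine_allele_score <- function(gm, dset) {
  if (!nrow(dset)) return(rep(0L, nrow(gm$data)))
  if (any(dset$snp > ncol(gm$data)))
    stop("divergent set references SNPs absent from the genotype matrix")
  G <- gm$data[, dset$snp, drop = FALSE]
  flip <- dset$taurine_allele == "A"
  G[, flip] <- 2L - G[, flip, drop = FALSE]
  n_obs <- rowSums(!is.na(G))
  raw <- rowSums(G, na.rm = TRUE)
  score <- ifelse(n_obs == 0L, NA_real_, raw * nrow(dset) / pmax(n_obs, 1L))
  as.integer(round(score))
}
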