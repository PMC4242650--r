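#' Composite-genotype linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the 0/1/2 dosage vectors of two SNPs over
#' jointly non-missing individuals. This is the composite (genotypic) measure
#' of LD, the natural choice for unphased data; it is invariant to relabeling
#' either SNP's alleles (a 0<->2 flip changes the sign of r only).
#'
#' @param gm a [geno_matrix()].
#' @param i,j SNP column indices.
#' @return r-squared in `[0, 1]`; a pair monomorphic among jointly observed
#'   individuals is undefined and returned as 0 with attribute
#'   `monomorphic = TRUE` (treated as no LD by the pruner).
#' @export
ld_r2 <- function(gm, i, j) {
  x <- gm$data[, i]; y <- gm$data[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0) {
    out <- 0
    attr(out, "monomorphic") <- TRUE
    return(out)
  }
  stats::cor(x, y)^2
}

# dosage correlation matrix over a block of SNP columns, pairwise-complete,
# monomorphic columns giving r = 0
block_r2 <- function(G) {
  suppressWarnings(r <- stats::cor(G, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Sliding-window LD pruning
#'
#' Works per chromosome on SNPs sorted by position. A window of `window`
#' currently retained SNPs is examined; while any pair inside has
#' r-squared above `r2_max`, the pair with the highest r-squared is located
#' and one member is removed (the one with the lower minor-allele frequency;
#' on ties, the later SNP). The window then advances by `step` retained SNPs.
#' Whole sweeps repeat until a sweep removes nothing, so the output is a
#' fixed point: pruning it again changes nothing, and no final window
#' placement contains a violating pair.
#'
#' @param gm a [geno_matrix()] with SNPs sorted by (chrom, pos).
#' @param window window size in retained SNPs (default 50).
#' @param step window advance in retained SNPs (default 10).
#' @param r2_max removal threshold on r-squared (default 0.5, strict `>`).
#' @return Integer vector of retained SNP column indices, in input order.
#' @export
ld_prune <- function(gm, window = 50, step = 10, r2_max = 0.5) {
  snps <- gm$snps
  ord <- order(snps$chrom, snps$pos)
  if (any(ord != seq_along(ord)))
    stop("SNPs must be sorted by (chrom, pos) before pruning")
  freq <- allele_frequencies(gm)
  maf <- pmin(freq, 1 - freq)
  keep_all <- integer(0)
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    retained <- idx
    repeat {
      removed_this_sweep <- FALSE
      pos <- 1L
      repeat {
        if (pos > length(retained)) break
        win_end <- min(pos + window - 1L, length(retained))
        win <- retained[pos:win_end]
        if (length(win) >= 2L) {
          repeat {
            R2 <- block_r2(gm$data[, win, drop = FALSE])
            R2[lower.tri(R2, diag = TRUE)] <- 0
            if (max(R2) <= r2_max) break
            hit <- which(R2 == max(R2), arr.ind = TRUE)[1L, ]
            a <- win[hit[1L]]; b <- win[hit[2L]]
            drop_snp <- if (isTRUE(maf[a] < maf[b])) a
                        else if (isTRUE(maf[b] < maf[a])) b
                        else max(a, b)
            win <- setdiff(win, drop_snp)
            retained <- setdiff(retained, drop_snp)
            removed_this_sweep <- TRUE
            if (length(win) < 2L) break
          }
        }
        if (win_end >= length(retained)) break
        pos <- pos + step
      }
      if (!removed_this_sweep) break
    }
    keep_all <- c(keep_all, retained)
  }
  sort(keep_all)
}

#' Sliding-window mean allele frequency
#'
#' Mean B-allele ("forward" allele of the file encoding) frequency in windows
#' of `window` consecutive SNPs advanced at `pace` SNPs, on one chromosome.
#' Used to profile divergent-frequency regions along a chromosome.
#'
#' @param gm a [geno_matrix()].
#' @param chrom chromosome to profile.
#' @param subset optional SNP column indices restricting the profile (e.g. a
#'   pruned set); defaults to all SNPs on `chrom`.
#' @param window number of consecutive SNPs per window (default 100).
#' @param pace window advance in SNPs (default 1).
#' @return data.frame with `start`, `end` (SNP column indices), `mid_pos`
#'   (midpoint in bp) and `mean_freq` per window.
#' @export
sliding_allele_freq <- function(gm, chrom, subset = NULL, window = 100,
                                pace = 1) {
  idx <- which(gm$snps$chrom == chrom)
  if (!is.null(subset)) idx <- intersect(subset, idx)
  idx <- idx[order(gm$snps$pos[idx])]
  if (length(idx) < window)
    stop("need at least ", window, " SNPs on chromosome ", chrom)
  freq <- allele_frequencies(gm)[idx]
  starts <- seq(1L, length(idx) - window + 1L, by = pace)
  means <- vapply(starts,
                  function(s) mean(freq[s:(s + window - 1L)], na.rm = TRUE),
                  numeric(1))
  mids <- vapply(starts, function(s) {
    p <- gm$snps$pos[idx[c(s, s + window - 1L)]]
    mean(p)
  }, numeric(1))
  data.frame(start = idx[starts], end = idx[starts + window - 1L],
             mid_pos = mids, mean_freq = means)
}
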