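#' Genotype matrix container
#'
#' Bundles an individuals x SNPs matrix of counted B alleles (0, 1, 2, with
#' `NA` marking missing calls) together with individual identifiers and SNP
#' metadata. All association and population-structure machinery in the
#' package operates on this container.
#'
#' @param data integer matrix, individuals in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param ids character vector of individual identifiers, one per row.
#' @param snps data.frame of SNP metadata with columns `id`, `chrom`, `pos`
#'   (base pairs, 1-based in all file output), `allele_A`, `allele_B`. The
#'   B allele is the counted allele.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(data, ids, snps) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (nrow(data) != length(ids))
    stop("number of rows of 'data' must equal length of 'ids'")
  if (ncol(data) != nrow(snps))
    stop("number of columns of 'data' must equal rows of 'snps'")
  required <- c("id", "chrom", "pos", "allele_A", "allele_B")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols))
    stop("'snps' lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- data[!is.na(data)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotypes must be 0, 1, 2 or NA")
  if (any(snps$pos < 1)) stop("SNP positions must be >= 1")
  if (any(snps$allele_A == snps$allele_B))
    stop("allele_A and allele_B must differ for every SNP")
  key <- paste(snps$chrom, snps$pos, snps$allele_A, snps$allele_B)
  if (anyDuplicated(key))
    stop("duplicated SNP by (chrom, pos, alleles)")
  snps$id <- as.character(snps$id)
  snps$pos <- as.integer(snps$pos)
  rownames(data) <- ids
  colnames(data) <- snps$id
  structure(list(data = data, ids = as.character(ids),
                 snps = as.data.frame(snps, stringsAsFactors = FALSE)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d SNPs (%d chromosome(s), %.2f%% missing)\n",
              nrow(x$data), ncol(x$data), length(unique(x$snps$chrom)),
              100 * mean(is.na(x$data))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$data)

#' Subset a genotype matrix
#'
#' @param x a `geno_matrix`.
#' @param i individual (row) index, optional.
#' @param j SNP (column) index, optional.
#' @param ... ignored.
#' @return A `geno_matrix` restricted to the requested individuals and SNPs.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$data))
  if (missing(j)) j <- seq_len(ncol(x$data))
  geno_matrix(x$data[i, j, drop = FALSE], x$ids[i], x$snps[j, , drop = FALSE])
}

#' Per-SNP B-allele frequencies
#'
#' Frequency of the counted (B) allele, computed over non-missing calls:
#' sum of dosages over twice the number of non-missing individuals. SNPs with
#' no non-missing call get `NA` and are flagged so callers can exclude them.
#'
#' @param gm a `geno_matrix`.
#' @return Numeric vector of B-allele frequencies (named by SNP id) with an
#'   attribute `undefined`: logical vector marking all-missing SNPs.
#' @export
allele_frequencies <- function(gm) {
  n_called <- colSums(!is.na(gm$data))
  freq <- colSums(gm$data, na.rm = TRUE) / (2 * n_called)
  undefined <- n_called == 0L
  freq[undefined] <- NA_real_
  names(freq) <- gm$snps$id
  attr(freq, "undefined") <- undefined
  freq
}

# mean-impute missing dosages, column-wise; all-missing columns -> 0
impute_mean <- function(G) {
  if (!anyNA(G)) return(G)
  mu <- colMeans(G, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(G), arr.ind = TRUE)
  G[idx] <- mu[idx[, 2L]]
  G
}
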