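#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centres each SNP's dosage by twice its allele frequency and scales the
#' cross-product by 2*sum(p*q): K = Z Z' / (2*sum p(1-p)). Missing genotypes
#' are mean-imputed per SNP; monomorphic SNPs contribute nothing.
#'
#' @param gm a [geno_matrix()].
#' @param freq optional externally supplied B-allele frequencies (e.g. base
#'   population frequencies); defaults to the cohort's observed frequencies.
#' @return n x n symmetric matrix of class `relationship_matrix` with
#'   attribute `kind = "genomic"`.
#' @export
genomic_relationship <- function(gm, freq = NULL) {
  G <- impute_mean(gm$data)
  storage.mode(G) <- "double"
  if (is.null(freq)) freq <- colMeans(G) / 2
  poly <- freq > 0 & freq < 1
  if (sum(poly) < 2L) stop("need at least 2 polymorphic SNPs")
  Z <- sweep(G[, poly, drop = FALSE], 2, 2 * freq[poly])
  denom <- 2 * sum(freq[poly] * (1 - freq[poly]))
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(gm$ids, gm$ids)
  structure(K, kind = "genomic", class = c("relationship_matrix", "matrix",
                                           "array"))
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds A over all individuals in the pedigree by the tabular recursion:
#' a_ij = 0.5 (a_{i,sire(j)} + a_{i,dam(j)}) for i earlier than j, and
#' a_jj = 1 + 0.5 a_{sire(j),dam(j)}. Unknown parents (NA, "0" or "")
#' contribute zero. The pedigree is topologically sorted internally, so input
#' order is free; the returned matrix follows the input record order.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return n x n matrix of class `relationship_matrix`, `kind = "pedigree"`.
#' @export
pedigree_nrm <- function(ped) {
  ids <- as.character(ped$id)
  if (anyDuplicated(ids)) stop("duplicated individual ids in pedigree")
  clean <- function(p) {
    p <- as.character(p)
    p[is.na(p) | p %in% c("0", "")] <- NA_character_
    p
  }
  sire <- clean(ped$sire); dam <- clean(ped$dam)
  unknown_refs <- setdiff(stats::na.omit(c(sire, dam)), ids)
  if (length(unknown_refs))
    stop("pedigree references absent individuals: ",
         paste(utils::head(unknown_refs, 5), collapse = ", "))
  n <- length(ids)
  # topological order: parents before offspring
  order_idx <- integer(0)
  placed <- logical(n)
  si <- match(sire, ids); di <- match(dam, ids)
  repeat {
    ready <- which(!placed &
                   (is.na(si) | placed[pmax(si, 1L)] | is.na(si)) &
                   (is.na(di) | placed[pmax(di, 1L)] | is.na(di)))
    ready <- ready[(is.na(si[ready]) | placed[si[ready]]) &
                   (is.na(di[ready]) | placed[di[ready]])]
    if (!length(ready)) break
    order_idx <- c(order_idx, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed)) stop("pedigree contains a cycle")
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in order_idx) {
    s <- si[j]; d <- di[j]
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
    earlier <- order_idx[seq_len(which(order_idx == j) - 1L)]
    if (length(earlier)) {
      contrib <- 0.5 * ((if (!is.na(s)) A[earlier, s] else 0) +
                        (if (!is.na(d)) A[earlier, d] else 0))
      A[earlier, j] <- contrib
      A[j, earlier] <- contrib
    }
  }
  structure(A, kind = "pedigree", class = c("relationship_matrix", "matrix",
                                            "array"))
}

#' Classical multidimensional scaling of genotype similarity
#'
#' Computes allele-sharing distance 1 - IBS (mean absolute dosage difference
#' over 2m, after per-SNP mean imputation) and applies classical MDS
#' (double-centred eigendecomposition, `cmdscale`). A precomputed distance
#' matrix may be supplied instead of genotypes.
#'
#' @param x a [geno_matrix()] or an n x n distance matrix (class `dist` or
#'   symmetric matrix).
#' @param k number of coordinates (default 2).
#' @return List with `points` (n x k, ordered by eigenvalue) and
#'   `eig` (all eigenvalues, non-increasing).
#' @export
mds <- function(x, k = 2) {
  if (inherits(x, "geno_matrix")) {
    G <- impute_mean(x$data)
    storage.mode(G) <- "double"
    D <- as.matrix(stats::dist(G, method = "manhattan")) / (2 * ncol(G))
  } else {
    D <- as.matrix(x)
  }
  if (nrow(D) < k + 1) stop("need at least k + 1 individuals")
  fit <- stats::cmdscale(D, k = k, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {  # cmdscale drops null dimensions; pad with zeros
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  list(points = pts, eig = fit$eig)
}
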