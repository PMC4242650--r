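#' Panel allele frequencies with pseudocount smoothing
#'
#' B-allele frequencies from reference-panel genotypes with a +0.5 / +1
#' pseudocount, keeping fixed sites away from 0 and 1 so the supervised
#' likelihood never evaluates log(0).
#'
#' @param gm a [geno_matrix()] of reference-panel individuals.
#' @return Numeric vector of smoothed frequencies.
#' @export
panel_frequencies <- function(gm) {
  n_called <- colSums(!is.na(gm$data))
  (colSums(gm$data, na.rm = TRUE) + 0.5) / (2 * n_called + 1)
}

#' Supervised two-population ancestry estimation
#'
#' Per individual i, the genotype at SNP j is modelled Binomial(2, pi_ij)
#' with pi_ij = lambda_i f_Bj + (1 - lambda_i) f_Aj, and lambda_i (the
#' proportion attributed to panel B, "indicine%") maximizes the
#' log-likelihood by EM on allele-origin posteriors. The two-population
#' supervised problem decouples across individuals, so each lambda is an
#' independent 1-D maximization; the EM update is monotone in the
#' likelihood. An LD-pruned SNP set is recommended as input.
#'
#' @param gm cohort [geno_matrix()].
#' @param freq_A,freq_B per-SNP panel frequencies of the B allele; numeric
#'   vectors (e.g. from [panel_frequencies()] or an `ancestral_panels`
#'   object's fields). Clamped to `[eps, 1-eps]`.
#' @param eps frequency clamp (default 1e-4).
#' @param tol EM convergence on `|delta lambda|` (default 1e-8).
#' @param max_iter maximum EM iterations (default 500).
#' @return data.frame of class `ancestry_estimate`: `id`, `lambda_hat`,
#'   `loglik`, `iterations`, `degenerate` (TRUE when the panels carry no
#'   information, in which case `lambda_hat` is 0.5).
#' @export
estimate_ancestry_supervised <- function(gm, freq_A, freq_B, eps = 1e-4,
                                         tol = 1e-8, max_iter = 500) {
  if (length(freq_A) != ncol(gm$data) || length(freq_B) != ncol(gm$data))
    stop("panel frequency vectors must match the SNP count")
  fA <- pmin(pmax(freq_A, eps), 1 - eps)
  fB <- pmin(pmax(freq_B, eps), 1 - eps)
  n <- nrow(gm$data)
  degenerate <- all(abs(fA - fB) < 1e-12)
  if (degenerate) {
    out <- data.frame(id = gm$ids, lambda_hat = 0.5, loglik = NA_real_,
                      iterations = 0L, degenerate = TRUE,
                      stringsAsFactors = FALSE)
    class(out) <- c("ancestry_estimate", "data.frame")
    return(out)
  }
  G <- t(gm$data)                       # SNPs x individuals
  miss <- is.na(G)
  G0 <- G; G0[miss] <- 0L
  m_eff <- colSums(!miss)               # informative allele draws / 2
  # loop-invariant observed-allele counts (missing already zeroed)
  nB <- G0
  nA <- (2L - G0) * !miss
  lambda <- rep(0.5, n)
  it <- 0L
  repeat {
    it <- it + 1L
    # posterior that a B-type (counted) allele copy is of B-panel origin,
    # and likewise for an A-type copy, per SNP x individual
    pB <- fB %o% lambda
    denB <- pB + fA %o% (1 - lambda)
    pA <- (1 - fB) %o% lambda
    denA <- pA + (1 - fA) %o% (1 - lambda)
    expected_B_origin <- colSums(nB * (pB / denB) + nA * (pA / denA))
    lambda_new <- expected_B_origin / (2 * m_eff)
    lambda_new[m_eff == 0] <- 0.5
    delta <- max(abs(lambda_new - lambda))
    lambda <- lambda_new
    if (delta < tol || it >= max_iter) break
  }
  pi_hat <- outer(fB, lambda, function(f, l) l * f) +
    outer(fA, lambda, function(f, l) (1 - l) * f)
  ll_terms <- G0 * log(pi_hat) + (2L - G0) * log(1 - pi_hat)
  ll_terms[miss] <- 0
  out <- data.frame(id = gm$ids, lambda_hat = pmin(pmax(lambda, 0), 1),
                    loglik = colSums(ll_terms), iterations = it,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("ancestry_estimate", "data.frame")
  out
}

# log-likelihood of one lambda vector (diagnostic / test hook)
ancestry_loglik <- function(gm, freq_A, freq_B, lambda, eps = 1e-4) {
  fA <- pmin(pmax(freq_A, eps), 1 - eps)
  fB <- pmin(pmax(freq_B, eps), 1 - eps)
  G <- t(gm$data); miss <- is.na(G); G0 <- G; G0[miss] <- 0L
  pi_hat <- outer(fB, lambda, function(f, l) l * f) +
    outer(fA, lambda, function(f, l) (1 - l) * f)
  ll <- G0 * log(pi_hat) + (2L - G0) * log(1 - pi_hat)
  ll[miss] <- 0
  colSums(ll)
}

#' Sensitivity of ancestry estimates to the reference panels
#'
#' Re-estimates per-individual ancestry under each supplied panel pair and
#' returns the Pearson correlation matrix of the estimates, mirroring the
#' check that alternative taurine/indicine reference breeds give highly
#' correlated indicine% estimates.
#'
#' @param gm cohort [geno_matrix()].
#' @param panel_sets named list; each element a list with `freq_A` and
#'   `freq_B` vectors (or a `geno_matrix` pair under names `A`, `B`, from
#'   which smoothed frequencies are taken).
#' @param ... passed to [estimate_ancestry_supervised()].
#' @return List with `correlations` (set x set matrix), `estimates`
#'   (individuals x set matrix of lambda-hat) and `degenerate` (per-set
#'   flag).
#' @export
panel_sensitivity <- function(gm, panel_sets, ...) {
  if (length(panel_sets) < 2) stop("need at least 2 panel sets")
  est <- sapply(panel_sets, function(ps) {
    fA <- if (inherits(ps$A, "geno_matrix")) panel_frequencies(ps$A)
          else ps$freq_A
    fB <- if (inherits(ps$B, "geno_matrix")) panel_frequencies(ps$B)
          else ps$freq_B
    estimate_ancestry_supervised(gm, fA, fB, ...)$lambda_hat
  })
  deg <- apply(est, 2, function(v) stats::sd(v) < 1e-12)
  suppressWarnings(r <- stats::cor(est))
  r[deg, ] <- NA_real_; r[, deg] <- NA_real_
  diag(r) <- 1
  list(correlations = r, estimates = est, degenerate = deg)
}

#' Split a cohort by estimated ancestry
#'
#' Partitions individuals at a threshold on lambda-hat with `<` versus `>=`
#' semantics (an individual exactly at the threshold belongs to the upper
#' group).
#'
#' @param estimates an `ancestry_estimate` data.frame or a numeric
#'   lambda-hat vector.
#' @param threshold split point (default 0.30).
#' @return List with index vectors `below` and `at_or_above`.
#' @export
split_by_ancestry <- function(estimates, threshold = 0.30) {
  lam <- if (is.data.frame(estimates)) estimates$lambda_hat else estimates
  below <- which(lam < threshold)
  above <- which(lam >= threshold)
  if (!length(above)) warning("upper ancestry group is empty")
  if (!length(below)) warning("lower ancestry group is empty")
  list(below = below, at_or_above = above)
}
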