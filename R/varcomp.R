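#' Model specification for the animal model and GWAS
#'
#' Records the trait column and the fixed-effect structure used throughout:
#' contemporary group (categorical, sex x year x location by default), age
#' of dam (linear covariate by default), ancestry proportion (linear
#' covariate), and optionally the AGE12 covariate for the yearling-weight
#' analogue.
#'
#' @param trait trait column name in the phenotype table.
#' @param contemporary_group name of the categorical contemporary-group
#'   column (default `"cg"`); `NULL` drops it.
#' @param age_of_dam name of the age-of-dam column (default
#'   `"age_of_dam"`); fitted as linear unless `age_of_dam_categorical`.
#' @param age_of_dam_categorical fit age of dam as a factor (default FALSE).
#' @param ancestry name of the ancestry-proportion column (default
#'   `"lambda_true"`; use the estimate column when available); `NULL` drops
#'   the covariate.
#' @param age12 optional name of the AGE12 covariate column (default NULL).
#' @return List of class `model_spec`.
#' @export
model_spec <- function(trait, contemporary_group = "cg",
                       age_of_dam = "age_of_dam",
                       age_of_dam_categorical = FALSE,
                       ancestry = "lambda_true", age12 = NULL) {
  structure(list(trait = trait, contemporary_group = contemporary_group,
                 age_of_dam = age_of_dam,
                 age_of_dam_categorical = age_of_dam_categorical,
                 ancestry = ancestry, age12 = age12),
            class = "model_spec")
}

# fixed-effect design matrix (with intercept), reference levels dropped,
# then reduced to full column rank
design_matrix <- function(phenotypes, model) {
  terms <- character(0)
  if (!is.null(model$contemporary_group))
    terms <- c(terms, sprintf("factor(%s)", model$contemporary_group))
  if (!is.null(model$age_of_dam))
    terms <- c(terms, if (model$age_of_dam_categorical)
      sprintf("factor(%s)", model$age_of_dam) else model$age_of_dam)
  if (!is.null(model$ancestry)) terms <- c(terms, model$ancestry)
  if (!is.null(model$age12)) terms <- c(terms, model$age12)
  f <- stats::as.formula(paste("~", if (length(terms))
    paste(terms, collapse = " + ") else "1"))
  X <- stats::model.matrix(f, data = phenotypes)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) X <- X[, qr_x$pivot[seq_len(qr_x$rank)],
                                  drop = FALSE]
  X
}

# eigendecomposition of a relationship matrix with PSD bending
relmat_eigen <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < 0) {
    warning("relationship matrix not positive semi-definite; ",
            "bending smallest eigenvalues to 1e-6")
    e$values <- pmax(e$values, 1e-6)
  }
  e
}

# REML log-likelihood profiled over sigma2_e, as a function of
# log(delta = sigma2_g / sigma2_e); yr, Xr rotated by eigenvectors
reml_profile_ll <- function(log_delta, yr, Xr, d) {
  delta <- exp(log_delta)
  v <- delta * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xr, Xr * w)
  XtWy <- crossprod(Xr, yr * w)
  beta <- solve(XtWX, XtWy)
  r <- yr - Xr %*% beta
  np <- length(yr) - ncol(Xr)
  rss <- sum(w * r^2)
  sigma2_e <- rss / np
  ll <- -0.5 * (np * log(2 * pi * sigma2_e) + np +
                  sum(log(v)) + determinant(XtWX)$modulus[1])
  attr(ll, "sigma2_e") <- sigma2_e
  attr(ll, "beta") <- beta
  ll
}

#' Animal-model REML fit
#'
#' Univariate mixed model y = Xb + g + e with Var(g) = sigma2_g K and
#' Var(e) = sigma2_e I, maximized by restricted maximum likelihood. The
#' relationship matrix is eigendecomposed once; rotating into its
#' eigenbasis diagonalizes the covariance, so the REML likelihood reduces
#' to a 1-D profile over the variance ratio delta = sigma2_g / sigma2_e,
#' optimized by golden-section/parabolic search on log(delta). Exact for
#' this model class; O(n^3) once.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (with intercept), or a
#'   [model_spec()] together with `phenotypes`.
#' @param K relationship matrix (genomic or pedigree), covering the same
#'   individuals in the same order as `y`; or a precomputed eigen object
#'   via `eig`.
#' @param phenotypes optional phenotype data.frame when `X` is a
#'   [model_spec()].
#' @param eig optional precomputed `eigen(K)` (reused across traits).
#' @return List of class `reml_fit`: `sigma2_g`, `sigma2_e`, `h2`,
#'   `se_h2`, `loglik`, `converged`, `delta`, `beta`, `eig`, `X`.
#' @export
reml_fit <- function(y, X, K = NULL, phenotypes = NULL, eig = NULL) {
  if (inherits(X, "model_spec")) {
    model <- X
    ok <- stats::complete.cases(phenotypes[[model$trait]])
    phenotypes <- phenotypes[ok, , drop = FALSE]
    y <- phenotypes[[model$trait]]
    X <- design_matrix(phenotypes, model)
    if (!is.null(K) && nrow(K) != length(y))
      K <- K[ok, ok, drop = FALSE]
  }
  if (length(y) < 50)
    stop("need at least 50 records for REML")
  if (is.null(eig)) {
    if (is.null(K)) stop("supply K or its eigendecomposition")
    eig <- relmat_eigen(unclass(K))
  }
  d <- eig$values
  yr <- crossprod(eig$vectors, y)
  Xr <- crossprod(eig$vectors, X)

  opt <- stats::optimize(function(ld) as.numeric(
    reml_profile_ll(ld, yr, Xr, d)), interval = c(-12, 12), maximum = TRUE,
    tol = 1e-10)
  # boundary handling: compare against a vanishing genetic component
  ll_null <- as.numeric(reml_profile_ll(-30, yr, Xr, d))
  at_boundary <- ll_null >= opt$objective - 1e-8
  log_delta <- if (at_boundary) -30 else opt$maximum
  ll <- reml_profile_ll(log_delta, yr, Xr, d)
  sigma2_e <- attr(ll, "sigma2_e")
  delta <- exp(log_delta)
  sigma2_g <- delta * sigma2_e
  h2 <- sigma2_g / (sigma2_g + sigma2_e)

  # numerical gradient at the optimum (convergence diagnostic)
  if (!at_boundary) {
    h <- 1e-5
    grad <- (as.numeric(reml_profile_ll(log_delta + h, yr, Xr, d)) -
             as.numeric(reml_profile_ll(log_delta - h, yr, Xr, d))) / (2 * h)
    converged <- abs(grad) < 1e-3
  } else converged <- TRUE

  # SE of h2 by the delta method on log(delta); curvature from finite
  # differences of the profile likelihood
  se_h2 <- NA_real_
  if (!at_boundary) {
    h <- 1e-3
    f0 <- opt$objective
    fp <- as.numeric(reml_profile_ll(log_delta + h, yr, Xr, d))
    fm <- as.numeric(reml_profile_ll(log_delta - h, yr, Xr, d))
    curv <- -(fp - 2 * f0 + fm) / h^2
    if (is.finite(curv) && curv > 0) {
      var_logdelta <- 1 / curv
      dh_dlogdelta <- delta / (1 + delta)^2
      se_h2 <- sqrt(var_logdelta) * dh_dlogdelta
    }
  }
  structure(list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, h2 = h2,
                 se_h2 = se_h2, loglik = as.numeric(ll),
                 converged = converged, delta = delta,
                 beta = attr(ll, "beta"), eig = eig, X = X),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "reml_fit: sigma2_g = %.4f, sigma2_e = %.4f, h2 = %.3f (SE %.3f)%s\n",
    x$sigma2_g, x$sigma2_e, x$h2, x$se_h2,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}

# fixed-effect-adjusted, standardized trait (OLS residuals, unit variance)
adjust_trait <- function(phenotypes, model) {
  y <- phenotypes[[model$trait]]
  X <- design_matrix(phenotypes, model)
  r <- stats::lm.fit(X, y)$residuals
  r / stats::sd(r)
}

#' Genetic correlation via the sum-trait variance identity
#'
#' Both traits are adjusted for their fixed effects and standardized; the
#' genetic variances of x, y and x + y are each estimated by univariate
#' REML against the same relationship matrix, and
#' rg = (Vg(x+y) - Vg(x) - Vg(y)) / (2 sqrt(Vg(x) Vg(y))), clamped to
#' [-1, 1]. A deliberate simplification of full bivariate REML: one
#' well-tested univariate maximizer is reused three times.
#'
#' @param phenotypes phenotype data.frame (complete cases on both traits
#'   are used).
#' @param K relationship matrix over the phenotype rows.
#' @param model_x,model_y [model_spec()] for the two traits.
#' @return List: `rg`, `vg_x`, `vg_y`, `vg_sum`.
#' @export
genetic_correlation <- function(phenotypes, K, model_x, model_y) {
  ok <- stats::complete.cases(phenotypes[[model_x$trait]],
                              phenotypes[[model_y$trait]])
  ph <- phenotypes[ok, , drop = FALSE]
  Ksub <- unclass(K)[ok, ok, drop = FALSE]
  eig <- relmat_eigen(Ksub)
  x <- adjust_trait(ph, model_x)
  y <- adjust_trait(ph, model_y)
  one <- matrix(1, length(x), 1)
  fx <- reml_fit(x, one, eig = eig)
  fy <- reml_fit(y, one, eig = eig)
  fs <- reml_fit(x + y, one, eig = eig)
  if (fx$sigma2_g <= 0 || fy$sigma2_g <= 0)
    return(list(rg = NA_real_, vg_x = fx$sigma2_g, vg_y = fy$sigma2_g,
                vg_sum = fs$sigma2_g))
  rg <- (fs$sigma2_g - fx$sigma2_g - fy$sigma2_g) /
    (2 * sqrt(fx$sigma2_g * fy$sigma2_g))
  list(rg = min(max(rg, -1), 1), vg_x = fx$sigma2_g, vg_y = fy$sigma2_g,
       vg_sum = fs$sigma2_g)
}

#' Phenotypic correlation of fixed-effect-adjusted traits
#'
#' Pearson correlation of the OLS residuals of the two traits on their
#' fixed effects.
#'
#' @inheritParams genetic_correlation
#' @return Scalar correlation.
#' @export
phenotypic_correlation <- function(phenotypes, model_x, model_y) {
  ok <- stats::complete.cases(phenotypes[[model_x$trait]],
                              phenotypes[[model_y$trait]])
  ph <- phenotypes[ok, , drop = FALSE]
  stats::cor(adjust_trait(ph, model_x), adjust_trait(ph, model_y))
}

#' Effect of ancestry proportion on a trait
#'
#' Ordinary least squares of the trait on the ancestry covariate plus the
#' model's other fixed effects, within the full cohort or an ancestry
#' subgroup, with significance judged at the Bonferroni-adjusted level
#' alpha = 0.005.
#'
#' @param phenotypes phenotype data.frame including the ancestry column.
#' @param model a [model_spec()]; its `ancestry` column is the covariate of
#'   interest.
#' @param subgroup `"all"`, `"below"` or `"at_or_above"` relative to
#'   `threshold` on the ancestry column.
#' @param threshold ancestry split point (default 0.30).
#' @param alpha significance level (default 0.005).
#' @return data.frame: `trait`, `subgroup`, `estimate`, `se`, `p`, `n`,
#'   `significant`.
#' @export
ancestry_effect <- function(phenotypes, model,
                            subgroup = c("all", "below", "at_or_above"),
                            threshold = 0.30, alpha = 0.005) {
  subgroup <- match.arg(subgroup)
  if (is.null(model$ancestry))
    stop("model has no ancestry covariate")
  lam <- phenotypes[[model$ancestry]]
  keep <- switch(subgroup,
                 all = rep(TRUE, nrow(phenotypes)),
                 below = lam < threshold,
                 at_or_above = lam >= threshold)
  ph <- phenotypes[keep & stats::complete.cases(phenotypes[[model$trait]],
                                                lam), , drop = FALSE]
  X <- design_matrix(ph, model)
  fit <- stats::lm.fit(X, ph[[model$trait]])
  col <- which(colnames(X) == model$ancestry)
  rss <- sum(fit$residuals^2)
  df <- nrow(X) - ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(rss / df * XtXinv[col, col])
  est <- fit$coefficients[col]
  tval <- est / se
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(trait = model$trait, subgroup = subgroup, estimate = est,
             se = se, p = p, n = nrow(X), significant = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired comparison of two sets of correlation estimates
#'
#' Two-sided paired t-test on the element-wise differences between two
#' equal-length vectors of correlation estimates (e.g. the 45 pairwise
#' genetic correlations estimated in two cohorts).
#'
#' @param rg_set_1,rg_set_2 equal-length numeric vectors, length >= 2.
#' @return List: `t`, `df`, `p`, `mean_diff`, `degenerate` (TRUE when the
#'   differences have zero variance, in which case `t`/`p` are NA).
#' @export
compare_correlation_sets <- function(rg_set_1, rg_set_2) {
  if (length(rg_set_1) != length(rg_set_2))
    stop("correlation sets must have equal length")
  if (length(rg_set_1) < 2) stop("need at least 2 pairs")
  diffs <- rg_set_1 - rg_set_2
  tol <- 1e-10 * (mean(abs(diffs)) + 1)
  if (all(abs(diffs) <= tol))
    return(list(t = 0, df = length(diffs) - 1L, p = 1, mean_diff = 0,
                degenerate = FALSE))
  if (stats::sd(diffs) <= tol) {
    # constant non-zero difference: the t statistic is unbounded
    return(list(t = NA_real_, df = length(diffs) - 1L, p = NA_real_,
                mean_diff = mean(diffs), degenerate = TRUE))
  }
  tt <- stats::t.test(rg_set_1, rg_set_2, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(diffs), degenerate = FALSE)
}
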