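#' Code marker genotypes to \[-1, 1\]
#'
#' Homozygotes are enumerated as -1 and 1 and the heterozygote as 0:
#' `discrete_012` dosages map to `dosage - 1`, posterior-mean `dosage_01`
#' values to `2 * dosage - 1`.
#'
#' @param genotypes A [genotype_matrix()].
#' @return Numeric matrix with entries in `[-1, 1]`, dimnames preserved.
#' @export
code_markers <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  switch(genotypes$coding,
         discrete_012 = genotypes$values - 1,
         dosage_01 = 2 * genotypes$values - 1,
         abort("unknown genotype coding."))
}

as_coded <- function(X) {
  if (inherits(X, "genotype_matrix")) code_markers(X) else as.matrix(X)
}

# Spectral REML core for y = 1*mu + u + e, u ~ N(0, sigma_u^2 K),
# e ~ N(0, sigma_e^2 I), lambda = sigma_e^2 / sigma_u^2.
# Projects out the intercept, eigendecomposes the projected kernel, and
# maximizes the restricted likelihood over log(lambda): coarse grid on
# [-10, 10] then local refinement at relative tolerance 1e-8.
reml_eigen <- function(y, K) {
  n <- length(y)
  if (n < 2L) abort("REML requires at least 2 individuals.")
  if (any(!is.finite(y))) abort("`y` must be finite.")
  if (nrow(K) != n || ncol(K) != n) abort("K dimension does not match y.")
  S <- diag(n) - matrix(1 / n, n, n)
  # eigen of S(K + I)S: dropping the single zero mode of S leaves clean
  # spectra even when K is rank-deficient (theta = xi - 1, clipped at 0)
  es <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  theta <- pmax(es$values[seq_len(n - 1L)] - 1, 0)
  U <- es$vectors[, seq_len(n - 1L), drop = FALSE]
  eta <- as.numeric(crossprod(U, y))
  if (sum(theta) < 1e-12 * n) {
    abort("kernel has no genetic signal (all-constant markers?).")
  }
  neg_restricted_ll <- function(log_lambda) {
    lam <- exp(log_lambda)
    dv <- theta + lam
    q <- sum(eta^2 / dv)
    0.5 * ((n - 1) * log(q) + sum(log(dv)))
  }
  grid <- seq(-10, 10, by = 0.2)
  vals <- vapply(grid, neg_restricted_ll, 0)
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(neg_restricted_ll, c(lo, hi), tol = 1e-8)
  lambda <- exp(opt$minimum)
  dv <- theta + lambda
  sigma2_u <- sum(eta^2 / dv) / (n - 1)
  sigma2_e <- lambda * sigma2_u
  ll <- 0.5 * ((n - 1) * (log((n - 1) / (2 * pi)) - 1 -
                            log(sum(eta^2 / dv))) - sum(log(dv)))
  # GLS intercept at lambda-hat using V = K + lambda I directly
  Vfull <- K + lambda * diag(n)
  w <- solve(Vfull, y)
  one <- solve(Vfull, rep(1, n))
  beta0 <- sum(w) / sum(one)
  resid <- y - beta0
  list(lambda = lambda, sigma2_u = sigma2_u, sigma2_e = sigma2_e,
       h2 = sigma2_u / (sigma2_u + sigma2_e), loglik_reml = ll,
       beta0 = beta0, Vinv_resid = solve(Vfull, resid))
}

#' Fit an RR-BLUP genomic selection model by REML
#'
#' Fits `y = 1 b0 + X beta + e` with i.i.d. random marker effects
#' `beta ~ N(0, I sigma_beta^2)` and residuals `e ~ N(0, I sigma_E^2)`.
#' Variance components are estimated by restricted maximum likelihood using
#' an eigendecomposition of `X X'` and a one-dimensional search over
#' `log(lambda)`, `lambda = sigma_E^2 / sigma_beta^2`; marker-effect BLUPs
#' are `X'(XX' + lambda I)^{-1}(y - 1 b0)` with the generalized least
#' squares intercept at the REML optimum. This parameterization is
#' numerically stable when markers far outnumber individuals.
#'
#' @param y Phenotype vector.
#' @param X Coded marker matrix in `[-1, 1]` (see [code_markers()]), or a
#'   [genotype_matrix()] which is coded automatically.
#' @return An object of class `rrblup_fit`: intercept, marker-effect BLUPs,
#'   `sigma2_beta`, `sigma2_e`, `lambda`, restricted log-likelihood, and the
#'   narrow-sense heritability implied by the induced GBLUP. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
rrblup_fit <- function(y, X) {
  X <- as_coded(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X).")
  if (length(y) < 2L) abort("RR-BLUP requires at least 2 individuals.")
  if (any(!is.finite(y))) abort("`y` must be finite.")
  if (all(apply(X, 2, function(col) length(unique(col)) == 1L))) {
    abort("all marker columns are constant; nothing to fit.")
  }
  K <- tcrossprod(X)
  fit <- reml_eigen(y, K)
  beta <- as.numeric(crossprod(X, fit$Vinv_resid))
  names(beta) <- colnames(X)
  # narrow-sense heritability implied by the induced GBLUP: the per-marker
  # variance scales to genetic variance via the centered kernel diagonal
  Xc <- sweep(X, 2, colMeans(X))
  sigma2_g <- fit$sigma2_u * mean(rowSums(Xc^2))
  structure(
    list(intercept = fit$beta0, effects = beta,
         sigma2_beta = fit$sigma2_u, sigma2_e = fit$sigma2_e,
         lambda = fit$lambda, h2 = sigma2_g / (sigma2_g + fit$sigma2_e),
         loglik_reml = fit$loglik_reml, n = length(y), p = ncol(X),
         fitted_gebv = stats::setNames(as.numeric(X %*% beta), rownames(X))),
    class = "rrblup_fit"
  )
}

#' @export
print.rrblup_fit <- function(x, ...) {
  cat(sprintf(
    "<rrblup_fit> n = %d, p = %d | sigma2_beta = %.4g, sigma2_e = %.4g, lambda = %.4g, h2 = %.3f\n",
    x$n, x$p, x$sigma2_beta, x$sigma2_e, x$lambda, x$h2))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' `GEBV = X_new beta-hat`. The intercept is deliberately excluded: accuracy
#' is measured by Pearson correlation, which is location-invariant.
#'
#' @param fit An [rrblup_fit()].
#' @param X_new Coded marker matrix (or [genotype_matrix()]) with the same
#'   markers as the training matrix.
#' @return Named numeric vector of GEBVs.
#' @export
predict_gebv <- function(fit, X_new) {
  stopifnot(inherits(fit, "rrblup_fit"))
  X_new <- as_coded(X_new)
  if (ncol(X_new) != length(fit$effects)) {
    abort("X_new marker count does not match the fitted effects.")
  }
  stats::setNames(as.numeric(X_new %*% fit$effects), rownames(X_new))
}

#' Sum GEBVs from two models trained in different panels
#'
#' Element-wise sum of two GEBV vectors for the same target individuals,
#' the combined-panel prediction rule: a model trained in each whole panel
#' scores the target, and the two scores are added.
#'
#' @param gebv_a,gebv_b Equal-length GEBV vectors; when both are named the
#'   names must agree element-wise.
#' @return Named numeric vector.
#' @export
sum_gebv <- function(gebv_a, gebv_b) {
  if (length(gebv_a) != length(gebv_b)) {
    abort("GEBV vectors must have equal length.")
  }
  if (!is.null(names(gebv_a)) && !is.null(names(gebv_b)) &&
      !identical(names(gebv_a), names(gebv_b))) {
    abort("GEBV vectors are not aligned: individual ids differ.")
  }
  out <- gebv_a + gebv_b
  names(out) <- names(gebv_a) %||% names(gebv_b)
  out
}

#' Principal-component-only structure model
#'
#' Quantifies how much of the predictive signal is carried by population
#' structure alone: markers are column-centered over all individuals of the
#' panel, the top `q` principal components are computed once from the
#' genotypes (no phenotype can leak), and the trait is regressed on the
#' training individuals' scores by ordinary least squares. Predictions for
#' the validation individuals use their scores under the same loadings.
#'
#' @param genotypes_all Panel-wide [genotype_matrix()] or coded matrix.
#' @param y_train Phenotypes of the training individuals.
#' @param train_idx,valid_idx Row indices of training and validation sets.
#' @param q Number of principal components (default 7).
#' @return Named numeric predictions for `valid_idx`, with the fitted
#'   `pc_fit` (centers, loadings, coefficients) as attribute `"fit"`.
#' @export
pca_fit_predict <- function(genotypes_all, y_train, train_idx, valid_idx,
                            q = 7L) {
  X <- as_coded(genotypes_all)
  q <- check_count(q, "q")
  if (length(y_train) != length(train_idx)) {
    abort("`y_train` must align with `train_idx`.")
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2, centers)
  sv <- svd(Xc, nu = 0, nv = min(q, min(dim(Xc))))
  rank <- sum(sv$d > max(dim(Xc)) * .Machine$double.eps * max(sv$d))
  if (q > rank) abort(sprintf("q = %d exceeds the marker-matrix rank %d.",
                              q, rank))
  loadings <- sv$v[, seq_len(q), drop = FALSE]
  scores <- Xc %*% loadings
  df <- as.data.frame(scores[train_idx, , drop = FALSE])
  df$y <- as.numeric(y_train)
  ols <- lm(y ~ ., data = df)
  newdf <- as.data.frame(scores[valid_idx, , drop = FALSE])
  pred <- stats::setNames(unname(predict(ols, newdata = newdf)),
                          rownames(X)[valid_idx])
  attr(pred, "fit") <- structure(
    list(centers = centers, loadings = loadings,
         coefficients = coef(ols), q = q),
    class = "pc_fit")
  pred
}

#' Genomic relationship matrix
#'
#' Centered cross-product relationship: markers are column-centered, the
#' cross-product is normalized so the mean diagonal equals 1, and a small
#' ridge (`1e-6` by default) is added for invertibility.
#'
#' @param X Coded marker matrix or [genotype_matrix()], >= 2 individuals.
#' @param ridge Diagonal stabilizer (set 0 to disable).
#' @return A symmetric positive semi-definite matrix of class `kinship`
#'   with individual ids as dimnames.
#' @export
kinship <- function(X, ridge = 1e-6) {
  X <- as_coded(X)
  if (nrow(X) < 2L) abort("kinship requires at least 2 individuals.")
  Xc <- sweep(X, 2, colMeans(X))
  A <- tcrossprod(Xc)
  scale <- mean(diag(A))
  if (scale <= 0) abort("all individuals are genetically identical.")
  A <- A / scale
  if (ridge > 0) A <- A + ridge * diag(nrow(A))
  structure(A, class = c("kinship", "matrix"))
}

#' GBLUP REML fit on a relationship matrix
#'
#' Fits `y = 1 mu + u + e`, `u ~ N(0, A sigma_u^2)`, by the same spectral
#' REML machinery as [rrblup_fit()].
#'
#' @param y Phenotype vector.
#' @param A Relationship matrix from [kinship()] (or any PSD matrix).
#' @return List with `h2`, `sigma2_u`, `sigma2_e`, `lambda`,
#'   `loglik_reml`, `beta0`, and the BLUP `u_hat`.
#' @export
gblup_reml <- function(y, A) {
  A <- unclass(A)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("relationship matrix is not positive semi-definite.")
  }
  fit <- reml_eigen(as.numeric(y), A)
  u_hat <- as.numeric(A %*% fit$Vinv_resid)
  list(h2 = fit$h2, sigma2_u = fit$sigma2_u, sigma2_e = fit$sigma2_e,
       lambda = fit$lambda, loglik_reml = fit$loglik_reml,
       beta0 = fit$beta0, u_hat = u_hat)
}

#' Narrow-sense heritability from a GBLUP REML fit
#'
#' The genetic variance component divided by the sum of genetic and
#' residual variance components.
#'
#' @inheritParams gblup_reml
#' @return Heritability estimate in `[0, 1]`.
#' @export
narrow_h2 <- function(y, A) {
  gblup_reml(y, A)$h2
}
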