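# Dense closed-form ridge solution, coded independently of the package's
# kernel-space solver: beta = (X'X + lambda I)^{-1} X'(y - b0).
ridge_oracle <- function(y, X, lambda, b0) {
  solve(crossprod(X) + lambda * diag(ncol(X)), crossprod(X, y - b0))
}

# Marker BLUPs at a FIXED lambda via the package's kernel parameterization.
kernel_blup <- function(y, X, lambda) {
  n <- nrow(X)
  V <- tcrossprod(X) + lambda * diag(n)
  one <- rep(1, n)
  b0 <- sum(solve(V, y)) / sum(solve(V, one))
  list(b0 = b0, beta = as.numeric(crossprod(X, solve(V, y - b0))))
}

test_that("marker coding maps dosages to [-1, 1]", {
  g <- genotype_matrix(matrix(c(0, 1, 2, 1), 2, 2), "discrete_012")
  expect_equal(unname(code_markers(g)), matrix(c(-1, 0, 1, 0), 2, 2))
  d <- genotype_matrix(matrix(c(0, 0.5, 1, 0.25), 2, 2), "dosage_01")
  expect_equal(unname(code_markers(d)), matrix(c(-1, 0, 1, -0.5), 2, 2))
})

test_that("marker BLUPs at fixed lambda equal the dense ridge closed form", {
  for (dims in list(c(5, 8), c(30, 100))) {
    set.seed(dims[1])
    X <- matrix(sample(-1:1, prod(dims), replace = TRUE), dims[1], dims[2])
    y <- rnorm(dims[1])
    for (lambda in c(0.5, 3)) {
      kb <- kernel_blup(y, X, lambda)
      oracle <- as.numeric(ridge_oracle(y, X, lambda, kb$b0))
      expect_lt(max(abs(kb$beta - oracle)) / max(abs(oracle)), 1e-8)
    }
  }
})

test_that("REML recovers heritability and shrinks null traits", {
  pan <- small_panel()
  X <- code_markers(pan$genotypes)
  arch <- select_qtns("S.QTN", pan$genotypes$marker_ids, n_add = 10,
                      seed = 1)
  g <- genetic_value(pan$genotypes, arch$panel_a)
  y <- add_noise_to_target_h2(g, 0.6, seed = 2)$phenotype
  fit <- rrblup_fit(y, X)
  expect_gt(cor(fit$fitted_gebv, g), 0.5)
  expect_gt(fit$h2, 0.3)

  # pure noise: lambda large, GEBVs shrunk near zero
  y0 <- rnorm(nrow(X))
  fit0 <- rrblup_fit(y0, X)
  expect_gt(fit0$lambda, fit$lambda)
  expect_lt(var(fit0$fitted_gebv), var(y0))
  expect_lt(fit0$h2, 0.35)

  expect_error(rrblup_fit(y[1], X[1, , drop = FALSE]), "at least 2")
  expect_error(rrblup_fit(c(y[-1], NA), X), "finite")
  expect_error(rrblup_fit(y, matrix(1, nrow(X), 3)), "constant")
})

test_that("restricted likelihood is locally optimal at lambda-hat", {
  pan <- small_panel()
  X <- code_markers(pan$genotypes)
  set.seed(3)
  y <- X[, 5] * 0.8 + rnorm(nrow(X))
  fit <- rrblup_fit(y, X)
  # evaluate the restricted log-likelihood profile directly
  n <- length(y)
  S <- diag(n) - matrix(1 / n, n, n)
  es <- eigen(S %*% (tcrossprod(X) + diag(n)) %*% S, symmetric = TRUE)
  theta <- pmax(es$values[seq_len(n - 1)] - 1, 0)
  eta <- as.numeric(crossprod(es$vectors[, seq_len(n - 1)], y))
  rll <- function(lam) {
    -0.5 * ((n - 1) * log(sum(eta^2 / (theta + lam))) +
              sum(log(theta + lam)))
  }
  expect_gte(rll(fit$lambda), rll(fit$lambda / 2))
  expect_gte(rll(fit$lambda), rll(fit$lambda * 2))
})

test_that("RR-BLUP GEBVs equal GBLUP BLUPs at the same lambda", {
  set.seed(4)
  X <- matrix(sample(-1:1, 30 * 100, replace = TRUE), 30, 100)
  y <- X[, 1] - 0.5 * X[, 50] + rnorm(30, sd = 0.8)
  fit <- rrblup_fit(y, X)
  gebv <- as.numeric(X %*% fit$effects)
  # independent GBLUP route: Henderson mixed-model equations with K = XX'
  K <- tcrossprod(X)
  lam <- fit$lambda
  n <- nrow(X)
  C <- rbind(cbind(n, t(rep(1, n))),
             cbind(rep(1, n), diag(n) + lam * solve(K)))
  sol <- solve(C, c(sum(y), y))
  u_mme <- sol[-1]
  expect_lt(max(abs(gebv - u_mme)) / max(abs(u_mme)), 1e-6)
  expect_equal(fit$intercept, unname(sol[1]), tolerance = 1e-8)
})

test_that("GEBV prediction is consistent, aligned and shift-invariant", {
  pan <- small_panel()
  X <- code_markers(pan$genotypes)
  set.seed(5)
  y <- rnorm(nrow(X)) + X[, 2]
  fit <- rrblup_fit(y, X)
  expect_equal(predict_gebv(fit, X), fit$fitted_gebv)
  z <- matrix(0, 2, ncol(X))
  expect_equal(unname(predict_gebv(fit, z)), c(0, 0))
  expect_error(predict_gebv(fit, X[, 1:3]), "marker count")

  fit_shift <- rrblup_fit(y + 100, X)
  expect_equal(fit_shift$effects, fit$effects, tolerance = 1e-6)
  expect_equal(fit_shift$intercept, fit$intercept + 100, tolerance = 1e-4)
})

test_that("sum_gebv adds aligned vectors and guards misalignment", {
  a <- c(i1 = 1, i2 = 2)
  b <- c(i1 = 0.5, i2 = -1)
  expect_equal(sum_gebv(a, b), c(i1 = 1.5, i2 = 1))
  expect_equal(sum_gebv(a, c(i1 = 0, i2 = 0)), a)
  expect_error(sum_gebv(a, rev(b)), "aligned")
  expect_error(sum_gebv(a, 1), "equal length")

  set.seed(6)
  x1 <- rnorm(5000); x2 <- rnorm(5000)
  expect_lt(abs(cor(x1 + x2, x1) - 1 / sqrt(2)), 0.05)
})

test_that("PC-only model captures structure-confounded traits", {
  pan <- simulate_panel(80, small_map(), n_subpops = 2, fst = 0.4, seed = 7)
  X <- code_markers(pan$genotypes)
  y <- ifelse(pan$subpop == 1, 0, 5) # trait equals subpopulation mean
  train <- seq(1, 80, by = 2)
  valid <- seq(2, 80, by = 2)
  pred <- pca_fit_predict(X, y[train], train, valid, q = 1)
  expect_gt(cor(pred, y[valid]), 0.95)

  const <- pca_fit_predict(X, rep(2, length(train)), train, valid, q = 2)
  expect_lt(diff(range(const)), 1e-8)

  expect_error(pca_fit_predict(X, y[train], train, valid, q = 5000),
               "rank")
  # leakage guard: validation phenotypes never enter the fit
  expect_identical(pred, pca_fit_predict(X, y[train], train, valid, q = 1))
})

test_that("kinship matrix is normalized, symmetric and PSD", {
  set.seed(8)
  X <- matrix(sample(-1:1, 50 * 200, replace = TRUE), 50, 200)
  A <- kinship(X, ridge = 0)
  expect_equal(mean(diag(A)), 1, tolerance = 1e-12)
  expect_equal(unclass(A), t(unclass(A)))
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)

  Xdup <- rbind(X[1, ], X[1, ], X[2:10, ])
  Adup <- kinship(Xdup, ridge = 0)
  expect_equal(Adup[1, ], Adup[2, ], tolerance = 1e-12)
  expect_equal(Adup[1, 2], Adup[1, 1], tolerance = 1e-12)

  expect_error(kinship(X[1, , drop = FALSE]), "at least 2")
})

test_that("narrow-sense heritability estimates behave at the extremes", {
  pan <- small_panel()
  A <- kinship(pan$genotypes)
  # null traits: near-zero heritability on average
  h0 <- vapply(1:30, function(s) {
    set.seed(s)
    narrow_h2(rnorm(nrow(A)), A)
  }, 0)
  expect_lt(mean(h0), 0.1)
  # noiseless genetic values: heritability near 1
  set.seed(9)
  u <- as.numeric(t(chol(unclass(A))) %*% rnorm(nrow(A)))
  h1 <- narrow_h2(u, A)
  expect_gt(h1, 0.95)
  expect_true(all(h0 >= 0 & h0 <= 1))
  expect_error(gblup_reml(u, -unclass(A)), "positive semi-definite")
})
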