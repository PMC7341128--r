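#' Mean coefficient of determination of contrasts
#'
#' Phenotype-free criterion for training-set quality. For the mixed model
#' `y_train = 1 mu + Z u + e`, `u ~ N(0, A sigma_u^2)`,
#' `lambda = sigma_e^2 / sigma_u^2`, the CD of a contrast `c` is
#' `CD(c) = c' (A - lambda (Z'MZ + lambda A^{-1})^{-1}) c / (c' A c)`,
#' with `M = I - 11'/m` absorbing the fixed mean over the `m` training
#' observations. Contrasts are `c_i = e_i - (1/N) 1`, the difference between
#' individual `i` and the population mean, for each target individual; the
#' mean CD over targets is returned. Higher values mean the training set is
#' expected to predict the targets' deviations more reliably.
#'
#' @param A Relationship matrix from [kinship()] (ridge-stabilized, so
#'   invertible).
#' @param train_ids Indices or ids of the training set.
#' @param target_ids Indices or ids of the (unphenotyped) target
#'   individuals whose contrasts are evaluated.
#' @param lambda Positive noise-to-genetic variance ratio.
#' @return Mean CD, a scalar in `[0, 1]`.
#' @export
cd_of_contrasts <- function(A, train_ids, target_ids, lambda = 1) {
  A <- unclass(A)
  train <- resolve_ids(A, train_ids)
  targets <- resolve_ids(A, target_ids)
  if (length(train) < 1L) abort("training set must be non-empty.")
  if (!is.numeric(lambda) || lambda <= 0) abort("`lambda` must be positive.")
  Ainv <- solve(A)
  cd_core(A, Ainv, train, targets, lambda)
}

resolve_ids <- function(A, ids) {
  if (is.character(ids)) {
    idx <- match(ids, rownames(A))
    if (anyNA(idx)) abort("some ids are not rows of the relationship matrix.")
    idx
  } else {
    ids <- as.integer(ids)
    if (any(ids < 1L) || any(ids > nrow(A))) {
      abort("train/target indices out of range.")
    }
    ids
  }
}

# Shared evaluation with a precomputed A^{-1}; O(N^3) solve per call.
cd_core <- function(A, Ainv, train, targets, lambda) {
  N <- nrow(A)
  m <- length(train)
  B <- lambda * Ainv
  # Z'MZ: Z is the m x N incidence of training rows; M = I_m - 11'/m
  B[train, train] <- B[train, train] - 1 / m
  diag(B)[train] <- diag(B)[train] + 1
  Q <- A - lambda * solve(B)
  cd_one <- function(M) {
    rs <- rowSums(M)
    tot <- sum(rs)
    diag(M)[targets] - (2 / N) * rs[targets] + tot / N^2
  }
  num <- cd_one(Q)
  den <- cd_one(A)
  mean(num / den)
}

#' Optimize a training set by stochastic exchange (Algo1)
#'
#' Starts from a seeded random subset of size `m` and performs `n_iter`
#' one-for-one exchange proposals: a uniformly chosen selected individual is
#' swapped with a uniformly chosen unselected calibration individual, and
#' the swap is accepted if and only if the mean CD of contrasts strictly
#' increases. Contrasts always target the calibration individuals not
#' currently selected, re-derived after each accepted swap.
#'
#' @param A Relationship matrix over (at least) the calibration set.
#' @param calibration_ids Indices or ids of the calibration set (> `m`).
#' @param m Training-set size (default 200).
#' @param n_iter Number of exchange proposals (default 3000).
#' @param lambda Noise-to-genetic variance ratio for the CD; estimate it
#'   from calibration phenotypes via [gblup_reml()] when available
#'   (see [lambda_policy()]).
#' @param seed Integer seed.
#' @return An object of class `training_selection`: `selected` ids, the
#'   non-decreasing `cdmean_trace` of accepted values (initial value first),
#'   `n_iter`, `lambda`, `seed`. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
algo1_exchange <- function(A, calibration_ids, m = 200L, n_iter = 3000L,
                           lambda = 1, seed = 1L) {
  A <- unclass(A)
  calib <- resolve_ids(A, calibration_ids)
  m <- check_count(m, "m")
  n_iter <- check_count(n_iter, "n_iter", min = 0L)
  if (m >= length(calib)) {
    abort("`m` must be smaller than the calibration set.")
  }
  if (!is.numeric(lambda) || lambda <= 0) abort("`lambda` must be positive.")
  Ainv <- solve(A)
  with_seed(seed, {
    sel <- sample(calib, m)
    unsel <- setdiff(calib, sel)
    cur <- cd_core(A, Ainv, sel, unsel, lambda)
    trace <- cur
    if (n_iter > 0) {
      for (it in seq_len(n_iter)) {
        i <- sample.int(m, 1L)
        j <- sample.int(length(unsel), 1L)
        cand_sel <- sel
        cand_sel[i] <- unsel[j]
        cand_unsel <- unsel
        cand_unsel[j] <- sel[i]
        cand <- cd_core(A, Ainv, cand_sel, cand_unsel, lambda)
        if (cand > cur) {
          sel <- cand_sel
          unsel <- cand_unsel
          cur <- cand
          trace <- c(trace, cur)
        }
      }
    }
    new_training_selection(
      selected = selection_labels(A, sel), cdmean_trace = trace,
      n_iter = n_iter, lambda = lambda, seed = seed, method = "cdmean")
  })
}

selection_labels <- function(A, idx) {
  if (!is.null(rownames(A))) rownames(A)[idx] else idx
}

new_training_selection <- function(selected, cdmean_trace, n_iter, lambda,
                                   seed, method) {
  structure(
    list(selected = selected, cdmean_trace = cdmean_trace, n_iter = n_iter,
         lambda = lambda, seed = seed, method = method),
    class = "training_selection"
  )
}

#' @export
print.training_selection <- function(x, ...) {
  cat(sprintf(
    "<training_selection %s> m = %d, CDmean %.4f -> %.4f (%d accepted)\n",
    x$method, length(x$selected),
    x$cdmean_trace[1], x$cdmean_trace[length(x$cdmean_trace)],
    length(x$cdmean_trace) - 1L))
  invisible(x)
}

#' Random training subset baseline
#'
#' Uniform sample without replacement from the calibration set; the CDmean
#' of the drawn set is recorded as a single-value trace for comparison with
#' [algo1_exchange()].
#'
#' @inheritParams algo1_exchange
#' @return A `training_selection` with a length-1 `cdmean_trace`.
#' @export
random_subset <- function(A, calibration_ids, m = 200L, lambda = 1,
                          seed = 1L) {
  A <- unclass(A)
  calib <- resolve_ids(A, calibration_ids)
  m <- check_count(m, "m")
  if (m > length(calib)) abort("`m` exceeds the calibration set size.")
  with_seed(seed, {
    sel <- sample(calib, m)
    unsel <- setdiff(calib, sel)
    cd <- if (length(unsel)) {
      cd_core(A, solve(A), sel, unsel, lambda)
    } else NA_real_
    new_training_selection(
      selected = selection_labels(A, sel), cdmean_trace = cd,
      n_iter = 0L, lambda = lambda, seed = seed, method = "random")
  })
}

#' Noise-to-genetic variance ratio for CDmean
#'
#' The CD criterion is trait-specific only through `lambda`. When
#' calibration phenotypes are available, `lambda` is estimated as
#' `sigma_e^2 / sigma_u^2` from a GBLUP REML fit; without phenotypes the
#' fallback is `lambda = 1` (heritability 0.5).
#'
#' @param A Relationship matrix over the calibration individuals.
#' @param y Optional calibration phenotypes aligned to `A`.
#' @return Positive scalar lambda.
#' @export
lambda_policy <- function(A, y = NULL) {
  if (is.null(y)) return(1)
  fit <- gblup_reml(y, A)
  max(fit$lambda, 1e-6)
}
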