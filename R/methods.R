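#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_boxplot geom_step geom_point
#'   labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy marker effects of an RR-BLUP fit
#'
#' @param x An [rrblup_fit()].
#' @param ... Unused.
#' @return A tibble with `marker_id` and `effect` (the marker BLUPs).
#' @method tidy rrblup_fit
#' @export
tidy.rrblup_fit <- function(x, ...) {
  tibble::tibble(
    marker_id = names(x$effects) %||% as.character(seq_along(x$effects)),
    effect = unname(x$effects))
}

#' One-row summary of an RR-BLUP fit
#'
#' @param x An [rrblup_fit()].
#' @param ... Unused.
#' @return A one-row tibble: intercept, variance components, ridge ratio
#'   `lambda`, implied narrow-sense heritability, restricted log-likelihood,
#'   and problem size.
#' @method glance rrblup_fit
#' @export
glance.rrblup_fit <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, sigma2_beta = x$sigma2_beta,
                 sigma2_e = x$sigma2_e, lambda = x$lambda, h2 = x$h2,
                 loglik_reml = x$loglik_reml, n = x$n, p = x$p)
}

#' Tidy the accepted CDmean trace of a training selection
#'
#' @param x A [algo1_exchange()] / [random_subset()] result.
#' @param ... Unused.
#' @return A tibble with `step` (0 = initial set) and `cdmean`.
#' @method tidy training_selection
#' @export
tidy.training_selection <- function(x, ...) {
  tibble::tibble(step = seq_along(x$cdmean_trace) - 1L,
                 cdmean = x$cdmean_trace)
}

#' One-row summary of a training selection
#'
#' @param x A `training_selection`.
#' @param ... Unused.
#' @return A one-row tibble: method, subset size, initial and final CDmean,
#'   accepted exchanges, iterations, lambda and seed.
#' @method glance training_selection
#' @export
glance.training_selection <- function(x, ...) {
  tibble::tibble(
    method = x$method, m = length(x$selected),
    cdmean_initial = x$cdmean_trace[1],
    cdmean_final = x$cdmean_trace[length(x$cdmean_trace)],
    n_accepted = length(x$cdmean_trace) - 1L,
    n_iterations = x$n_iter, lambda = x$lambda, seed = x$seed)
}

#' One-row summary of a simulated trait
#'
#' @param x An [add_noise_to_target_h2()] result.
#' @param ... Unused.
#' @return A one-row tibble: target and realized broad-sense heritability,
#'   noise variance, and sample size.
#' @method glance simulated_trait
#' @export
glance.simulated_trait <- function(x, ...) {
  tibble::tibble(target_h2 = attr(x, "target_h2"),
                 noise_var = attr(x, "noise_var"),
                 realized_h2 = attr(x, "realized_h2"),
                 n = nrow(x))
}

#' Plot the accepted CDmean trace
#'
#' @param object A `training_selection`.
#' @param ... Unused.
#' @return A ggplot: accepted CDmean value against acceptance step.
#' @method autoplot training_selection
#' @export
autoplot.training_selection <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$step, y = .data$cdmean)) +
    geom_step() + geom_point(size = 0.8) +
    labs(x = "accepted exchange", y = "CDmean",
         title = sprintf("CDmean trace (%s, m = %d)", object$method,
                         length(object$selected))) +
    theme_minimal()
}

#' Boxplots of prediction accuracy distributions
#'
#' Mirrors the usual presentation of genomic-prediction benchmarks: one box
#' per training configuration (or per within-panel method), optionally
#' faceted by scenario and architecture when those columns are present.
#'
#' @param object An `accuracy_results` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot accuracy_results
#' @export
autoplot.accuracy_results <- function(object, ...) {
  xvar <- if ("configuration" %in% names(object)) "configuration" else "method"
  p <- ggplot(object, aes(x = .data[[xvar]], y = .data$r)) +
    geom_boxplot() +
    labs(x = NULL, y = "prediction accuracy (Pearson r)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (all(c("scenario", "architecture") %in% names(object))) {
    p <- p + ggplot2::facet_grid(architecture ~ scenario)
  }
  p
}

#' Histogram of bootstrap accuracies
#'
#' @param object A [bootstrap_accuracy()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bootstrap_accuracy
#' @export
autoplot.bootstrap_accuracy <- function(object, ...) {
  ggplot(object, aes(x = .data$r)) +
    ggplot2::geom_histogram(bins = 40) +
    labs(x = "bootstrap prediction accuracy (Pearson r)", y = "count") +
    theme_minimal()
}

#' Scatter of panel individuals on the first two marker PCs
#'
#' Visual check that subpopulation structure is recoverable from the
#' marker matrix, colored by the simulated subpopulation label.
#'
#' @param object A `panel`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot panel
#' @export
autoplot.panel <- function(object, ...) {
  X <- code_markers(object$genotypes)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 2, nv = 0)
  df <- tibble::tibble(PC1 = sv$u[, 1] * sv$d[1], PC2 = sv$u[, 2] * sv$d[2],
                       subpop = factor(object$subpop))
  ggplot(df, aes(x = .data$PC1, y = .data$PC2, colour = .data$subpop)) +
    geom_point() +
    labs(title = sprintf("panel %s marker PCA", object$species_tag)) +
    theme_minimal()
}

#' @importFrom rlang .data
NULL
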