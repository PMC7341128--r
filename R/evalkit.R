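CROSS_CONFIGS <- c("Msi.Random", "Msa.Random", "Msi.CDmean", "Msa.CDmean",
                   "Msi.Whole", "Msa.Whole", "Whole.Msi.Msa")

#' Pearson prediction accuracy
#'
#' Sample Pearson correlation between observed (or simulated) trait values
#' and GEBVs. Returns `NA` (undefined) when either vector has zero
#' variance rather than imputing 0.
#'
#' @param y_true Observed/simulated trait values (length >= 3).
#' @param gebv Predicted breeding values, same length and order.
#' @return Correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
#' @examples
#' pearson_accuracy(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.8
pearson_accuracy <- function(y_true, gebv) {
  if (length(y_true) != length(gebv)) {
    abort("`y_true` and `gebv` must have equal length.")
  }
  if (length(y_true) < 3L) abort("need at least 3 pairs for a correlation.")
  if (var(y_true) == 0 || var(gebv) == 0) return(NA_real_)
  cor(y_true, gebv)
}

#' Replicated k-fold cross-validation plan
#'
#' Each replicate is an independent random permutation split into `k` folds
#' whose sizes differ by at most one.
#'
#' @param n Number of individuals.
#' @param k Folds per replicate (default 5).
#' @param n_reps Replicates (default 10).
#' @param seed Integer seed.
#' @return A tibble of class `cv_plan` with columns `rep`, `fold`, `index`.
#' @export
make_cv_plan <- function(n, k = 5L, n_reps = 10L, seed = 1L) {
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  n_reps <- check_count(n_reps, "n_reps")
  if (n < k) abort("`n` must be at least `k`.")
  plan <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_reps), function(r) {
      perm <- sample.int(n)
      # near-equal folds: first (n %% k) folds get the extra individual
      sizes <- rep(n %/% k, k)
      extra <- n %% k
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      tibble::tibble(rep = r, fold = rep(seq_len(k), sizes), index = perm)
    })
  })
  attr(plan, "k") <- k
  attr(plan, "n_reps") <- n_reps
  attr(plan, "seed") <- seed
  class(plan) <- c("cv_plan", class(plan))
  plan
}

new_accuracy_results <- function(df) {
  class(df) <- c("accuracy_results", class(tibble::tibble()))
  df
}

#' Within-panel cross-validation experiment
#'
#' For every replicate-by-fold training set of a replicated k-fold
#' cross-validation, four models are fitted and scored on the held-out
#' fold by Pearson accuracy:
#' `rrblup_whole` (RR-BLUP on the full training set), `rrblup_random`
#' (RR-BLUP on a random subset), `rrblup_cdmean` (RR-BLUP on an
#' Algo1/CDmean-optimized subset using the training set as calibration
#' set), and `pc_only` (the principal-component structure model).
#'
#' @param panel A `panel`.
#' @param y Phenotypes aligned to the panel (a numeric vector or a
#'   `simulated_trait`).
#' @param plan A [make_cv_plan()]; defaults to 10 x 5-fold on the panel.
#' @param subset_size Size of the random/CDmean subsets. `NULL` (default)
#'   means 200, scaled down to `round(0.5 * training-set size)` on smaller
#'   panels; an explicit value is used as-is and must not exceed the
#'   training fold size.
#' @param cdmean_iters Algo1 exchange proposals (default 3000).
#' @param q Principal components for the structure model (default 7).
#' @param seed Integer seed for subset draws.
#' @return An `accuracy_results` tibble: `method`, `rep`, `fold`,
#'   `n_train`, `r`, `seed`.
#' @export
within_panel_experiment <- function(panel, y, plan = NULL,
                                    subset_size = NULL,
                                    cdmean_iters = 3000L, q = 7L,
                                    seed = 1L) {
  stopifnot(inherits(panel, "panel"))
  if (inherits(y, "simulated_trait")) y <- y$phenotype
  X <- code_markers(panel$genotypes)
  n <- nrow(X)
  if (length(y) != n) abort("`y` must align with the panel.")
  if (is.null(plan)) plan <- make_cv_plan(n, seed = child_seed(seed, 0L))
  A <- kinship(X)
  cells <- dplyr::distinct(plan[, c("rep", "fold")])
  out <- purrr::pmap_dfr(cells, function(rep, fold) {
    valid <- plan$index[plan$rep == rep & plan$fold == fold]
    train <- setdiff(seq_len(n), valid)
    ssize <- if (is.null(subset_size)) {
      min(200L, round(0.5 * length(train)))
    } else {
      if (subset_size > length(train)) {
        abort("`subset_size` exceeds the training fold size.")
      }
      as.integer(subset_size)
    }
    if (ssize < 2L) abort("subset size too small for this training fold.")
    cell_seed <- child_seed(seed, rep * 1000L + fold)
    lam <- lambda_policy(A[train, train, drop = FALSE], y[train])
    rand <- with_seed(cell_seed, sample(train, ssize))
    cdsel <- algo1_exchange(A, train, m = ssize, n_iter = cdmean_iters,
                            lambda = lam, seed = cell_seed)
    cd_idx <- resolve_ids(A, cdsel$selected)
    fits <- list(
      rrblup_whole = predict_gebv(
        rrblup_fit(y[train], X[train, , drop = FALSE]),
        X[valid, , drop = FALSE]),
      rrblup_random = predict_gebv(
        rrblup_fit(y[rand], X[rand, , drop = FALSE]),
        X[valid, , drop = FALSE]),
      rrblup_cdmean = predict_gebv(
        rrblup_fit(y[cd_idx], X[cd_idx, , drop = FALSE]),
        X[valid, , drop = FALSE]),
      pc_only = pca_fit_predict(X, y[train], train, valid, q = q)
    )
    ns <- c(length(train), ssize, ssize, length(train))
    tibble::tibble(
      method = names(fits), rep = rep, fold = fold, n_train = ns,
      r = vapply(fits, function(p) pearson_accuracy(y[valid], p), 0),
      seed = cell_seed
    )
  })
  new_accuracy_results(out)
}

#' Cross-population training configurations
#'
#' Trains GS models under up to seven training-set configurations drawn
#' from two diversity panels and scores their GEBVs in a target population
#' sharing the marker universe: random 200-individual subsets
#' (`Msi.Random`, `Msa.Random`), CDmean-optimized subsets (`Msi.CDmean`,
#' `Msa.CDmean`), whole panels (`Msi.Whole`, `Msa.Whole`), and the sum of
#' the two whole-panel GEBV vectors (`Whole.Msi.Msa`).
#'
#' @param panel_a,panel_b Panels (conventionally the Msi-like and Msa-like
#'   species).
#' @param y_a,y_b Panel phenotypes (vectors or `simulated_trait`s).
#' @param target [genotype_matrix()] of the target population.
#' @param y_target Target phenotypes.
#' @param configs Subset of the seven configuration labels.
#' @param subset_size Random/CDmean subset size. `NULL` (default) means
#'   200, scaled down to half the panel on smaller panels; an explicit
#'   value is capped at the panel size (a subset as large as the panel is
#'   the whole panel).
#' @param cdmean_iters Algo1 proposals (default 3000).
#' @param seed Integer seed.
#' @return An `accuracy_results` tibble with one row per configuration:
#'   `configuration`, `n_train`, `r`, `seed`, and a `gebv` list-column for
#'   downstream bootstrapping.
#' @export
cross_panel_experiment <- function(panel_a, panel_b, y_a, y_b, target,
                                   y_target, configs = CROSS_CONFIGS,
                                   subset_size = NULL,
                                   cdmean_iters = 3000L, seed = 1L) {
  bad <- setdiff(configs, CROSS_CONFIGS)
  if (length(bad)) {
    abort(sprintf("unknown configuration label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  if (inherits(y_a, "simulated_trait")) y_a <- y_a$phenotype
  if (inherits(y_b, "simulated_trait")) y_b <- y_b$phenotype
  if (inherits(y_target, "simulated_trait")) y_target <- y_target$phenotype
  Xa <- code_markers(panel_a$genotypes)
  Xb <- code_markers(panel_b$genotypes)
  Xt <- as_coded(target)
  panels <- list(Msi = list(X = Xa, y = y_a), Msa = list(X = Xb, y = y_b))

  whole_gebv <- list()
  need_whole <- function(tag) {
    if (is.null(whole_gebv[[tag]])) {
      p <- panels[[tag]]
      whole_gebv[[tag]] <<- predict_gebv(rrblup_fit(p$y, p$X), Xt)
    }
    whole_gebv[[tag]]
  }
  subset_gebv <- function(tag, how, stream) {
    p <- panels[[tag]]
    np <- nrow(p$X)
    m <- if (is.null(subset_size)) min(200L, round(0.5 * np)) else {
      min(as.integer(subset_size), np)
    }
    s <- child_seed(seed, stream)
    idx <- if (how == "random") {
      with_seed(s, sample.int(np, m))
    } else {
      A <- kinship(p$X)
      lam <- lambda_policy(A, p$y)
      sel <- algo1_exchange(A, seq_len(np), m = m, n_iter = cdmean_iters,
                            lambda = lam, seed = s)
      resolve_ids(A, sel$selected)
    }
    list(gebv = predict_gebv(rrblup_fit(p$y[idx],
                                        p$X[idx, , drop = FALSE]), Xt),
         n = m)
  }

  rows <- purrr::map(configs, function(cf) {
    res <- switch(cf,
      Msi.Whole = list(gebv = need_whole("Msi"), n = nrow(Xa)),
      Msa.Whole = list(gebv = need_whole("Msa"), n = nrow(Xb)),
      Whole.Msi.Msa = list(
        gebv = sum_gebv(need_whole("Msi"), need_whole("Msa")),
        n = nrow(Xa) + nrow(Xb)),
      Msi.Random = subset_gebv("Msi", "random", 1L),
      Msa.Random = subset_gebv("Msa", "random", 2L),
      Msi.CDmean = subset_gebv("Msi", "cdmean", 3L),
      Msa.CDmean = subset_gebv("Msa", "cdmean", 4L))
    tibble::tibble(configuration = cf, n_train = res$n,
                   r = pearson_accuracy(y_target, res$gebv),
                   seed = seed, gebv = list(res$gebv))
  })
  new_accuracy_results(dplyr::bind_rows(rows))
}

#' Bootstrap distribution of prediction accuracy
#'
#' Resamples the target population with replacement (resample size equal to
#' the population size) and computes the Pearson accuracy in each resample.
#' Zero-variance resamples are excluded and counted, never imputed.
#'
#' @param y_target Target phenotypes.
#' @param gebv_target GEBVs aligned to `y_target`.
#' @param n_boot Number of bootstrap samples (default 1000).
#' @param seed Integer seed.
#' @return A tibble of class `bootstrap_accuracy` with columns `boot`, `r`;
#'   attribute `n_excluded` counts dropped zero-variance resamples.
#' @export
bootstrap_accuracy <- function(y_target, gebv_target, n_boot = 1000L,
                               seed = 1L) {
  if (length(y_target) != length(gebv_target)) {
    abort("`y_target` and `gebv_target` must align.")
  }
  n_boot <- check_count(n_boot, "n_boot")
  n <- length(y_target)
  rs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (var(y_target[idx]) == 0 || var(gebv_target[idx]) == 0) {
        return(NA_real_)
      }
      cor(y_target[idx], gebv_target[idx])
    }, 0)
  })
  out <- tibble::tibble(boot = seq_len(n_boot), r = rs)
  excluded <- sum(is.na(rs))
  out <- out[!is.na(out$r), ]
  attr(out, "n_excluded") <- excluded
  class(out) <- c("bootstrap_accuracy", class(tibble::tibble()))
  out
}

#' Simulation experiment across F2 families
#'
#' For each (scenario, architecture) pair, simulates a trait suite in the
#' two panels and all F2 families, trains the requested cross-population
#' configurations on the panel phenotypes, and scores each family's GEBVs
#' against its simulated phenotypes. The correlation with true genetic
#' values is emitted alongside as a diagnostic.
#'
#' @param panel_a,panel_b Panels sharing the marker universe.
#' @param families List of `f2_family` objects.
#' @param scenarios Character vector of QTN-sharing scenarios.
#' @param architectures Character vector of architecture codes.
#' @param configs Cross-population configurations to evaluate.
#' @param h2_panel,h2_f2 Heritability targets (defaults 0.60 and 0.37).
#' @param subset_size,cdmean_iters Passed to [cross_panel_experiment()].
#' @param seed Master integer seed.
#' @return An `accuracy_results` tibble: `scenario`, `architecture`,
#'   `configuration`, `family`, `n_train`, `r`, `r_true_g`, `seed`.
#' @export
simulation_experiment <- function(panel_a, panel_b, families,
                                  scenarios = SCENARIOS,
                                  architectures = c("A20D0E0", "A20D4E0",
                                                    "A20D0E4"),
                                  configs = CROSS_CONFIGS,
                                  h2_panel = 0.60, h2_f2 = 0.37,
                                  subset_size = NULL, cdmean_iters = 3000L,
                                  seed = 1L) {
  grid <- expand.grid(scenario = scenarios, architecture = architectures,
                      stringsAsFactors = FALSE)
  out <- purrr::pmap_dfr(grid, function(scenario, architecture) {
    suite_seed <- child_seed(
      seed, match(scenario, SCENARIOS) * 100L +
        match(architecture, c("A20D0E0", "A20D4E0", "A20D0E4")))
    suite <- simulate_trait_suite(
      panel_a, panel_b, families, scenario = scenario,
      architecture = architecture, h2_panel = h2_panel, h2_f2 = h2_f2,
      seed = suite_seed)
    purrr::imap_dfr(suite$family_traits, function(trait, fam_id) {
      fam <- families[[match(fam_id, vapply(families,
                                            function(f) f$family_id, ""))]]
      res <- cross_panel_experiment(
        panel_a, panel_b, suite$trait_a, suite$trait_b, fam$f2,
        trait$phenotype, configs = configs, subset_size = subset_size,
        cdmean_iters = cdmean_iters, seed = suite_seed)
      tibble::tibble(
        scenario = scenario, architecture = architecture,
        configuration = res$configuration, family = fam_id,
        n_train = res$n_train, r = res$r,
        r_true_g = vapply(res$gebv, function(g) {
          pearson_accuracy(trait$genetic_value, g)
        }, 0),
        seed = suite_seed
      )
    })
  })
  new_accuracy_results(out)
}
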