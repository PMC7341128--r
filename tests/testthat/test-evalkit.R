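test_that("Pearson accuracy handles affine, inverse and undefined cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(pearson_accuracy(y, 2 * y + 5), 1)
  expect_equal(pearson_accuracy(y, -y), -1)
  expect_equal(pearson_accuracy(y, c(1, 3, 2, 4)), 0.8)
  expect_true(is.na(pearson_accuracy(y, rep(1, 4))))
  expect_error(pearson_accuracy(y, y[1:3]), "equal length")
  expect_error(pearson_accuracy(y[1:2], y[1:2]), "at least 3")
  # invariance to affine transforms of the GEBVs
  g <- c(0.3, -1, 2, 0.7)
  expect_equal(pearson_accuracy(y, g), pearson_accuracy(y, 10 * g - 3))
})

test_that("cross-validation plans partition individuals evenly", {
  plan <- make_cv_plan(10, k = 5, n_reps = 2, seed = 1)
  for (r in 1:2) {
    sub <- plan[plan$rep == r, ]
    expect_setequal(sub$index, 1:10)
    expect_true(all(table(sub$fold) == 2))
  }
  plan2 <- make_cv_plan(23, k = 5, n_reps = 3, seed = 2)
  for (r in 1:3) {
    sub <- plan2[plan2$rep == r, ]
    expect_setequal(sub$index, 1:23)
    expect_lte(diff(range(table(sub$fold))), 1)
  }
  expect_equal(attr(make_cv_plan(50), "k"), 5)
  expect_equal(attr(make_cv_plan(50), "n_reps"), 10)
  expect_error(make_cv_plan(3, k = 5), "at least")
  expect_identical(make_cv_plan(10, seed = 3), make_cv_plan(10, seed = 3))
})

test_that("within-panel experiment runs all four methods per fold", {
  pan <- small_panel()
  arch <- select_qtns("S.QTN", pan$genotypes$marker_ids, n_add = 10,
                      seed = 1)
  trait <- add_noise_to_target_h2(
    genetic_value(pan$genotypes, arch$panel_a), 0.6, seed = 2)
  plan <- make_cv_plan(nrow(pan$genotypes$values), k = 3, n_reps = 2,
                       seed = 3)
  res <- within_panel_experiment(pan, trait, plan, subset_size = 15,
                                 cdmean_iters = 15, q = 3, seed = 4)
  expect_equal(nrow(res), 2 * 3 * 4)
  expect_setequal(unique(res$method),
                  c("rrblup_whole", "rrblup_random", "rrblup_cdmean",
                    "pc_only"))
  expect_true(all(res$n_train[res$method == "rrblup_random"] == 15))
  expect_true(all(is.finite(res$r)))
  # reruns with the recorded seed reproduce the rows
  res2 <- within_panel_experiment(pan, trait, plan, subset_size = 15,
                                  cdmean_iters = 15, q = 3, seed = 4)
  expect_identical(res$r, res2$r)
})

test_that("null traits give near-zero accuracy for every method", {
  pan <- small_panel()
  set.seed(5)
  y <- rnorm(nrow(pan$genotypes$values))
  plan <- make_cv_plan(length(y), k = 3, n_reps = 2, seed = 6)
  res <- within_panel_experiment(pan, y, plan, subset_size = 15,
                                 cdmean_iters = 5, q = 3, seed = 7)
  means <- tapply(res$r, res$method, mean)
  expect_true(all(abs(means) < 0.25))
  expect_lt(abs(mean(res$r)), 0.1)
})

test_that("structure-confounded traits make the PC model competitive", {
  pan <- simulate_panel(72, small_map(), n_subpops = 3, fst = 0.35,
                        seed = 8)
  y <- c(-2, 0, 3)[pan$subpop] + rnorm(72, sd = 0.3)
  plan <- make_cv_plan(72, k = 3, n_reps = 2, seed = 9)
  res <- within_panel_experiment(pan, y, plan, subset_size = 20,
                                 cdmean_iters = 5, q = 2, seed = 10)
  m <- tapply(res$r, res$method, mean)
  expect_gt(m[["pc_only"]], 0.6)
  expect_lt(abs(m[["pc_only"]] - m[["rrblup_whole"]]),
            2 * stats::sd(res$r))
})

test_that("validation phenotypes never leak into training", {
  pan <- small_panel()
  set.seed(11)
  y <- rnorm(nrow(pan$genotypes$values))
  plan <- make_cv_plan(length(y), k = 3, n_reps = 1, seed = 12)
  valid1 <- plan$index[plan$rep == 1 & plan$fold == 1]
  X <- code_markers(pan$genotypes)
  train <- setdiff(seq_along(y), valid1)
  fit <- rrblup_fit(y[train], X[train, , drop = FALSE])
  y_perm <- y
  y_perm[valid1] <- sample(y[valid1])
  fit_perm <- rrblup_fit(y_perm[train], X[train, , drop = FALSE])
  expect_identical(fit$effects, fit_perm$effects)
  pc <- pca_fit_predict(X, y[train], train, valid1, q = 3)
  pc_perm <- pca_fit_predict(X, y_perm[train], train, valid1, q = 3)
  expect_identical(pc, pc_perm)
})

test_that("cross-panel configurations compose correctly", {
  pair <- small_pair()
  fams <- sample_parents_and_families(pair$a, pair$b, n_families = 1,
                                      n_f1 = 10, n_f2 = 60, seed = 13)
  suite <- simulate_trait_suite(pair$a, pair$b, fams, scenario = "S.QTN",
                                architecture = "A20D0E0", seed = 14)
  res <- cross_panel_experiment(
    pair$a, pair$b, suite$trait_a, suite$trait_b, fams[[1]]$f2,
    suite$family_traits[[1]], subset_size = 12, cdmean_iters = 10,
    seed = 15)
  expect_equal(nrow(res), 7)
  expect_setequal(res$configuration,
                  c("Msi.Random", "Msa.Random", "Msi.CDmean", "Msa.CDmean",
                    "Msi.Whole", "Msa.Whole", "Whole.Msi.Msa"))
  g <- setNames(res$gebv, res$configuration)
  expect_equal(g[["Whole.Msi.Msa"]],
               sum_gebv(g[["Msi.Whole"]], g[["Msa.Whole"]]))
  expect_error(
    cross_panel_experiment(pair$a, pair$b, suite$trait_a, suite$trait_b,
                           fams[[1]]$f2, suite$family_traits[[1]],
                           configs = "Nope"),
    "unknown configuration")

  # a random subset as large as the whole panel reduces to the whole panel
  res_big <- cross_panel_experiment(
    pair$a, pair$b, suite$trait_a, suite$trait_b, fams[[1]]$f2,
    suite$family_traits[[1]], configs = c("Msi.Random", "Msi.Whole"),
    subset_size = 2 * nrow(pair$a$genotypes$values), seed = 16)
  gb <- setNames(res_big$gebv, res_big$configuration)
  expect_equal(sort(gb[["Msi.Random"]]), sort(gb[["Msi.Whole"]]),
               tolerance = 1e-5)
})

test_that("bootstrap accuracy is consistent with the full-sample value", {
  set.seed(17)
  y <- rnorm(216)
  gebv <- 0.6 * y + rnorm(216, sd = 0.8)
  boot <- bootstrap_accuracy(y, gebv, n_boot = 400, seed = 18)
  expect_lte(nrow(boot), 400)
  full <- pearson_accuracy(y, gebv)
  se <- stats::sd(boot$r)
  expect_lt(abs(mean(boot$r) - full), 2 * se)
  expect_equal(attr(boot, "n_excluded"), 0)

  ident <- bootstrap_accuracy(y, y, n_boot = 20, seed = 19)
  expect_true(all(abs(ident$r - 1) < 1e-12))
  expect_error(bootstrap_accuracy(y, gebv, n_boot = 0), "integer")
  expect_error(bootstrap_accuracy(y, gebv[1:5]), "align")

  # constant data: every resample is undefined, excluded and counted
  cons <- bootstrap_accuracy(rep(1, 10), rnorm(10), n_boot = 15, seed = 20)
  expect_equal(nrow(cons), 0)
  expect_equal(attr(cons, "n_excluded"), 15)
})

test_that("simulation experiments tabulate scenario x config accuracies", {
  pair <- small_pair()
  fams <- sample_parents_and_families(pair$a, pair$b, n_families = 2,
                                      n_f1 = 10, n_f2 = 50, seed = 21)
  res <- simulation_experiment(
    pair$a, pair$b, fams, scenarios = c("S.QTN", "D.QTN"),
    architectures = "A20D0E0",
    configs = c("Msi.Whole", "Msa.Whole", "Whole.Msi.Msa"), seed = 22)
  expect_equal(nrow(res), 2 * 1 * 3 * 2) # scenarios x arch x configs x fams
  expect_true(all(c("scenario", "architecture", "configuration", "family",
                    "r", "r_true_g") %in% names(res)))
  expect_true(all(res$r >= -1 & res$r <= 1, na.rm = TRUE))
  res2 <- simulation_experiment(
    pair$a, pair$b, fams, scenarios = c("S.QTN", "D.QTN"),
    architectures = "A20D0E0",
    configs = c("Msi.Whole", "Msa.Whole", "Whole.Msi.Msa"), seed = 22)
  expect_identical(res$r, res2$r)
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
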