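markers356 <- sprintf("M%04d", 1:356)

test_that("scenario S.QTN gives identical QTN sets and effects", {
  arch <- select_qtns("S.QTN", markers356, n_add = 20, n_dom = 4, n_epi = 4,
                      seed = 1)
  expect_identical(arch$panel_a, arch$panel_b)
  expect_equal(nrow(arch$panel_a$add), 20)
  expect_equal(nrow(arch$panel_a$dom), 4)
  expect_equal(nrow(arch$panel_a$epi), 2) # 4 loci in 2 pairs
  expect_length(intersect(arch$panel_a$add$marker, arch$panel_b$add$marker),
                20)
  all_loci <- c(arch$panel_a$add$marker, arch$panel_a$dom$marker,
                arch$panel_a$epi$marker_1, arch$panel_a$epi$marker_2)
  expect_false(anyDuplicated(all_loci) > 0)
})

test_that("scenario P.QTN shares exactly half the additive QTNs", {
  arch <- select_qtns("P.QTN", markers356, n_add = 20, seed = 2)
  shared <- intersect(arch$panel_a$add$marker, arch$panel_b$add$marker)
  expect_length(shared, 10)
  ea <- arch$panel_a$add$effect[match(shared, arch$panel_a$add$marker)]
  eb <- arch$panel_b$add$effect[match(shared, arch$panel_b$add$marker)]
  expect_equal(ea, eb)
  # panel-specific halves are disjoint
  own_a <- setdiff(arch$panel_a$add$marker, shared)
  own_b <- setdiff(arch$panel_b$add$marker, shared)
  expect_length(intersect(own_a, own_b), 0)
})

test_that("large/small-effect scenarios draw from the stated ranges", {
  arch <- select_qtns("D.QTN.Msi", markers356, n_add = 20, n_dom = 4,
                      n_epi = 4, seed = 3)
  a_eff <- abs(c(arch$panel_a$add$effect, arch$panel_a$dom$effect,
                 arch$panel_a$epi$effect))
  b_eff <- abs(c(arch$panel_b$add$effect, arch$panel_b$dom$effect,
                 arch$panel_b$epi$effect))
  expect_true(all(a_eff >= 0.5 & a_eff <= 0.99))
  expect_true(all(b_eff >= 0 & b_eff <= 0.25))
  expect_length(intersect(arch$panel_a$add$marker, arch$panel_b$add$marker),
                0)

  mirrored <- select_qtns("D.QTN.Msa", markers356, n_add = 20, seed = 3)
  expect_true(all(abs(mirrored$panel_b$add$effect) >= 0.5))
  expect_true(all(abs(mirrored$panel_a$add$effect) <= 0.25))

  expect_error(select_qtns("X.QTN", markers356), "unknown scenario")
})

test_that("unsigned effects stay positive when requested", {
  arch <- select_qtns("D.QTN", markers356, n_add = 20, seed = 4,
                      signed_effects = FALSE)
  expect_true(all(arch$panel_a$add$effect >= 0))
  expect_true(all(arch$panel_b$add$effect >= 0))
})

test_that("genetic values match a hand-computed oracle", {
  # 3 individuals x 4 markers; additive at m1 (a=0.5), m2 (a=-0.2),
  # dominance at m3 (d=0.3), epistasis m1 x m4 (w=0.4)
  dos <- matrix(c(0, 1, 2,
                  2, 2, 0,
                  1, 0, 1,
                  0, 2, 2), nrow = 3,
                dimnames = list(c("i1", "i2", "i3"), paste0("m", 1:4)))
  geno <- genotype_matrix(dos, "discrete_012")
  qtns <- list(
    add = tibble::tibble(marker = c(1L, 2L), effect = c(0.5, -0.2)),
    dom = tibble::tibble(marker = 3L, effect = 0.3),
    epi = tibble::tibble(marker_1 = 1L, marker_2 = 4L, effect = 0.4)
  )
  g <- genetic_value(geno, qtns)
  x <- dos - 1
  expected <- 0.5 * x[, 1] - 0.2 * x[, 2] + 0.3 * (dos[, 3] == 1) +
    0.4 * x[, 1] * x[, 4]
  expect_equal(unname(g), unname(expected))

  # single additive QTN with unit effect reproduces the {-1,0,1} code
  one <- list(add = tibble::tibble(marker = 2L, effect = 1),
              dom = tibble::tibble(marker = integer(), effect = numeric()),
              epi = tibble::tibble(marker_1 = integer(),
                                   marker_2 = integer(), effect = numeric()))
  expect_equal(unname(genetic_value(geno, one)), unname(x[, 2]))

  bad <- one
  bad$add$marker <- 99L
  expect_error(genetic_value(geno, bad), "out of range")
})

test_that("shared QTNs contribute once in the F2 union", {
  arch_s <- select_qtns("S.QTN", markers356, n_add = 20, seed = 5)
  expect_equal(nrow(qtn_union(arch_s)$add), 20)
  arch_p <- select_qtns("P.QTN", markers356, n_add = 20, seed = 5)
  expect_equal(nrow(qtn_union(arch_p)$add), 30) # 10 shared + 10 + 10
  arch_d <- select_qtns("D.QTN", markers356, n_add = 20, seed = 5)
  expect_equal(nrow(qtn_union(arch_d)$add), 40)
})

test_that("noise calibration hits the target heritability", {
  pan <- small_panel()
  arch <- select_qtns("S.QTN", pan$genotypes$marker_ids, n_add = 10,
                      seed = 6)
  g <- genetic_value(pan$genotypes, arch$panel_a)

  exact <- add_noise_to_target_h2(g, 1, seed = 1)
  expect_equal(exact$phenotype, exact$genetic_value)
  expect_equal(realized_h2(exact), 1)

  h2s <- vapply(1:100, function(s) {
    realized_h2(add_noise_to_target_h2(g, 0.60, seed = s))
  }, 0)
  expect_lt(abs(mean(h2s) - 0.60), 0.05)

  expect_error(add_noise_to_target_h2(rep(1, 10), 0.5), "degenerate")
  expect_error(add_noise_to_target_h2(g, 0), "target_h2")
  expect_error(add_noise_to_target_h2(g, 1.2), "target_h2")

  gl <- generics::glance(exact)
  expect_equal(gl$realized_h2, 1)
  expect_equal(gl$n, length(g))
})

test_that("realized heritability concentrates with sample size", {
  map <- small_map()
  spread <- vapply(c(50, 400), function(n) {
    pan <- simulate_panel(n, map, seed = 7)
    arch <- select_qtns("S.QTN", pan$genotypes$marker_ids, n_add = 10,
                        seed = 8)
    g <- genetic_value(pan$genotypes, arch$panel_a)
    stats::sd(vapply(1:40, function(s) {
      realized_h2(add_noise_to_target_h2(g, 0.6, seed = s))
    }, 0))
  }, 0)
  expect_lt(spread[2], spread[1])
})

test_that("permuting individuals permutes genetic values identically", {
  pan <- small_panel()
  arch <- select_qtns("D.QTN", pan$genotypes$marker_ids, n_add = 10,
                      seed = 9)
  g <- genetic_value(pan$genotypes, arch$panel_a)
  perm <- sample(seq_along(g))
  g_perm <- genetic_value(subset_individuals(pan$genotypes, perm),
                          arch$panel_a)
  expect_equal(g_perm, g[perm])
})

test_that("trait suites cover panels and families deterministically", {
  pair <- small_pair()
  fams <- sample_parents_and_families(pair$a, pair$b, n_families = 2,
                                      n_f1 = 10, n_f2 = 40, seed = 10)
  suite <- simulate_trait_suite(pair$a, pair$b, fams, scenario = "S.QTN",
                                architecture = "A20D0E0", seed = 11)
  expect_equal(nrow(suite$architecture$panel_a$dom), 0)
  expect_equal(nrow(suite$architecture$panel_a$epi), 0)
  expect_length(suite$family_traits, 2)
  expect_equal(attr(suite$trait_a, "target_h2"), 0.60)
  expect_equal(attr(suite$family_traits[[1]], "target_h2"), 0.37)

  suite2 <- simulate_trait_suite(pair$a, pair$b, fams, scenario = "S.QTN",
                                 architecture = "A20D0E0", seed = 11)
  expect_identical(suite$trait_a$phenotype, suite2$trait_a$phenotype)
  expect_identical(suite$family_traits[[2]]$phenotype,
                   suite2$family_traits[[2]]$phenotype)

  withdom <- simulate_trait_suite(pair$a, pair$b, fams, scenario = "P.QTN",
                                  architecture = "A20D4E4", seed = 12)
  expect_equal(nrow(withdom$architecture$panel_a$dom), 4)
  expect_equal(nrow(withdom$architecture$panel_a$epi), 2)

  # family in which no QTN segregates surfaces a degenerate-trait error
  map <- small_map()
  m <- nrow(map)
  hom <- phased_individual(rep(1L, m), rep(1L, m), id = "hom")
  fam_fixed <- make_f2_family(hom, hom, map, n_f1 = 5, n_f2 = 10,
                              seed = 13, family_id = "fixedfam")
  expect_error(
    simulate_trait_suite(pair$a, pair$b, list(fam_fixed),
                         scenario = "S.QTN", architecture = "A20D0E0",
                         seed = 14),
    "fixedfam")
})
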