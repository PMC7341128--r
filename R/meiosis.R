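#' Haldane mapping function
#'
#' Converts genetic distance in centimorgans to a recombination fraction
#' under the Haldane (no crossover interference) model:
#' `r = (1 - exp(-2 d / 100)) / 2`.
#'
#' @param distance_cM Non-negative genetic distance(s) in cM.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
#' @examples
#' haldane_r(50) # (1 - exp(-1)) / 2
haldane_r <- function(distance_cM) {
  if (!is.numeric(distance_cM) || any(!is.finite(distance_cM)) ||
      any(distance_cM < 0)) {
    abort("`distance_cM` must be non-negative and finite.")
  }
  (1 - exp(-2 * distance_cM / 100)) / 2
}

#' Construct a phased individual
#'
#' @param hap1,hap2 Binary haplotype vectors aligned to a map's marker order.
#' @param id Optional individual id.
#' @return An object of class `phased_individual`.
#' @export
phased_individual <- function(hap1, hap2, id = NULL) {
  if (length(hap1) != length(hap2)) abort("haplotypes must have equal length.")
  if (!all(c(hap1, hap2) %in% c(0, 1))) {
    abort("haplotype entries must be 0 or 1.")
  }
  structure(list(hap1 = as.integer(hap1), hap2 = as.integer(hap2), id = id),
            class = "phased_individual")
}

#' Extract one panel member as a phased individual
#'
#' @param panel A `panel` with stored haplotypes.
#' @param i Row index or individual id.
#' @return A `phased_individual`.
#' @export
panel_individual <- function(panel, i) {
  stopifnot(inherits(panel, "panel"))
  if (is.character(i)) i <- match(i, panel$genotypes$individual_ids)
  phased_individual(panel$haplotypes$h1[i, ], panel$haplotypes$h2[i, ],
                    id = panel$genotypes$individual_ids[i])
}

#' Phase an unphased diploid genotype at random
#'
#' Heterozygous markers are assigned to the two haplotypes uniformly at
#' random (seeded once). Single-locus genotype distributions of descendants
#' are invariant to this choice; multi-locus linkage phase is approximate.
#'
#' @param dosage Integer vector of 0/1/2 dosages.
#' @param seed Integer seed.
#' @param id Optional id.
#' @return A `phased_individual`.
#' @export
phase_randomly <- function(dosage, seed = 1L, id = NULL) {
  if (!all(dosage %in% c(0, 1, 2))) abort("dosages must be in {0, 1, 2}.")
  with_seed(seed, {
    h1 <- as.integer(dosage == 2)
    h2 <- h1
    het <- which(dosage == 1)
    flip <- runif(length(het)) < 0.5
    h1[het] <- as.integer(flip)
    h2[het] <- as.integer(!flip)
    phased_individual(h1, h2, id = id)
  })
}

# Per-marker "switch" probabilities for a gamete walk along the map:
# 0.5 at the first marker of each linkage group (fresh uniform choice of
# source haplotype), haldane_r(distance) between adjacent markers within a
# group. Assumes map rows ordered by group then position (validated).
switch_probs <- function(map) {
  map <- validate_map(map)
  m <- nrow(map)
  pr <- numeric(m)
  start <- !duplicated(map$linkage_group)
  pr[start] <- 0.5
  d <- diff(map$position_cM)
  pr[!start] <- haldane_r(d[!start[-1]])
  pr
}

# Vectorized gamete generation: n gametes from one phased parent.
# The source-haplotype indicator is a Markov chain along each linkage group;
# this inter-marker walk is exact under Haldane/no interference.
gametes_matrix <- function(parent, map, n) {
  m <- nrow(map)
  if (length(parent$hap1) != m) {
    abort("parent haplotype length does not match the map.")
  }
  pr <- switch_probs(map)
  sw <- matrix(rbinom(n * m, 1L, rep(pr, each = n)), nrow = n)
  src <- sw
  for (j in seq_len(m)[-1]) {
    # carry state across markers, reset implicitly at group starts (pr = 0.5)
    src[, j] <- (src[, j] + src[, j - 1L]) %% 2L
  }
  g <- matrix(parent$hap1, n, m, byrow = TRUE)
  h2 <- matrix(parent$hap2, n, m, byrow = TRUE)
  pick2 <- src == 1L
  g[pick2] <- h2[pick2]
  g
}

#' Simulate gametes from a phased parent
#'
#' Simulates meiosis along a genetic map under the Haldane model with no
#' crossover interference: within a linkage group the source haplotype
#' follows a Markov walk whose switch probability between adjacent markers
#' is [haldane_r()] of their distance; linkage groups assort independently.
#'
#' @param parent A [phased_individual()].
#' @param map Genetic map the haplotypes are aligned to.
#' @param n Number of gametes.
#' @param seed Integer seed.
#' @return If `n = 1` a binary haplotype vector, else an `n` x markers
#'   binary matrix.
#' @export
simulate_gamete <- function(parent, map, n = 1L, seed = 1L) {
  stopifnot(inherits(parent, "phased_individual"))
  n <- check_count(n, "n")
  map <- validate_map(map)
  g <- with_seed(seed, gametes_matrix(parent, map, n))
  if (n == 1L) g[1, ] else g
}

#' Simulate an interspecific F2 family
#'
#' From two phased parents: `n_f1` F1 individuals each receive one gamete
#' from each parent; F2 individuals are produced by intermating the F1
#' (two distinct F1 parents drawn uniformly at random per F2 individual;
#' selfing disallowed). Normal meiotic segregation is assumed throughout.
#'
#' @param parent_a,parent_b Phased founder individuals on a common map.
#' @param map Genetic map.
#' @param n_f1 Number of F1 individuals (>= 2).
#' @param n_f2 Number of F2 individuals.
#' @param seed Integer seed; the family is deterministic given the seed.
#' @param family_id Optional label.
#' @return An object of class `f2_family`: parent ids, the F1 as phased
#'   individuals, the F2 as a `discrete_012` [genotype_matrix()], and the map.
#' @export
make_f2_family <- function(parent_a, parent_b, map, n_f1 = 50L, n_f2 = 216L,
                           seed = 1L, family_id = "F2fam") {
  stopifnot(inherits(parent_a, "phased_individual"),
            inherits(parent_b, "phased_individual"))
  n_f1 <- check_count(n_f1, "n_f1")
  n_f2 <- check_count(n_f2, "n_f2")
  if (n_f1 < 2L) abort("cannot intermate fewer than 2 F1 individuals.")
  map <- validate_map(map)
  with_seed(seed, {
    gam_a <- gametes_matrix(parent_a, map, n_f1)
    gam_b <- gametes_matrix(parent_b, map, n_f1)
    f1 <- lapply(seq_len(n_f1), function(i) {
      phased_individual(gam_a[i, ], gam_b[i, ],
                        id = sprintf("%s_F1_%03d", family_id, i))
    })
    p1 <- sample.int(n_f1, n_f2, replace = TRUE)
    p2 <- sample.int(n_f1, n_f2, replace = TRUE)
    while (any(self <- p1 == p2)) {
      p2[self] <- sample.int(n_f1, sum(self), replace = TRUE)
    }
    m <- nrow(map)
    g1 <- matrix(0L, n_f2, m)
    g2 <- matrix(0L, n_f2, m)
    for (par in unique(p1)) {
      rows <- which(p1 == par)
      g1[rows, ] <- gametes_matrix(f1[[par]], map, length(rows))
    }
    for (par in unique(p2)) {
      rows <- which(p2 == par)
      g2[rows, ] <- gametes_matrix(f1[[par]], map, length(rows))
    }
    ids <- sprintf("%s_F2_%03d", family_id, seq_len(n_f2))
    geno <- genotype_matrix(g1 + g2, coding = "discrete_012",
                            individual_ids = ids, marker_ids = map$marker_id)
    structure(
      list(family_id = family_id,
           parent_a_id = parent_a$id %||% "parent_a",
           parent_b_id = parent_b$id %||% "parent_b",
           f1 = f1, f2 = geno, map = map, seed = seed),
      class = "f2_family"
    )
  })
}

#' @export
print.f2_family <- function(x, ...) {
  cat(sprintf("<f2_family %s> %s x %s: %d F1, %d F2\n", x$family_id,
              x$parent_a_id, x$parent_b_id, length(x$f1),
              nrow(x$f2$values)))
  invisible(x)
}

#' Sample parents from two panels and build F2 families
#'
#' For each family one parent is drawn uniformly at random from each panel
#' (draws independent across families), and an F2 family is built with
#' [make_f2_family()] under a family-specific child seed.
#'
#' @param panel_a,panel_b Phased panels on a common map.
#' @param n_families Number of families.
#' @param n_f1,n_f2 Family design; defaults 50 F1 intermated to 216 F2.
#' @param seed Master integer seed.
#' @return A list of `f2_family` objects with recorded parent ids.
#' @export
sample_parents_and_families <- function(panel_a, panel_b, n_families = 50L,
                                        n_f1 = 50L, n_f2 = 216L, seed = 1L) {
  stopifnot(inherits(panel_a, "panel"), inherits(panel_b, "panel"))
  n_families <- check_count(n_families, "n_families")
  na <- nrow(panel_a$genotypes$values)
  nb <- nrow(panel_b$genotypes$values)
  if (na < 1L || nb < 1L) abort("panels must be non-empty.")
  if (!identical(panel_a$map$marker_id, panel_b$map$marker_id)) {
    abort("panels must share a common map.")
  }
  idx <- with_seed(seed, {
    list(a = sample.int(na, n_families, replace = TRUE),
         b = sample.int(nb, n_families, replace = TRUE))
  })
  lapply(seq_len(n_families), function(f) {
    make_f2_family(
      panel_individual(panel_a, idx$a[f]),
      panel_individual(panel_b, idx$b[f]),
      panel_a$map, n_f1 = n_f1, n_f2 = n_f2,
      seed = child_seed(seed, f),
      family_id = sprintf("fam%02d", f)
    )
  })
}
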