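#' Simulate a genetic map
#'
#' Allocates markers as evenly as possible across linkage groups (remainder
#' markers go to the first groups) and draws marker positions uniformly on
#' `[0, length_cM]` within each group, sorted so positions are strictly
#' increasing.
#'
#' @param n_markers Total number of markers (>= `n_linkage_groups`).
#' @param n_linkage_groups Number of linkage groups (chromosomes).
#' @param length_cM Genetic length of each linkage group in centimorgans.
#' @param seed Integer seed; the map is deterministic given the seed.
#' @return A tibble of class `genetic_map` with columns `marker_id`,
#'   `linkage_group`, `position_cM`, ordered by group then position.
#' @export
#' @examples
#' simulate_map(356, 19, 150, seed = 1)
simulate_map <- function(n_markers, n_linkage_groups, length_cM = 150,
                         seed = 1L) {
  n_markers <- check_count(n_markers, "n_markers")
  n_linkage_groups <- check_count(n_linkage_groups, "n_linkage_groups")
  if (n_markers < n_linkage_groups) {
    abort("`n_markers` must be at least `n_linkage_groups`.")
  }
  if (!is.numeric(length_cM) || length_cM <= 0) {
    abort("`length_cM` must be a positive number.")
  }
  sizes <- rep(n_markers %/% n_linkage_groups, n_linkage_groups)
  rem <- n_markers %% n_linkage_groups
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  with_seed(seed, {
    pos <- lapply(sizes, function(k) {
      p <- sort(runif(k, 0, length_cM))
      while (anyDuplicated(p)) p <- sort(runif(k, 0, length_cM))
      p
    })
    map <- tibble::tibble(
      marker_id = sprintf("M%04d", seq_len(n_markers)),
      linkage_group = rep(seq_len(n_linkage_groups), sizes),
      position_cM = unlist(pos)
    )
    validate_map(map)
  })
}

#' Validate a genetic map
#'
#' Checks uniqueness of marker ids and strictly increasing positions within
#' each linkage group; used on both simulated and imported maps.
#'
#' @param map A data frame with columns `marker_id`, `linkage_group`,
#'   `position_cM`.
#' @return The map as a `genetic_map` tibble (invisibly the same data).
#' @export
validate_map <- function(map) {
  need <- c("marker_id", "linkage_group", "position_cM")
  if (!all(need %in% names(map))) {
    abort(sprintf("map must have columns %s.", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(map$marker_id)) abort("marker ids must be unique.")
  if (any(map$position_cM < 0)) abort("map positions must be non-negative.")
  for (lg in unique(map$linkage_group)) {
    p <- map$position_cM[map$linkage_group == lg]
    if (any(diff(p) <= 0)) {
      abort(sprintf(
        "positions must be strictly increasing within linkage group %s.", lg))
    }
  }
  out <- tibble::as_tibble(map[, need])
  class(out) <- c("genetic_map", class(tibble::tibble()))
  out
}

# Balding-Nichols draw of subpopulation allele frequencies around ancestral p.
bn_draw <- function(p, fst) {
  if (fst == 0) return(p)
  if (fst >= 1) return(as.numeric(runif(length(p)) < p))
  rbeta(length(p), shape1 = p * (1 - fst) / fst,
        shape2 = (1 - p) * (1 - fst) / fst)
}

# Even split of n individuals into K subpopulations, remainder to the first.
subpop_assignment <- function(n, k) {
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  rep(seq_len(k), sizes)
}

# Core generator: structured panel from per-marker base allele frequencies.
panel_from_base <- function(base_p, n_individuals, map, n_subpops, fst,
                            species_tag, id_prefix) {
  m <- length(base_p)
  subpop <- subpop_assignment(n_individuals, n_subpops)
  freq <- matrix(0, n_subpops, m)
  for (k in seq_len(n_subpops)) freq[k, ] <- bn_draw(base_p, fst)
  pr <- freq[subpop, , drop = FALSE]
  h1 <- matrix(rbinom(n_individuals * m, 1L, pr), n_individuals, m)
  h2 <- matrix(rbinom(n_individuals * m, 1L, pr), n_individuals, m)
  ids <- sprintf("%s_%04d", id_prefix, seq_len(n_individuals))
  dimnames(h1) <- dimnames(h2) <- list(ids, map$marker_id)
  geno <- genotype_matrix(h1 + h2, coding = "discrete_012",
                          individual_ids = ids, marker_ids = map$marker_id)
  structure(
    list(genotypes = geno, haplotypes = list(h1 = h1, h2 = h2),
         subpop = subpop, species_tag = species_tag, map = map),
    class = "panel"
  )
}

#' Simulate a structured diversity panel
#'
#' Generates a diploid panel with subpopulation structure under the
#' Balding-Nichols model: per-marker ancestral frequencies are drawn
#' `Uniform(0.05, 0.95)`, subpopulation frequencies from
#' `Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`, and phased haplotype alleles
#' Bernoulli at the subpopulation frequency. Individuals are split as evenly
#' as possible across subpopulations. Markers that come out monomorphic are
#' retained.
#'
#' @param n_individuals Panel size.
#' @param map A [simulate_map()] / [validate_map()] genetic map.
#' @param n_subpops Number of subpopulations K (>= 1).
#' @param fst Differentiation among subpopulations, strictly in (0, 1).
#' @param seed Integer seed.
#' @param species_tag `"A"` or `"B"`; carried through to results.
#' @return An object of class `panel`: genotypes (`discrete_012`), phased
#'   haplotypes whose sum reproduces the dosages, subpopulation labels, the
#'   map, and the species tag.
#' @export
#' @examples
#' map <- simulate_map(50, 5, 120, seed = 1)
#' pan <- simulate_panel(30, map, n_subpops = 3, fst = 0.25, seed = 2)
simulate_panel <- function(n_individuals, map, n_subpops = 3, fst = 0.25,
                           seed = 1L, species_tag = "A") {
  n_individuals <- check_count(n_individuals, "n_individuals")
  n_subpops <- check_count(n_subpops, "n_subpops")
  map <- validate_map(map)
  if (n_individuals < n_subpops) {
    abort("`n_individuals` must be >= `n_subpops`.")
  }
  if (!is.numeric(fst) || length(fst) != 1L || fst <= 0 || fst >= 1) {
    abort("`fst` must lie strictly in (0, 1).")
  }
  with_seed(seed, {
    p <- runif(nrow(map), 0.05, 0.95)
    panel_from_base(p, n_individuals, map, n_subpops, fst, species_tag,
                    paste0(species_tag, "pan"))
  })
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf(
    "<panel %s> %d individuals, %d markers, %d subpopulations\n",
    x$species_tag, nrow(x$genotypes$values), ncol(x$genotypes$values),
    max(x$subpop)))
  invisible(x)
}

#' Simulate a pair of related species panels
#'
#' One ancestral frequency vector is drawn, each species' base frequencies
#' are derived from it by a Balding-Nichols step with parameter `divergence`,
#' and within-species subpopulation structure is then applied as in
#' [simulate_panel()]. Emulates two congeneric diversity panels (e.g., the
#' two parental species of an interspecific hybrid) whose cross-species
#' kinship is depressed relative to within-species kinship.
#'
#' @param n_a,n_b Panel sizes for species A and B.
#' @param map Shared genetic map.
#' @param n_subpops_each Subpopulations per species.
#' @param fst_within Within-species differentiation, in (0, 1).
#' @param divergence Between-species Balding-Nichols parameter in \[0, 1\];
#'   0 means the species share base frequencies.
#' @param seed Integer seed.
#' @return A list with elements `a` and `b`, each a `panel` (species tags
#'   `"A"` and `"B"`).
#' @export
simulate_species_pair <- function(n_a, n_b, map, n_subpops_each = 3,
                                  fst_within = 0.25, divergence = 0.5,
                                  seed = 1L) {
  if (!is.numeric(divergence) || length(divergence) != 1L ||
      divergence < 0 || divergence > 1) {
    abort("`divergence` must lie in [0, 1].")
  }
  if (!is.numeric(fst_within) || length(fst_within) != 1L ||
      fst_within <= 0 || fst_within >= 1) {
    abort("`fst_within` must lie strictly in (0, 1).")
  }
  map <- validate_map(map)
  with_seed(seed, {
    p <- runif(nrow(map), 0.05, 0.95)
    base_a <- bn_draw(p, divergence)
    base_b <- bn_draw(p, divergence)
    a <- panel_from_base(base_a, check_count(n_a, "n_a"), map,
                         check_count(n_subpops_each, "n_subpops_each"),
                         fst_within, "A", "Apan")
    b <- panel_from_base(base_b, check_count(n_b, "n_b"), map,
                         check_count(n_subpops_each, "n_subpops_each"),
                         fst_within, "B", "Bpan")
    list(a = a, b = b)
  })
}

#' Per-marker allele frequencies of a panel
#'
#' @param panel A `panel`.
#' @return Numeric vector of alternate-allele frequencies.
#' @export
allele_freq <- function(panel) {
  colMeans(panel$genotypes$values) / 2
}
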