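SCENARIOS <- c("S.QTN", "P.QTN", "D.QTN", "D.QTN.Msi", "D.QTN.Msa")

#' Parse an architecture code
#'
#' Codes like `"A20D4E0"` give the number of additive, dominance, and
#' epistatic quantitative trait nucleotides (QTNs). The epistatic count is
#' the number of loci engaged in additive-by-additive epistasis and must be
#' even (loci act in disjoint pairs, one interaction effect per pair).
#'
#' @param code Architecture string `"A<n>D<n>E<n>"`.
#' @return A list with `n_add`, `n_dom`, `n_epi`.
#' @export
#' @examples
#' parse_architecture("A20D0E4")
parse_architecture <- function(code) {
  m <- regmatches(code, regexec("^A([0-9]+)D([0-9]+)E([0-9]+)$", code))[[1]]
  if (length(m) != 4L) {
    abort(sprintf("malformed architecture code '%s' (expect A#D#E#).", code))
  }
  out <- list(n_add = as.integer(m[2]), n_dom = as.integer(m[3]),
              n_epi = as.integer(m[4]))
  if (out$n_epi %% 2L != 0L) {
    abort("epistatic locus count must be even (loci act in pairs).")
  }
  out
}

# Draw effect magnitudes for one panel under a scenario's range, with an
# optional random sign per effect.
draw_effects <- function(n, range, signed) {
  if (n == 0L) return(numeric(0))
  e <- runif(n, range[1], range[2])
  if (signed) e <- e * sample(c(-1, 1), n, replace = TRUE)
  e
}

qtn_set <- function(add_idx, add_eff, dom_idx, dom_eff, epi_idx1, epi_idx2,
                    epi_eff, marker_ids) {
  list(
    add = tibble::tibble(marker = add_idx, marker_id = marker_ids[add_idx],
                         effect = add_eff),
    dom = tibble::tibble(marker = dom_idx, marker_id = marker_ids[dom_idx],
                         effect = dom_eff),
    epi = tibble::tibble(marker_1 = epi_idx1, marker_2 = epi_idx2,
                         marker_id_1 = marker_ids[epi_idx1],
                         marker_id_2 = marker_ids[epi_idx2],
                         effect = epi_eff)
  )
}

#' Select QTNs and effects under a sharing scenario
#'
#' Designates a subset of the mapped markers as quantitative trait
#' nucleotides for two diversity panels under one of five sharing scenarios:
#' \describe{
#'   \item{S.QTN}{the same QTNs with the same effects in both panels;}
#'   \item{P.QTN}{half of the QTNs shared (same effects), half
#'     panel-specific;}
#'   \item{D.QTN}{completely different QTNs in the two panels, effects drawn
#'     from the same distribution;}
#'   \item{D.QTN.Msi}{different QTNs, panel A carrying large effects
#'     (Uniform(0.5, 0.99)) and panel B small effects (Uniform(0, 0.25));}
#'   \item{D.QTN.Msa}{the mirror image, large effects in panel B.}
#' }
#' Unless a large/small scenario applies, effect magnitudes are
#' Uniform(0, 1). By default each magnitude is given a random sign; set
#' `signed_effects = FALSE` for strictly positive effects.
#'
#' @param scenario One of `"S.QTN"`, `"P.QTN"`, `"D.QTN"`, `"D.QTN.Msi"`,
#'   `"D.QTN.Msa"`.
#' @param marker_ids Character vector: the marker universe shared by both
#'   panels.
#' @param n_add,n_dom,n_epi QTN counts (additive, dominance, epistatic loci;
#'   `n_epi` even). Defaults 20/0/0.
#' @param seed Integer seed.
#' @param signed_effects Give each effect a random sign (default `TRUE`).
#' @return An object of class `trait_architecture` with per-panel QTN sets
#'   (`$panel_a`, `$panel_b`), each holding `add`, `dom` and `epi` tibbles.
#' @export
select_qtns <- function(scenario, marker_ids, n_add = 20L, n_dom = 0L,
                        n_epi = 0L, seed = 1L, signed_effects = TRUE) {
  if (!scenario %in% SCENARIOS) {
    abort(sprintf("unknown scenario '%s'; expected one of %s.", scenario,
                  paste(SCENARIOS, collapse = ", ")))
  }
  n_add <- check_count(n_add, "n_add")
  n_dom <- check_count(n_dom, "n_dom", min = 0L)
  n_epi <- check_count(n_epi, "n_epi", min = 0L)
  if (n_epi %% 2L != 0L) abort("`n_epi` must be even (loci act in pairs).")
  n_total <- n_add + n_dom + n_epi
  m <- length(marker_ids)
  need <- if (scenario == "S.QTN") n_total else 2L * n_total
  if (need > m) abort("not enough markers for the requested QTN counts.")

  big <- c(0.5, 0.99); small <- c(0, 0.25); std <- c(0, 1)
  ranges <- switch(scenario,
    D.QTN.Msi = list(a = big, b = small),
    D.QTN.Msa = list(a = small, b = big),
    list(a = std, b = std))

  with_seed(seed, {
    draw_panel <- function(idx, range) {
      qtn_set(idx[seq_len(n_add)],
              draw_effects(n_add, range, signed_effects),
              idx[n_add + seq_len(n_dom)],
              draw_effects(n_dom, range, signed_effects),
              idx[n_add + n_dom + seq_len(n_epi / 2)],
              idx[n_add + n_dom + n_epi / 2 + seq_len(n_epi / 2)],
              draw_effects(n_epi / 2, range, signed_effects),
              marker_ids)
    }
    if (scenario == "S.QTN") {
      idx <- sample.int(m, n_total)
      set_a <- draw_panel(idx, std)
      set_b <- set_a
    } else if (scenario == "P.QTN") {
      # per category: first half of the loci shared with equal effects,
      # second half drawn separately (disjointly) for each panel
      h_add <- n_add %/% 2L; h_dom <- n_dom %/% 2L
      h_pair <- (n_epi %/% 2L) %/% 2L
      n_shared <- h_add + h_dom + 2L * h_pair
      idx <- sample.int(m, n_shared + 2L * (n_total - n_shared))
      shared <- idx[seq_len(n_shared)]
      rest <- idx[-seq_len(n_shared)]
      own_a <- rest[seq_len(n_total - n_shared)]
      own_b <- rest[(n_total - n_shared) + seq_len(n_total - n_shared)]
      build <- function(own) {
        c(shared[seq_len(h_add)], own[seq_len(n_add - h_add)],
          shared[h_add + seq_len(h_dom)],
          own[(n_add - h_add) + seq_len(n_dom - h_dom)],
          shared[h_add + h_dom + seq_len(2L * h_pair)],
          own[(n_add - h_add) + (n_dom - h_dom) +
                seq_len(n_epi - 2L * h_pair)])
      }
      loci_a <- build(own_a); loci_b <- build(own_b)
      # epistatic loci order: shared pairs first, then own pairs
      reorder_epi <- function(loci) {
        if (n_epi == 0L) return(loci)
        e <- loci[n_add + n_dom + seq_len(n_epi)]
        c(loci[seq_len(n_add + n_dom)], e[seq(1, n_epi, by = 2)],
          e[seq(2, n_epi, by = 2)])
      }
      set_a <- draw_panel(reorder_epi(loci_a), std)
      set_b <- draw_panel(reorder_epi(loci_b), std)
      # equalize effects on the shared halves
      if (h_add > 0) set_b$add$effect[seq_len(h_add)] <-
          set_a$add$effect[seq_len(h_add)]
      if (h_dom > 0) set_b$dom$effect[seq_len(h_dom)] <-
          set_a$dom$effect[seq_len(h_dom)]
      if (h_pair > 0) set_b$epi$effect[seq_len(h_pair)] <-
          set_a$epi$effect[seq_len(h_pair)]
    } else {
      idx <- sample.int(m, 2L * n_total)
      set_a <- draw_panel(idx[seq_len(n_total)], ranges$a)
      set_b <- draw_panel(idx[n_total + seq_len(n_total)], ranges$b)
    }
    structure(
      list(scenario = scenario,
           architecture = sprintf("A%dD%dE%d", n_add, n_dom, n_epi),
           panel_a = set_a, panel_b = set_b, seed = seed,
           signed_effects = signed_effects),
      class = "trait_architecture"
    )
  })
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("<trait_architecture> scenario %s, %s\n", x$scenario,
              x$architecture))
  invisible(x)
}

#' Merge the two panels' QTN sets for F2 genetic values
#'
#' Shared QTNs (identical locus and effect) contribute once; panel-specific
#' QTNs are concatenated.
#'
#' @param arch A [select_qtns()] architecture.
#' @return A single QTN set (`add`, `dom`, `epi` tibbles).
#' @export
qtn_union <- function(arch) {
  stopifnot(inherits(arch, "trait_architecture"))
  list(
    add = dplyr::distinct(dplyr::bind_rows(arch$panel_a$add,
                                           arch$panel_b$add)),
    dom = dplyr::distinct(dplyr::bind_rows(arch$panel_a$dom,
                                           arch$panel_b$dom)),
    epi = dplyr::distinct(dplyr::bind_rows(arch$panel_a$epi,
                                           arch$panel_b$epi))
  )
}

#' Genetic values from a QTN set
#'
#' With `x = dosage - 1` coded in `{-1, 0, 1}`, the genetic value is
#' `g = sum_j a_j x_j + sum_j d_j 1(dosage_j == 1) + sum_k w_k x_k1 x_k2`:
#' additive effects on the signed allele count, dominance deviations at the
#' heterozygote, and additive-by-additive epistasis on products of codes.
#' QTNs that do not segregate contribute zero variance by construction.
#'
#' @param genotypes A `discrete_012` [genotype_matrix()].
#' @param qtns A QTN set: one panel component of a [select_qtns()]
#'   architecture, or a [qtn_union()].
#' @return Named numeric vector of genetic values.
#' @export
genetic_value <- function(genotypes, qtns) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (genotypes$coding != "discrete_012") {
    abort("genetic values require discrete_012 genotypes.")
  }
  v <- genotypes$values
  all_idx <- c(qtns$add$marker, qtns$dom$marker, qtns$epi$marker_1,
               qtns$epi$marker_2)
  if (length(all_idx) && (min(all_idx) < 1L || max(all_idx) > ncol(v))) {
    abort("QTN marker index out of range for this genotype matrix.")
  }
  g <- numeric(nrow(v))
  if (nrow(qtns$add)) {
    g <- g + (v[, qtns$add$marker, drop = FALSE] - 1) %*% qtns$add$effect
  }
  if (nrow(qtns$dom)) {
    g <- g + (v[, qtns$dom$marker, drop = FALSE] == 1) %*% qtns$dom$effect
  }
  if (nrow(qtns$epi)) {
    x1 <- v[, qtns$epi$marker_1, drop = FALSE] - 1
    x2 <- v[, qtns$epi$marker_2, drop = FALSE] - 1
    g <- g + (x1 * x2) %*% qtns$epi$effect
  }
  stats::setNames(as.numeric(g), genotypes$individual_ids)
}

#' Add environmental noise to hit a target heritability
#'
#' Sets the noise variance from the realized genetic variance,
#' `sigma_e^2 = Var(g) (1 - H2) / H2`, and draws i.i.d. Gaussian
#' environmental deviations, so the expected broad-sense heritability of the
#' simulated phenotype equals the target.
#'
#' @param g Named vector of genetic values with positive variance.
#' @param target_h2 Target broad-sense heritability in (0, 1].
#' @param seed Integer seed.
#' @return A tibble of class `simulated_trait` with columns `individual_id`,
#'   `genetic_value`, `phenotype`; attributes `target_h2`, `noise_var`,
#'   `realized_h2`. See [glance.simulated_trait()].
#' @export
add_noise_to_target_h2 <- function(g, target_h2, seed = 1L) {
  if (!is.numeric(target_h2) || length(target_h2) != 1L ||
      target_h2 <= 0 || target_h2 > 1) {
    abort("`target_h2` must lie in (0, 1].")
  }
  vg <- var(g)
  if (vg == 0 && target_h2 < 1) {
    abort("degenerate trait: genetic values have zero variance.",
          class = "crosstrain_degenerate_trait")
  }
  sigma2_e <- vg * (1 - target_h2) / target_h2
  y <- if (sigma2_e == 0) g else {
    with_seed(seed, g + rnorm(length(g), 0, sqrt(sigma2_e)))
  }
  out <- tibble::tibble(
    individual_id = names(g) %||% as.character(seq_along(g)),
    genetic_value = unname(g),
    phenotype = unname(y)
  )
  attr(out, "target_h2") <- target_h2
  attr(out, "noise_var") <- sigma2_e
  attr(out, "realized_h2") <- vg / var(y)
  class(out) <- c("simulated_trait", class(out))
  out
}

#' Realized heritability of a simulated trait
#'
#' @param x A `simulated_trait`.
#' @return `Var(g) / Var(y)`.
#' @export
realized_h2 <- function(x) {
  stopifnot(inherits(x, "simulated_trait"))
  attr(x, "realized_h2")
}

#' Simulate a full trait suite for two panels and their F2 families
#'
#' Draws one trait architecture for the (scenario, architecture) pair,
#' phenotypes each panel at the panel-level heritability, and phenotypes
#' every F2 family at the F2-level heritability with a family-specific noise
#' variance computed from that family's genetic variance. F2 genetic values
#' use the union of both panels' QTNs (shared QTNs counted once).
#'
#' @param panel_a,panel_b Panels sharing a marker universe.
#' @param families List of `f2_family` objects on the same markers.
#' @param scenario QTN-sharing scenario, see [select_qtns()].
#' @param architecture Architecture code, e.g. `"A20D4E0"`.
#' @param h2_panel Panel broad-sense heritability target (default 0.60).
#' @param h2_f2 F2 broad-sense heritability target (default 0.37).
#' @param seed Master integer seed.
#' @param signed_effects Passed to [select_qtns()].
#' @return A list with the `architecture` object, `trait_a`, `trait_b`
#'   (panel `simulated_trait`s) and `family_traits` (one per family).
#' @export
simulate_trait_suite <- function(panel_a, panel_b, families,
                                 scenario = "S.QTN",
                                 architecture = "A20D0E0",
                                 h2_panel = 0.60, h2_f2 = 0.37, seed = 1L,
                                 signed_effects = TRUE) {
  counts <- parse_architecture(architecture)
  marker_ids <- panel_a$genotypes$marker_ids
  if (!identical(marker_ids, panel_b$genotypes$marker_ids)) {
    abort("panels must share a marker universe.")
  }
  arch <- select_qtns(scenario, marker_ids, n_add = counts$n_add,
                      n_dom = counts$n_dom, n_epi = counts$n_epi,
                      seed = child_seed(seed, 0L),
                      signed_effects = signed_effects)
  trait_a <- add_noise_to_target_h2(
    genetic_value(panel_a$genotypes, arch$panel_a), h2_panel,
    seed = child_seed(seed, 1L))
  trait_b <- add_noise_to_target_h2(
    genetic_value(panel_b$genotypes, arch$panel_b), h2_panel,
    seed = child_seed(seed, 2L))
  uni <- qtn_union(arch)
  family_traits <- lapply(seq_along(families), function(f) {
    fam <- families[[f]]
    g <- genetic_value(fam$f2, uni)
    tryCatch(
      add_noise_to_target_h2(g, h2_f2, seed = child_seed(seed, 2L + f)),
      crosstrain_degenerate_trait = function(e) {
        abort(sprintf("no QTN segregates in family '%s': %s",
                      fam$family_id, conditionMessage(e)),
              class = "crosstrain_degenerate_trait")
      })
  })
  names(family_traits) <- vapply(families, function(f) f$family_id, "")
  list(architecture = arch, trait_a = trait_a, trait_b = trait_b,
       family_traits = family_traits)
}
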