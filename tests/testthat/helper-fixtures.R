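# Shared small fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

small_map <- function() {
  fixture("small_map", function() simulate_map(60, 4, 120, seed = 11))
}

small_panel <- function() {
  fixture("small_panel", function() {
    simulate_panel(60, small_map(), n_subpops = 3, fst = 0.25, seed = 12)
  })
}

small_pair <- function() {
  fixture("small_pair", function() {
    simulate_species_pair(40, 40, small_map(), n_subpops_each = 2,
                          fst_within = 0.2, divergence = 0.5, seed = 13)
  })
}

# A two-marker single-group map at a given distance, for meiosis oracles.
two_marker_map <- function(d_cM) {
  validate_map(data.frame(marker_id = c("A", "B"), linkage_group = c(1L, 1L),
                          position_cM = c(0, d_cM)))
}

# Weir/Cockerham-flavoured frequency-based Fst estimate across subpops,
# used as an independent oracle for the Balding-Nichols generator.
freq_fst <- function(panel) {
  dos <- panel$genotypes$values
  sub <- panel$subpop
  k <- max(sub)
  pbar <- colMeans(dos) / 2
  psub <- sapply(seq_len(k), function(s) colMeans(dos[sub == s, , drop = FALSE]) / 2)
  keep <- pbar > 0 & pbar < 1
  vb <- apply(psub[keep, , drop = FALSE], 1, var)
  # p-bar(1-p-bar) understates the ancestral p(1-p) by Var(p-bar) ~ vb/k
  mean(vb) / (mean(pbar[keep] * (1 - pbar[keep])) + mean(vb) / k)
}
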