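---
title: "Training-set composition for cross-population genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-set composition for cross-population genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstrain)
```

## The question the package addresses

A recurring design problem in plant breeding is whether diversity panels of
two related species can train a genomic selection (GS) model that predicts
breeding values in interspecific hybrid families derived from them. The
answer hinges on two things that are hard to disentangle on real data:
how much of the apparent predictive signal is really subpopulation
structure, and whether the causal loci segregating in the training panels
are the same ones segregating in the hybrid families. `crosstrain`
provides a fully seeded simulation-and-evaluation pipeline for studying
exactly this: it generates structured species panels and interspecific F2
families on a shared genetic map, simulates traits whose causal
architecture is controlled explicitly, and evaluates RR-BLUP prediction
accuracy under a battery of training-set configurations, including
CDmean-optimized subsets.

## Models and procedures

### Panel simulation

Panels are generated under the Balding–Nichols model: a per-marker
ancestral frequency `p ~ Uniform(0.05, 0.95)`, subpopulation frequencies
`Beta(p(1-Fst)/Fst, (1-p)(1-Fst)/Fst)`, and phased Bernoulli haplotypes.
For a species pair, one ancestral vector is drawn and each species' base
frequencies are derived from it by an extra Balding–Nichols step with a
`divergence` parameter before within-species structure is applied. This is
deliberately the simplest generative model with a tunable Fst that
reproduces the qualitative facts that matter downstream — recoverable
subpopulation clusters in a marker PCA, and depressed cross-species
kinship. It does not attempt realistic linkage disequilibrium, missing
data, or sequencing error (see *Limitations*).

Defaults were chosen once and are stated rather than fitted: three
subpopulations per panel at `Fst = 0.25`, species `divergence = 0.5`. The
source panels report ubiquitous structure but no Fst estimate, so these
are generic "strongly structured diversity panel" values, not claims about
any real germplasm; they are ordinary config knobs.

### Meiosis and F2 families

Gametes follow the Haldane (no crossover interference) model on a genetic
map: the source-haplotype indicator is a Markov walk whose switch
probability between adjacent markers at distance `d` cM is
`r = (1 - exp(-2d/100))/2`, with a fresh uniform choice at the start of
each linkage group. Simulating the inter-marker walk directly is exactly
equivalent in law to placing crossover points under no interference, and
is simpler to test: observed switch frequencies are compared against the
closed form by Monte Carlo in the test suite.

An F2 family takes one phased parent per species, makes `n_f1 = 50` F1 by
one gamete from each parent, and intermates the F1 into `n_f2 = 216` F2.
Two F1 parents are drawn uniformly per F2 individual with selfing
disallowed — the source material only says "intermated", and excluding
selfing matches the self-incompatibility of the perennial grasses that
motivated the design; it is a documented default, not a biological claim.
Founders simulated by the package carry true phase. Imported unphased
dosages are phased uniformly at random once (seeded): single-locus F2
genotype distributions are invariant to that choice, while multi-locus
founder linkage is acknowledged as approximate. No mutation or
segregation distortion is simulated.

### Trait architectures

Traits are controlled by a QTN-sharing scenario and an architecture code
`A#D#E#` (additive / dominance / epistatic QTN counts; defaults 20
additive, with `D4` or `E4` variants). The five scenarios are: identical
QTNs and effects in both panels (`S.QTN`), half shared (`P.QTN`),
completely different (`D.QTN`), and different with large effects
(Uniform(0.5, 0.99)) confined to one species and small effects
(Uniform(0, 0.25)) in the other (`D.QTN.Msi`, `D.QTN.Msa`); otherwise
effects are Uniform(0, 1). Two interpretation choices were genuinely open
and are resolved as documented defaults:

* "4 epistatic QTN" means four *loci* in two disjoint pairs, each pair
  contributing one additive-by-additive effect on the product of
  `{-1, 0, 1}` codes — this matches the locus-counting convention of the
  `A#D#E#` naming. A four-pair reading would double the loci.
* Uniform effect draws are magnitudes; each is assigned a random sign
  (seeded), since only magnitude ranges are specified. Set
  `signed_effects = FALSE` for strictly positive effects.

Dominance deviations act at the heterozygote only, consistent with the
`{-1, 0, 1}` additive enumeration of the prediction model. In F2
families the union of both panels' QTNs drives the genetic value, with
shared QTNs contributing once — a shared QTN is one biological locus, not
two.

Noise is calibrated per population: `sigma_e^2 = Var(g) (1 - H2) / H2`
with panel target `H2 = 0.60` and F2 target `H2 = 0.37`. The F2 target is
applied per family from that family's own genetic variance, because a
fixed family-level heritability is only achievable that way — families
differ in how many QTNs segregate. A family in which no QTN segregates
has zero genetic variance and raises an explicit degenerate-trait error
naming the family rather than silently producing noise.

### Prediction models

The GS model is RR-BLUP: `y = 1 b0 + X beta + e` with
`beta ~ N(0, I sigma_beta^2)` on `{-1, 0, 1}`-coded markers. Variance
components are estimated by REML in the kernel parameterization
(`K = XX'`), which is the numerically stable choice when markers far
outnumber individuals: the intercept is projected out, the projected
kernel is eigendecomposed once, and the restricted likelihood is
maximized over `log(lambda)` by a coarse grid on `[-10, 10]` followed by
local refinement at relative tolerance `1e-8`. Marker BLUPs are recovered
as `X'(XX' + lambda I)^{-1}(y - 1 b0)`, which the test suite verifies
against the dense ridge closed form and against a separately coded
Henderson mixed-model-equation GBLUP route. GEBVs are reported without
the intercept because accuracy is a Pearson correlation, which is
location-invariant. Monomorphic markers are retained with zero effect so
marker indices stay aligned across panels and families.

The structure-only benchmark regresses the trait on the top `q = 7`
principal components of the column-centered marker matrix. PCs are
computed once per panel from genotypes alone — phenotype leakage is
impossible because only training phenotypes enter the regression — which
mirrors a single scree analysis per panel; a per-fold recomputation would
change the loadings slightly but not the leakage properties.

The genomic relationship matrix is the centered cross-product normalized
to mean diagonal 1, with a `1e-6` ridge for invertibility. A
minimum-kinship rescaled estimator would also serve; the CD machinery only
requires a valid positive semi-definite relationship, and the estimator is
a configurable entry point.

### CDmean training-set optimization

The CD of a contrast `c` under the training mixed model is
`c'(A - lambda (Z'MZ + lambda A^{-1})^{-1}) c / (c'Ac)`; the criterion is
the mean CD over contrasts `e_i - 1/N` for each unphenotyped target
individual. `algo1_exchange()` maximizes it by one-for-one stochastic
exchange from a seeded random start, accepting a swap only on strict
improvement (ties rejected, so every accepted trace is strictly
increasing and runs are reproducible). Contrast targets are the
calibration individuals currently *unselected*, re-derived after each
accepted swap. Defaults are 200 selected individuals and 3,000 proposals.
Two inputs the criterion needs are not fully specified anywhere and are
therefore explicit policy: `lambda` is trait-specific, estimated as
`sigma_e^2/sigma_u^2` from a GBLUP REML fit on calibration phenotypes
when they exist, else 1 (heritability one-half); and the
`(Z'MZ + lambda A^{-1})` system is re-solved per proposal rather than
rank-one-updated — correctness first, and panels of a few hundred
individuals make the cubic solve tractable.

### Evaluation harnesses

Accuracy is always the Pearson correlation between trait values and
GEBVs, with zero-variance cases flagged `NA`, excluded and counted, never
imputed as 0. Within-panel experiments run ten replicates of five-fold
cross-validation, comparing whole-training-set RR-BLUP, a random subset,
a CDmean subset, and the PC-only model. Cross-population experiments
implement seven training configurations — random-200, CDmean-200 and
whole panel per species, plus the element-wise sum of the two whole-panel
GEBV vectors — and can push any configuration through a 1,000-resample
bootstrap of the target population. In simulation experiments accuracy is
measured against simulated *phenotypes* (the correlation with true
genetic values is emitted alongside as a diagnostic), and all mapped
markers including the QTNs are used for prediction, since the same marker
set served as both QTN pool and prediction set in the motivating design;
both choices are flagged and the QTN-exclusion variant is a one-line
filter away from the architecture manifest.

## Problem sizes and reproducibility

Every stochastic operation takes one integer seed, and one master seed
spawns per-stage child seeds through a small multiplicative hash
(`child_seed()`), so any figure-level experiment is regenerable from its
manifest. The package's own test suite runs the full study dimensions
where they are cheap — 356 markers on 19 linkage groups, 300-individual
panels, families of 50 F1 intermated to 216 F2, 100 noise replicates,
10^5 gametes for the recombination oracle — and scales down where the
cost is in optimization loops rather than in the science: qualitative
configuration-ordering checks use 300-member panels with 10 families, and
CDmean contract checks use subsets of 15 from panels of 60 with tens of
exchange proposals. Those sizes were chosen as the smallest at which the
orderings under study are stable across seeds, and they are stated here
as the package's own benchmark dimensions.

## What passing tests do and do not show

The generator reproduces the features the design questions depend on —
controllable differentiation, Mendelian F2 segregation on a real map
geometry, heritability-calibrated traits, and the qualitative accuracy
orderings: summed whole-panel GEBVs dominate single panels when causal
loci are shared, and the large-effect panel wins when they are not. It
does not reproduce linkage-disequilibrium decay, allele-frequency spectra
of real germplasm, genotyping error, or missingness; accuracies on real
panels are further depressed by sparse marker coverage of causal loci, so
absolute accuracy levels simulated here should not be read as forecasts
for any particular crop. On real data the summed-GEBV configuration has
been observed *not* to win for observed traits — a behavior driven by the
real panels' architectures that synthetic shared-QTN traits cannot, and
are not meant to, replicate.

## A worked example

```{r example, eval = FALSE}
library(crosstrain)

map  <- simulate_map(356, 19, 150, seed = 1)
pair <- simulate_species_pair(300, 300, map, seed = 2)
fams <- sample_parents_and_families(pair$a, pair$b, n_families = 10,
                                    seed = 3)

res <- simulation_experiment(
  pair$a, pair$b, fams,
  scenarios = c("S.QTN", "D.QTN.Msi"), architectures = "A20D0E0",
  configs = c("Msi.Whole", "Msa.Whole", "Whole.Msi.Msa"), seed = 4)

library(dplyr)
res |>
  group_by(scenario, configuration) |>
  summarise(mean_r = mean(r), .groups = "drop")

autoplot(res)
```

## Known limitations

* Founder haplotypes carry no linkage disequilibrium beyond what
  subpopulation structure induces, so F1 gametes recombine essentially
  unlinked founder alleles; map geometry matters for the meiosis model,
  not for the panels.
* Only diploid, biallelic genetics: no polyploid meiosis, no sex-specific
  maps, no crossover interference.
* The prediction model is additive RR-BLUP only — dominance and epistasis
  exist in the simulated traits but deliberately not in the predictor.
* CDmean here is the contrast-CD exchange heuristic; PEV-based and
  population-CD variants are out of scope.
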