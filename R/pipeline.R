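CONFIG_SCHEMA <- list(
  experiment = c("within_panel", "cross_panel", "simulation"),
  seed = NULL, output_dir = NULL,
  map = c("n_markers", "n_linkage_groups", "length_cM"),
  panels = c("n_a", "n_b", "n_subpops", "fst", "divergence"),
  families = c("n_families", "n_f1", "n_f2"),
  traits = c("scenarios", "architectures", "h2_panel", "h2_f2"),
  model = c("q_pcs", "subset_size", "cdmean_iters"),
  cv = c("k", "n_reps"),
  configs = NULL
)

default_config <- function() {
  list(
    experiment = "simulation", seed = 1L, output_dir = "crosstrain_run",
    map = list(n_markers = 356L, n_linkage_groups = 19L, length_cM = 150),
    panels = list(n_a = 530L, n_b = 598L, n_subpops = 3L, fst = 0.25,
                  divergence = 0.5),
    families = list(n_families = 50L, n_f1 = 50L, n_f2 = 216L),
    traits = list(scenarios = SCENARIOS,
                  architectures = c("A20D0E0", "A20D4E0", "A20D0E4"),
                  h2_panel = 0.60, h2_f2 = 0.37),
    model = list(q_pcs = 7L, subset_size = 200L, cdmean_iters = 3000L),
    cv = list(k = 5L, n_reps = 10L),
    configs = CROSS_CONFIGS
  )
}

#' Validate an experiment configuration
#'
#' Fills unset entries with full-scale defaults (the published study
#' dimensions: 530/598-member panels, 356 markers on 19 linkage groups,
#' 50 families of 216 F2 from 50 F1, five scenarios by three architectures,
#' 200-individual subsets with 3000 CDmean exchanges, 10 x 5-fold CV) and
#' rejects unknown keys with a descriptive error.
#'
#' @param config A named list, or a path to a YAML file.
#' @return The completed configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(sprintf("config file %s not found.",
                                            config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path.")
  unknown <- setdiff(names(config), names(CONFIG_SCHEMA))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  for (section in intersect(names(config), names(CONFIG_SCHEMA))) {
    allowed <- CONFIG_SCHEMA[[section]]
    if (!is.null(allowed) && is.list(config[[section]])) {
      bad <- setdiff(names(config[[section]]), allowed)
      if (length(bad)) {
        abort(sprintf("unknown key(s) in config section '%s': %s", section,
                      paste(bad, collapse = ", ")))
      }
    }
  }
  full <- default_config()
  for (nm in names(config)) {
    full[[nm]] <- if (is.list(full[[nm]]) && is.list(config[[nm]])) {
      modifyList(full[[nm]], config[[nm]])
    } else {
      config[[nm]]
    }
  }
  if (!full$experiment %in% CONFIG_SCHEMA$experiment) {
    abort(sprintf("unknown experiment kind '%s'.", full$experiment))
  }
  bad_cf <- setdiff(full$configs, CROSS_CONFIGS)
  if (length(bad_cf)) {
    abort(sprintf("unknown configuration label(s): %s",
                  paste(bad_cf, collapse = ", ")))
  }
  full
}

#' Run a configured experiment end to end
#'
#' Builds the synthetic inputs (map, species panels, F2 families), simulates
#' traits, runs the requested experiment, and writes a results CSV, a run
#' manifest (the completed config plus seeds and timing) and, for
#' simulation experiments, the family and architecture manifests. All
#' randomness derives from the single master seed via per-stage child
#' seeds, so the run is reproducible from the manifest alone.
#'
#' @param config Configuration list or YAML path; see [validate_config()].
#' @return The results tibble, invisibly, with attribute `"paths"` naming
#'   the written files.
#' @export
run_experiment <- function(config) {
  cfg <- validate_config(config)
  t0 <- Sys.time()
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  map <- simulate_map(cfg$map$n_markers, cfg$map$n_linkage_groups,
                      cfg$map$length_cM, seed = child_seed(seed, 101L))
  pair <- simulate_species_pair(
    cfg$panels$n_a, cfg$panels$n_b, map,
    n_subpops_each = cfg$panels$n_subpops, fst_within = cfg$panels$fst,
    divergence = cfg$panels$divergence, seed = child_seed(seed, 102L))

  results <- switch(cfg$experiment,
    within_panel = {
      suite <- simulate_trait_suite(
        pair$a, pair$b, families = list(),
        scenario = cfg$traits$scenarios[1],
        architecture = cfg$traits$architectures[1],
        h2_panel = cfg$traits$h2_panel, h2_f2 = cfg$traits$h2_f2,
        seed = child_seed(seed, 103L))
      plan <- make_cv_plan(nrow(pair$a$genotypes$values), k = cfg$cv$k,
                           n_reps = cfg$cv$n_reps,
                           seed = child_seed(seed, 104L))
      within_panel_experiment(
        pair$a, suite$trait_a, plan, subset_size = cfg$model$subset_size,
        cdmean_iters = cfg$model$cdmean_iters, q = cfg$model$q_pcs,
        seed = child_seed(seed, 105L))
    },
    cross_panel = {
      fams <- sample_parents_and_families(
        pair$a, pair$b, n_families = 1L, n_f1 = cfg$families$n_f1,
        n_f2 = cfg$families$n_f2, seed = child_seed(seed, 106L))
      suite <- simulate_trait_suite(
        pair$a, pair$b, fams, scenario = cfg$traits$scenarios[1],
        architecture = cfg$traits$architectures[1],
        h2_panel = cfg$traits$h2_panel, h2_f2 = cfg$traits$h2_f2,
        seed = child_seed(seed, 103L))
      res <- cross_panel_experiment(
        pair$a, pair$b, suite$trait_a, suite$trait_b, fams[[1]]$f2,
        suite$family_traits[[1]], configs = cfg$configs,
        subset_size = cfg$model$subset_size,
        cdmean_iters = cfg$model$cdmean_iters,
        seed = child_seed(seed, 105L))
      res$gebv <- NULL
      res
    },
    simulation = {
      fams <- sample_parents_and_families(
        pair$a, pair$b, n_families = cfg$families$n_families,
        n_f1 = cfg$families$n_f1, n_f2 = cfg$families$n_f2,
        seed = child_seed(seed, 106L))
      write_families(fams, file.path(cfg$output_dir, "families"))
      simulation_experiment(
        pair$a, pair$b, fams, scenarios = cfg$traits$scenarios,
        architectures = cfg$traits$architectures, configs = cfg$configs,
        h2_panel = cfg$traits$h2_panel, h2_f2 = cfg$traits$h2_f2,
        subset_size = cfg$model$subset_size,
        cdmean_iters = cfg$model$cdmean_iters,
        seed = child_seed(seed, 105L))
    })

  results_path <- file.path(cfg$output_dir, "results.csv")
  readr::write_csv(results, results_path)
  manifest <- list(config = cfg,
                   package_version = as.character(
                     utils::packageVersion("crosstrain")),
                   elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                                   units = "secs")))
  manifest_path <- file.path(cfg$output_dir, "manifest.yml")
  yaml::write_yaml(manifest, manifest_path)
  attr(results, "paths") <- c(results = results_path,
                              manifest = manifest_path)
  invisible(results)
}
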