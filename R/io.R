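#' Read and write genetic maps
#'
#' Tab-delimited, three columns (`marker_id`, `linkage_group`,
#' `position_cM`), header line required. Maps are validated on read:
#' positions must be strictly increasing within each linkage group.
#'
#' @param path File path.
#' @return `read_map()` returns a validated `genetic_map` tibble.
#' @export
read_map <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          marker_id = readr::col_character(),
                          linkage_group = readr::col_integer(),
                          position_cM = readr::col_double()))
  stop_on_parse_problems(df, path)
  validate_map(df)
}

#' @param map A `genetic_map`.
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  readr::write_tsv(validate_map(map), path)
  invisible(path)
}

stop_on_parse_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr) > 0) {
    abort(sprintf("malformed row(s) in %s: first at line %d (%s).",
                  path, pr$row[1] + 1L, pr$expected[1]))
  }
  invisible(df)
}

#' Read and write genotype matrices
#'
#' Tab-delimited: a first metadata line `# coding=<coding>` recording the
#' dosage convention, then a header, then one row per individual with the
#' individual id in the first column and marker dosages after it.
#' Round-trips to full precision.
#'
#' @param path File path.
#' @return `read_genotypes()` returns a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*coding=(\\S+)", first))[[1]]
  if (length(m) != 2L) {
    abort(sprintf("%s: missing '# coding=...' metadata line.", path))
  }
  df <- readr::read_tsv(path, skip = 1L, show_col_types = FALSE)
  stop_on_parse_problems(df, path)
  if (names(df)[1] != "individual_id") {
    abort(sprintf("%s: first column must be 'individual_id'.", path))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) abort(sprintf("%s: non-numeric dosage value.", path))
  rownames(vals) <- df$individual_id
  genotype_matrix(vals, coding = m[2])
}

#' @param genotypes A [genotype_matrix()].
#' @rdname read_genotypes
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  writeLines(sprintf("# coding=%s", genotypes$coding), path)
  df <- tibble::as_tibble(genotypes$values, .name_repair = "minimal")
  df <- dplyr::bind_cols(
    tibble::tibble(individual_id = genotypes$individual_ids), df)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write phenotype tables
#'
#' Tab-delimited with columns `individual_id`, `value`, `population`.
#'
#' @param path File path.
#' @return `read_phenotypes()` returns a tibble.
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          individual_id = readr::col_character(),
                          value = readr::col_double(),
                          population = readr::col_character()))
  stop_on_parse_problems(df, path)
  df
}

#' @param phenotypes Tibble with `individual_id`, `value`, `population`.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  need <- c("individual_id", "value", "population")
  if (!all(need %in% names(phenotypes))) {
    abort(sprintf("phenotype table needs columns %s.",
                  paste(need, collapse = ", ")))
  }
  readr::write_tsv(phenotypes[, need], path)
  invisible(path)
}

#' Import dosages from a VCF file
#'
#' Diploid biallelic records only; GT fields are mapped to 0/1/2 alternate
#' allele counts. Records with missing genotypes, more than one ALT allele,
#' or non-diploid calls are rejected.
#'
#' @param path Path to an (uncompressed or gzipped) VCF.
#' @return A `discrete_012` [genotype_matrix()] (individuals x markers).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF import requires the 'vcfR' package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) abort("only biallelic VCF records are supported.")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    if (is.na(g)) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) != 2L || any(al == ".")) return(NA_real_)
    sum(al == "1")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  if (anyNA(dos)) abort("missing or non-diploid genotypes in VCF.")
  genotype_matrix(t(dos), coding = "discrete_012",
                  individual_ids = colnames(gt), marker_ids = rownames(gt))
}

#' Export an F2 family set
#'
#' Writes each family's F2 genotypes as a genotype TSV plus one manifest
#' TSV (`family_id`, `parent_a`, `parent_b`, `seed`, `file`).
#'
#' @param families List of `f2_family` objects.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_families <- function(families, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::map_dfr(families, function(fam) {
    file <- file.path(dir, paste0(fam$family_id, "_genotypes.tsv"))
    write_genotypes(fam$f2, file)
    tibble::tibble(family_id = fam$family_id, parent_a = fam$parent_a_id,
                   parent_b = fam$parent_b_id, seed = fam$seed,
                   file = basename(file))
  })
  readr::write_tsv(manifest, file.path(dir, "families_manifest.tsv"))
  invisible(manifest)
}

#' Export a trait architecture manifest
#'
#' Long-format TSV: `scenario`, `architecture`, `panel`, `marker_id`,
#' `effect_type` (A/D/E), `partner_marker_id` (epistasis only), `effect`,
#' `seed`.
#'
#' @param arch A [select_qtns()] architecture.
#' @param path Output TSV path.
#' @return The manifest tibble, invisibly.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "trait_architecture"))
  one_panel <- function(set, panel) {
    dplyr::bind_rows(
      tibble::tibble(panel = panel, marker_id = set$add$marker_id,
                     effect_type = "A", partner_marker_id = NA_character_,
                     effect = set$add$effect),
      tibble::tibble(panel = panel, marker_id = set$dom$marker_id,
                     effect_type = "D", partner_marker_id = NA_character_,
                     effect = set$dom$effect),
      tibble::tibble(panel = panel, marker_id = set$epi$marker_id_1,
                     effect_type = "E",
                     partner_marker_id = set$epi$marker_id_2,
                     effect = set$epi$effect)
    )
  }
  out <- dplyr::bind_rows(one_panel(arch$panel_a, "A"),
                          one_panel(arch$panel_b, "B"))
  out <- dplyr::mutate(out, scenario = arch$scenario,
                       architecture = arch$architecture, seed = arch$seed,
                       .before = 1)
  readr::write_tsv(out, path)
  invisible(out)
}
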