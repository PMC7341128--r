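#' Genotype dosage matrix
#'
#' Light container for an individuals-by-markers dosage matrix together with
#' its coding convention. Two codings are supported: `discrete_012` (exact
#' diploid allele counts 0/1/2) and `dosage_01` (posterior-mean dosages on
#' `[0, 1]`, as produced by probabilistic genotype callers for reduced-
#' representation sequencing data).
#'
#' @param values Numeric matrix, individuals in rows, markers in columns.
#' @param coding `"discrete_012"` or `"dosage_01"`.
#' @param individual_ids,marker_ids Character vectors naming rows/columns;
#'   default to the dimnames of `values`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values,
                            coding = c("discrete_012", "dosage_01"),
                            individual_ids = rownames(values),
                            marker_ids = colnames(values)) {
  coding <- match.arg(coding)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(individual_ids)) {
    individual_ids <- sprintf("ind_%03d", seq_len(nrow(values)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- sprintf("M%04d", seq_len(ncol(values)))
  }
  if (length(individual_ids) != nrow(values)) {
    abort("`individual_ids` length must equal nrow(values).")
  }
  if (length(marker_ids) != ncol(values)) {
    abort("`marker_ids` length must equal ncol(values).")
  }
  if (anyNA(values)) abort("genotype matrix must not contain missing values.")
  if (coding == "discrete_012" && !all(values %in% c(0, 1, 2))) {
    abort("discrete_012 genotype values must all be in {0, 1, 2}.")
  }
  if (coding == "dosage_01" && (min(values) < 0 || max(values) > 1)) {
    abort("dosage_01 genotype values must lie in [0, 1].")
  }
  dimnames(values) <- list(individual_ids, marker_ids)
  structure(
    list(values = values, coding = coding,
         individual_ids = as.character(individual_ids),
         marker_ids = as.character(marker_ids)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d markers (%s)\n",
              nrow(x$values), ncol(x$values), x$coding))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Subset a genotype matrix by individuals
#'
#' @param x A [genotype_matrix()].
#' @param i Integer or character index of individuals to keep.
#' @return A `genotype_matrix` with the selected rows.
#' @export
subset_individuals <- function(x, i) {
  stopifnot(inherits(x, "genotype_matrix"))
  v <- x$values[i, , drop = FALSE]
  genotype_matrix(v, coding = x$coding, individual_ids = rownames(v),
                  marker_ids = x$marker_ids)
}

as_geno_values <- function(x) {
  if (inherits(x, "genotype_matrix")) x$values else x
}
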