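#' Per-variant call rate
#'
#' Fraction of individuals with a non-missing genotype at a variant.
#'
#' @param genotypes integer genotype matrix (rows = individuals).
#' @param variant variant key (column name).
#' @return fraction in \[0, 1\].
#' @export
variant_call_rate <- function(genotypes, variant) {
  if (!variant %in% colnames(genotypes)) stop("variant not in matrix: ", variant)
  mean(!is.na(genotypes[, variant]))
}

#' Remove samples missing at every panel variant
#'
#' Individuals with no genotype call at any variant of the panel are
#' dropped; individuals missing at some but not all variants are retained
#' (their per-variant sample sizes simply differ).
#'
#' @param genotypes integer genotype matrix (rows = individuals).
#' @param cohort optional cohort label per individual (named by individual
#'   id or aligned with the matrix rows); used to break down the removal
#'   counts.
#' @return list with `genotypes` (filtered matrix) and `removed` (named
#'   integer vector of removal counts per cohort, or a single total).
#' @export
drop_fully_missing_samples <- function(genotypes, cohort = NULL) {
  if (is.null(dim(genotypes)) || ncol(genotypes) < 1L) {
    stop("genotype matrix must cover at least one panel variant")
  }
  all_missing <- rowSums(!is.na(genotypes)) == 0L
  if (is.null(cohort)) {
    removed <- c(all = sum(all_missing))
  } else {
    if (!is.null(names(cohort))) cohort <- cohort[rownames(genotypes)]
    removed <- table(factor(cohort)[all_missing])
    removed <- setNames(as.integer(removed), names(removed))
  }
  list(genotypes = genotypes[!all_missing, , drop = FALSE], removed = removed)
}
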