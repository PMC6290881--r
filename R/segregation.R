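#' Tabulate co-segregation of a variant with affection status
#'
#' Counts genotyped family members by (phenotype, carrier) cell, where a
#' carrier holds at least one copy of the alternate allele (heterozygous
#' or homozygous alternate — segregation describes whatever is observed,
#' even though the discovery filter demands heterozygotes).  Members with
#' a missing genotype are `untyped`; members with unknown phenotype are
#' excluded from the four cells and reported separately.  Affected
#' non-carriers that married into the family are counted inside
#' `affected_noncarriers` and also broken out as
#' `married_in_affected_noncarriers`; they are phenocopies that carry no
#' weight in the segregation argument, so `complete_segregation` (all
#' affected members are carriers and all unaffected members non-carriers)
#' is evaluated over blood-line members only.
#'
#' @param pedigree a [pedigree()].
#' @param genotypes genotype matrix; members absent from its rows count as
#'   untyped.
#' @param variant variant key (must be a matrix column).
#' @return one-row data frame: `variant`, `family_id`, the four
#'   phenotype-by-carrier counts, `untyped`, `unknown_phenotype`,
#'   `married_in_affected_noncarriers`, `carrier_penetrance` (affected
#'   carriers over all carriers; `NA` when there are no carriers) and
#'   `complete_segregation`.
#' @export
tabulate_segregation <- function(pedigree, genotypes, variant) {
  if (!variant %in% colnames(genotypes)) {
    stop("variant not in genotype matrix: ", variant)
  }
  g <- genotypes[match(pedigree$individual_id, rownames(genotypes)), variant]
  typed <- !is.na(g)
  carrier <- typed & g >= 1L
  ph <- pedigree$phenotype
  known <- ph != "unknown"
  aff <- ph == "affected"
  una <- ph == "unaffected"
  blood <- !pedigree$married_in

  affected_carriers <- sum(typed & aff & carrier)
  affected_noncarriers <- sum(typed & aff & !carrier)
  unaffected_carriers <- sum(typed & una & carrier)
  unaffected_noncarriers <- sum(typed & una & !carrier)
  carriers_total <- affected_carriers + unaffected_carriers
  bt <- typed & known & blood
  data.frame(
    variant = variant,
    family_id = pedigree$family_id[1],
    affected_carriers = affected_carriers,
    affected_noncarriers = affected_noncarriers,
    unaffected_carriers = unaffected_carriers,
    unaffected_noncarriers = unaffected_noncarriers,
    untyped = sum(!typed & known),
    unknown_phenotype = sum(!known),
    married_in_affected_noncarriers = sum(typed & aff & !carrier & !blood),
    carrier_penetrance = if (carriers_total > 0) affected_carriers / carriers_total else NA_real_,
    complete_segregation = all(carrier[bt & aff]) && all(!carrier[bt & una]),
    stringsAsFactors = FALSE
  )
}

#' Penetrance and phenocopy report across families
#'
#' Summarises a collection of segregation tables: per family and variant,
#' the carrier penetrance, the phenocopy count split into blood relatives
#' and married-in individuals, and a flag for incomplete penetrance
#' (unaffected carriers observed).
#'
#' @param summaries data frame of rows from [tabulate_segregation()]
#'   (rbind of one or more).
#' @return data frame with columns `family_id`, `variant`,
#'   `carrier_penetrance`, `phenocopies_blood`, `phenocopies_married_in`,
#'   `incomplete_penetrance`.
#' @export
penetrance_report <- function(summaries) {
  if (is.null(summaries) || !nrow(summaries)) {
    return(data.frame(family_id = character(0), variant = character(0),
                      carrier_penetrance = numeric(0),
                      phenocopies_blood = integer(0),
                      phenocopies_married_in = integer(0),
                      incomplete_penetrance = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    family_id = summaries$family_id,
    variant = summaries$variant,
    carrier_penetrance = summaries$carrier_penetrance,
    phenocopies_blood = summaries$affected_noncarriers -
      summaries$married_in_affected_noncarriers,
    phenocopies_married_in = summaries$married_in_affected_noncarriers,
    incomplete_penetrance = summaries$unaffected_carriers > 0,
    stringsAsFactors = FALSE
  )
}
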