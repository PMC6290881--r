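#' Configuration of the variant filter cascade
#'
#' @param max_frequency variants with an allele frequency at or above this
#'   value in a screened source are removed (strict `<` threshold;
#'   default 1%).
#' @param frequency_sources population frequency sources screened against
#'   (columns of the annotation table).
#' @param qualifying_consequences consequence classes kept by the
#'   protein-altering filter.
#' @param min_families minimum number of distinct families that must
#'   contribute a surviving variant for a gene to be reported.
#' @param require_all_sequenced_affected kept for completeness; the
#'   sharing filter always demands the variant in every sequenced affected
#'   member.
#' @param frequency_rule `"all"`: a variant must be absent-or-rare in every
#'   screened source (conservative AND); `"any"`: one passing source
#'   suffices.
#' @param allow_hom_alt also accept homozygous-alternate calls in the
#'   sharing filter (default off: the dominant-model filter is strictly
#'   heterozygous).
#' @return a `filter_config` list.
#' @export
filter_config <- function(max_frequency = 0.01,
                          frequency_sources = c("exac", "inhouse"),
                          qualifying_consequences = c("missense", "nonsense",
                                                      "frameshift", "splice_canonical"),
                          min_families = 2L,
                          require_all_sequenced_affected = TRUE,
                          frequency_rule = c("all", "any"),
                          allow_hom_alt = FALSE) {
  frequency_rule <- match.arg(frequency_rule)
  stopifnot(max_frequency >= 0, max_frequency <= 1, min_families >= 1,
            length(frequency_sources) >= 1)
  bad <- setdiff(qualifying_consequences, consequence_levels)
  if (length(bad)) stop("unknown consequence class(es): ", paste(bad, collapse = ", "))
  structure(list(
    max_frequency = max_frequency,
    frequency_sources = frequency_sources,
    qualifying_consequences = qualifying_consequences,
    min_families = as.integer(min_families),
    require_all_sequenced_affected = isTRUE(require_all_sequenced_affected),
    frequency_rule = frequency_rule,
    allow_hom_alt = isTRUE(allow_hom_alt)
  ), class = "filter_config")
}

#' Variants heterozygous in every sequenced affected family member
#'
#' The dominant-model sharing filter: a variant survives only when every
#' whole-exome-sequenced affected member of the family is heterozygous for
#' it.  Homozygous-reference, homozygous-alternate (unless
#' `allow_hom_alt`) and missing calls all exclude the variant (strict
#' sharing; leniency is expressed through the sequenced flag, not through
#' missingness).  Genotyped affected relatives that were not sequenced do
#' not constrain this filter.
#'
#' @param pedigree a [pedigree()].
#' @param genotypes genotype matrix covering the sequenced affected
#'   members.
#' @param config a [filter_config()].
#' @return character vector of surviving variant keys.
#' @export
shared_het_in_affecteds <- function(pedigree, genotypes, config = filter_config()) {
  ids <- sequenced_affected_ids(pedigree)
  if (!length(ids)) {
    stop("family ", pedigree$family_id[1],
         ": no sequenced affected member; the family cannot be analysed")
  }
  absent <- setdiff(ids, rownames(genotypes))
  if (length(absent)) {
    stop("family ", pedigree$family_id[1], ": sequenced affected member(s) ",
         paste(absent, collapse = ", "), " missing from the genotype matrix")
  }
  sub <- genotypes[ids, , drop = FALSE]
  ok <- if (config$allow_hom_alt) sub == 1L | sub == 2L else sub == 1L
  ok[is.na(ok)] <- FALSE
  colnames(sub)[colSums(ok) == length(ids)]
}

#' Keep protein-altering variants
#'
#' Retains variants whose annotated consequence is in
#' `config$qualifying_consequences` (by default missense, nonsense,
#' frameshift and canonical splice-site changes).
#'
#' @param variants character vector of variant keys.
#' @param annotations an [annotation_table()] covering every variant.
#' @param config a [filter_config()].
#' @return the qualifying subset of `variants`.
#' @export
filter_protein_altering <- function(variants, annotations, config = filter_config()) {
  if (!length(variants)) return(character(0))
  ann <- ann_lookup(annotations, variants)
  variants[ann$consequence %in% config$qualifying_consequences]
}

#' Keep rare variants
#'
#' A variant passes when, in every screened frequency source (or any one
#' source under `frequency_rule = "any"`), it is either absent or has an
#' allele frequency strictly below `max_frequency`.  Variants absent from
#' all sources are additionally flagged as novel (attribute `"novel"` on
#' the returned vector).
#'
#' @inheritParams filter_protein_altering
#' @return surviving subset of `variants`, with attribute `novel`.
#' @export
filter_rare <- function(variants, annotations, config = filter_config()) {
  if (!length(variants)) return(structure(character(0), novel = character(0)))
  ann <- ann_lookup(annotations, variants)
  freq <- as.matrix(ann[, config$frequency_sources, drop = FALSE])
  pass_cell <- is.na(freq) | freq < config$max_frequency
  pass <- if (config$frequency_rule == "all") {
    rowSums(pass_cell) == ncol(freq)
  } else {
    rowSums(pass_cell) > 0
  }
  novel <- rowSums(!is.na(freq)) == 0L
  structure(variants[pass], novel = variants[pass & novel])
}

#' Genes recurrently hit across families
#'
#' Groups each family's surviving variants by gene (gene identity comes
#' solely from the annotation table) and keeps genes supported by at least
#' `min_families` distinct families; the supporting variants may be
#' identical or different between families.
#'
#' @param per_family list of per-family candidate sets as produced by
#'   [run_cascade()] (each a list with `family_id` and `stages`, whose
#'   final stage is `rare`).
#' @param annotations an [annotation_table()].
#' @param config a [filter_config()].
#' @return data frame with one row per (gene, family, variant) for the
#'   recurrent genes, plus a `genes` attribute summarising gene-level
#'   support (`gene`, `n_families`).
#' @export
genes_recurrent_across_families <- function(per_family, annotations,
                                            config = filter_config()) {
  rows <- lapply(per_family, function(f) {
    v <- f$stages$rare
    if (!length(v)) return(NULL)
    data.frame(gene = ann_lookup(annotations, v)$gene,
               family_id = f$family_id, variant = v,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) {
    empty <- data.frame(gene = character(0), family_id = character(0),
                        variant = character(0), stringsAsFactors = FALSE)
    return(structure(empty,
                     genes = data.frame(gene = character(0), n_families = integer(0))))
  }
  support <- tapply(tab$family_id, tab$gene, function(f) length(unique(f)))
  keep <- names(support)[support >= config$min_families]
  hits <- tab[tab$gene %in% keep, , drop = FALSE]
  hits <- hits[order(hits$gene, hits$family_id, hits$variant), , drop = FALSE]
  rownames(hits) <- NULL
  genes <- data.frame(gene = keep,
                      n_families = as.integer(support[keep]),
                      stringsAsFactors = FALSE)
  genes <- genes[order(-genes$n_families, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  structure(hits, genes = genes)
}

#' Run the full variant filter cascade
#'
#' Applies, per family, the shared-heterozygote filter, the
#' protein-altering consequence filter and the rare-frequency filter (in
#' that order; the two annotation-based filters are pointwise predicates,
#' so the final per-family set is order-independent), then the
#' cross-family gene recurrence step.
#'
#' @param families list of families, each a list with elements `pedigree`
#'   (a [pedigree()]) and `genotypes` (genotype matrix for that family's
#'   members).
#' @param annotations an [annotation_table()] covering all variants.
#' @param config a [filter_config()].
#' @return a `cascade_result`: list with `per_family` (stage-wise variant
#'   sets per family), `gene_hits` (data frame gene/family/variant),
#'   `genes` (gene-level support), `stage_counts` (distinct
#'   family-by-variant pairs surviving each stage, pooled over families),
#'   `gene_count` and `novel_count` (final-stage variants absent from all
#'   frequency sources).
#' @export
run_cascade <- function(families, annotations, config = filter_config()) {
  per_family <- lapply(families, function(f) {
    s1 <- shared_het_in_affecteds(f$pedigree, f$genotypes, config)
    s2 <- filter_protein_altering(s1, annotations, config)
    s3 <- filter_rare(s2, annotations, config)
    list(family_id = f$pedigree$family_id[1],
         stages = list(shared_het = s1, protein_altering = s2,
                       rare = as.character(s3)),
         novel = attr(s3, "novel"))
  })
  names(per_family) <- vapply(per_family, `[[`, "", "family_id")
  stage_counts <- vapply(c("shared_het", "protein_altering", "rare"), function(s) {
    sum(vapply(per_family, function(f) length(f$stages[[s]]), integer(1)))
  }, integer(1))
  gene_hits <- genes_recurrent_across_families(per_family, annotations, config)
  genes <- attr(gene_hits, "genes")
  novel <- unique(unlist(lapply(per_family, `[[`, "novel"), use.names = FALSE))
  structure(list(
    per_family = per_family,
    gene_hits = gene_hits,
    genes = genes,
    stage_counts = stage_counts,
    gene_count = nrow(genes),
    novel_count = length(novel),
    config = config
  ), class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Variant filter cascade over", length(x$per_family), "families\n")
  cat("  stage counts (family x variant pairs):\n")
  for (s in names(x$stage_counts)) cat("    ", s, ": ", x$stage_counts[[s]], "\n", sep = "")
  cat("  novel final-stage variants:", x$novel_count, "\n")
  cat("  recurrent genes (>= ", x$config$min_families, " families): ",
      x$gene_count, "\n", sep = "")
  if (nrow(x$genes)) print.data.frame(x$genes)
  invisible(x)
}
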