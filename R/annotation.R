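#' Consequence vocabulary
#'
#' Closed set of consequence classes used throughout the cascade.
#' @export
consequence_levels <- c("missense", "nonsense", "frameshift",
                        "splice_canonical", "synonymous", "other")

#' Default synonym map from common annotation-tool labels to the vocabulary
#' @export
default_consequence_synonyms <- c(
  missense_variant        = "missense",
  nonsynonymous_snv       = "missense",
  stop_gained             = "nonsense",
  stopgain                = "nonsense",
  frameshift_variant      = "frameshift",
  frameshift_insertion    = "frameshift",
  frameshift_deletion     = "frameshift",
  splice_acceptor_variant = "splice_canonical",
  splice_donor_variant    = "splice_canonical",
  splicing                = "splice_canonical",
  synonymous_variant      = "synonymous"
)

#' Build an annotation table
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence` (from [consequence_levels]) and one numeric allele
#'   frequency column per entry of `source_names` (`NA` = not observed in
#'   that source).  Extra columns (rsID, protein change, pathogenicity
#'   scores) are carried through untouched.
#' @param source_names names of the population frequency columns.
#' @return an `annotation_table`: the data frame keyed by a `key` column,
#'   with the frequency source names stored as an attribute.
#' @export
annotation_table <- function(df, source_names) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  mandatory <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(c(mandatory, source_names), names(df))
  if (length(miss)) stop("annotation table is missing column(s): ", paste(miss, collapse = ", "))
  bad <- !df$consequence %in% consequence_levels
  if (any(bad)) stop("unknown consequence value: ", df$consequence[which(bad)[1]])
  for (s in source_names) {
    f <- suppressWarnings(as.numeric(df[[s]]))
    if (any(!is.na(df[[s]]) & df[[s]] != "" & is.na(f))) {
      stop("non-numeric frequency in source '", s, "'")
    }
    if (any(!is.na(f) & (f < 0 | f > 1))) {
      stop("allele frequency outside [0, 1] in source '", s, "': ",
           f[which(!is.na(f) & (f < 0 | f > 1))[1]])
    }
    df[[s]] <- f
  }
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(df$key)) stop("duplicate variant in annotation table: ",
                                  df$key[anyDuplicated(df$key)])
  df <- df[, c("key", setdiff(names(df), "key"))]
  rownames(df) <- df$key
  structure(df, sources = source_names, class = c("annotation_table", "data.frame"))
}

#' Read a variant annotation table
#'
#' Tab-separated file with a header and mandatory columns `chrom`, `pos`,
#' `ref`, `alt`, `gene`, `consequence`, plus one allele-frequency column
#' per requested source (empty cell = variant not observed in that
#' source).  Consequence strings outside the vocabulary are mapped through
#' `synonyms`; anything still unknown becomes `"other"` with a warning.
#'
#' @param path TSV path (optionally gzipped).
#' @param source_names frequency column names to ingest.
#' @param synonyms named character vector mapping foreign consequence
#'   labels to [consequence_levels].
#' @return an [annotation_table()].
#' @export
read_annotation_table <- function(path, source_names,
                                  synonyms = default_consequence_synonyms) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  # read everything as character first: allele columns like "T" must not
  # collapse to logicals
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  for (nm in setdiff(names(df), c("chrom", "ref", "alt", "gene", "consequence"))) {
    df[[nm]] <- utils::type.convert(df[[nm]], as.is = TRUE)
  }
  mandatory <- c("chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(c(mandatory, source_names), names(df))
  if (length(miss)) stop("annotation table ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  cons <- tolower(trimws(df$consequence))
  mapped <- ifelse(cons %in% consequence_levels, cons, unname(synonyms[cons]))
  unknown <- is.na(mapped)
  if (any(unknown)) {
    warning("unknown consequence value(s) mapped to 'other': ",
            paste(unique(cons[unknown]), collapse = ", "))
    mapped[unknown] <- "other"
  }
  df$consequence <- mapped
  annotation_table(df, source_names)
}

# Rows of `ann` for the given keys; errors on unannotated keys.
ann_lookup <- function(ann, keys, context = "variant") {
  idx <- match(keys, ann$key)
  if (anyNA(idx)) {
    stop("unannotated ", context, "(s): ", paste(keys[is.na(idx)], collapse = ", "))
  }
  ann[idx, , drop = FALSE]
}
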