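#' Build normalised variant keys
#'
#' A variant key is the string `"chrom:pos:ref:alt"` with 1-based VCF
#' coordinates.  Alleles are uppercased and reduced to their minimal
#' representation: shared trailing bases are trimmed, then shared leading
#' bases (advancing `pos`), never below one base per allele.
#'
#' @param chrom chromosome names.
#' @param pos 1-based positions (>= 1).
#' @param ref,alt allele strings (non-empty, `ref != alt`).
#' @return character vector of keys, one per input variant.
#' @seealso [parse_variant_key()]
#' @export
#' @examples
#' variant_key("19", 55441902, "C", "T")
#' variant_key("1", 100, "CAT", "CGT")  # trimmed to 101:A:G
variant_key <- function(chrom, pos, ref, alt) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  vapply(seq_len(n), function(i) {
    v <- normalize_variant(chrom[i], pos[i], ref[i], alt[i])
    paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  }, character(1))
}

normalize_variant <- function(chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  pos <- as.integer(pos)
  if (is.na(pos) || pos < 1L) stop("variant position must be a 1-based integer >= 1")
  if (!nzchar(ref) || !nzchar(alt)) stop("ref and alt alleles must be non-empty")
  if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) {
    stop("alleles may only contain A, C, G, T or N: ", ref, "/", alt)
  }
  # trim shared trailing bases, then shared leading bases (minimal representation)
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  if (ref == alt) stop("ref and alt alleles are identical after normalisation")
  list(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt)
}

#' Split variant keys back into their components
#'
#' @param key character vector of `"chrom:pos:ref:alt"` keys.
#' @return data frame with columns `key`, `chrom`, `pos`, `ref`, `alt`.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  if (any(lengths(parts) != 4L)) {
    stop("malformed variant key: ", key[which(lengths(parts) != 4L)[1]])
  }
  data.frame(
    key   = key,
    chrom = vapply(parts, `[[`, "", 1L),
    pos   = as.integer(vapply(parts, `[[`, "", 2L)),
    ref   = vapply(parts, `[[`, "", 3L),
    alt   = vapply(parts, `[[`, "", 4L),
    stringsAsFactors = FALSE
  )
}
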