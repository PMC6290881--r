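#' Read a genotype matrix from a VCF file
#'
#' Parses the GT field of a VCF 4.x file (via \pkg{vcfR}) into an
#' individuals-by-variants integer matrix coded 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing.  Phased
#' separators are treated as unphased.  Multiallelic records are split into
#' one variant key per alternate allele, with genotypes recoded against
#' that allele: a genotype carrying the target allele plus any other allele
#' counts as heterozygous for the target, two copies as homozygous
#' alternate, none as homozygous reference.  A genotype with any missing
#' allele is `NA` for every split allele.
#'
#' @param path VCF file (plain or gzipped).
#' @param sample_subset optional sample ids to keep (error if absent from
#'   the header).
#' @return list with `variants` (data frame: `key`, `chrom`, `pos`, `ref`,
#'   `alt`) and `genotypes` (integer matrix, rows = samples, columns =
#'   variant keys).
#' @export
read_vcf_genotypes <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample columns: ", path)
  fmt <- vcf@gt[, "FORMAT"]
  if (any(!grepl("(^|:)GT(:|$)", fmt))) {
    stop("VCF record without GT in FORMAT (record ",
         which(!grepl("(^|:)GT(:|$)", fmt))[1], ")")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, colnames(vcf@gt)[-1]))
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing)) {
      stop("requested sample(s) not in VCF header: ", paste(missing, collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }

  keys <- character(0)
  meta <- list()
  cols <- list()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    raw <- gt[r, ]
    tokens <- strsplit(gsub("|", "/", raw, fixed = TRUE), "/", fixed = TRUE)
    for (k in seq_along(alts)) {
      v <- normalize_variant(fix[r, "CHROM"], as.integer(fix[r, "POS"]), fix[r, "REF"], alts[k])
      key <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
      code <- vapply(seq_along(tokens), function(s) {
        tk <- tokens[[s]]
        if (length(tk) == 1L && is.na(tk)) return(NA_integer_)
        if (any(tk == "." | is.na(tk))) return(NA_integer_)
        if (!all(grepl("^[0-9]+$", tk))) {
          stop("unparseable genotype '", raw[s], "' for sample ", samples[s],
               " at ", fix[r, "CHROM"], ":", fix[r, "POS"])
        }
        if (length(tk) != 2L) {
          stop("non-diploid genotype '", raw[s], "' for sample ", samples[s],
               " at ", fix[r, "CHROM"], ":", fix[r, "POS"])
        }
        hits <- sum(tk == as.character(k))
        if (hits == 2L) 2L else if (hits == 1L) 1L else 0L
      }, integer(1))
      keys <- c(keys, key)
      meta[[length(meta) + 1L]] <- data.frame(
        key = key, chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
        stringsAsFactors = FALSE
      )
      cols[[length(cols) + 1L]] <- code
    }
  }
  mat <- do.call(cbind, cols)
  dimnames(mat) <- list(samples, keys)
  list(variants = do.call(rbind, meta), genotypes = mat)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT as the only FORMAT field, one record per
#' matrix column (variant keys carry the coordinates and alleles).
#'
#' @param genotypes integer matrix as produced by [read_vcf_genotypes()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- parse_variant_key(colnames(genotypes))
  gt_str <- function(code) {
    out <- rep("./.", length(code))
    out[!is.na(code) & code == 0L] <- "0/0"
    out[!is.na(code) & code == 1L] <- "0/1"
    out[!is.na(code) & code == 2L] <- "1/1"
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            rownames(genotypes)), collapse = "\t")
  ), con)
  ord <- order(v$chrom, v$pos)
  for (j in ord) {
    writeLines(paste(c(v$chrom[j], v$pos[j], ".", v$ref[j], v$alt[j], ".", ".", ".", "GT",
                       gt_str(genotypes[, j])), collapse = "\t"), con)
  }
  invisible(path)
}
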