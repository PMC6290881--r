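fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "varcascade")
  if (!nzchar(p)) stop("fixture not installed: ", name)
  p
}

S361L <- "19:55441902:C:T"
R801H <- "19:55449713:G:A"

load_gs_fixture <- function() {
  peds <- read_ped(fixture_path("gs_families.ped"))
  gv <- read_vcf_genotypes(fixture_path("nlrp7_variants.vcf"))
  ann <- read_annotation_table(fixture_path("nlrp7_annotation.tsv"),
                               c("exac", "inhouse"))
  list(peds = peds, genotypes = gv$genotypes, variants = gv$variants, ann = ann)
}

table1_counts <- function() read_genotype_counts(fixture_path("nlrp7_genotype_counts.tsv"))

# Minimal pedigree builder: affected/sequenced children of one founder couple.
make_toy_ped <- function(n_affected = 2, n_unaffected = 0, family_id = "F1",
                         sequenced = NULL) {
  n <- n_affected + n_unaffected
  kids <- sprintf("c%d", seq_len(n))
  df <- data.frame(
    family_id = family_id,
    individual_id = c("dad", "mum", kids),
    father_id = c(NA, NA, rep("dad", n)),
    mother_id = c(NA, NA, rep("mum", n)),
    sex = c("male", "female", rep("unknown", n)),
    phenotype = c("unaffected", "unaffected",
                  rep(c("affected", "unaffected"), c(n_affected, n_unaffected))),
    stringsAsFactors = FALSE
  )
  if (!is.null(sequenced)) df$sequenced <- df$individual_id %in% sequenced
  pedigree(df)
}

# Genotype matrix from a named list variant_key -> integer codes per individual.
make_gm <- function(ids, calls) {
  m <- do.call(cbind, calls)
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  m
}

write_temp_vcf <- function(body_lines, samples) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            samples), collapse = "\t"),
    body_lines
  ), path)
  path
}

# Independent two-sided Fisher oracle: exhaustive hypergeometric enumeration.
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  xs <- max(0, k - n2):min(k, m)
  pr <- stats::dhyper(xs, m, n2, k)
  sum(pr[pr <= stats::dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# Independent HWE oracle: closed-form conditional probability via lgamma.
hwe_enum_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_alt <- n_het + 2 * n_hom_alt
  nm <- min(n_alt, 2 * n - n_alt)
  if (nm == 0) return(1)
  hs <- seq(nm %% 2, nm, by = 2)
  logp <- vapply(hs, function(h) {
    hm <- (nm - h) / 2
    hM <- n - h - hm
    lfactorial(n) - lfactorial(hm) - lfactorial(h) - lfactorial(hM) +
      h * log(2) + lfactorial(nm) + lfactorial(2 * n - nm) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[match(n_het, hs)]
  sum(p[p <= obs * (1 + 1e-9)])
}
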