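SEX_CODES <- c("0" = "unknown", "1" = "male", "2" = "female")
PHENO_CODES <- c("0" = "unknown", "1" = "unaffected", "2" = "affected", "-9" = "unknown")

#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per family member and columns
#' `family_id`, `individual_id`, `father_id`, `mother_id` (`NA` for
#' founders), `sex` (`male`/`female`/`unknown`), `phenotype`
#' (`affected`/`unaffected`/`unknown`), `diagnosis`, `sequenced` (was the
#' member whole-exome sequenced) and `married_in`.  The constructor
#' validates that ids are unique, that parent pointers resolve within the
#' family, and that the parent graph is acyclic; it then classifies
#' married-in members structurally: a founder (no parents in the pedigree)
#' is married-in when it has a child with a bloodline (non-founder) member.
#' The two founders of the top generation are bloodline by this rule.
#'
#' @param members data frame with at least `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype`.  Optional: `diagnosis`
#'   (default `"none"`), `sequenced` (default: affected members),
#'   `married_in` (overrides the structural classification where not `NA`).
#' @return a `pedigree` (classed data frame).
#' @export
pedigree <- function(members) {
  members <- as.data.frame(members, stringsAsFactors = FALSE)
  required <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "phenotype")
  miss <- setdiff(required, names(members))
  if (length(miss)) stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(members) < 1L) stop("a pedigree needs at least one member")
  if (length(unique(members$family_id)) != 1L) {
    stop("a pedigree holds exactly one family; got ids: ",
         paste(unique(members$family_id), collapse = ", "))
  }
  if (anyDuplicated(members$individual_id)) {
    stop("duplicate individual id in family ", members$family_id[1], ": ",
         members$individual_id[anyDuplicated(members$individual_id)])
  }
  bad_sex <- !members$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) stop("invalid sex value: ", members$sex[which(bad_sex)[1]])
  bad_ph <- !members$phenotype %in% c("affected", "unaffected", "unknown")
  if (any(bad_ph)) stop("invalid phenotype value: ", members$phenotype[which(bad_ph)[1]])

  ids <- members$individual_id
  for (col in c("father_id", "mother_id")) {
    ref <- members[[col]]
    bad <- !is.na(ref) & !ref %in% ids
    if (any(bad)) {
      stop("family ", members$family_id[1], ": ", sub("_id$", "", col), " '",
           ref[which(bad)[1]], "' of '", ids[which(bad)[1]],
           "' is not a member of the pedigree")
    }
  }
  check_acyclic(members)

  if (is.null(members$diagnosis)) members$diagnosis <- "none"
  if (is.null(members$sequenced)) members$sequenced <- members$phenotype == "affected"
  override <- members$married_in
  members$married_in <- detect_married_in(members)
  if (!is.null(override)) {
    keep <- !is.na(override)
    members$married_in[keep] <- as.logical(override)[keep]
  }
  cols <- c("family_id", "individual_id", "father_id", "mother_id", "sex",
            "phenotype", "diagnosis", "sequenced", "married_in")
  members <- members[, cols]
  rownames(members) <- NULL
  class(members) <- c("pedigree", "data.frame")
  members
}

check_acyclic <- function(members) {
  ids <- members$individual_id
  fa <- match(members$father_id, ids)
  mo <- match(members$mother_id, ids)
  resolved <- is.na(fa) & is.na(mo)
  repeat {
    newly <- !resolved &
      (is.na(fa) | resolved[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | resolved[ifelse(is.na(mo), 1L, mo)])
    if (!any(newly)) break
    resolved <- resolved | newly
  }
  if (!all(resolved)) {
    stop("family ", members$family_id[1], ": pedigree contains a cycle involving '",
         ids[which(!resolved)[1]], "'")
  }
  invisible(TRUE)
}

detect_married_in <- function(members) {
  ids <- members$individual_id
  founder <- is.na(members$father_id) & is.na(members$mother_id)
  out <- logical(nrow(members))
  for (i in which(founder)) {
    id <- ids[i]
    kids <- which(members$father_id %in% id | members$mother_id %in% id)
    co <- unique(c(members$father_id[kids], members$mother_id[kids]))
    co <- setdiff(co[!is.na(co)], id)
    # married-in: only reproduces with bloodline (non-founder) members
    out[i] <- length(co) > 0 && all(!founder[match(co, ids)])
  }
  out
}

#' Read pedigrees from a PED file
#'
#' Standard whitespace-delimited 6-column PED (family, individual, father,
#' mother, sex, phenotype), optionally with a 7th column flagging
#' whole-exome-sequenced members (0/1).  Sex codes: 1 male, 2 female,
#' 0 unknown.  Phenotype codes: 2 affected, 1 unaffected, 0 or -9 unknown.
#' Parent code 0 means founder.  Lines starting with `#` are skipped and
#' gzip-compressed files are read transparently.  When no sequenced column
#' is present (and `sequenced_ids` is not given), all affected members are
#' treated as sequenced.
#'
#' @param path PED file path (optionally gzipped).
#' @param sequenced_ids optional character vector of individual ids that
#'   were sequenced; overrides any 7th column.
#' @return named list of [pedigree()] objects, one per family, in order of
#'   first appearance.
#' @export
read_ped <- function(path, sequenced_ids = NULL) {
  if (!file.exists(path)) stop("PED file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  if (!length(keep)) stop("no records in PED file: ", path)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  ncols <- lengths(fields)
  if (any(ncols < 6L)) {
    stop("PED line ", keep[which(ncols < 6L)[1]], ": fewer than 6 columns")
  }
  col <- function(k) vapply(fields, `[[`, "", k)
  rec <- data.frame(
    line = keep,
    family_id = col(1L), individual_id = col(2L),
    father_id = col(3L), mother_id = col(4L),
    sex_code = col(5L), pheno_code = col(6L),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(rec[c("family_id", "individual_id")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop("PED line ", rec$line[i], ": duplicate individual '",
         rec$individual_id[i], "' in family '", rec$family_id[i], "'")
  }
  bad <- !rec$sex_code %in% names(SEX_CODES)
  if (any(bad)) {
    stop("PED line ", rec$line[which(bad)[1]], ": malformed sex code '",
         rec$sex_code[which(bad)[1]], "'")
  }
  bad <- !rec$pheno_code %in% names(PHENO_CODES)
  if (any(bad)) {
    stop("PED line ", rec$line[which(bad)[1]], ": malformed phenotype code '",
         rec$pheno_code[which(bad)[1]], "'")
  }
  rec$sex <- unname(SEX_CODES[rec$sex_code])
  rec$phenotype <- unname(PHENO_CODES[rec$pheno_code])
  rec$father_id[rec$father_id == "0"] <- NA_character_
  rec$mother_id[rec$mother_id == "0"] <- NA_character_

  if (all(ncols >= 7L)) {
    seq_code <- col(7L)
    bad <- !seq_code %in% c("0", "1")
    if (any(bad)) {
      stop("PED line ", rec$line[which(bad)[1]], ": malformed sequenced flag '",
           seq_code[which(bad)[1]], "' (expected 0/1)")
    }
    rec$sequenced <- seq_code == "1"
  }
  if (!is.null(sequenced_ids)) rec$sequenced <- rec$individual_id %in% sequenced_ids

  # parent references checked here to report source line numbers
  for (fam in unique(rec$family_id)) {
    sub <- rec[rec$family_id == fam, ]
    for (col_nm in c("father_id", "mother_id")) {
      ref <- sub[[col_nm]]
      bad <- !is.na(ref) & !ref %in% sub$individual_id
      if (any(bad)) {
        i <- which(bad)[1]
        stop("PED line ", sub$line[i], ": ", sub("_id$", "", col_nm), " '",
             ref[i], "' of '", sub$individual_id[i],
             "' not found in family '", fam, "'")
      }
    }
  }
  fams <- unique(rec$family_id)
  rec$line <- rec$sex_code <- rec$pheno_code <- NULL
  out <- lapply(fams, function(f) pedigree(rec[rec$family_id == f, ]))
  names(out) <- fams
  out
}

#' Write pedigrees to a PED file
#'
#' Inverse of [read_ped()]: emits the 6 standard columns plus (by default)
#' the sequenced flag as a 7th column.
#'
#' @param pedigrees a [pedigree()] or list of them.
#' @param path output file path.
#' @param sequenced_column write the 7th (sequenced) column?
#' @return `path`, invisibly.
#' @export
write_ped <- function(pedigrees, path, sequenced_column = TRUE) {
  if (inherits(pedigrees, "pedigree")) pedigrees <- list(pedigrees)
  rows <- lapply(pedigrees, function(p) {
    sex <- names(SEX_CODES)[match(p$sex, SEX_CODES)]
    ph <- c(affected = "2", unaffected = "1", unknown = "0")[p$phenotype]
    out <- data.frame(
      p$family_id, p$individual_id,
      ifelse(is.na(p$father_id), "0", p$father_id),
      ifelse(is.na(p$mother_id), "0", p$mother_id),
      sex, unname(ph), stringsAsFactors = FALSE
    )
    if (sequenced_column) out[[7]] <- as.integer(p$sequenced)
    out
  })
  tab <- do.call(rbind, lapply(rows, function(r) { names(r) <- paste0("V", seq_along(r)); r }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree ", x$family_id[1], ": ", nrow(x), " members (",
      sum(x$phenotype == "affected"), " affected, ",
      sum(x$sequenced), " sequenced, ",
      sum(x$married_in), " married-in)\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

founder_ids <- function(ped) ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]

sequenced_affected_ids <- function(ped) {
  ped$individual_id[ped$phenotype == "affected" & ped$sequenced]
}
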