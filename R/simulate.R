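#' Penetrance model for a dominant risk allele
#'
#' @param carrier_penetrance probability `f` that a carrier is affected.
#' @param phenocopy_rate probability `phi` that a non-carrier is affected
#'   (disease from other causes); must satisfy `0 <= phi < f <= 1`.
#' @return a `penetrance_model` list.
#' @export
penetrance_model <- function(carrier_penetrance = 0.6, phenocopy_rate = 0.05) {
  if (!(phenocopy_rate >= 0 && phenocopy_rate < carrier_penetrance &&
        carrier_penetrance <= 1)) {
    stop("penetrance model requires 0 <= phenocopy_rate < carrier_penetrance <= 1")
  }
  structure(list(carrier_penetrance = carrier_penetrance,
                 phenocopy_rate = phenocopy_rate),
            class = "penetrance_model")
}

#' Configuration for the multiplex-family simulator
#'
#' Defaults emulate the discovery design: 10 three-generation families
#' ascertained for three or more affected members, each segregating one
#' founder-introduced rare protein-altering risk variant under a dominant
#' model with incomplete penetrance (0.6) and phenocopies (0.05).
#' `n_causal_families` families share the configured causal gene; the
#' remaining families carry risk variants in private genes (locus
#' heterogeneity), so only the shared gene can satisfy the cross-family
#' recurrence filter.
#'
#' @param n_families number of families.
#' @param generations pedigree depth (default 3).
#' @param mean_sibship mean number of children per couple (Poisson,
#'   truncated at 1).
#' @param causal_gene gene symbol shared by the causal families.
#' @param causal_allele_frequency reference-panel allele frequency
#'   recorded for the planted risk variants (well below the 1% screen).
#' @param n_causal_families families sharing `causal_gene`.
#' @param background_variants number of background exome variants.
#' @param background_af_range allele-frequency range of background
#'   variants (log-uniform).
#' @param consequence_mix sampling probabilities over
#'   [consequence_levels] for background variants.
#' @param penetrance a [penetrance_model()].
#' @param novel_fraction fraction of background variants absent from all
#'   frequency sources.
#' @param seed integer RNG seed.
#' @return a `family_sim_config` list.
#' @export
family_sim_config <- function(n_families = 10L, generations = 3L,
                              mean_sibship = 2.5, causal_gene = "RISK1",
                              causal_allele_frequency = 4e-4,
                              n_causal_families = 2L,
                              background_variants = 200L,
                              background_af_range = c(1e-5, 0.5),
                              consequence_mix = c(missense = 0.50, synonymous = 0.30,
                                                  nonsense = 0.05, frameshift = 0.05,
                                                  splice_canonical = 0.05, other = 0.05),
                              penetrance = penetrance_model(),
                              novel_fraction = 0.1,
                              seed = 1L) {
  stopifnot(n_causal_families <= n_families, generations >= 2,
            abs(sum(consequence_mix) - 1) < 1e-8,
            all(names(consequence_mix) %in% consequence_levels))
  structure(list(
    n_families = as.integer(n_families), generations = as.integer(generations),
    mean_sibship = mean_sibship, causal_gene = causal_gene,
    causal_allele_frequency = causal_allele_frequency,
    n_causal_families = as.integer(n_causal_families),
    background_variants = as.integer(background_variants),
    background_af_range = background_af_range,
    consequence_mix = consequence_mix, penetrance = penetrance,
    novel_fraction = novel_fraction, seed = as.integer(seed)
  ), class = "family_sim_config")
}

#' Simulate a multi-generation pedigree structure
#'
#' Builds a connected pedigree from a founding couple: every couple has a
#' Poisson-distributed sibship (at least one child) and, below the last
#' generation, each child takes a married-in spouse.  Phenotypes are
#' `"unknown"` at this stage (see [assign_phenotypes()]).  Deterministic
#' given `(config$seed, family_index)`.
#'
#' @param config a [family_sim_config()].
#' @param family_index 1-based family number (also seeds the RNG).
#' @return a [pedigree()].
#' @export
simulate_pedigree <- function(config, family_index = 1L) {
  fam <- sprintf("SIMFAM%02d", family_index)
  with_seed(derive_seed(config$seed, 1L, family_index), {
    k <- 0L
    new_id <- function() {
      k <<- k + 1L
      sprintf("%s_%02d", fam, k)
    }
    rows <- list()
    add <- function(id, father, mother, sex) {
      rows[[length(rows) + 1L]] <<- data.frame(
        family_id = fam, individual_id = id,
        father_id = father, mother_id = mother, sex = sex,
        phenotype = "unknown", stringsAsFactors = FALSE
      )
    }
    p1 <- new_id(); add(p1, NA_character_, NA_character_, "male")
    p2 <- new_id(); add(p2, NA_character_, NA_character_, "female")
    couples <- list(c(father = p1, mother = p2))
    for (g in seq_len(config$generations - 1L) + 1L) {
      next_couples <- list()
      for (cp in couples) {
        nk <- max(1L, rpois(1L, config$mean_sibship))
        for (j in seq_len(nk)) {
          sex <- sample(c("male", "female"), 1L)
          kid <- new_id(); add(kid, cp[["father"]], cp[["mother"]], sex)
          if (g < config$generations) {
            spouse_sex <- if (sex == "male") "female" else "male"
            sp <- new_id(); add(sp, NA_character_, NA_character_, spouse_sex)
            next_couples[[length(next_couples) + 1L]] <-
              if (sex == "male") c(father = kid, mother = sp) else c(father = sp, mother = kid)
          }
        }
      }
      couples <- next_couples
    }
    df <- do.call(rbind, rows)
    df$sequenced <- FALSE
    pedigree(df)
  })
}

#' Drop a variant through a pedigree under Mendelian transmission
#'
#' Founders receive the specified genotypes; every non-founder inherits
#' one allele from each parent uniformly at random.  Alleles absent from
#' the founders can never appear downstream.  Deterministic given `seed`.
#'
#' @param pedigree a [pedigree()].
#' @param founder_genotypes named integer vector (0/1/2) covering every
#'   founder (married-in spouses included).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return named integer genotype vector (0/1/2) over all members.
#' @export
gene_drop <- function(pedigree, founder_genotypes, seed = NULL) {
  ids <- pedigree$individual_id
  founders <- founder_ids(pedigree)
  miss <- setdiff(founders, names(founder_genotypes))
  if (length(miss)) stop("missing founder genotype for: ", paste(miss, collapse = ", "))
  bad <- !founder_genotypes[founders] %in% 0:2
  if (any(bad)) stop("founder genotypes must be coded 0/1/2")
  with_seed(seed, {
    alleles <- matrix(NA_integer_, nrow = length(ids), ncol = 2,
                      dimnames = list(ids, NULL))
    for (f in founders) {
      g <- founder_genotypes[[f]]
      alleles[f, ] <- if (g == 0L) c(0L, 0L) else if (g == 1L) c(0L, 1L) else c(1L, 1L)
    }
    todo <- setdiff(ids, founders)
    while (length(todo)) {
      ready <- todo[vapply(todo, function(id) {
        i <- match(id, ids)
        !anyNA(alleles[pedigree$father_id[i], ]) && !anyNA(alleles[pedigree$mother_id[i], ])
      }, logical(1))]
      for (id in ready) {
        i <- match(id, ids)
        alleles[id, ] <- c(
          alleles[pedigree$father_id[i], sample.int(2L, 1L)],
          alleles[pedigree$mother_id[i], sample.int(2L, 1L)]
        )
      }
      todo <- setdiff(todo, ready)
    }
    setNames(as.integer(rowSums(alleles)), ids)
  })
}

#' Assign affection status under incomplete penetrance and phenocopies
#'
#' Carriers of the risk allele become affected with probability
#' `carrier_penetrance`; non-carriers with probability `phenocopy_rate`.
#' Affected members receive a CD or UC diagnosis label (7:3).
#' Deterministic given `seed`.
#'
#' @param pedigree a [pedigree()].
#' @param causal_calls named genotype vector (0/1/2) covering all members.
#' @param model a [penetrance_model()].
#' @param seed integer seed or `NULL`.
#' @return the pedigree with `phenotype` and `diagnosis` filled in
#'   (sequenced flags untouched).
#' @export
assign_phenotypes <- function(pedigree, causal_calls, model = penetrance_model(),
                              seed = NULL) {
  ids <- pedigree$individual_id
  miss <- setdiff(ids, names(causal_calls))
  if (length(miss)) stop("causal calls missing for: ", paste(miss, collapse = ", "))
  carrier <- causal_calls[ids] >= 1L
  with_seed(seed, {
    prob <- ifelse(carrier, model$carrier_penetrance, model$phenocopy_rate)
    affected <- runif(length(ids)) < prob
    pedigree$phenotype <- ifelse(affected, "affected", "unaffected")
    pedigree$diagnosis <- ifelse(affected,
                                 sample(c("CD", "UC"), length(ids), replace = TRUE,
                                        prob = c(0.7, 0.3)),
                                 "none")
  })
  pedigree(pedigree)
}

draw_founder_genotypes <- function(ped, af, seed = NULL) {
  founders <- founder_ids(ped)
  with_seed(seed, {
    g <- sample(0:2, length(founders), replace = TRUE,
                prob = c((1 - af)^2, 2 * af * (1 - af), af^2))
    setNames(as.integer(g), founders)
  })
}

#' Simulate a complete multiplex-family exome dataset
#'
#' End-to-end generator for the filter cascade.  Each family carries one
#' founder-introduced rare missense risk variant; `n_causal_families`
#' (chosen at random under the seed) share the causal gene, the remainder
#' carry private genes.  Families are ascertained by rejection sampling to
#' at least three affected members and at least two affected carriers, and
#' whole-exome-sequenced members are drawn from the affected carriers (up
#' to three, spread across the member list), so sequenced affected members
#' share the family's risk variant heterozygously by construction.
#' Background variants with log-uniform allele frequencies and a mixed
#' consequence spectrum are gene-dropped independently; a configurable
#' fraction of them is absent from all frequency sources (novel).
#'
#' @param config a [family_sim_config()].
#' @return list with `families` (list of `list(pedigree, genotypes)`),
#'   `annotations` (an [annotation_table()] with sources `exac` and
#'   `inhouse`) and `truth` (causal gene, causal family ids, planted
#'   variant keys, carrier and sequenced sets per family).
#' @export
simulate_family_dataset <- function(config = family_sim_config()) {
  n <- config$n_families
  if (n == 0L) {
    return(list(families = list(),
                annotations = annotation_table(
                  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                             alt = character(0), gene = character(0),
                             consequence = character(0), exac = numeric(0),
                             inhouse = numeric(0)),
                  c("exac", "inhouse")),
                truth = list(causal_gene = config$causal_gene,
                             causal_families = character(0), causal_variants = character(0),
                             carriers = list(), sequenced = list())))
  }
  causal_idx <- with_seed(derive_seed(config$seed, 99L),
                          sort(sample.int(n, config$n_causal_families)))

  # one risk variant per family; causal families share the causal gene
  risk <- data.frame(
    chrom = "19", pos = 1000000L + seq_len(n) * 1500L, ref = "C", alt = "T",
    gene = ifelse(seq_len(n) %in% causal_idx, config$causal_gene,
                  sprintf("PRIV%02d", seq_len(n))),
    consequence = "missense",
    exac = config$causal_allele_frequency, inhouse = NA_real_,
    stringsAsFactors = FALSE
  )
  risk_keys <- variant_key(risk$chrom, risk$pos, risk$ref, risk$alt)

  nb <- config$background_variants
  bg <- with_seed(derive_seed(config$seed, 98L), {
    lo <- log10(config$background_af_range[1])
    hi <- log10(config$background_af_range[2])
    af <- 10^runif(nb, lo, hi)
    novel <- runif(nb) < config$novel_fraction
    ref <- sample(c("A", "C", "G", "T"), nb, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    data.frame(
      chrom = as.character(sample(1:22, nb, replace = TRUE)),
      pos = sample.int(5e7, nb),
      ref = ref,
      alt = alt,
      gene = sprintf("BG%03d", sample.int(max(1L, ceiling(nb / 1.5)), nb, replace = TRUE)),
      consequence = sample(names(config$consequence_mix), nb, replace = TRUE,
                           prob = config$consequence_mix),
      af = af,
      exac = ifelse(novel, NA_real_, af),
      inhouse = ifelse(novel, NA_real_, af),
      stringsAsFactors = FALSE
    )
  })
  bg <- bg[!duplicated(paste(bg$chrom, bg$pos)), , drop = FALSE]
  nb <- nrow(bg)
  bg_keys <- variant_key(bg$chrom, bg$pos, bg$ref, bg$alt)

  ann <- annotation_table(
    rbind(risk[, c("chrom", "pos", "ref", "alt", "gene", "consequence", "exac", "inhouse")],
          bg[, c("chrom", "pos", "ref", "alt", "gene", "consequence", "exac", "inhouse")]),
    c("exac", "inhouse")
  )

  truth_carriers <- list()
  truth_sequenced <- list()
  families <- vector("list", n)
  for (i in seq_len(n)) {
    ped0 <- simulate_pedigree(config, i)
    founders <- founder_ids(ped0)
    ped <- NULL
    calls_risk <- NULL
    for (try in seq_len(500L)) {
      fg <- setNames(rep(0L, length(founders)), founders)
      fg[[1]] <- 1L  # risk allele enters through the first top-generation founder
      calls_risk <- gene_drop(ped0, fg, seed = derive_seed(config$seed, i, try, 1L))
      cand <- assign_phenotypes(ped0, calls_risk, config$penetrance,
                                seed = derive_seed(config$seed, i, try, 2L))
      aff <- cand$phenotype == "affected"
      aff_car <- aff & calls_risk[cand$individual_id] >= 1L
      if (sum(aff) >= 3L && sum(aff_car) >= 2L) {
        ped <- cand
        break
      }
    }
    if (is.null(ped)) {
      stop("family ", i, ": could not ascertain >= 3 affected members with >= 2 ",
           "affected carriers in 500 attempts; penetrance settings too low")
    }
    aff_car_ids <- ped$individual_id[ped$phenotype == "affected" &
                                       calls_risk[ped$individual_id] >= 1L]
    pick <- if (length(aff_car_ids) <= 3L) aff_car_ids else {
      aff_car_ids[unique(round(seq(1L, length(aff_car_ids), length.out = 3L)))]
    }
    ped$sequenced <- ped$individual_id %in% pick
    ped <- pedigree(ped)

    gm <- matrix(NA_integer_, nrow = nrow(ped), ncol = 1L + nb,
                 dimnames = list(ped$individual_id, c(risk_keys[i], bg_keys)))
    gm[, 1L] <- calls_risk[ped$individual_id]
    for (j in seq_len(nb)) {
      fg <- draw_founder_genotypes(ped, bg$af[j], seed = derive_seed(config$seed, i, 500L + j))
      gm[, j + 1L] <- gene_drop(ped, fg, seed = derive_seed(config$seed, i, 10000L + j))[ped$individual_id]
    }
    families[[i]] <- list(pedigree = ped, genotypes = gm)
    fam_id <- ped$family_id[1]
    truth_carriers[[fam_id]] <- ped$individual_id[calls_risk[ped$individual_id] >= 1L]
    truth_sequenced[[fam_id]] <- pick
  }
  fam_ids <- vapply(families, function(f) f$pedigree$family_id[1], "")
  names(families) <- fam_ids
  list(
    families = families,
    annotations = ann,
    truth = list(
      causal_gene = config$causal_gene,
      causal_families = fam_ids[causal_idx],
      causal_variants = setNames(risk_keys[causal_idx], fam_ids[causal_idx]),
      risk_variants = setNames(risk_keys, fam_ids),
      carriers = truth_carriers,
      sequenced = truth_sequenced,
      config = config
    )
  )
}

#' Configuration for the case-control cohort simulator
#'
#' Defaults emulate the follow-up genotyping panel: 2948 CD and 3077 UC
#' cases versus 7238 controls, two rare variants with control carrier
#' frequencies 5/7074 and 2/6986 and the odds ratios recomputed from the
#' published genotype counts, and 0.5% genotype missingness (call rate
#' above the 99% QC gate).
#'
#' @param n_cd,n_uc,n_control cohort sizes.
#' @param variants data frame with columns `label`,
#'   `control_carrier_frequency`, `odds_ratio_cd`, `odds_ratio_uc`.
#' @param missing_rate per-genotype missingness probability.
#' @param seed integer RNG seed.
#' @return a `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_cd = 2948L, n_uc = 3077L, n_control = 7238L,
                              variants = data.frame(
                                label = c("S361L_like", "R801H_like"),
                                control_carrier_frequency = c(5 / 7074, 2 / 6986),
                                odds_ratio_cd = c(1.49, 2.49),
                                odds_ratio_uc = c(4.79, 1.18),
                                stringsAsFactors = FALSE
                              ),
                              missing_rate = 0.005, seed = 1L) {
  stopifnot(n_cd > 0, n_uc > 0, n_control > 0,
            all(variants$control_carrier_frequency >= 0 &
                  variants$control_carrier_frequency <= 1),
            all(variants$odds_ratio_cd > 0), all(variants$odds_ratio_uc > 0),
            missing_rate >= 0, missing_rate < 1)
  structure(list(n_cd = as.integer(n_cd), n_uc = as.integer(n_uc),
                 n_control = as.integer(n_control), variants = variants,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

odds_transform <- function(or, q) {
  t <- or * q / (1 - q)
  t / (1 + t)
}

#' Simulate per-variant case-control genotype counts
#'
#' Retrospective (case-control) sampling: control carriers are binomial
#' at the control carrier frequency `q`; case carrier probability comes
#' from the odds transform `p/(1-p) = OR * q/(1-q)`.  All carriers are
#' heterozygous (rare-variant regime; the homozygote probability `q^2` is
#' negligible and none were observed in the study data this emulates).
#' CD and UC effects are drawn independently per variant; the IBD cohort
#' is the union of the CD and UC draws.  Missingness is applied per
#' genotype at `missing_rate`.  Deterministic given `config$seed`.
#'
#' @param config a [cohort_sim_config()].
#' @return data frame of genotype counts (`cohort` in CD/UC/IBD/control,
#'   `variant`, `n_hom_ref`, `n_het`, `n_hom_alt`), as read by
#'   [read_genotype_counts()].
#' @export
simulate_casecontrol_counts <- function(config = cohort_sim_config()) {
  v <- config$variants
  rows <- list()
  for (j in seq_len(nrow(v))) {
    q <- v$control_carrier_frequency[j]
    draws <- with_seed(derive_seed(config$seed, 7L, j), {
      car_ctrl <- rbinom(1L, config$n_control, q)
      car_cd <- rbinom(1L, config$n_cd, odds_transform(v$odds_ratio_cd[j], q))
      car_uc <- rbinom(1L, config$n_uc, odds_transform(v$odds_ratio_uc[j], q))
      apply_missing <- function(car, n) {
        mr <- config$missing_rate
        miss_car <- rbinom(1L, car, mr)
        miss_non <- rbinom(1L, n - car, mr)
        c(n_hom_ref = n - car - miss_non, n_het = car - miss_car, n_hom_alt = 0L)
      }
      list(cd = apply_missing(car_cd, config$n_cd),
           uc = apply_missing(car_uc, config$n_uc),
           control = apply_missing(car_ctrl, config$n_control))
    })
    for (cohort in c("CD", "UC", "IBD", "control")) {
      cnt <- switch(cohort,
                    CD = draws$cd, UC = draws$uc, control = draws$control,
                    IBD = draws$cd + draws$uc)
      rows[[length(rows) + 1L]] <- data.frame(
        cohort = cohort, variant = v$label[j],
        n_hom_ref = cnt[["n_hom_ref"]], n_het = cnt[["n_het"]],
        n_hom_alt = cnt[["n_hom_alt"]], stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
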