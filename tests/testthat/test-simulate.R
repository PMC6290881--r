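test_that("simulated pedigrees are valid, multi-generation and reproducible", {
  cfg <- family_sim_config(seed = 3)
  ped <- simulate_pedigree(cfg, 1)
  expect_s3_class(ped, "pedigree")
  expect_gt(nrow(ped), 4)
  # PED round-trip validates structure (acyclic, parents resolve)
  path <- withr::local_tempfile(fileext = ".ped")
  write_ped(ped, path)
  back <- read_ped(path)[[1]]
  expect_equal(back$individual_id, ped$individual_id)
  # determinism
  expect_identical(simulate_pedigree(cfg, 1), ped)
  expect_false(identical(simulate_pedigree(cfg, 2)$individual_id, ped$individual_id))
  # minimal configuration gives a trio-sized family
  tiny <- simulate_pedigree(family_sim_config(generations = 2, mean_sibship = 0.1,
                                              seed = 1), 1)
  expect_equal(nrow(tiny), 3)
})

test_that("gene dropping obeys Mendelian transmission and allele conservation", {
  # het x hom-ref cross: offspring carrier fraction converges to 1/2
  n <- 4000
  df <- data.frame(
    family_id = "F", individual_id = c("p1", "p2", sprintf("k%d", 1:n)),
    father_id = c(NA, NA, rep("p1", n)), mother_id = c(NA, NA, rep("p2", n)),
    sex = c("male", "female", rep("unknown", n)),
    phenotype = "unknown", stringsAsFactors = FALSE
  )
  ped <- pedigree(df)
  calls <- gene_drop(ped, c(p1 = 1L, p2 = 0L), seed = 77)
  frac <- mean(calls[sprintf("k%d", 1:n)] >= 1)
  expect_equal(frac, 0.5, tolerance = 3 * sqrt(0.25 / n) / 0.5)
  # hom-ref x hom-ref: no allele can appear
  expect_true(all(gene_drop(ped, c(p1 = 0L, p2 = 0L), seed = 1) == 0L))
  # three-generation chain never creates alleles absent in founders
  cfg <- family_sim_config(seed = 5)
  ped3 <- simulate_pedigree(cfg, 2)
  founders <- ped3$individual_id[is.na(ped3$father_id)]
  fg <- setNames(rep(0L, length(founders)), founders)
  expect_true(all(gene_drop(ped3, fg, seed = 9) == 0L))
  fg[1] <- 2L
  calls3 <- gene_drop(ped3, fg, seed = 9)
  expect_true(all(calls3 %in% 0:2))
  expect_error(gene_drop(ped3, fg[-1], seed = 1), "missing founder genotype")
})

test_that("phenotype assignment follows the penetrance model", {
  cfg <- family_sim_config(seed = 21)
  ped <- simulate_pedigree(cfg, 1)
  founders <- ped$individual_id[is.na(ped$father_id)]
  fg <- setNames(rep(0L, length(founders)), founders)
  fg[1] <- 1L
  calls <- gene_drop(ped, fg, seed = 2)
  # deterministic limit: full penetrance, no phenocopies
  full <- assign_phenotypes(ped, calls, penetrance_model(1, 0), seed = 4)
  expect_equal(full$phenotype == "affected", unname(calls[full$individual_id] >= 1))
  # no phenocopies among non-carriers when phi = 0
  some <- assign_phenotypes(ped, calls, penetrance_model(0.6, 0), seed = 4)
  noncar <- some$individual_id[calls[some$individual_id] == 0]
  expect_true(all(some$phenotype[match(noncar, some$individual_id)] == "unaffected"))
})

test_that("averaged carrier penetrance converges to the generating value", {
  cfg <- family_sim_config(seed = 13)
  ped <- simulate_pedigree(cfg, 1)
  founders <- ped$individual_id[is.na(ped$father_id)]
  f_true <- 0.6
  pen <- numeric(0)
  for (i in 1:300) {
    fg <- setNames(rep(0L, length(founders)), founders)
    fg[1] <- 1L
    calls <- gene_drop(ped, fg, seed = 1000 + i)
    sim <- assign_phenotypes(ped, calls, penetrance_model(f_true, 0.05),
                             seed = 2000 + i)
    gm <- matrix(calls[sim$individual_id], ncol = 1,
                 dimnames = list(sim$individual_id, "19:100:C:T"))
    s <- tabulate_segregation(sim, gm, "19:100:C:T")
    if (!is.na(s$carrier_penetrance)) pen <- c(pen, s$carrier_penetrance)
  }
  se <- stats::sd(pen) / sqrt(length(pen))
  expect_lt(abs(mean(pen) - f_true), 3 * se + 0.01)
})

test_that("the family dataset plants its risk variants as described by the truth record", {
  cfg <- family_sim_config(n_families = 4, background_variants = 30, seed = 17)
  ds <- simulate_family_dataset(cfg)
  expect_length(ds$families, 4)
  expect_length(ds$truth$causal_families, 2)
  for (fam in names(ds$families)) {
    f <- ds$families[[fam]]
    key <- ds$truth$risk_variants[[fam]]
    carriers <- rownames(f$genotypes)[f$genotypes[, key] >= 1]
    expect_setequal(carriers, ds$truth$carriers[[fam]])
    # sequenced members are affected carriers, so the risk variant is shared het
    seq_aff <- f$pedigree$individual_id[f$pedigree$sequenced]
    expect_setequal(seq_aff, ds$truth$sequenced[[fam]])
    expect_true(all(f$genotypes[seq_aff, key] == 1L))
    expect_gte(sum(f$pedigree$phenotype == "affected"), 3)
  }
  # bitwise reproducibility
  ds2 <- simulate_family_dataset(cfg)
  expect_identical(ds$families[[1]]$genotypes, ds2$families[[1]]$genotypes)
  expect_identical(as.data.frame(ds$families[[3]]$pedigree),
                   as.data.frame(ds2$families[[3]]$pedigree))
})

test_that("cohort simulation matches its generating frequencies and call rate", {
  cfg <- cohort_sim_config(
    variants = data.frame(label = "v1", control_carrier_frequency = 0.02,
                          odds_ratio_cd = 1, odds_ratio_uc = 1,
                          stringsAsFactors = FALSE),
    missing_rate = 0.005, seed = 8)
  reps <- lapply(1:60, function(i) {
    cfg$seed <- 100 + i
    simulate_casecontrol_counts(cfg)
  })
  freq <- function(rows, cohort) {
    r <- do.call(rbind, lapply(rows, function(x) x[x$cohort == cohort, ]))
    sum(r$n_het) / sum(r$n_hom_ref + r$n_het + r$n_hom_alt)
  }
  # OR = 1: case and control carrier frequencies agree in expectation
  expect_equal(freq(reps, "UC"), freq(reps, "control"), tolerance = 0.08)
  expect_equal(freq(reps, "control"), 0.02, tolerance = 0.05)
  # IBD is the union of the CD and UC draws
  one <- reps[[1]]
  expect_equal(one$n_het[one$cohort == "IBD"],
               one$n_het[one$cohort == "CD"] + one$n_het[one$cohort == "UC"])
  # call rate clears the >99% QC gate at 0.5% missingness
  n_typed <- sum(one$n_hom_ref + one$n_het + one$n_hom_alt)
  # individuals over the CD, UC, IBD (= CD + UC) and control rows
  call_rate <- n_typed / (2 * (cfg$n_cd + cfg$n_uc) + cfg$n_control)
  expect_gt(call_rate, 0.99)
  # determinism
  expect_identical(simulate_casecontrol_counts(cfg), simulate_casecontrol_counts(cfg))
})
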