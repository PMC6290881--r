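#' 2x2 contingency table for an allelic or carrier test
#'
#' Cell order is `a` = case minor/carrier, `b` = case major/non-carrier,
#' `c` = control minor/carrier, `d` = control major/non-carrier.
#'
#' @param a,b,c,d non-negative counts.
#' @return named numeric vector of length 4.
#' @export
table2x2 <- function(a, b, c, d) {
  tab <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(tab)) || any(tab < 0)) stop("2x2 cells must be non-negative counts")
  tab
}

as_table2x2 <- function(tab) {
  tab <- as.numeric(tab)
  if (length(tab) != 4L || any(is.na(tab)) || any(tab < 0)) {
    stop("expected a 2x2 table as 4 non-negative counts (a, b, c, d)")
  }
  names(tab) <- c("a", "b", "c", "d")
  tab
}

chi2_statistic <- function(tab, yates = FALSE) {
  tab <- as_table2x2(tab)
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) stop("degenerate margins: chi-square statistic undefined")
  delta <- abs(a * d - b * cc)
  if (yates) delta <- max(0, delta - n / 2)
  unname(n * delta^2 / prod(margins))
}

#' Allelic case-control association test on a 2x2 table
#'
#' `chi2` is the 1-df Pearson statistic `N(ad-bc)^2 /
#' ((a+b)(c+d)(a+c)(b+d))`; `chi2_yates` applies the continuity
#' correction, replacing `(ad-bc)^2` by `(|ad-bc| - N/2)^2` floored at
#' zero; `fisher_exact` is the two-sided exact hypergeometric test (sum of
#' tables with probability at most that of the observed table).
#'
#' @param tab 2x2 counts (see [table2x2()]).
#' @param method one of `"chi2_yates"` (default), `"chi2"`,
#'   `"fisher_exact"`.
#' @return two-sided p-value.
#' @export
allelic_association_test <- function(tab, method = c("chi2_yates", "chi2", "fisher_exact")) {
  method <- match.arg(method)
  tab <- as_table2x2(tab)
  if (method == "fisher_exact") {
    # fisher.test can overshoot 1 by floating-point noise
    return(min(1, fisher.test(matrix(tab, nrow = 2, byrow = TRUE))$p.value))
  }
  pchisq(chi2_statistic(tab, yates = method == "chi2_yates"), df = 1, lower.tail = FALSE)
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `ad / bc`.  When any cell is zero and
#' `zero_correction` is on, 0.5 is added to every cell first
#' (Haldane-Anscombe); with the correction off, a zero in `b` or `c`
#' leaves the ratio undefined and raises an error.
#'
#' @inheritParams allelic_association_test
#' @param zero_correction apply the Haldane-Anscombe +0.5 correction when
#'   a zero cell is present.
#' @return positive odds ratio.
#' @export
odds_ratio_2x2 <- function(tab, zero_correction = TRUE) {
  tab <- as_table2x2(tab)
  if (any(tab == 0)) {
    if (zero_correction) {
      tab <- tab + 0.5
    } else if (tab[2] * tab[3] == 0) {
      stop("odds ratio undefined: zero cell without zero correction")
    }
  }
  unname(tab[1] * tab[4] / (tab[2] * tab[3]))
}

#' Woolf confidence interval for an odds ratio
#'
#' Normal approximation on the log scale:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.  Zero cells are
#' handled by the Haldane-Anscombe correction (or raise an error when
#' disabled).
#'
#' @inheritParams odds_ratio_2x2
#' @param level confidence level (default 0.95).
#' @return named numeric vector `c(low, high)`.
#' @export
woolf_confidence_interval <- function(tab, level = 0.95, zero_correction = TRUE) {
  tab <- as_table2x2(tab)
  if (any(tab == 0)) {
    if (!zero_correction) stop("Woolf interval undefined: zero cell without zero correction")
    tab <- tab + 0.5
  }
  or <- tab[1] * tab[4] / (tab[2] * tab[3])
  se <- sqrt(sum(1 / tab))
  z <- qnorm(1 - (1 - level) / 2)
  c(low = unname(exp(log(or) - z * se)), high = unname(exp(log(or) + z * se)))
}

#' Bonferroni correction
#'
#' @param p p-value(s) in \[0, 1\].
#' @param m number of tests (>= 1).
#' @return `min(1, m * p)`, vectorised over `p`.
#' @export
bonferroni_correct <- function(p, m) {
  stopifnot(m >= 1, all(p >= 0 & p <= 1))
  pmin(1, m * p)
}

#' Exact conditional Hardy-Weinberg equilibrium test
#'
#' Conditions on the observed allele counts and enumerates every
#' heterozygote count compatible with them; the p-value is the summed
#' probability of all configurations no more probable than the observed
#' one (two-sided by probability mass, no mid-p).  Probabilities follow
#' the conditional-on-margins distribution, evaluated through the upward
#' recurrence `P(h+2)/P(h) = 4 n_AA(h) n_BB(h) / ((h+2)(h+1))` on the log
#' scale.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value; 1 for a monomorphic site.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("no genotyped individuals")
  n_alt <- n_het + 2 * n_hom_alt
  nm <- min(n_alt, 2 * n - n_alt)  # minor allele count
  if (nm == 0) return(1)
  hs <- seq(nm %% 2, nm, by = 2)
  logp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    hom_minor <- (nm - h) / 2
    hom_major <- n - h - hom_minor
    logp[i] <- logp[i - 1] + log(4 * hom_minor * hom_major) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hs)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  sum(p[p <= obs * (1 + 1e-9)])
}

#' Genotype counts to allele counts
#'
#' @param counts genotype counts `c(n_hom_ref, n_het, n_hom_alt)`.
#' @return `c(n_minor, n_total)` with `n_minor = n_het + 2 n_hom_alt` and
#'   `n_total = 2 n` (diploid).
#' @export
genotype_to_allele_counts <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  c(n_minor = counts[2] + 2 * counts[3], n_total = 2 * sum(counts))
}

#' Minor allele frequency from genotype counts
#'
#' @inheritParams genotype_to_allele_counts
#' @return allele-based frequency `n_minor / n_total`.
#' @export
minor_allele_frequency <- function(counts) {
  ac <- genotype_to_allele_counts(counts)
  if (ac["n_total"] == 0) stop("minor allele frequency undefined for n = 0")
  unname(ac["n_minor"] / ac["n_total"])
}

carrier_count <- function(counts) sum(as.numeric(counts)[2:3])

assoc_row <- function(variant, phenotype, basis, tab, method, m_tests, level,
                      n_case, n_control, maf_case, maf_control,
                      freq_case = NA_real_, freq_control = NA_real_) {
  p <- allelic_association_test(tab, method)
  ci <- woolf_confidence_interval(tab, level = level)
  data.frame(
    variant = variant, phenotype = phenotype, basis = basis, method = method,
    n_case = n_case, n_control = n_control,
    maf_case = maf_case, maf_control = maf_control,
    freq_case = freq_case, freq_control = freq_control,
    or = odds_ratio_2x2(tab), ci_low = ci[["low"]], ci_high = ci[["high"]],
    p = p, p_corrected = bonferroni_correct(p, m_tests),
    stringsAsFactors = FALSE
  )
}

#' Single-variant case-control association
#'
#' Builds the allele-basis (default) or carrier-basis 2x2 table from case
#' and control genotype counts, then computes the association p-value,
#' odds ratio, Woolf confidence interval, minor allele frequencies and
#' Bonferroni-corrected p-value.
#'
#' @param case_counts,control_counts genotype counts
#'   `c(n_hom_ref, n_het, n_hom_alt)` for one variant.
#' @param method test method, see [allelic_association_test()].
#' @param m_tests Bonferroni denominator (default 6: two variants by three
#'   phenotypes).
#' @param basis `"allele"` (minor vs major allele counts) or `"carrier"`
#'   (carrier vs non-carrier individuals).
#' @param level confidence level for the Woolf interval.
#' @param phenotype,variant labels carried into the result row.
#' @return one-row data frame (association result).
#' @export
single_variant_association <- function(case_counts, control_counts,
                                       method = c("chi2_yates", "chi2", "fisher_exact"),
                                       m_tests = 6, basis = c("allele", "carrier"),
                                       level = 0.95,
                                       phenotype = NA_character_,
                                       variant = NA_character_) {
  method <- match.arg(method)
  basis <- match.arg(basis)
  case_counts <- as.numeric(case_counts)
  control_counts <- as.numeric(control_counts)
  if (basis == "allele") {
    ca <- genotype_to_allele_counts(case_counts)
    co <- genotype_to_allele_counts(control_counts)
    tab <- table2x2(ca[["n_minor"]], ca[["n_total"]] - ca[["n_minor"]],
                    co[["n_minor"]], co[["n_total"]] - co[["n_minor"]])
  } else {
    tab <- table2x2(carrier_count(case_counts), case_counts[1],
                    carrier_count(control_counts), control_counts[1])
  }
  assoc_row(variant, phenotype, basis, tab, method, m_tests, level,
            n_case = sum(case_counts), n_control = sum(control_counts),
            maf_case = minor_allele_frequency(case_counts),
            maf_control = minor_allele_frequency(control_counts),
            freq_case = carrier_count(case_counts) / sum(case_counts),
            freq_control = carrier_count(control_counts) / sum(control_counts))
}

normalize_panel <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("n_hom_ref", "n_het", "n_hom_alt")])
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, x)
  x <- matrix(as.numeric(x), ncol = 3)
  if (any(is.na(x)) || any(x < 0)) stop("invalid genotype counts in panel")
  x
}

#' Cumulative carrier (burden) analysis over a variant panel
#'
#' Pools carriers of several rare variants into a single case-control
#' comparison.  Working from counts, carrier sets are assumed disjoint
#' across variants (no individual carries two panel variants — the
#' rare-variant regime); the per-cohort panel sample size is the smallest
#' per-variant total, i.e. the individuals typed across the panel.  Under
#' `basis = "allele"` the 2x2 table opposes summed minor alleles to the
#' remaining alleles; under `basis = "carrier"` it opposes carrier to
#' non-carrier individuals.  The combined carrier frequency (fraction of
#' individuals carrying any panel variant) is reported for both cohorts.
#'
#' @param case_counts,control_counts genotype counts for the same variant
#'   panel: a matrix/data frame with one row per variant and columns
#'   `n_hom_ref`, `n_het`, `n_hom_alt`, or a list of length-3 vectors.
#' @param method test method, see [allelic_association_test()].
#' @param m_tests Bonferroni denominator (default 3: one combined test per
#'   phenotype).
#' @param basis `"allele"` (default, matches the reported combined odds
#'   ratios) or `"carrier"`.
#' @param level confidence level for the Woolf interval.
#' @param phenotype label carried into the result row.
#' @return one-row data frame (association result, `variant = "combined"`).
#' @export
combined_carrier_analysis <- function(case_counts, control_counts,
                                      method = c("chi2_yates", "chi2", "fisher_exact"),
                                      m_tests = 3, basis = c("allele", "carrier"),
                                      level = 0.95, phenotype = NA_character_) {
  method <- match.arg(method)
  basis <- match.arg(basis)
  ca <- normalize_panel(case_counts)
  co <- normalize_panel(control_counts)
  if (nrow(ca) != nrow(co)) stop("mismatched variant panels between cases and controls")
  n_case <- min(rowSums(ca))
  n_control <- min(rowSums(co))
  carriers_case <- sum(ca[, 2:3])
  carriers_control <- sum(co[, 2:3])
  minor_case <- sum(ca[, 2] + 2 * ca[, 3])
  minor_control <- sum(co[, 2] + 2 * co[, 3])
  tab <- if (basis == "allele") {
    table2x2(minor_case, 2 * n_case - minor_case,
             minor_control, 2 * n_control - minor_control)
  } else {
    table2x2(carriers_case, n_case - carriers_case,
             carriers_control, n_control - carriers_control)
  }
  assoc_row("combined", phenotype, basis, tab, method, m_tests, level,
            n_case = n_case, n_control = n_control,
            maf_case = minor_case / (2 * n_case),
            maf_control = minor_control / (2 * n_control),
            freq_case = carriers_case / n_case,
            freq_control = carriers_control / n_control)
}

#' Read a genotype-count table
#'
#' TSV with header and columns `cohort`, `variant`, `n_hom_ref`, `n_het`,
#' `n_hom_alt` (one row per cohort-by-variant cell).
#'
#' @param path TSV path.
#' @return validated data frame.
#' @export
read_genotype_counts <- function(path) {
  if (!file.exists(path)) stop("genotype count file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("cohort", "variant", "n_hom_ref", "n_het", "n_hom_alt")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("genotype count table ", path, " is missing column(s): ",
                         paste(miss, collapse = ", "))
  for (nm in c("n_hom_ref", "n_het", "n_hom_alt")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- is.na(v) | v < 0 | v != round(v)
    if (any(bad)) {
      stop("genotype count table ", path, " row ", which(bad)[1],
           ": invalid count in column ", nm)
    }
    df[[nm]] <- as.integer(v)
  }
  df
}

# Genotype count vector for one (cohort, variant) cell of a count table.
counts_for <- function(counts, cohort, variant) {
  row <- counts[counts$cohort == cohort & counts$variant == variant, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("expected exactly one count row for cohort ", cohort, ", variant ", variant)
  }
  c(row$n_hom_ref, row$n_het, row$n_hom_alt)
}
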