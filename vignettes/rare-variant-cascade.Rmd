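---
title: "Prioritising rare variants in multiplex pedigrees and testing them in case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising rare variants in multiplex pedigrees and testing them in case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varcascade)
```

## The analysis this package implements

Families with three or more members affected by an adult-onset complex
disease — here, inflammatory bowel disease (IBD) with its Crohn's disease
(CD) and ulcerative colitis (UC) forms — are enriched for rare, relatively
highly penetrant coding risk alleles. `varcascade` implements the two-stage
analysis built around that idea:

1. **Discovery in multiplex pedigrees.** Whole-exome variant calls from the
   affected members of each family are pushed through a filter cascade under
   a dominant model: keep variants that are *heterozygous in every sequenced
   affected member of the family* (shared alleles in distant affected
   relatives are likely identical by descent), *protein-altering* (missense,
   nonsense, frameshift, canonical splice site), and *rare* (absent or at
   allele frequency strictly below 1% in each screened reference panel).
   Finally, genes are kept only when variants surviving all per-family
   filters occur in **two or more distinct families** — recurrence across
   families is the main guard against private neutral variation.

2. **Follow-up in case-control cohorts.** Candidate variants are genotyped
   in large unrelated case and control panels and tested for association on
   the allele level; because qualifying variants are individually very rare,
   a *cumulative carrier (burden) analysis* pools the carriers of all panel
   variants into a single comparison.

Between the two stages sits the *segregation tabulation*: for each candidate
variant and family, members are cross-classified by phenotype and carrier
status, quantifying incomplete penetrance (unaffected carriers), phenocopies
(affected non-carriers), and the special case of affected non-carriers who
married into the family and therefore carry no weight in the segregation
argument.

## Statistical machinery

For a 2×2 table with cells $a$ (case minor alleles or carriers), $b$ (case
major alleles), $c$, $d$ (controls):

* **Association test.** The default is the 1-df chi-square with Yates
  continuity correction,
  $\chi^2 = N\,(|ad-bc| - N/2)^2 / \big((a+b)(c+d)(a+c)(b+d)\big)$,
  floored at zero. The uncorrected statistic and the two-sided Fisher exact
  test (summing hypergeometric tables no more probable than the observed
  one) are selectable. The continuity-corrected statistic is the default
  because, on the genotype counts of the published table this package
  re-derives, it reproduces the printed single-variant p-values; the printed
  *combined* p-values match the uncorrected statistic instead, and
  `cmd_report()` checks each printed cell against both.
* **Odds ratio.** The cross-product $ad/bc$; when a zero cell occurs, the
  Haldane–Anscombe correction adds 0.5 to every cell. Reporting truncates
  (never rounds) odds ratios to two decimals, because the published values
  this package reproduces follow truncation (4.7991 → 4.79, 2.7781 → 2.77,
  1.1857 → 1.18), whereas frequencies follow ordinary rounding.
* **Confidence interval.** Woolf's log-scale interval
  $\exp(\ln \mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$. The source report
  does not state its interval method and its printed intervals sit slightly
  below Woolf's (1.60–14.00 vs 1.64–14.05 for the strongest single-variant
  signal); Woolf is implemented and the difference is not treated as an
  error.
* **Multiple testing.** Bonferroni, $\min(1, m\,p)$, with $m = 6$ for
  single-variant runs (two variants × three phenotypes) and $m = 3$ for the
  combined analysis (one test per phenotype) — the defaults generalise to
  (variants × phenotypes) and (phenotypes) for other panels.
* **Hardy–Weinberg QC.** The exact conditional test: conditioning on the
  observed allele counts, all compatible heterozygote counts are enumerated
  through the stable log-scale recurrence
  $P(h+2)/P(h) = 4\,n_{AA}(h)\,n_{BB}(h)/((h+2)(h+1))$, and the p-value is
  the summed probability of configurations no more probable than the
  observed one (two-sided by probability mass, no mid-p). A monomorphic
  site returns $p = 1$ — note that a table such as (0, 0, n) is monomorphic
  once conditioned on its margins, so the exact test cannot flag it.

### Choices in the cascade itself

* **Strict heterozygosity.** The dominant-model filter accepts only
  heterozygous calls; homozygous-alternate calls do *not* qualify by
  default (`allow_hom_alt` relaxes this). A *missing* call in a sequenced
  affected member excludes the variant: leniency about an untyped relative
  is expressed through the sequenced flag, never through missingness, which
  would otherwise silently inflate sharing.
* **Frequency screen semantics.** Multiple reference panels are screened
  with AND semantics (a variant must be absent-or-rare in *every* source);
  this is the conservative reading when a protocol lists several panels.
  OR semantics (`frequency_rule = "any"`) is available. The threshold is
  strict: a variant at exactly 1% is removed.
* **Filter order.** Sharing → consequence → frequency, mirroring the staged
  narrative of such analyses; the two annotation-based filters are
  pointwise predicates, so the final per-family set is provably
  order-independent (and tested to be).
* **Gene identity** comes solely from the annotation table's gene column;
  there is no coordinate-overlap assignment.
* **Married-in detection** is structural: a founder (no parents in the
  pedigree) who has children with a non-founder is married-in; the
  top-generation founder couple, whose co-parents are each other, is
  bloodline. The flag can be overridden per individual.
* **Combined-analysis denominator.** Working from per-variant genotype
  counts, the per-cohort panel sample size is the *smallest* per-variant
  total — the individuals typed across the whole panel — which is exactly
  the denominator the published combined rows use (e.g. 5752 IBD cases,
  giving a combined carrier frequency of 16/5752 = 0.28%). Counts-level
  pooling assumes carrier sets are disjoint across variants, which is the
  rare-variant regime; from a full genotype matrix a multi-variant carrier
  would be counted once.

## The synthetic-data generator

No raw exomes or cohort genotypes accompany the published analysis, so the
package ships a generator that reproduces the *statistical structure* the
methods assume, at desk scale:

* **Pedigrees** grow from a founding couple over three generations (default)
  with Poisson sibships (mean 2.5) and married-in spouses — the shape of
  the published example families.
* **Gene dropping** transmits founder alleles under Mendel's law; a single
  top-generation founder introduces the family's risk variant, so carriers
  are heterozygous by construction (no inbreeding loops are generated).
* **Phenotypes** follow a penetrance/phenocopy model: carriers are affected
  with probability $f = 0.6$ (the published strongest family shows 3
  affected among 5 carriers), non-carriers with $\varphi = 0.05$ (one
  married-in phenocopy was observed among a handful of relatives).
* **Ascertainment.** Families are redrawn until they have ≥ 3 affected
  members and ≥ 2 affected carriers, mirroring how multiplex families are
  recruited; sequenced members are then chosen among the affected carriers
  (up to three, spread across the pedigree). This models the premise of the
  discovery design — the families followed up are precisely those whose
  sequenced affected members shared a variant — and it is what makes the
  cascade's recovery of a gene planted in ≥ `min_families` families
  deterministic rather than probabilistic.
* **Locus heterogeneity.** Every family carries one founder-introduced rare
  risk variant; `n_causal_families` share the configured causal gene, the
  rest carry private genes. Only the shared gene can satisfy recurrence, so
  the generator's truth record gives exact expectations for sensitivity and
  for the rejection of singleton genes.
* **Background variation**: 200 variants (a desk-scale stand-in for the
  post-sharing exome tail; genome-scale counts are out of scope) with
  log-uniform allele frequencies on $[10^{-5}, 0.5]$, a mixed consequence
  spectrum dominated by missense and synonymous changes, and 10% of them
  absent from all reference panels ("novel").
* **Cohorts** are simulated retrospectively: control carriers are binomial
  at carrier frequency $q$; case carriers use the odds transform
  $p^*/(1-p^*) = \mathrm{OR}\cdot q/(1-q)$ — no population liability model,
  matching the case-control design. CD and UC effects are independent; the
  IBD cohort is the union of the two draws. All carriers are heterozygous
  (at $q \sim 10^{-3}$ the homozygote probability $q^2$ is negligible, and
  the emulated data contain no homozygote). Genotype missingness (0.5%
  default) keeps the call rate above the 99% QC gate. Defaults use the
  published cohort sizes (2948 CD, 3077 UC, 7238 controls) and the
  recomputed per-variant odds ratios.

What the generator deliberately does **not** model: linkage
disequilibrium, genome-scale variant counts, sequencing error, relatedness
between cohort members, covariates and population structure. Passing tests
on generated data therefore validate the *logic and calibration* of the
cascade and the statistics — not robustness to the artefacts of real
sequencing data.

## Reproducibility and numerical notes

* Every stochastic routine takes a seed and is bitwise reproducible given
  it; derived seeds stay within 32-bit integer range.
* Test problem sizes are chosen for quick desk runs: the Fisher oracle
  enumerates all 2×2 tables with margins ≤ 12; the HWE oracle covers
  $n \le 200$; parameter recovery uses 500 cohort replicates and the
  type-I-error check 2000.
* The published table's own inconsistencies are treated as data, not
  targets: the CD and IBD odds ratios of the second variant recompute to
  2.49 and 1.82 (printed 2.40 and 1.80), and the printed single-variant
  case MAFs of the first variant are genotype-based rather than
  allele-based. `cmd_report()` flags these cells as known discrepancies
  rather than matching them.
* The absolute exome-stage counts of the discovery screen (tens of
  thousands of shared variants down to tens of candidates) depend on the
  raw exomes and are documented as non-reproducible; the cascade's
  bookkeeping is instead validated exactly on generated data.

## A worked example

```{r example, eval = FALSE}
library(varcascade)

# Discovery: simulate ten multiplex families, two sharing a causal gene
ds <- simulate_family_dataset(family_sim_config(seed = 1))
res <- run_cascade(ds$families, ds$annotations)
res$genes                      # the planted gene, with 2 supporting families

# Segregation in the packaged two-family fixture
peds <- read_ped(system.file("extdata", "gs_families.ped", package = "varcascade"))
gm <- read_vcf_genotypes(system.file("extdata", "nlrp7_variants.vcf",
                                     package = "varcascade"))$genotypes
tabulate_segregation(peds$GS13, gm, "19:55441902:C:T")

# Follow-up: association from the packaged genotype counts
cmd_assoc(system.file("extdata", "nlrp7_genotype_counts.tsv",
                      package = "varcascade"))
```

## Known limitations

* Only dominant-model heterozygous sharing is implemented — no recessive or
  compound-heterozygote models, no kinship inference, no linkage (LOD)
  scores.
* The association layer offers no covariate adjustment, stratification
  control or genome-wide multiple-testing machinery; it is scoped to small
  candidate panels.
* VCF support is limited to the GT field of diploid calls; structural
  variants and gVCF blocks are out of scope.
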