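---
title: "Family-based segregation analysis with famseg: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based segregation analysis with famseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famseg)
library(dplyr)
```

## The question the package answers

In multiplex late-onset familial Alzheimer's disease, common GWAS variants
individually explain little of the aggregation seen inside any one family.
`famseg` operationalises a complementary question, asked family by family:
does a *rare, damaging coding variant* at one of the known candidate loci
travel with disease through this family; failing that, is APOE ε4 the only
risk allele that does; and failing both, the family is unexplained. The
output is a per-variant segregation table, a per-family label
(`RARE_EXPLAINED` / `APOE_ONLY` / `UNEXPLAINED`), and cohort summaries.

This is deliberately *not* a statistical test. With sibship-style pedigrees,
few informative meioses, and no phase information, formal linkage or
segregation likelihoods are underpowered and fragile; the rule-based
classifier trades power calculations for a transparent, auditable
definition. No p-values, LOD scores or penetrance estimates are produced.

## The classification rule and its assumptions

A variant **segregates completely** in a family when

1. every affected member with a non-missing genotype carries it,
2. at least two affected members carry it, and
3. every unaffected carrier is at least Δ years younger than the reference
   onset age: `onset_ref − age ≥ Δ`.

Carriage is dominant (`alt_count ≥ 1`; homozygotes count as carriers),
reflecting the heterozygous transmission seen for rare high-penetrance
alleles in late-onset families. Condition 3 is what makes the rule usable in
a late-onset disease: an unaffected 62-year-old sibling carrying the variant
is *consistent* with a fully penetrant allele whose carriers fall ill around
75, while an unaffected 78-year-old carrier is evidence against it.

Assumptions worth stating plainly:

* **Affection status is taken at face value.** Uncorroborated or
  intermediate phenotypes should be coded `unaffected` or `unknown`
  upstream; `unknown` individuals are excluded from both the
  all-affected-carry test and the unaffected-carrier test, because no
  genotype rule for them can be justified from the disease model.
* **Affected members with missing (or QC-masked) genotypes are excluded**
  from condition 1 rather than counted as non-carriers; the two-carrier
  floor in condition 2 prevents a family from qualifying on a single
  genotyped affected member.
* **A family-level verdict is binary** (`COMPLETE` / `NONE`). The
  intermediate notion, *incomplete segregation*, is defined at cohort scope
  (below) and never upgrades a family to `RARE_EXPLAINED`.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `buffer` (Δ) | 5 | years | margin an unaffected carrier must be below the reference onset |
| `onset_reference` | `"carrier_mean"` | — | mean onset of affected *carriers* vs of all affected (`"family_mean"`) |
| `min_dp` / `min_gq` | 10 / 20 | reads / phred | genotype masking thresholds (mask iff DP < 10 **or** GQ < 20; the boundary call DP = 10, GQ = 20 is kept) |
| `max_missing` | 0.02 | fraction | per-site call-rate filter, strict `>` |
| `max_af` | 0.01 | fraction | gnomAD rarity bound, strict `<`; absent AF kept and flagged |
| `cadd_threshold` | 20 | phred | strict `>` for damaging missense; LoF ignores CADD |
| `min_affected` | 2 | members | family inclusion floor |
| `cross_family` | `"strict"` | — | consistency mode for carriers outside the segregating family |

Two of these encode genuinely open design choices, and both alternatives are
shipped:

* **Onset reference.** The buffer can be anchored on the mean onset of the
  affected *carriers* of the variant under test (default) or on the mean
  onset of all affected members. The two coincide whenever all affected are
  carriers — which condition 1 forces for any variant that ends up
  `COMPLETE` — so the choice matters only for rejected variants' diagnostic
  counts and for the cohort-level incomplete rule, where carriers are a
  strict subset of the affected.
* **Cross-family strictness.** When a variant is `COMPLETE` in one family
  but carried in another, strict mode demotes it if *any* unaffected member
  carries it elsewhere; lenient mode tolerates buffer-qualified unaffected
  carriers, i.e. applies the same pre-symptomatic argument across families.
  Strict is the default because the cross-family requirement is stated as
  "seen only in affected members"; lenient is arguably more internally
  consistent with the buffer rule, and a one-argument switch.

### Cohort-level incomplete segregation

Pooling all families of one cohort, a variant is `INCOMPLETE` when it has at
least four affected carriers, more affected than unaffected carriers, and
every unaffected carrier passes the buffer against **their own family's**
onset reference. The four-carrier floor keeps singleton and duo signals out;
the affected-majority condition guards against common-ish alleles drifting
through unaffected members.

### APOE ε4

ε haplotypes are defined jointly by rs429358 (T>C) and rs7412 (C>T):
C–C = ε4, T–C = ε3, T–T = ε2. All nine unphased genotype pairs resolve
uniquely except the double heterozygote, which is reported as ε2/ε4 with an
`ambiguous` flag (the alternative ε1/ε3 phase is far rarer in all surveyed
populations); a configuration option excludes ambiguous individuals instead.
The three genotype pairs that force a C–T (ε1-like) haplotype cannot be
written on the ε2/ε3/ε4 alphabet and are returned as explicitly missing
diplotypes with a warning — the mapping stays total without inventing an
allele the model does not track. ε4 segregation uses the identical
three-condition rule (carrier = ≥ 1 ε4 allele). Because ε4 is common, an
unaffected elderly ε4 carrier is unremarkable; `require_buffer = FALSE`
implements the alternative of ignoring unaffected ε4 carriers entirely, and
is left off by default so that one segregation definition serves all alleles.

### Family labels

`RARE_EXPLAINED` takes precedence: a family with a qualifying damaging
variant in complete segregation keeps that label even if ε4 also segregates
(the ε4 co-segregation is reported separately in the variant table).
`APOE_ONLY` requires ε4 segregation and no qualifying rare variant;
everything else is `UNEXPLAINED`. The three labels partition the cohort by
construction, which the tests assert.

## Linkage disequilibrium

The default LD measure is the squared Pearson correlation of alternate
allele dosages over pairwise-complete samples (`genotype_r2()`), the same
composite measure PLINK-style tools report for unphased data. It is computed
across all genotyped individuals — the cohorts *are* families, so
relatedness inflates the effective correlation slightly; a `samples`
argument allows founders-only estimates.

`em_haplotype_r2()` is the companion maximum-likelihood estimator: EM over
the four two-locus haplotype frequencies, where only the double
heterozygote's cis/trans split is latent, and
`r² = D²/(p_A q_A p_B q_B)`. With no double heterozygotes the EM fixed point
equals direct haplotype counting, which the tests check. One numerical
subtlety the test design respects: the dosage-correlation and EM estimators
are *not* finite-sample identical on arbitrary no-double-het data (and
conditioning HWE draws on "no double het" changes the distribution — we
measured a ~0.18 gap doing so). They coincide exactly when phase is trivial,
e.g. when each individual carries two copies of one haplotype, because the
binary Pearson correlation then reduces algebraically to the D̂
normalisation; the agreement test uses that construction, and the planted-
frequency recovery test covers the HWE case within sampling error.

Because no universally accepted r² cutoff defines "in LD" for a rare–common
pair, `ld_scan()` always reports the continuous r² and applies a
configurable threshold (default 0.2) only for its convenience flag.

Index-SNP co-segregation (`cosegregates_with_index()`) asks whether the
locus's common GWAS index SNP itself satisfies the complete-segregation rule
in a family where the rare variant does — a phase-free, frequency-robust
alternative to r² for family data.

## The synthetic cohort generator

`simulate_cohorts()` exists so every pipeline stage is verifiable without
access-restricted cohort data. Its defaults *are* the study conditions being
emulated: two cohorts of 197 and 214 multiplex families, 4–8 members with
2–4 affected, affected onset ~ Normal(75.2, 8.0) years, unaffected exam ages
~ Normal(71.6, 9.5), and family-label fractions 17.5% / 22.6% / 59.9%.
Per family one truth is planted; per cohort a configurable number of
incompletely segregating variants (≥ 4 affected carriers spread one per
family, fewer qualifying unaffected carriers), carried-but-non-segregating
variants, per-gene common index SNPs, and one variant pair with a planted
haplotype-frequency r² (default 0.5).

Design choices:

* **Carriers are assigned directly; Mendelian transmission is not simulated
  through the pedigree** (parent ids are cosmetic). The classifier consumes
  carrier status and ages only, so simulating meioses would add machinery
  without adding test power. Consequently the simulator cannot exercise
  Mendelian-error QC or phasing — both out of scope.
* **Unaffected carrier ages straddle the buffer boundary deliberately**
  (about a fifth land exactly on it) to exercise the `≥` comparison. Planted
  ages are floored to one decimal and then nudged down while
  `onset_ref − age < Δ` *as evaluated in doubles*: an age placed exactly on
  the boundary can otherwise fail the comparison by one ulp.
* **Planted structures are self-checked** against the classifier rule before
  the simulator returns, so an infeasible configuration fails loudly rather
  than producing silently wrong truth records.
* **QC noise** (`qc_noise`) independently injects low-DP, low-GQ and missing
  calls into the damaging-variant genotype rows; recovery of planted truth
  is exact at zero noise and degrades monotonically with the rate, which is
  regression-tested at fixed seeds.
* One annotation dialect is emitted (the package's own TSV), not VEP or
  ANNOVAR mimicry.

What passing tests on simulated data do **not** show about real data: the
generator has no population structure, no relatedness-driven LD, no
annotation disagreements between transcripts, no mosaic or somatic calls,
and its missingness is independent of genotype — so the pipeline's behaviour
under structured artefacts (batch effects, reference bias at indels) is
untested by construction.

## Numerical and degenerate-input conventions

* Percentages are rounded half away from zero to one decimal
  (`percent()`); base `round()`'s banker's rounding would print 12.4 for
  99.5/8. The reference counts shipped with the package reproduce their
  printed percentages under this rule. (One published combined partition,
  72 + 93 + 248 over 411 families, sums to 413; the counts are stored
  verbatim rather than corrected, and the arithmetic is reproduced from the
  printed integers.)
* LD on a monomorphic locus is an error in the scalar API and an `NA` row in
  `ld_scan()`, which must keep going over many pairs.
* EM runs to a `1e-8` max-change tolerance with a 1000-iteration cap;
  non-convergence is an error carrying the last estimate. Frequencies stay
  non-negative and sum to one at every iteration by construction of the
  M-step.
* A BED interval `start end` selects 1-based positions `start+1 .. end`;
  multi-allelic VCF records are split per alternate allele with genotypes
  recoded against that allele and DP/GQ copied from the original record.
* Families with no genotyped affected member yield `NONE` with
  `n_affected_genotyped = 0`, never an error, since sparse genotyping is
  routine.
* In the long genotype table, an absent (variant, sample) row means a
  confident homozygous-reference call — joint-called VCFs emit a call for
  every sample — while an explicit `NA` means missing/masked. The VCF writer
  and reader preserve this convention.

## Problem sizes used in the checks

The bundled checks run at sizes chosen to make sampling error negligible
while keeping the suite quick on a laptop: exhaustive classifier-vs-oracle
enumeration over all member-state configurations for families of 2–6
members (6 states per member, ≈ 56k families); planted-truth recovery at 500
families per cohort; LD estimator calibration at n = 10,000 individuals,
where three delta-method standard errors of r̂² ≈ 0.02.

## Known limitations

* The classifier is deterministic given its inputs; it propagates no
  uncertainty from genotype likelihoods (only the hard DP/GQ mask).
* Phenocopies and incomplete penetrance are handled only through the age
  buffer, not modelled.
* The cross-family rule treats cohorts symmetrically; site- or
  ancestry-specific error structure is invisible to it.
* gnomAD rarity uses a single AF column; population-matched AF filtering is
  a matter of supplying that column instead.
* The EM estimator handles exactly two biallelic loci; multi-locus
  haplotypes are out of scope.
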