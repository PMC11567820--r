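# Packaged reference tables: transcriptions of the published cohort-level
# results for two late-onset familial AD cohorts (a US family-based study,
# AD_FBS, and a Caribbean Hispanic study, EFIGA). Used by reporting tests
# and as a realistic default gene/index-SNP set.

#' Reference table of damaging variants by cohort
#'
#' One row per (variant, cohort): gene, chrom:pos:ref:alt key, cohort and
#' variant type for every damaging missense or LoF variant reported in the
#' two reference cohorts. Variants observed in both cohorts appear once per
#' cohort.
#'
#' @return A tibble with `gene`, `variant`, `cohort`, `variant_type`.
#' @export
ref_damaging_variants <- function() {
  readr::read_tsv(
    path_to_extdata("cohort_damaging_variants.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
}

#' Reference table of completely segregating variants
#'
#' One row per (variant, cohort) in complete segregation in at least one
#' family: counts of segregating families, affected patients and healthy
#' members in those families, APOE co-segregation, the locus's GWAS index
#' SNP and the number of family members carrying it.
#'
#' @return A tibble with `variant_type`, `cohort`, `variant`, `gene`,
#'   `families_complete`, `n_affected`, `n_healthy`, `coseg_apoe`,
#'   `index_snp`, `index_carriers`.
#' @export
ref_complete_segregation <- function() {
  readr::read_tsv(
    path_to_extdata("cohort_complete_segregation.tsv"),
    col_types = readr::cols(
      variant_type = readr::col_character(), cohort = readr::col_character(),
      variant = readr::col_character(), gene = readr::col_character(),
      families_complete = readr::col_integer(), n_affected = readr::col_integer(),
      n_healthy = readr::col_integer(), coseg_apoe = readr::col_character(),
      index_snp = readr::col_character(), index_carriers = readr::col_integer()
    )
  )
}

#' Reference cohort counts
#'
#' The printed integer counts for the two reference cohorts and their
#' combination: screened and retained families and individuals, affected /
#' unaffected members, and family explanation counts. Note that the
#' combined explanation counts (72 + 93 + 248 over 411 families) do not
#' partition exactly in the source report; they are stored verbatim rather
#' than corrected.
#'
#' @return A tibble with `cohort`, `statistic`, `value`.
#' @export
ref_cohort_counts <- function() {
  readr::read_tsv(
    path_to_extdata("cohort_reference_counts.tsv"),
    col_types = readr::cols(
      cohort = readr::col_character(), statistic = readr::col_character(),
      value = readr::col_integer()
    )
  )
}

# Convenience lookup into ref_cohort_counts().
ref_count <- function(counts, cohort, statistic) {
  v <- counts$value[counts$cohort == cohort & counts$statistic == statistic]
  if (length(v) != 1) {
    rlang::abort(paste0("reference count not found: ", cohort, "/", statistic))
  }
  v
}
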