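#' Run the full segregation pipeline over one or two cohorts
#'
#' Convenience wrapper chaining the pipeline stages: family inclusion
#' filter, genotype QC masking, site missingness filter, rarity filter,
#' damaging-variant prioritisation, per-family complete segregation,
#' cross-family consistency, cohort-level incomplete segregation, APOE
#' epsilon-4 calls and co-segregation, per-family explanation labels, the
#' per-variant report and the cohort summary.
#'
#' @param pedigree Pedigree tibble ([read_pedigree()] or simulator output).
#' @param variants Annotated variant tibble.
#' @param genotypes Long genotype tibble.
#' @param index_snps Optional tibble with `gene`, `index_variant_id`.
#' @param min_affected Family inclusion threshold (default 2).
#' @param min_dp,min_gq Genotype QC thresholds (defaults 10 / 20).
#' @param max_missing Per-site missingness bound (default 0.02).
#' @param max_af Rarity bound on gnomAD AF (default 0.01).
#' @param cadd_threshold Damaging-missense CADD cutoff (default 20).
#' @param buffer Age buffer in years (default 5).
#' @param onset_reference `"carrier_mean"` (default) or `"family_mean"`.
#' @param cross_family `"strict"` (default) or `"lenient"`, see
#'   [cross_family_consistency()].
#' @param apoe_sites APOE site keys, default [apoe_default_sites()].
#' @param require_pass Honour the VCF FILTER column (default FALSE).
#' @return A list: `pedigree` (filtered), `variants` (prioritised),
#'   `calls`, `incomplete`, `apoe_calls`, `explanations`, `report`,
#'   `summary`.
#' @export
analyze_cohorts <- function(pedigree, variants, genotypes,
                            index_snps = NULL,
                            min_affected = 2,
                            min_dp = 10, min_gq = 20,
                            max_missing = 0.02, max_af = 0.01,
                            cadd_threshold = 20,
                            buffer = 5,
                            onset_reference = c("carrier_mean", "family_mean"),
                            cross_family = c("strict", "lenient"),
                            apoe_sites = apoe_default_sites(),
                            require_pass = FALSE) {
  onset_reference <- match.arg(onset_reference)
  cross_family <- match.arg(cross_family)

  ped <- filter_families_min_affected(pedigree, min_affected = min_affected)
  geno <- suppressMessages(mask_low_quality_genotypes(genotypes, min_dp = min_dp, min_gq = min_gq))
  qc <- drop_high_missingness_sites(
    variants, geno,
    max_missing_fraction = max_missing,
    n_samples = nrow(pedigree)
  )
  vars <- qc$variants |>
    filter_pass(require_pass = require_pass) |>
    is_damaging(cadd_threshold = cadd_threshold)

  # APOE sites and index SNPs bypass the rare-damaging track.
  damaging <- vars |>
    filter(.data$damaging != "NOT_DAMAGING") |>
    filter_rare(max_af = max_af)

  calls <- segregate_cohort(
    ped, qc$genotypes,
    variant_ids = damaging$variant_id,
    buffer = buffer, onset_reference = onset_reference
  ) |>
    cross_family_consistency(
      ped, qc$genotypes,
      mode = cross_family, buffer = buffer, onset_reference = onset_reference
    )

  incomplete <- classify_cohort_incomplete(
    ped, qc$genotypes,
    variant_ids = damaging$variant_id,
    buffer = buffer, onset_reference = onset_reference
  )

  apoe <- call_apoe(ped, qc$genotypes, sites = apoe_sites)
  apoe_calls <- apoe_e4_segregation(apoe, buffer = buffer, onset_reference = onset_reference)

  calls <- cosegregates_with_apoe(calls, apoe_calls)
  if (!is.null(index_snps) && nrow(index_snps) > 0) {
    calls <- index_carriers_by_family(calls, ped, qc$genotypes, index_snps, damaging)
  }

  explanations <- classify_family_explanation(ped, calls, apoe_calls)
  report <- variant_report(calls, variants = damaging)
  summary <- summarize_cohorts(explanations, calls, damaging, pedigree = ped)

  list(
    pedigree = ped, variants = vars, calls = calls, incomplete = incomplete,
    apoe_calls = apoe_calls, explanations = explanations,
    report = report, summary = summary
  )
}
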