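#' Mask low-quality genotype calls
#'
#' Sets a genotype to missing when its depth or quality falls below threshold:
#' masked iff `DP < min_dp` or `GQ < min_gq`, evaluated only where the field
#' is present. Boundary calls with `DP = min_dp` and `GQ = min_gq` are kept.
#' Masked calls keep their row (with `alt_count = NA`) so downstream
#' missingness filters can see them.
#'
#' @param genotypes Long genotype tibble (`variant_id`, `individual_id`,
#'   `alt_count`, `dp`, `gq`).
#' @param min_dp Minimum depth of coverage (default 10).
#' @param min_gq Minimum genotype quality (default 20).
#' @return The genotype tibble with failing calls set to `NA`; the number of
#'   newly masked calls is reported via a message and stored in the
#'   `"n_masked"` attribute.
#' @export
mask_low_quality_genotypes <- function(genotypes, min_dp = 10, min_gq = 20) {
  stopifnot(min_dp >= 0, min_gq >= 0)
  fail <- (!is.na(genotypes$dp) & genotypes$dp < min_dp) |
    (!is.na(genotypes$gq) & genotypes$gq < min_gq)
  n_masked <- sum(fail & !is.na(genotypes$alt_count))
  genotypes$alt_count[fail] <- NA_integer_
  rlang::inform(paste0("masked ", n_masked, " genotype call(s) below DP/GQ thresholds"))
  attr(genotypes, "n_masked") <- n_masked
  genotypes
}

#' Drop sites with excess missing genotypes
#'
#' Removes variants whose fraction of missing genotype calls across all
#' samples is strictly greater than `max_missing_fraction` (a per-variant
#' call-rate filter; 2% by default). Apply after
#' [mask_low_quality_genotypes()] so that masked calls count as missing.
#'
#' @param variants Variant tibble.
#' @param genotypes Long genotype tibble; rows absent for a (variant, sample)
#'   pair are counted as confidently called homozygous reference, not missing.
#' @param max_missing_fraction Strict upper bound on the missing fraction.
#' @param n_samples Total number of samples; inferred from `genotypes` when
#'   `NULL`.
#' @return A list with the filtered `variants` and `genotypes` tibbles; the
#'   number of dropped sites is stored in the `"n_dropped"` attribute of
#'   `variants`.
#' @export
drop_high_missingness_sites <- function(variants, genotypes,
                                        max_missing_fraction = 0.02,
                                        n_samples = NULL) {
  n_samples <- n_samples %||% dplyr::n_distinct(genotypes$individual_id)
  miss <- genotypes |>
    group_by(.data$variant_id) |>
    summarise(n_missing = sum(is.na(.data$alt_count)), .groups = "drop") |>
    mutate(missing_fraction = .data$n_missing / n_samples)
  dropped <- miss$variant_id[miss$missing_fraction > max_missing_fraction]
  out_variants <- filter(variants, !.data$variant_id %in% dropped)
  out_genotypes <- filter(genotypes, !.data$variant_id %in% dropped)
  attr(out_variants, "n_dropped") <- length(dropped)
  list(variants = out_variants, genotypes = out_genotypes)
}

#' Per-sample missingness
#'
#' Companion diagnostic to [drop_high_missingness_sites()]: the fraction of
#' missing calls per sample, for optional sample-level exclusion.
#'
#' @param genotypes Long genotype tibble.
#' @return A tibble with `individual_id`, `n_missing`, `n_sites`,
#'   `missing_fraction`.
#' @export
sample_missingness <- function(genotypes) {
  n_sites <- dplyr::n_distinct(genotypes$variant_id)
  genotypes |>
    group_by(.data$individual_id) |>
    summarise(n_missing = sum(is.na(.data$alt_count)), .groups = "drop") |>
    mutate(n_sites = n_sites, missing_fraction = .data$n_missing / n_sites)
}

#' Keep variants that are rare in the reference population
#'
#' Retains variants with gnomAD allele frequency strictly below `max_af`
#' (default 1%). Variants with no reference frequency are kept and flagged
#' `af_absent = TRUE`: absence from the reference panel is treated as
#' unobserved-in-reference, which is consistent with rarity rather than
#' evidence against it.
#'
#' @param variants Annotated variant tibble (needs a `gnomad_af` column).
#' @param max_af Strict upper bound on the reference allele frequency.
#' @return The filtered variant tibble with an `af_absent` logical column.
#' @export
filter_rare <- function(variants, max_af = 0.01) {
  variants |>
    mutate(af_absent = is.na(.data$gnomad_af)) |>
    filter(.data$af_absent | .data$gnomad_af < max_af)
}

#' Honour the upstream FILTER column
#'
#' Optionally restricts to records whose VCF FILTER status is `PASS` (or
#' `"."`). Site-level recalibration (e.g. VQSR) happens upstream; this just
#' consumes its verdict.
#'
#' @param variants Variant tibble with a `filter_status` column.
#' @param require_pass If `TRUE`, drop non-PASS records; default `FALSE`.
#' @return The (possibly filtered) variant tibble.
#' @export
filter_pass <- function(variants, require_pass = FALSE) {
  if (!require_pass) {
    return(variants)
  }
  filter(variants, .data$filter_status %in% c("PASS", "."))
}
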