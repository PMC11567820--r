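# Per-family complete segregation, cohort-level incomplete segregation,
# cross-family consistency, and per-family explanation labels.

#' Does an unaffected carrier's age leave room for pre-symptomatic carriage?
#'
#' An unaffected carrier is tolerated in a segregating family only when they
#' are at least `buffer` years (default 5) younger than the reference onset
#' age, i.e. `reference_onset - unaffected_age >= buffer`. Someone exactly
#' `buffer` years younger qualifies. A missing age (either side) does not
#' qualify and raises a warning, since the comparison is then undefined.
#'
#' @param unaffected_age Age at last disease-free exam (years); vectorised.
#' @param reference_onset Reference onset age (years): mean onset of the
#'   affected carriers of the variant under test, or of all affected members.
#' @param buffer Required margin in years (default 5).
#' @return Logical vector.
#' @export
#' @examples
#' unaffected_qualifies(69, 75) # TRUE, 6 >= 5
#' unaffected_qualifies(71, 75) # FALSE, 4 < 5
#' unaffected_qualifies(70, 75) # TRUE, exactly 5
unaffected_qualifies <- function(unaffected_age, reference_onset, buffer = 5) {
  out <- reference_onset - unaffected_age >= buffer
  if (anyNA(out)) {
    rlang::warn("missing age in buffer comparison; treating as not qualifying")
    out[is.na(out)] <- FALSE
  }
  out
}

# Fast scalar-family core used by both the tidy wrappers and the enumeration
# tests. Plain base R on parallel vectors; one family, one variant.
seg_classify_core <- function(affection, age, dosage, buffer = 5,
                              onset_reference = c("carrier_mean", "family_mean")) {
  onset_reference <- match.arg(onset_reference)
  aff <- affection == "affected"
  una <- affection == "unaffected"
  genotyped <- !is.na(dosage)
  carrier <- genotyped & dosage >= 1

  n_aff_gen <- sum(aff & genotyped)
  n_aff_car <- sum(aff & carrier)

  ref_ages <- if (onset_reference == "carrier_mean") age[aff & carrier] else age[aff]
  ref_ages <- ref_ages[!is.na(ref_ages)]
  onset_ref <- if (length(ref_ages) > 0) mean(ref_ages) else NA_real_

  u_car <- una & carrier
  n_una_car <- sum(u_car)
  qual <- !is.na(age[u_car]) & !is.na(onset_ref) & (onset_ref - age[u_car] >= buffer)
  n_una_qual <- sum(qual)

  complete <- n_aff_gen > 0 &&
    n_aff_car == n_aff_gen &&
    n_aff_car >= 2 &&
    n_una_car == n_una_qual

  list(
    status = if (complete) "COMPLETE" else "NONE",
    n_affected_carriers = n_aff_car,
    n_affected_genotyped = n_aff_gen,
    n_unaffected_carriers = n_una_car,
    n_unaffected_carriers_qualifying = n_una_qual,
    onset_reference_age = onset_ref
  )
}

#' Classify complete segregation of one variant in one family
#'
#' A variant segregates completely in a family when (a) every affected member
#' with a non-missing genotype carries it, (b) there are at least two affected
#' carriers, and (c) every unaffected carrier is at least `buffer` years
#' younger than the reference onset age ([unaffected_qualifies()]).
#' Otherwise the family-level verdict is `NONE` (the `INCOMPLETE` label is a
#' cohort-level notion, see [classify_cohort_incomplete()]). Individuals with
#' unknown affection are excluded from both the all-affected-carry test and
#' the unaffected-carrier test; affected members with missing genotypes are
#' excluded from (a) rather than counted as non-carriers.
#'
#' @param family Pedigree tibble rows for one family.
#' @param dosages Alternate-allele dosages for the family's members: a tibble
#'   with `individual_id` and `alt_count`, or a vector named by individual
#'   id. Members absent from `dosages` are taken as genotyped non-carriers
#'   (dosage 0); an explicit `NA` encodes a missing/masked call. Carriage is
#'   dominant: `alt_count >= 1`.
#' @param buffer Age buffer in years (default 5).
#' @param onset_reference `"carrier_mean"` (default): mean onset age of the
#'   affected carriers of this variant; `"family_mean"`: mean onset age of
#'   all affected members.
#' @return A one-row tibble: `family_id`, `status`, `n_affected_carriers`,
#'   `n_affected_genotyped`, `n_unaffected_carriers`,
#'   `n_unaffected_carriers_qualifying`, `onset_reference_age`.
#' @export
classify_family_segregation <- function(family, dosages, buffer = 5,
                                        onset_reference = c("carrier_mean", "family_mean")) {
  onset_reference <- match.arg(onset_reference)
  if (dplyr::n_distinct(family$family_id) != 1) {
    rlang::abort("`family` must contain exactly one family")
  }
  if (is.data.frame(dosages)) {
    dosages <- setNames(dosages$alt_count, dosages$individual_id)
  }
  dosage <- dosages[family$individual_id]
  dosage[!family$individual_id %in% names(dosages)] <- 0L
  res <- seg_classify_core(
    as.character(family$affection), family$age_years, unname(dosage),
    buffer = buffer, onset_reference = onset_reference
  )
  tibble::tibble(
    family_id = family$family_id[1],
    cohort_id = family$cohort_id[1],
    !!!res
  )
}

#' Classify segregation for every carried (variant, family) pair
#'
#' Applies the complete-segregation rule of [classify_family_segregation()]
#' across a cohort: every pair of a variant and a family in which at least
#' one member carries it. Families without a carrier of a variant trivially
#' fail the rule and are omitted from the output.
#'
#' @param pedigree Pedigree tibble (already restricted to families passing
#'   [filter_families_min_affected()]).
#' @param genotypes Long genotype tibble, QC-masked
#'   ([mask_low_quality_genotypes()]). Members of a carrier family without a
#'   row at a site are taken as genotyped non-carriers.
#' @param variant_ids Optional character vector restricting which variants to
#'   classify (e.g. the damaging ones).
#' @inheritParams classify_family_segregation
#' @return A tibble of segregation calls, one row per (variant, family) pair
#'   with at least one carrier.
#' @export
segregate_cohort <- function(pedigree, genotypes, variant_ids = NULL, buffer = 5,
                             onset_reference = c("carrier_mean", "family_mean")) {
  onset_reference <- match.arg(onset_reference)
  if (!is.null(variant_ids)) {
    genotypes <- filter(genotypes, .data$variant_id %in% variant_ids)
  }
  carrier_families <- genotypes |>
    filter(!is.na(.data$alt_count) & .data$alt_count >= 1) |>
    inner_join(
      select(pedigree, "cohort_id", "family_id", "individual_id"),
      by = "individual_id"
    ) |>
    distinct(.data$variant_id, .data$cohort_id, .data$family_id)
  if (nrow(carrier_families) == 0) {
    return(empty_seg_calls())
  }
  grid <- carrier_families |>
    inner_join(pedigree, by = c("cohort_id", "family_id"),
      relationship = "many-to-many"
    ) |>
    left_join(
      genotypes |> select("variant_id", "individual_id", "alt_count") |> mutate(.present = TRUE),
      by = c("variant_id", "individual_id")
    ) |>
    mutate(alt_count = ifelse(is.na(.data$.present), 0L, .data$alt_count))
  seg_summarise(grid, buffer = buffer, onset_reference = onset_reference)
}

# Shared grouped computation of the three-condition rule.
seg_summarise <- function(grid, buffer, onset_reference) {
  use_carrier_mean <- onset_reference == "carrier_mean"
  grid |>
    mutate(
      aff = .data$affection == "affected",
      una = .data$affection == "unaffected",
      carrier = !is.na(.data$alt_count) & .data$alt_count >= 1
    ) |>
    group_by(.data$variant_id, .data$cohort_id, .data$family_id) |>
    summarise(
      n_affected_genotyped = sum(.data$aff & !is.na(.data$alt_count)),
      n_affected_carriers = sum(.data$aff & .data$carrier),
      onset_reference_age = {
        ages <- if (use_carrier_mean) {
          .data$age_years[.data$aff & .data$carrier]
        } else {
          .data$age_years[.data$aff]
        }
        ages <- ages[!is.na(ages)]
        if (length(ages) > 0) mean(ages) else NA_real_
      },
      n_unaffected_carriers = sum(.data$una & .data$carrier),
      n_unaffected_carriers_qualifying = sum(
        .data$una & .data$carrier & !is.na(.data$age_years) &
          !is.na(.data$onset_reference_age) &
          (.data$onset_reference_age - .data$age_years >= buffer)
      ),
      .groups = "drop"
    ) |>
    mutate(
      status = ifelse(
        .data$n_affected_genotyped > 0 &
          .data$n_affected_carriers == .data$n_affected_genotyped &
          .data$n_affected_carriers >= 2 &
          .data$n_unaffected_carriers == .data$n_unaffected_carriers_qualifying,
        "COMPLETE", "NONE"
      )
    ) |>
    relocate("status", .after = "family_id")
}

empty_seg_calls <- function() {
  tibble::tibble(
    variant_id = character(), cohort_id = character(), family_id = character(),
    status = character(), n_affected_genotyped = integer(),
    n_affected_carriers = integer(), onset_reference_age = numeric(),
    n_unaffected_carriers = integer(), n_unaffected_carriers_qualifying = integer()
  )
}

#' Cohort-level incomplete segregation
#'
#' A variant shows incomplete segregation within a cohort when, pooling all
#' of the cohort's families, it is carried by at least `min_affected_carriers`
#' (default 4) affected individuals, by more affected than unaffected
#' individuals, and every unaffected carrier passes the age buffer against
#' their own family's onset reference. This is a cohort-scope label: it never
#' upgrades a family to rare-variant-explained.
#'
#' @inheritParams segregate_cohort
#' @param min_affected_carriers Minimum pooled affected carriers (default 4).
#' @return A tibble with one row per (variant, cohort):
#'   `variant_id`, `cohort_id`, `status` (`"INCOMPLETE"` or `"NONE"`) and the
#'   pooled carrier counts.
#' @export
classify_cohort_incomplete <- function(pedigree, genotypes, variant_ids = NULL,
                                       buffer = 5,
                                       onset_reference = c("carrier_mean", "family_mean"),
                                       min_affected_carriers = 4) {
  onset_reference <- match.arg(onset_reference)
  if (!is.null(variant_ids)) {
    genotypes <- filter(genotypes, .data$variant_id %in% variant_ids)
  }
  carriers <- genotypes |>
    filter(!is.na(.data$alt_count) & .data$alt_count >= 1) |>
    inner_join(pedigree, by = "individual_id")
  if (nrow(carriers) == 0) {
    return(tibble::tibble(
      variant_id = character(), cohort_id = character(), status = character(),
      n_affected_carriers = integer(), n_unaffected_carriers = integer(),
      n_unaffected_carriers_qualifying = integer()
    ))
  }
  # Per-family onset reference for each carried variant.
  fam_ref <- carriers |>
    group_by(.data$variant_id, .data$cohort_id, .data$family_id) |>
    summarise(
      onset_ref = {
        ages <- if (onset_reference == "carrier_mean") {
          .data$age_years[.data$affection == "affected"]
        } else {
          NA_real_ # filled from the full family below
        }
        ages <- ages[!is.na(ages)]
        if (length(ages) > 0) mean(ages) else NA_real_
      },
      .groups = "drop"
    )
  if (onset_reference == "family_mean") {
    fam_means <- pedigree |>
      group_by(.data$cohort_id, .data$family_id) |>
      summarise(
        fam_onset = mean(.data$age_years[.data$affection == "affected"], na.rm = TRUE),
        .groups = "drop"
      )
    fam_ref <- fam_ref |>
      left_join(fam_means, by = c("cohort_id", "family_id")) |>
      mutate(onset_ref = ifelse(is.nan(.data$fam_onset), NA_real_, .data$fam_onset)) |>
      select(-"fam_onset")
  }
  carriers |>
    left_join(fam_ref, by = c("variant_id", "cohort_id", "family_id")) |>
    group_by(.data$variant_id, .data$cohort_id) |>
    summarise(
      n_affected_carriers = sum(.data$affection == "affected"),
      n_unaffected_carriers = sum(.data$affection == "unaffected"),
      n_unaffected_carriers_qualifying = sum(
        .data$affection == "unaffected" & !is.na(.data$age_years) &
          !is.na(.data$onset_ref) & (.data$onset_ref - .data$age_years >= buffer)
      ),
      .groups = "drop"
    ) |>
    mutate(
      status = ifelse(
        .data$n_affected_carriers >= min_affected_carriers &
          .data$n_affected_carriers > .data$n_unaffected_carriers &
          .data$n_unaffected_carriers == .data$n_unaffected_carriers_qualifying,
        "INCOMPLETE", "NONE"
      )
    ) |>
    relocate("status", .after = "cohort_id")
}

#' Cross-family consistency of qualifying variants
#'
#' A variant that segregates completely in one family but is also carried in
#' other families only remains qualifying if its carriers in those other
#' families are consistent with the disease model. In `"strict"` mode
#' (default) the variant must be seen only in affected members there; in
#' `"lenient"` mode unaffected carriers are tolerated when they pass the age
#' buffer against their family's onset reference. A violating variant is
#' demoted to `NONE` everywhere (`qualifying = FALSE`), and the demotion is
#' reported. Carriers of unknown affection are ignored in both modes.
#'
#' @param seg_calls Per-family segregation calls from [segregate_cohort()].
#' @param pedigree Pedigree tibble.
#' @param genotypes Long genotype tibble.
#' @param mode `"strict"` or `"lenient"`.
#' @param buffer Age buffer used in lenient mode.
#' @param onset_reference Onset reference used in lenient mode.
#' @return `seg_calls` with a `qualifying` logical column; demoted calls have
#'   `status = "NONE"` and `qualifying = FALSE`.
#' @export
cross_family_consistency <- function(seg_calls, pedigree, genotypes,
                                     mode = c("strict", "lenient"), buffer = 5,
                                     onset_reference = c("carrier_mean", "family_mean")) {
  mode <- match.arg(mode)
  onset_reference <- match.arg(onset_reference)
  seg_calls$qualifying <- TRUE
  complete_variants <- unique(seg_calls$variant_id[seg_calls$status == "COMPLETE"])
  if (length(complete_variants) == 0) {
    return(seg_calls)
  }

  complete_pairs <- seg_calls |>
    filter(.data$status == "COMPLETE") |>
    distinct(.data$variant_id, .data$family_id)
  carriers <- genotypes |>
    filter(.data$variant_id %in% complete_variants,
      !is.na(.data$alt_count), .data$alt_count >= 1
    ) |>
    inner_join(pedigree, by = "individual_id") |>
    anti_join(complete_pairs, by = c("variant_id", "family_id"))

  if (nrow(carriers) == 0) {
    return(seg_calls)
  }

  if (mode == "strict") {
    violations <- carriers |>
      filter(.data$affection == "unaffected") |>
      distinct(.data$variant_id)
  } else {
    fam_ref <- carriers |>
      group_by(.data$variant_id, .data$family_id) |>
      summarise(
        onset_ref = {
          ages <- if (onset_reference == "carrier_mean") {
            .data$age_years[.data$affection == "affected"]
          } else {
            .data$age_years[.data$affection == "affected"]
          }
          ages <- ages[!is.na(ages)]
          if (length(ages) > 0) mean(ages) else NA_real_
        },
        .groups = "drop"
      )
    if (onset_reference == "family_mean") {
      fam_means <- pedigree |>
        group_by(.data$family_id) |>
        summarise(
          fam_onset = mean(.data$age_years[.data$affection == "affected"], na.rm = TRUE),
          .groups = "drop"
        )
      fam_ref <- fam_ref |>
        left_join(fam_means, by = "family_id") |>
        mutate(onset_ref = ifelse(is.nan(.data$fam_onset), NA_real_, .data$fam_onset)) |>
        select(-"fam_onset")
    }
    violations <- carriers |>
      filter(.data$affection == "unaffected") |>
      left_join(fam_ref, by = c("variant_id", "family_id")) |>
      filter(is.na(.data$age_years) | is.na(.data$onset_ref) |
        .data$onset_ref - .data$age_years < buffer) |>
      distinct(.data$variant_id)
  }

  if (nrow(violations) > 0) {
    rlang::inform(paste0(
      "cross-family consistency: demoting ", nrow(violations),
      " variant(s) carried by unqualified members outside their segregating family: ",
      paste(violations$variant_id, collapse = ", ")
    ))
    demote <- seg_calls$variant_id %in% violations$variant_id
    seg_calls$status[demote] <- "NONE"
    seg_calls$qualifying[demote] <- FALSE
  }
  seg_calls
}

#' Label each family as rare-variant explained, APOE-only, or unexplained
#'
#' Precedence: a family with at least one qualifying damaging variant in
#' complete segregation is `RARE_EXPLAINED` (whether or not APOE epsilon-4
#' also segregates); otherwise, if epsilon-4 segregates it is `APOE_ONLY`;
#' otherwise `UNEXPLAINED`. The three labels partition the cohort's families.
#'
#' @param pedigree Pedigree tibble (defines the universe of families).
#' @param seg_calls Segregation calls for damaging variants (after
#'   [cross_family_consistency()] if used; calls with `qualifying = FALSE`
#'   are ignored).
#' @param apoe_calls Per-family epsilon-4 segregation calls from
#'   [apoe_e4_segregation()].
#' @return A tibble with `cohort_id`, `family_id`, `label`.
#' @export
classify_family_explanation <- function(pedigree, seg_calls, apoe_calls) {
  families <- distinct(pedigree, .data$cohort_id, .data$family_id)
  if (!"qualifying" %in% names(seg_calls)) {
    seg_calls$qualifying <- TRUE
  }
  rare <- seg_calls |>
    filter(.data$status == "COMPLETE", .data$qualifying) |>
    distinct(.data$cohort_id, .data$family_id) |>
    mutate(rare_explained = TRUE)
  apoe <- apoe_calls |>
    filter(.data$status == "COMPLETE") |>
    distinct(.data$cohort_id, .data$family_id) |>
    mutate(apoe_segregates = TRUE)
  families |>
    left_join(rare, by = c("cohort_id", "family_id")) |>
    left_join(apoe, by = c("cohort_id", "family_id")) |>
    mutate(
      label = dplyr::case_when(
        !is.na(.data$rare_explained) ~ "RARE_EXPLAINED",
        !is.na(.data$apoe_segregates) ~ "APOE_ONLY",
        .default = "UNEXPLAINED"
      )
    ) |>
    select("cohort_id", "family_id", "label")
}
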