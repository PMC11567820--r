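# Cohort summaries, percentage arithmetic, and the per-variant report table.

#' One-decimal percentage, rounded half away from zero
#'
#' `100 * numerator / denominator`, rounded to one decimal with halves away
#' from zero (so 17.45 prints as 17.5, not banker's 17.4). This is the
#' rounding rule used throughout the package's summaries.
#'
#' @param numerator,denominator Integer counts (vectorised); the denominator
#'   must be positive.
#' @return Numeric percentage(s) with one decimal.
#' @export
#' @examples
#' percent(72, 411) # 17.5
#' percent(99, 197) # 50.3
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    rlang::abort("percent() requires a positive denominator")
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Summarise family explanations per cohort and combined
#'
#' Counts families by explanation label within each cohort and pooled, with
#' one-decimal percentages ([percent()]), plus deduplicated counts of
#' completely segregating variants (by chrom:pos:ref:alt, per cohort) and of
#' their genes.
#'
#' @param explanations Output of [classify_family_explanation()].
#' @param seg_calls Optional segregation calls; used for the variant/gene
#'   counts (COMPLETE, qualifying calls only).
#' @param variants Optional variant tibble with `variant_id` and `gene`.
#' @param pedigree Optional pedigree for individual/affected counts.
#' @return A tibble of class `famseg_summary`: one row per cohort plus a
#'   `COMBINED` row.
#' @export
summarize_cohorts <- function(explanations, seg_calls = NULL, variants = NULL,
                              pedigree = NULL) {
  if (nrow(explanations) == 0) {
    rlang::warn("no families to summarise")
  }
  per_cohort <- explanations |>
    group_by(.data$cohort_id) |>
    summarise(
      n_families = dplyr::n(),
      n_families_rare_explained = sum(.data$label == "RARE_EXPLAINED"),
      n_families_apoe_only = sum(.data$label == "APOE_ONLY"),
      n_families_unexplained = sum(.data$label == "UNEXPLAINED"),
      .groups = "drop"
    )
  combined <- per_cohort |>
    summarise(
      cohort_id = "COMBINED",
      dplyr::across(dplyr::starts_with("n_"), sum)
    )
  out <- bind_rows(per_cohort, combined) |>
    mutate(
      pct_rare_explained = ifelse(.data$n_families > 0,
        percent(.data$n_families_rare_explained, pmax(.data$n_families, 1)), NA_real_
      ),
      pct_apoe_only = ifelse(.data$n_families > 0,
        percent(.data$n_families_apoe_only, pmax(.data$n_families, 1)), NA_real_
      ),
      pct_unexplained = ifelse(.data$n_families > 0,
        percent(.data$n_families_unexplained, pmax(.data$n_families, 1)), NA_real_
      )
    )

  if (!is.null(pedigree)) {
    ind <- pedigree |>
      group_by(.data$cohort_id) |>
      summarise(
        n_individuals = dplyr::n(),
        n_affected = sum(.data$affection == "affected"),
        n_unaffected = sum(.data$affection == "unaffected"),
        .groups = "drop"
      )
    ind <- bind_rows(ind, summarise(
      ind,
      cohort_id = "COMBINED", dplyr::across(dplyr::starts_with("n_"), sum)
    ))
    out <- left_join(out, ind, by = "cohort_id")
  }

  if (!is.null(seg_calls)) {
    calls <- seg_calls |> filter(.data$status == "COMPLETE")
    if ("qualifying" %in% names(calls)) calls <- filter(calls, .data$qualifying)
    if (!is.null(variants)) {
      calls <- left_join(calls, select(variants, "variant_id", "gene"), by = "variant_id")
    } else {
      calls$gene <- NA_character_
    }
    vc <- calls |>
      group_by(.data$cohort_id) |>
      summarise(
        n_variants_complete = dplyr::n_distinct(.data$variant_id),
        n_genes_complete = dplyr::n_distinct(.data$gene[!is.na(.data$gene)]),
        n_families_with_complete = dplyr::n_distinct(.data$family_id),
        .groups = "drop"
      )
    vc <- bind_rows(vc, tibble::tibble(
      cohort_id = "COMBINED",
      n_variants_complete = dplyr::n_distinct(calls$variant_id),
      n_genes_complete = dplyr::n_distinct(calls$gene[!is.na(calls$gene)]),
      n_families_with_complete = dplyr::n_distinct(paste(calls$cohort_id, calls$family_id))
    ))
    out <- left_join(out, vc, by = "cohort_id") |>
      mutate(dplyr::across(
        c("n_variants_complete", "n_genes_complete", "n_families_with_complete"),
        ~ dplyr::coalesce(.x, 0L)
      ))
  }

  class(out) <- c("famseg_summary", class(out))
  out
}

#' Distinct completely segregating variants per cohort
#'
#' Deduplicates a (variant, cohort) table on the variant key and counts
#' variants and gene symbols per cohort. A variant present in both cohorts
#' counts once in each.
#'
#' @param variant_table Tibble with `variant` (chrom:pos:ref:alt key),
#'   `cohort` and `gene` columns, e.g. [ref_damaging_variants()].
#' @return A tibble with `cohort`, `n_variants`, `n_genes`.
#' @export
count_distinct_variants <- function(variant_table) {
  variant_table |>
    distinct(.data$cohort, .data$variant, .keep_all = TRUE) |>
    group_by(.data$cohort) |>
    summarise(
      n_variants = dplyr::n(),
      n_genes = dplyr::n_distinct(.data$gene),
      .groups = "drop"
    )
}

#' Per-variant report of complete segregation
#'
#' One row per (variant, cohort) among COMPLETE, qualifying calls: the
#' number of families in which the variant completely segregates, the summed
#' affected carriers and (qualifying) unaffected carriers in those families,
#' whether it co-segregates with APOE epsilon-4 in any of them, and the
#' locus's index SNP with the summed index-SNP carrier count. Row order is
#' deterministic: chromosome, position, alt, cohort.
#'
#' @param seg_calls Segregation calls, ideally after
#'   [cosegregates_with_apoe()] (a `coseg_apoe` column) and
#'   [index_carriers_by_family()] (`index_variant_id`, `n_index_carriers`).
#' @param variants Optional variant tibble contributing `gene` and the
#'   consequence-derived `variant_type`.
#' @return A tibble with columns `variant`, `gene`, `variant_type`,
#'   `cohort`, `families_complete`, `n_affected_in_segregating_families`,
#'   `n_healthy_in_segregating_families`, `coseg_apoe`, `index_snp`,
#'   `n_index_carriers`.
#' @export
variant_report <- function(seg_calls, variants = NULL) {
  calls <- seg_calls |> filter(.data$status == "COMPLETE")
  if ("qualifying" %in% names(calls)) calls <- filter(calls, .data$qualifying)
  if (!"coseg_apoe" %in% names(calls)) calls$coseg_apoe <- NA
  if (!"index_variant_id" %in% names(calls)) calls$index_variant_id <- NA_character_
  if (!"n_index_carriers" %in% names(calls)) calls$n_index_carriers <- NA_integer_

  out <- calls |>
    group_by(.data$variant_id, .data$cohort_id) |>
    summarise(
      families_complete = dplyr::n(),
      n_affected_in_segregating_families = sum(.data$n_affected_carriers),
      n_healthy_in_segregating_families = sum(.data$n_unaffected_carriers),
      coseg_apoe = any(.data$coseg_apoe %in% TRUE),
      index_snp = dplyr::first(.data$index_variant_id[!is.na(.data$index_variant_id)], default = NA_character_),
      n_index_carriers = if (all(is.na(.data$n_index_carriers))) NA_integer_ else
        sum(.data$n_index_carriers, na.rm = TRUE),
      .groups = "drop"
    )
  if (!is.null(variants)) {
    ann <- variants |> select(dplyr::any_of(c("variant_id", "gene", "damaging", "consequence_class")))
    out <- left_join(out, ann, by = "variant_id") |>
      mutate(variant_type = dplyr::case_when(
        .data$consequence_class %in% lof_classes ~ "LoF",
        .data$consequence_class == "missense" ~ "Damaging missense (CADD > 20)",
        .default = NA_character_
      )) |>
      select(-dplyr::any_of(c("damaging", "consequence_class")))
  } else {
    out$gene <- NA_character_
    out$variant_type <- NA_character_
  }
  coords <- parse_variant_key(out$variant_id)
  out |>
    mutate(.rank = chrom_rank(coords$chrom), .pos = coords$pos, .alt = coords$alt) |>
    arrange(.data$.rank, .data$.pos, .data$.alt, .data$cohort_id) |>
    select(
      variant = "variant_id", "gene", "variant_type", cohort = "cohort_id",
      "families_complete", "n_affected_in_segregating_families",
      "n_healthy_in_segregating_families", "coseg_apoe", "index_snp",
      "n_index_carriers"
    )
}

#' Write the per-variant report as TSV
#' @param report Output of [variant_report()].
#' @param path Output file path.
#' @return `report`, invisibly.
#' @export
write_variant_report <- function(report, path) {
  readr::write_tsv(report, path)
  invisible(report)
}
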