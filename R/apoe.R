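# APOE epsilon-2/3/4 diplotype calling from rs429358 + rs7412, and
# epsilon-4 segregation / co-segregation.

#' Default APOE site definitions (GRCh38)
#'
#' Configuration constants, overridable in every APOE function:
#' rs429358 chr19:44908684 T>C and rs7412 chr19:44908822 C>T.
#' @return Named list with `rs429358` and `rs7412` variant keys.
#' @export
apoe_default_sites <- function() {
  list(
    rs429358 = "chr19:44908684:T:C",
    rs7412 = "chr19:44908822:C:T"
  )
}

#' Call APOE diplotypes from the two coding SNPs
#'
#' The epsilon haplotypes are defined jointly: rs429358-C with rs7412-C is
#' epsilon-4, T with C is epsilon-3, T with T is epsilon-2. From unphased
#' genotypes every combination resolves uniquely except the double
#' heterozygote, which is returned as e2/e4 with `ambiguous = TRUE` (the
#' e1/e3 phase is far rarer in every surveyed population). Genotype pairs
#' that force a C-T (epsilon-1-like) haplotype cannot be expressed on the
#' e2/e3/e4 alphabet and are returned with missing alleles and a warning.
#'
#' @param rs429358_alt Count of C (alternate) alleles at rs429358: 0, 1, 2
#'   or NA; vectorised.
#' @param rs7412_alt Count of T (alternate) alleles at rs7412.
#' @return A tibble with `allele1`, `allele2` (sorted, from `"e2" < "e3" <
#'   "e4"`), `ambiguous`, and `e4_count` (NA when the diplotype is unknown).
#' @export
#' @examples
#' call_apoe_diplotype(2, 0) # e4/e4
#' call_apoe_diplotype(0, 0) # e3/e3
#' call_apoe_diplotype(1, 1) # e2/e4, ambiguous
call_apoe_diplotype <- function(rs429358_alt, rs7412_alt) {
  n <- max(length(rs429358_alt), length(rs7412_alt))
  c4 <- rep_len(as.integer(rs429358_alt), n)
  t2 <- rep_len(as.integer(rs7412_alt), n)

  allele1 <- rep(NA_character_, n)
  allele2 <- rep(NA_character_, n)
  ambiguous <- rep(FALSE, n)
  e4_count <- rep(NA_integer_, n)

  known <- !is.na(c4) & !is.na(t2)
  expressible <- known & (c4 + t2 <= 2)
  if (any(known & !expressible)) {
    rlang::warn(paste0(
      sum(known & !expressible),
      " genotype pair(s) force an epsilon-1-like C-T haplotype; diplotype set to unknown"
    ))
  }
  idx <- which(expressible)
  for (i in idx) {
    alleles <- c(rep("e4", c4[i]), rep("e2", t2[i]), rep("e3", 2 - c4[i] - t2[i]))
    alleles <- sort(alleles)
    allele1[i] <- alleles[1]
    allele2[i] <- alleles[2]
    e4_count[i] <- c4[i]
  }
  ambiguous[expressible & c4 == 1 & t2 == 1] <- TRUE

  if (any(!known)) {
    rlang::warn(paste0(
      sum(!known), " individual(s) with a missing APOE genotype excluded from epsilon-4 logic"
    ))
  }
  tibble::tibble(
    allele1 = allele1, allele2 = allele2,
    ambiguous = ambiguous, e4_count = e4_count
  )
}

#' Call APOE diplotypes for every pedigree member
#'
#' Looks up the rs429358 and rs7412 genotypes in the long genotype table and
#' calls the diplotype per individual. Members without a row at a site are
#' taken as homozygous reference there; an explicit `NA` genotype makes the
#' diplotype unknown.
#'
#' @param pedigree Pedigree tibble.
#' @param genotypes Long genotype tibble containing the two APOE sites.
#' @param sites Named list with `rs429358` and `rs7412` variant keys,
#'   default [apoe_default_sites()].
#' @param exclude_ambiguous If `TRUE`, double heterozygotes are set to
#'   unknown instead of e2/e4.
#' @return The pedigree joined with `allele1`, `allele2`, `ambiguous`,
#'   `e4_count` and logical `e4_carrier`.
#' @export
call_apoe <- function(pedigree, genotypes, sites = apoe_default_sites(),
                      exclude_ambiguous = FALSE) {
  lookup <- function(site) {
    g <- genotypes |>
      filter(.data$variant_id == site) |>
      select("individual_id", "alt_count")
    out <- g$alt_count[match(pedigree$individual_id, g$individual_id)]
    out[!pedigree$individual_id %in% g$individual_id] <- 0L
    out
  }
  dip <- call_apoe_diplotype(lookup(sites$rs429358), lookup(sites$rs7412))
  if (exclude_ambiguous) {
    dip$allele1[dip$ambiguous] <- NA_character_
    dip$allele2[dip$ambiguous] <- NA_character_
    dip$e4_count[dip$ambiguous] <- NA_integer_
  }
  bind_cols(pedigree, dip) |>
    mutate(e4_carrier = !is.na(.data$e4_count) & .data$e4_count >= 1)
}

#' APOE epsilon-4 segregation per family
#'
#' Applies the same three-condition rule as rare variants
#' ([classify_family_segregation()]) with carrier defined as at least one
#' epsilon-4 allele: all genotyped affected members carry, at least two
#' affected carriers, and unaffected carriers pass the age buffer. Because
#' epsilon-4 is common, `require_buffer = FALSE` offers the alternative of
#' ignoring unaffected epsilon-4 carriers entirely.
#'
#' @param apoe Output of [call_apoe()] (pedigree + diplotypes).
#' @param buffer Age buffer in years.
#' @param onset_reference `"carrier_mean"` or `"family_mean"`, as in
#'   [classify_family_segregation()].
#' @param require_buffer If `FALSE`, condition (c) is dropped: unaffected
#'   epsilon-4 carriers never block segregation.
#' @return A tibble of per-family calls with `variant_id = "APOE_e4"`.
#' @export
apoe_e4_segregation <- function(apoe, buffer = 5,
                                onset_reference = c("carrier_mean", "family_mean"),
                                require_buffer = TRUE) {
  onset_reference <- match.arg(onset_reference)
  grid <- apoe |>
    mutate(variant_id = "APOE_e4", alt_count = .data$e4_count)
  calls <- seg_summarise(grid, buffer = buffer, onset_reference = onset_reference)
  if (!require_buffer) {
    calls <- calls |>
      mutate(status = ifelse(
        .data$n_affected_genotyped > 0 &
          .data$n_affected_carriers == .data$n_affected_genotyped &
          .data$n_affected_carriers >= 2,
        "COMPLETE", "NONE"
      ))
  }
  calls
}

#' Does a variant co-segregate with APOE epsilon-4?
#'
#' True for a family exactly when both the rare variant and epsilon-4 are in
#' complete segregation there.
#'
#' @param seg_calls Per-family variant segregation calls.
#' @param apoe_calls Per-family epsilon-4 calls from [apoe_e4_segregation()].
#' @return `seg_calls` with a logical `coseg_apoe` column.
#' @export
cosegregates_with_apoe <- function(seg_calls, apoe_calls) {
  apoe_complete <- apoe_calls |>
    filter(.data$status == "COMPLETE") |>
    distinct(.data$cohort_id, .data$family_id) |>
    mutate(.apoe_complete = TRUE)
  seg_calls |>
    left_join(apoe_complete, by = c("cohort_id", "family_id")) |>
    mutate(coseg_apoe = .data$status == "COMPLETE" & !is.na(.data$.apoe_complete)) |>
    select(-".apoe_complete")
}
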