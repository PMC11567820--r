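#' Read a pedigree with age-at-onset phenotypes
#'
#' Reads a whitespace-delimited PED/FAM file (six leading columns: family id,
#' individual id, father id, mother id, sex, phenotype) together with a
#' phenotype TSV holding affection status and ages. The age is interpreted as
#' age at onset for affected individuals and age at the last dementia-free
#' examination for unaffected individuals.
#'
#' When a phenotype table is supplied, its affection codes override the PED
#' 6th column (PED has no age fields). Individuals present in the PED but
#' missing from the phenotype table are kept with `affection = "unknown"`.
#' Without a phenotype table, PED codes are used (2 = affected,
#' 1 = unaffected, 0/-9 = unknown) and ages are missing.
#'
#' @param ped_path Path to a PED/FAM file. Founders carry parent id `"0"`.
#' @param phenotype_path Optional path to a TSV with header columns
#'   `family_id`, `individual_id`, `affection` (`affected` / `unaffected` /
#'   `unknown`), `age_years`.
#' @param cohort_id Cohort label attached to every individual.
#'
#' @return A tibble with one row per individual: `cohort_id`, `family_id`,
#'   `individual_id`, `father_id`, `mother_id`, `sex`, `affection`,
#'   `age_years`.
#' @export
#' @examples
#' ped <- tempfile(fileext = ".fam")
#' writeLines(c("F1 A 0 0 1 2", "F1 B 0 0 2 1"), ped)
#' phe <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "family_id\tindividual_id\taffection\tage_years",
#'   "F1\tA\taffected\t74", "F1\tB\tunaffected\t68"
#' ), phe)
#' read_pedigree(ped, phe, cohort_id = "demo")
read_pedigree <- function(ped_path, phenotype_path = NULL, cohort_id = "cohort") {
  ped_raw <- utils::read.table(
    ped_path,
    header = FALSE, colClasses = "character",
    col.names = c("family_id", "individual_id", "father_id", "mother_id", "sex", "ped_pheno"),
    fill = FALSE
  )
  ped <- tibble::as_tibble(ped_raw) |>
    mutate(
      sex = dplyr::case_match(.data$sex, "1" ~ "male", "2" ~ "female", .default = "unknown"),
      affection = dplyr::case_match(
        .data$ped_pheno,
        "2" ~ "affected", "1" ~ "unaffected", .default = "unknown"
      ),
      age_years = NA_real_
    ) |>
    select(-"ped_pheno")

  if (!is.null(phenotype_path)) {
    phe <- readr::read_tsv(
      phenotype_path,
      col_types = readr::cols(
        family_id = readr::col_character(),
        individual_id = readr::col_character(),
        affection = readr::col_character(),
        age_years = readr::col_character()
      )
    )
    age <- suppressWarnings(as.numeric(phe$age_years))
    bad_age <- which(!is.na(phe$age_years) & phe$age_years != "" & is.na(age))
    if (length(bad_age) > 0) {
      rlang::abort(paste0(
        "unparseable age_years in phenotype row(s) ",
        paste(bad_age, collapse = ", "), " (individual ",
        paste(phe$individual_id[bad_age], collapse = ", "), ")"
      ))
    }
    phe$age_years <- age
    ped <- ped |>
      select(-"affection", -"age_years") |>
      left_join(phe, by = c("family_id", "individual_id")) |>
      mutate(affection = dplyr::coalesce(.data$affection, "unknown"))
  }

  out <- ped |>
    mutate(cohort_id = cohort_id, .before = 1) |>
    mutate(affection = factor(.data$affection, levels = c("affected", "unaffected", "unknown")))
  validate_pedigree(out)
  out
}

#' Validate a pedigree tibble
#'
#' Checks the structural invariants of the pedigree representation:
#' unique (family, individual) pairs, ages within `[0, 130]`, an age present
#' for every affected individual, and parent ids that are either the founder
#' marker `"0"` or refer to a member of the same family.
#'
#' @param pedigree A pedigree tibble as returned by [read_pedigree()].
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_pedigree <- function(pedigree) {
  dup <- pedigree |> count(.data$family_id, .data$individual_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    rlang::abort(paste0(
      "duplicate individual id(s) within family: ",
      paste(paste(dup$family_id, dup$individual_id, sep = "/"), collapse = ", ")
    ))
  }
  bad <- which(!is.na(pedigree$age_years) &
    (pedigree$age_years < 0 | pedigree$age_years > 130))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "age_years outside [0, 130] for row(s) ", paste(bad, collapse = ", "),
      " (individual ", paste(pedigree$individual_id[bad], collapse = ", "), ")"
    ))
  }
  no_age <- which(pedigree$affection == "affected" & is.na(pedigree$age_years))
  if (length(no_age) > 0) {
    rlang::abort(paste0(
      "affected individual(s) without age at onset: ",
      paste(pedigree$individual_id[no_age], collapse = ", ")
    ))
  }
  members <- split(pedigree$individual_id, pedigree$family_id)
  for (fid in names(members)) {
    fam <- pedigree[pedigree$family_id == fid, ]
    parents <- setdiff(unique(c(fam$father_id, fam$mother_id)), "0")
    orphan <- setdiff(parents, members[[fid]])
    if (length(orphan) > 0) {
      rlang::abort(paste0(
        "family ", fid, ": parent id(s) not found among members: ",
        paste(orphan, collapse = ", ")
      ))
    }
  }
  invisible(pedigree)
}

#' Write a pedigree back to PED/FAM + phenotype TSV
#'
#' Inverse of [read_pedigree()]; `read_pedigree(write_pedigree(...))`
#' reproduces the tibble field for field.
#'
#' @param pedigree A pedigree tibble.
#' @param ped_path Output PED/FAM path.
#' @param phenotype_path Output phenotype TSV path.
#' @return The input pedigree, invisibly.
#' @export
write_pedigree <- function(pedigree, ped_path, phenotype_path) {
  fam <- pedigree |>
    mutate(
      sex_code = dplyr::case_match(as.character(.data$sex), "male" ~ "1", "female" ~ "2", .default = "0"),
      pheno_code = dplyr::case_match(
        as.character(.data$affection),
        "affected" ~ "2", "unaffected" ~ "1", .default = "0"
      )
    )
  writeLines(
    paste(fam$family_id, fam$individual_id, fam$father_id, fam$mother_id,
      fam$sex_code, fam$pheno_code,
      sep = " "
    ),
    ped_path
  )
  pedigree |>
    select("family_id", "individual_id", "affection", "age_years") |>
    mutate(affection = as.character(.data$affection)) |>
    readr::write_tsv(phenotype_path)
  invisible(pedigree)
}

#' Keep only families with enough affected members
#'
#' Restricts a cohort to multiplex families: those with at least
#' `min_affected` members whose affection status is `affected`. Members of
#' retained families are untouched. The default of 2 reflects the usual
#' entry criterion for family-based late-onset studies.
#'
#' @param pedigree A pedigree tibble.
#' @param min_affected Minimum number of affected members (>= 1).
#' @return The filtered pedigree tibble.
#' @export
filter_families_min_affected <- function(pedigree, min_affected = 2) {
  stopifnot(min_affected >= 1)
  keep <- pedigree |>
    group_by(.data$cohort_id, .data$family_id) |>
    summarise(n_affected = sum(.data$affection == "affected", na.rm = TRUE), .groups = "drop") |>
    filter(.data$n_affected >= min_affected) |>
    select("cohort_id", "family_id")
  semi_join(pedigree, keep, by = c("cohort_id", "family_id"))
}

#' Mean age at onset per family
#'
#' Arithmetic mean of the onset ages of affected members, by family.
#' Unaffected and unknown members are ignored. Families with no affected
#' member with a recorded onset age raise an error, since the quantity is
#' undefined for them.
#'
#' @param pedigree A pedigree tibble (one or more families).
#' @return A tibble with `cohort_id`, `family_id`, `mean_onset`.
#' @export
mean_onset_age <- function(pedigree) {
  out <- pedigree |>
    group_by(.data$cohort_id, .data$family_id) |>
    summarise(
      mean_onset = mean(.data$age_years[.data$affection == "affected"], na.rm = FALSE),
      n_affected = sum(.data$affection == "affected"),
      .groups = "drop"
    )
  bad <- out |> filter(.data$n_affected == 0 | is.na(.data$mean_onset))
  if (nrow(bad) > 0) {
    rlang::abort(paste0(
      "mean onset age undefined (no affected member with an onset age) for family: ",
      paste(bad$family_id, collapse = ", ")
    ))
  }
  select(out, -"n_affected")
}
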