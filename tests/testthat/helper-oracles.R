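# Independent oracles and fixture builders used across the test files.

# Literal brute-force re-implementation of the family segregation rule,
# written as a plain loop over members and kept independent of the package's
# vectorised classifier.
brute_force_segregation <- function(affection, age, dosage, buffer = 5,
                                    onset_reference = "carrier_mean") {
  n_aff_gen <- 0
  n_aff_car <- 0
  carrier_onsets <- c()
  affected_onsets <- c()
  for (i in seq_along(affection)) {
    if (affection[i] == "affected") {
      if (!is.na(age[i])) affected_onsets <- c(affected_onsets, age[i])
      if (!is.na(dosage[i])) {
        n_aff_gen <- n_aff_gen + 1
        if (dosage[i] >= 1) {
          n_aff_car <- n_aff_car + 1
          if (!is.na(age[i])) carrier_onsets <- c(carrier_onsets, age[i])
        }
      }
    }
  }
  ref_pool <- if (onset_reference == "carrier_mean") carrier_onsets else affected_onsets
  onset_ref <- if (length(ref_pool) > 0) mean(ref_pool) else NA

  all_unaffected_ok <- TRUE
  n_una_car <- 0
  n_una_qual <- 0
  for (i in seq_along(affection)) {
    if (affection[i] == "unaffected" && !is.na(dosage[i]) && dosage[i] >= 1) {
      n_una_car <- n_una_car + 1
      ok <- !is.na(age[i]) && !is.na(onset_ref) && (onset_ref - age[i] >= buffer)
      if (ok) n_una_qual <- n_una_qual + 1 else all_unaffected_ok <- FALSE
    }
  }

  status <- if (n_aff_gen > 0 && n_aff_car == n_aff_gen && n_aff_car >= 2 && all_unaffected_ok) {
    "COMPLETE"
  } else {
    "NONE"
  }
  list(
    status = status,
    n_affected_carriers = n_aff_car,
    n_affected_genotyped = n_aff_gen,
    n_unaffected_carriers = n_una_car,
    n_unaffected_carriers_qualifying = n_una_qual
  )
}

# Direct Pearson r^2 from raw sums (no stats::cor), the LD oracle.
pearson_r2_oracle <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  (num / den)^2
}

# Member state space for exhaustive segregation enumeration. Affected onset
# ages cycle 78/80/82 by position so the carrier-mean reference varies with
# which affected members carry; the unaffected ages are chosen so that 65
# always qualifies (max reference 82, 82-65 >= 5) and 79 never does
# (78..82 - 79 < 5).
member_state <- function(state, position) {
  onset <- c(78, 80, 82)[(position %% 3) + 1]
  switch(state,
    ac = list(affection = "affected", age = onset, dosage = 1),
    an = list(affection = "affected", age = onset, dosage = 0),
    am = list(affection = "affected", age = onset, dosage = NA),
    uqc = list(affection = "unaffected", age = 65, dosage = 1),
    unc = list(affection = "unaffected", age = 79, dosage = 1),
    u0 = list(affection = "unaffected", age = 72, dosage = 0)
  )
}

build_family_from_states <- function(states) {
  members <- lapply(seq_along(states), function(i) member_state(states[i], i))
  list(
    affection = vapply(members, `[[`, character(1), "affection"),
    age = vapply(members, function(m) as.numeric(m$age), numeric(1)),
    dosage = vapply(members, function(m) as.numeric(m$dosage), numeric(1))
  )
}

# Small pedigree builder for hand-constructed families.
make_family <- function(family_id, affection, age, cohort_id = "TEST") {
  n <- length(affection)
  tibble::tibble(
    cohort_id = cohort_id,
    family_id = family_id,
    individual_id = sprintf("%s_I%02d", family_id, seq_len(n)),
    father_id = "0", mother_id = "0",
    sex = rep(c("male", "female"), length.out = n),
    affection = affection,
    age_years = age
  )
}

# Long genotype rows for one variant in one family.
make_genotypes <- function(family, variant_id, dosage, dp = 30, gq = 99) {
  tibble::tibble(
    variant_id = variant_id,
    individual_id = family$individual_id,
    alt_count = as.integer(dosage),
    dp = rep_len(dp, nrow(family)),
    gq = rep_len(gq, nrow(family))
  )
}

# Minimal VCF writer for I/O tests.
write_test_vcf <- function(path, records, samples) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", samples),
      collapse = "\t"
    )
  )
  writeLines(c(header, records), path)
  path
}
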