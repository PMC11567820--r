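# The three-condition complete-segregation rule, cohort-level incomplete
# segregation, cross-family consistency and family explanation labels.

test_that("age buffer comparison is inclusive at exactly the buffer", {
  expect_true(unaffected_qualifies(69, 75))
  expect_false(unaffected_qualifies(71, 75))
  expect_true(unaffected_qualifies(70, 75)) # exactly 5 years younger
  expect_warning(res <- unaffected_qualifies(NA, 75), "missing age")
  expect_false(res)
})

test_that("family-level rule: all affected carry, >=2 carriers, buffered unaffected", {
  fam3 <- make_family("F1", rep(c("affected", "unaffected"), c(3, 1)), c(74, 76, 78, 60))
  # 3/3 affected carry, unaffected does not: COMPLETE
  call <- classify_family_segregation(fam3, make_genotypes(fam3, "v", c(1, 1, 1, 0)))
  expect_equal(call$status, "COMPLETE")
  expect_equal(call$n_affected_carriers, 3L)
  expect_equal(call$n_unaffected_carriers, 0L)

  # 2/3 genotyped affected carry: violates "all affected"
  call <- classify_family_segregation(fam3, make_genotypes(fam3, "v", c(1, 1, 0, 0)))
  expect_equal(call$status, "NONE")

  # unaffected carrier 72 vs carrier-mean onset 75: buffer 3 < 5 fails
  fam2 <- make_family("F2", c("affected", "affected", "unaffected"), c(74, 76, 72))
  call <- classify_family_segregation(fam2, make_genotypes(fam2, "v", c(1, 1, 1)))
  expect_equal(call$status, "NONE")
  expect_equal(call$n_unaffected_carriers, 1L)
  expect_equal(call$n_unaffected_carriers_qualifying, 0L)

  # a single affected carrier is never enough
  fam1 <- make_family("F3", c("affected", "unaffected"), c(74, 60))
  call <- classify_family_segregation(fam1, make_genotypes(fam1, "v", c(1, 0)))
  expect_equal(call$status, "NONE")

  # affected member with a masked genotype is excluded from condition (a)
  call <- classify_family_segregation(fam3, make_genotypes(fam3, "v", c(1, 1, NA, 0)))
  expect_equal(call$status, "COMPLETE")
  expect_equal(call$n_affected_genotyped, 2L)

  # no genotyped affected member at all
  call <- classify_family_segregation(fam3, make_genotypes(fam3, "v", c(NA, NA, NA, 1)))
  expect_equal(call$status, "NONE")
  expect_equal(call$n_affected_genotyped, 0L)
})

test_that("onset reference switches between carrier mean and family mean", {
  # affected: carrier at 80, non-genotyped at 60 -> carrier mean 80, family mean 70
  fam <- make_family("F1", c("affected", "affected", "affected", "unaffected"),
    c(80, 80, 60, 73)
  )
  g <- make_genotypes(fam, "v", c(1, 1, NA, 1))
  # carrier mean 80: 80 - 73 = 7 >= 5 qualifies -> COMPLETE
  expect_equal(classify_family_segregation(fam, g)$status, "COMPLETE")
  # family mean (80+80+60)/3 = 73.33: 0.33 < 5 -> NONE
  expect_equal(
    classify_family_segregation(fam, g, onset_reference = "family_mean")$status,
    "NONE"
  )
})

test_that("classifier matches the brute-force oracle on enumerated small families", {
  states <- c("ac", "an", "am", "uqc", "unc", "u0")
  for (size in 2:4) {
    grid <- do.call(expand.grid, c(rep(list(states), size), stringsAsFactors = FALSE))
    for (r in seq_len(nrow(grid))) {
      fam <- build_family_from_states(unlist(grid[r, ]))
      got <- famseg:::seg_classify_core(fam$affection, fam$age, fam$dosage)
      want <- brute_force_segregation(fam$affection, fam$age, fam$dosage)
      expect_identical(got$status, want$status)
      expect_identical(got$n_affected_carriers, as.integer(want$n_affected_carriers))
      expect_identical(got$n_unaffected_carriers, as.integer(want$n_unaffected_carriers))
    }
  }
})

test_that("adding members respects monotonicity of the COMPLETE verdict", {
  set.seed(21)
  states <- c("ac", "an", "am", "uqc", "unc", "u0")
  for (i in 1:200) {
    size <- sample(2:5, 1)
    base <- sample(states, size, TRUE)
    fam <- build_family_from_states(base)
    got <- famseg:::seg_classify_core(fam$affection, fam$age, fam$dosage)

    # adding an affected non-carrier can never create COMPLETE
    plus_nc <- build_family_from_states(c(base, "an"))
    got_nc <- famseg:::seg_classify_core(plus_nc$affection, plus_nc$age, plus_nc$dosage)
    if (got$status == "NONE") expect_equal(got_nc$status, "NONE")

    # adding an affected carrier can never destroy COMPLETE
    plus_c <- build_family_from_states(c(base, "ac"))
    got_c <- famseg:::seg_classify_core(plus_c$affection, plus_c$age, plus_c$dosage)
    if (got$status == "COMPLETE") expect_equal(got_c$status, "COMPLETE")
  }
})

test_that("increasing the buffer never turns NONE into COMPLETE", {
  set.seed(22)
  states <- c("ac", "an", "uqc", "unc", "u0")
  for (i in 1:200) {
    fam <- build_family_from_states(sample(states, sample(2:6, 1), TRUE))
    s <- vapply(c(0, 2, 5, 8, 20), function(b) {
      famseg:::seg_classify_core(fam$affection, fam$age, fam$dosage, buffer = b)$status
    }, character(1))
    complete <- s == "COMPLETE"
    # once lost, never regained as the buffer grows
    expect_true(all(diff(as.integer(complete)) <= 0))
  }
})

test_that("cohort-level incomplete segregation pools carriers across families", {
  # four affected carriers in four families + two young qualifying unaffected
  fams <- lapply(1:4, function(i) {
    make_family(paste0("F", i), c("affected", "affected", "unaffected"), c(74, 76, 72))
  })
  ped <- dplyr::bind_rows(fams)
  carrier_rows <- function(fam_ids, member, dosage) {
    tibble::tibble(
      variant_id = "v",
      individual_id = sprintf("%s_I%02d", fam_ids, member),
      alt_count = dosage, dp = 30, gq = 99
    )
  }
  # one affected carrier per family (member 1, onset 74)
  g_aff <- carrier_rows(paste0("F", 1:4), 1, 1L)
  # unaffected carriers in F1, F2 (member 3); age 72 vs family carrier mean 74 fails,
  # so force qualifying ages via a dedicated pedigree tweak
  ped$age_years[ped$individual_id %in% c("F1_I03", "F2_I03")] <- 65
  g_un <- carrier_rows(c("F1", "F2"), 3, 1L)

  out <- classify_cohort_incomplete(ped, dplyr::bind_rows(g_aff, g_un))
  expect_equal(out$status, "INCOMPLETE")
  expect_equal(out$n_affected_carriers, 4L)
  expect_equal(out$n_unaffected_carriers_qualifying, 2L)

  # only 3 affected carriers: below the >= 4 floor
  out <- classify_cohort_incomplete(ped, carrier_rows(paste0("F", 1:3), 1, 1L))
  expect_equal(out$status, "NONE")

  # 4 affected vs 4 unaffected carriers: not more affected than unaffected
  ped$age_years[ped$individual_id %in% c("F3_I03", "F4_I03")] <- 65
  g_un4 <- carrier_rows(paste0("F", 1:4), 3, 1L)
  out <- classify_cohort_incomplete(ped, dplyr::bind_rows(g_aff, g_un4))
  expect_equal(out$status, "NONE")

  # a non-qualifying unaffected carrier also blocks the label
  ped$age_years[ped$individual_id == "F1_I03"] <- 73
  out <- classify_cohort_incomplete(ped, dplyr::bind_rows(g_aff, g_un))
  expect_equal(out$status, "NONE")
})

test_that("cross-family consistency demotes by mode", {
  # family A: complete segregation; family B carries the same variant
  famA <- make_family("A", c("affected", "affected", "unaffected"), c(74, 76, 60))
  famB <- make_family("B", c("affected", "unaffected", "unaffected"), c(80, 62, 78))
  ped <- dplyr::bind_rows(famA, famB)

  run <- function(dosB, mode) {
    g <- dplyr::bind_rows(
      make_genotypes(famA, "v", c(1, 1, 0)),
      make_genotypes(famB, "v", dosB)
    )
    calls <- segregate_cohort(ped, g)
    suppressMessages(cross_family_consistency(calls, ped, g, mode = mode))
  }

  # carried only by an affected member of B: remains qualifying in both modes
  for (mode in c("strict", "lenient")) {
    out <- run(c(1, 0, 0), mode)
    expect_true(all(out$qualifying))
    expect_equal(out$status[out$family_id == "A"], "COMPLETE")
  }

  # carried by a young (qualifying-age) unaffected member of B:
  # demoted under strict, kept under lenient
  strict <- run(c(1, 1, 0), "strict")
  expect_equal(strict$status[strict$family_id == "A"], "NONE")
  expect_false(any(strict$qualifying))
  lenient <- run(c(1, 1, 0), "lenient")
  expect_equal(lenient$status[lenient$family_id == "A"], "COMPLETE")
  expect_true(all(lenient$qualifying))

  # carried by an old unaffected member of B: demoted in both modes
  for (mode in c("strict", "lenient")) {
    out <- run(c(1, 0, 1), mode)
    expect_equal(out$status[out$family_id == "A"], "NONE")
  }

  # variant seen in one family only: calls unchanged
  g1 <- make_genotypes(famA, "v", c(1, 1, 0))
  calls <- segregate_cohort(ped, g1)
  out <- cross_family_consistency(calls, ped, g1, mode = "strict")
  expect_equal(out$status, calls$status)
})

test_that("explanation labels follow the precedence rule and partition families", {
  ped <- dplyr::bind_rows(
    make_family("F1", c("affected", "affected"), c(74, 76)),
    make_family("F2", c("affected", "affected"), c(74, 76)),
    make_family("F3", c("affected", "affected"), c(74, 76))
  )
  seg <- tibble::tibble(
    variant_id = "v", cohort_id = "TEST",
    family_id = "F1", status = "COMPLETE",
    n_affected_genotyped = 2L, n_affected_carriers = 2L,
    onset_reference_age = 75, n_unaffected_carriers = 0L,
    n_unaffected_carriers_qualifying = 0L
  )
  apoe <- tibble::tibble(
    variant_id = "APOE_e4", cohort_id = "TEST",
    family_id = c("F1", "F2", "F3"), status = c("COMPLETE", "COMPLETE", "NONE")
  )
  out <- classify_family_explanation(ped, seg, apoe)
  expect_equal(out$label[out$family_id == "F1"], "RARE_EXPLAINED") # precedence over APOE
  expect_equal(out$label[out$family_id == "F2"], "APOE_ONLY")
  expect_equal(out$label[out$family_id == "F3"], "UNEXPLAINED")
  expect_equal(nrow(out), 3)
  expect_equal(sum(table(out$label)), dplyr::n_distinct(ped$family_id))

  # demoted (non-qualifying) calls do not explain a family
  seg$qualifying <- FALSE
  out <- classify_family_explanation(ped, seg, apoe)
  expect_equal(out$label[out$family_id == "F1"], "APOE_ONLY")
})

test_that("unknown-affection members are excluded from both carrier tests", {
  fam <- make_family("F1", c("affected", "affected", "unknown"), c(74, 76, NA))
  # unknown member carries; both affected carry -> COMPLETE (unknown ignored)
  call <- classify_family_segregation(fam, make_genotypes(fam, "v", c(1, 1, 1)))
  expect_equal(call$status, "COMPLETE")
  expect_equal(call$n_unaffected_carriers, 0L)
  # unknown member is the only non-carrier: still COMPLETE
  call <- classify_family_segregation(fam, make_genotypes(fam, "v", c(1, 1, 0)))
  expect_equal(call$status, "COMPLETE")
})
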