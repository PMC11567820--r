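# Percentage arithmetic, distinct-variant counting, the per-variant report
# and cohort summaries.

test_that("percent rounds half away from zero to one decimal", {
  expect_equal(percent(72, 411), 17.5)
  expect_equal(percent(0, 197), 0.0)
  expect_equal(percent(99, 197), 50.3)
  expect_equal(percent(1, 8), 12.5) # 12.5 stays 12.5, not banker's 12
  expect_equal(percent(1, 800), 0.1)
  expect_error(percent(1, 0), "positive denominator")
})

test_that("percent closes under complementation up to one rounding step", {
  set.seed(61)
  for (i in 1:200) {
    den <- sample(1:2000, 1)
    num <- sample(0:den, 1)
    s <- percent(num, den) + percent(den - num, den)
    expect_true(abs(s - 100) <= 0.1)
  }
})

test_that("distinct-variant counting reproduces the reference cohort totals", {
  counts <- count_distinct_variants(ref_damaging_variants())
  expect_equal(counts$n_variants[counts$cohort == "AD_FBS"], 46L)
  expect_equal(counts$n_variants[counts$cohort == "EFIGA"], 40L)
})

test_that("variant_report aggregation reproduces the reference per-row counts", {
  ref <- ref_complete_segregation()
  # expand each reference row into per-family COMPLETE calls: carrier counts
  # split across the families_complete families (first family takes the
  # remainder), then re-aggregate through variant_report()
  calls <- purrr::pmap(ref, function(variant, cohort, families_complete,
                                     n_affected, n_healthy, coseg_apoe, ...) {
    k <- families_complete
    aff <- rep(n_affected %/% k, k)
    aff[1] <- aff[1] + n_affected %% k
    hea <- rep(n_healthy %/% k, k)
    hea[1] <- hea[1] + n_healthy %% k
    tibble::tibble(
      variant_id = variant, cohort_id = cohort,
      family_id = paste0(cohort, "_", variant, "_fam", seq_len(k)),
      status = "COMPLETE",
      n_affected_genotyped = as.integer(aff),
      n_affected_carriers = as.integer(aff),
      onset_reference_age = 75,
      n_unaffected_carriers = as.integer(hea),
      n_unaffected_carriers_qualifying = as.integer(hea),
      coseg_apoe = coseg_apoe == "Yes"
    )
  }) |> dplyr::bind_rows()

  report <- variant_report(calls)
  joined <- ref |>
    dplyr::left_join(report, by = c(variant = "variant", cohort = "cohort"))
  expect_equal(nrow(joined), nrow(ref))
  expect_equal(joined$families_complete.y, joined$families_complete.x)
  expect_equal(joined$n_affected_in_segregating_families, joined$n_affected)
  expect_equal(joined$n_healthy_in_segregating_families, joined$n_healthy)
  expect_equal(joined$coseg_apoe.y, joined$coseg_apoe.x == "Yes")
})

test_that("variant_report rows are deterministic and minimal cases correct", {
  one <- tibble::tibble(
    variant_id = "chr14:73170945:C:T", cohort_id = "AD_FBS", family_id = "F1",
    status = "COMPLETE", n_affected_genotyped = 2L, n_affected_carriers = 2L,
    onset_reference_age = 75, n_unaffected_carriers = 0L,
    n_unaffected_carriers_qualifying = 0L
  )
  r <- variant_report(one)
  expect_equal(r$families_complete, 1L)
  expect_equal(r$n_affected_in_segregating_families, 2L)
  expect_equal(r$n_healthy_in_segregating_families, 0L)

  two <- dplyr::bind_rows(one, dplyr::mutate(one,
    family_id = "F2",
    n_affected_genotyped = 3L, n_affected_carriers = 3L,
    n_unaffected_carriers = 2L, n_unaffected_carriers_qualifying = 2L
  ))
  r <- variant_report(two)
  expect_equal(r$families_complete, 2L)
  expect_equal(r$n_affected_in_segregating_families, 5L)
  expect_equal(r$n_healthy_in_segregating_families, 2L)

  # no COMPLETE calls: empty (header-only) report
  none <- dplyr::mutate(one, status = "NONE")
  expect_equal(nrow(variant_report(none)), 0)

  # deterministic order: chrom, pos, alt, cohort
  set.seed(62)
  many <- dplyr::bind_rows(
    one,
    dplyr::mutate(one, variant_id = "chr2:100:A:T"),
    dplyr::mutate(one, variant_id = "chr2:100:A:G"),
    dplyr::mutate(one, variant_id = "chr2:99:A:G")
  )
  r1 <- variant_report(many)
  r2 <- variant_report(many[sample(nrow(many)), ])
  expect_equal(r1, r2)
  expect_equal(
    r1$variant,
    c("chr2:99:A:G", "chr2:100:A:G", "chr2:100:A:T", "chr14:73170945:C:T")
  )
})

test_that("cohort summaries partition families and recompute percentages", {
  sim <- simulate_cohorts(sim_config(seed = 63, n_families = c(A = 50, B = 50)))
  res <- suppressMessages(suppressWarnings(
    analyze_cohorts(sim$pedigree, sim$variants, sim$genotypes)
  ))
  s <- res$summary
  expect_s3_class(s, "famseg_summary")
  expect_true(all(
    s$n_families_rare_explained + s$n_families_apoe_only + s$n_families_unexplained ==
      s$n_families
  ))
  for (r in seq_len(nrow(s))) {
    expect_equal(
      s$pct_rare_explained[r],
      percent(s$n_families_rare_explained[r], s$n_families[r])
    )
  }
  comb <- s[s$cohort_id == "COMBINED", ]
  expect_equal(comb$n_families, 100L)

  # broom-style accessors
  long <- generics::tidy(s)
  expect_true(all(c("cohort_id", "statistic", "value") %in% names(long)))
  g <- generics::glance(s)
  expect_equal(nrow(g), 1)
  expect_equal(g$cohort_id, "COMBINED")
})

test_that("plot builders return ggplot objects", {
  sim <- simulate_cohorts(sim_config(seed = 64, n_families = c(A = 30, B = 30)))
  res <- suppressMessages(suppressWarnings(
    analyze_cohorts(sim$pedigree, sim$variants, sim$genotypes)
  ))
  expect_s3_class(plot_family_explanations(res$explanations), "ggplot")
  expect_s3_class(plot_segregation_calls(res$calls), "ggplot")
  expect_s3_class(ggplot2::autoplot(res$summary), "ggplot")
  ld <- ld_scan(sim$genotypes, dplyr::rename(sim$ld_pairs[1, ],
    variant_a = variant_a, variant_b = variant_b
  ) |> dplyr::select(variant_a, variant_b))
  expect_s3_class(plot_ld(ld), "ggplot")
})
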