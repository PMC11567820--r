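# LD: dosage correlation, EM haplotype frequencies, index-SNP carriers.

test_that("genotype r2 matches the direct Pearson oracle", {
  # identical non-constant vectors
  expect_equal(genotype_r2(c(0, 1, 2, 0), c(0, 1, 2, 0))$r2, 1.0)
  # perfect anti-correlation squares to 1
  expect_equal(genotype_r2(c(0, 0, 1, 1), c(1, 1, 0, 0))$r2, 1.0)
  # frozen value computed with the direct sum-formula oracle:
  # a = (0,1,2,0,1), b = (0,1,1,0,2) -> r2 = 3.24 / 7.84
  expect_equal(genotype_r2(c(0, 1, 2, 0, 1), c(0, 1, 1, 0, 2))$r2,
    0.413265306122449,
    tolerance = 1e-12
  )
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:60, 1)
    a <- sample(c(0:2, NA), n, TRUE, prob = c(.4, .3, .2, .1))
    b <- sample(c(0:2, NA), n, TRUE, prob = c(.4, .3, .2, .1))
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3 || length(unique(a[ok])) < 2 || length(unique(b[ok])) < 2) next
    got <- genotype_r2(a, b)
    expect_equal(got$r2, pearson_r2_oracle(a, b), tolerance = 1e-12)
    expect_equal(got$n_samples, sum(ok))
  }
})

test_that("genotype r2 is symmetric and invariant to ref/alt relabelling", {
  set.seed(32)
  a <- sample(0:2, 100, TRUE)
  b <- sample(0:2, 100, TRUE)
  expect_equal(genotype_r2(a, b)$r2, genotype_r2(b, a)$r2)
  expect_equal(genotype_r2(a, b)$r2, genotype_r2(2 - a, b)$r2)
  expect_equal(genotype_r2(a, b)$r2, genotype_r2(a, 2 - b)$r2)
})

test_that("degenerate LD inputs raise errors", {
  expect_error(genotype_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(genotype_r2(c(0, 1), c(0, 1, 2)), "equal length")
  expect_error(genotype_r2(c(0, NA, NA), c(0, 1, 2)), "at least 2")
  expect_error(em_haplotype_r2(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
})

test_that("EM equals direct haplotype counting when phase is unambiguous", {
  # no double heterozygotes: every genotype pair resolves uniquely
  a <- c(0, 0, 2, 2, 1, 0, 2, 1)
  b <- c(0, 2, 0, 2, 0, 1, 1, 2)
  em <- em_haplotype_r2(a, b)
  # count haplotypes by hand: each individual contributes two
  count <- c(0, 0, 0, 0)
  for (i in seq_along(a)) {
    ha <- c(rep(0, 2 - a[i]), rep(1, a[i]))
    hb <- c(rep(0, 2 - b[i]), rep(1, b[i]))
    for (k in 1:2) count[1 + 2 * ha[k] + hb[k]] <- count[1 + 2 * ha[k] + hb[k]] + 1
  }
  f <- count / sum(count)
  expect_equal(c(em$f00, em$f01, em$f10, em$f11), f, tolerance = 1e-9)
  expect_equal(em$r2, haplotype_r2(f), tolerance = 1e-9)
})

test_that("two haplotypes in complete LD give r2 = 1", {
  sim <- famseg:::with_seed(33, plant_ld_pair(c(0.5, 0, 0, 0.5), 400))
  em <- em_haplotype_r2(sim$dosage_a, sim$dosage_b)
  expect_equal(em$r2, 1.0, tolerance = 1e-9)
  expect_equal(attr(sim, "expected_r2"), 1.0)
})

test_that("EM recovers the planted r2 within sampling error at n = 10,000", {
  f <- local({
    d <- sqrt(0.5 * 0.0625)
    c(0.25 + d, 0.25 - d, 0.25 - d, 0.25 + d) # closed-form r2 = 0.5
  })
  expect_equal(haplotype_r2(f), 0.5, tolerance = 1e-12)
  sim <- famseg:::with_seed(34, plant_ld_pair(f, 10000))
  em <- em_haplotype_r2(sim$dosage_a, sim$dosage_b)
  # delta-method: se(r) ~ (1 - r^2)/sqrt(n), se(r2) ~ 2 r se(r)
  se_r2 <- 2 * sqrt(0.5) * (1 - 0.5) / sqrt(10000)
  expect_lt(abs(em$r2 - 0.5), 3 * se_r2)
  expect_true(all(c(em$f00, em$f01, em$f10, em$f11) >= 0))
  expect_equal(em$f00 + em$f01 + em$f10 + em$f11, 1, tolerance = 1e-9)
})

test_that("dosage correlation and EM agree exactly on phase-trivial genotypes", {
  # each individual carries two copies of one haplotype (genotypes 0/2),
  # so phase is trivially known and both estimators reduce to the same
  # haplotype-frequency arithmetic
  f <- c(0.35, 0.15, 0.1, 0.4)
  haps <- famseg:::with_seed(35, sample.int(4, 10000, TRUE, prob = f))
  a <- 2L * as.integer(haps %in% c(3, 4))
  b <- 2L * as.integer(haps %in% c(2, 4))
  g <- genotype_r2(a, b)
  em <- em_haplotype_r2(a, b)
  expect_equal(g$r2, em$r2, tolerance = 1e-6)
})

test_that("index-SNP carrier counting handles missing genotypes", {
  expect_equal(index_carrier_count(c(1, 0, 2, 0, 1)), 3L)
  expect_equal(index_carrier_count(c(0, 0, 0)), 0L)
  expect_warning(n <- index_carrier_count(c(NA, NA)), "missing")
  expect_equal(n, 0L)
  expect_equal(index_carrier_count(c(NA, 1, 0)), 1L)
})

test_that("index-SNP co-segregation applies the complete rule to the index SNP", {
  fam <- make_family("F1", c("affected", "affected", "unaffected"), c(74, 76, 60))
  vcall <- classify_family_segregation(fam, make_genotypes(fam, "v", c(1, 1, 0)))
  expect_equal(vcall$status, "COMPLETE")
  # index SNP carried by all affected, no unqualified unaffected carriers
  expect_true(cosegregates_with_index(vcall, fam, make_genotypes(fam, "idx", c(1, 2, 0))))
  # index SNP absent from one affected member
  expect_false(cosegregates_with_index(vcall, fam, make_genotypes(fam, "idx", c(1, 0, 0))))
  # precondition: variant call must be COMPLETE
  ncall <- classify_family_segregation(fam, make_genotypes(fam, "v", c(1, 0, 0)))
  expect_error(
    cosegregates_with_index(ncall, fam, make_genotypes(fam, "idx", c(1, 1, 0))),
    "COMPLETE"
  )
})

test_that("ld_scan reports r2 with the configurable in-LD flag", {
  f <- c(0.45, 0.05, 0.05, 0.45)
  sim <- famseg:::with_seed(36, plant_ld_pair(f, 2000))
  ids <- paste0("S", seq_len(nrow(sim)))
  g <- dplyr::bind_rows(
    tibble::tibble(variant_id = "a", individual_id = ids, alt_count = sim$dosage_a),
    tibble::tibble(variant_id = "b", individual_id = ids, alt_count = sim$dosage_b),
    tibble::tibble(variant_id = "mono", individual_id = ids, alt_count = 0L)
  )
  out <- ld_scan(g, tibble::tibble(
    variant_a = c("a", "a"), variant_b = c("b", "mono")
  ))
  expect_equal(nrow(out), 2)
  expect_true(out$in_ld[1]) # strongly correlated pair
  expect_true(is.na(out$r2[2])) # monomorphic partner: undefined, not an error
  expect_gt(out$r2[1], 0.5)
})
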