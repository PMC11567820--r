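# VCF region extraction, multi-allelic splitting, genotype masking,
# site missingness and rarity filters.

test_that("read_vcf_region restricts to BED intervals and splits multi-allelics", {
  dir <- withr::local_tempdir()
  vcf <- write_test_vcf(
    file.path(dir, "t.vcf"),
    records = c(
      "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:DP:GQ\t0/1:30:99\t0/0:25:80",
      "chr1\t250\t.\tG\tC\t.\tLowQual\t.\tGT:DP:GQ\t1/1:12:40\t0/1:9:35",
      "chr1\t900\t.\tA\tC,T\t.\tPASS\t.\tGT:DP:GQ\t1/2:33:90\t./.:.:.",
      "chr2\t150\t.\tC\tG\t.\tPASS\t.\tGT:DP:GQ\t0/0:40:99\t0/1:41:99",
      "chr2\t800\t.\tT\tA\t.\tPASS\t.\tGT:DP:GQ\t0/1:50:99\t0/0:50:99"
    ),
    samples = c("S1", "S2")
  )

  # BED covers chr1:101-300 (0-based 100..300) and chr2:1-200
  regions <- tibble::tibble(chrom = c("chr1", "chr2"), start = c(100, 0), end = c(300, 200))
  out <- read_vcf_region(vcf, regions)
  expect_equal(sort(out$variants$pos), c(150, 250))
  # position 100 is excluded: BED start is exclusive on the 1-based scale
  expect_false(100 %in% out$variants$pos)
  # FILTER passes through
  expect_equal(out$variants$filter_status[out$variants$pos == 250], "LowQual")

  # multi-allelic split: 1/2 becomes one alt allele against each split record
  all <- read_vcf_region(vcf, NULL)
  split_ids <- c("chr1:900:A:C", "chr1:900:A:T")
  expect_true(all(split_ids %in% all$variants$variant_id))
  g <- all$genotypes
  expect_equal(g$alt_count[g$variant_id == "chr1:900:A:C" & g$individual_id == "S1"], 1L)
  expect_equal(g$alt_count[g$variant_id == "chr1:900:A:T" & g$individual_id == "S1"], 1L)
  expect_true(is.na(g$alt_count[g$variant_id == "chr1:900:A:T" & g$individual_id == "S2"]))

  expect_error(read_vcf_region(vcf, tibble::tibble(chrom = "chr1", start = 10, end = 5)),
    "malformed"
  )
})

test_that("genotype masking honours DP/GQ thresholds with inclusive boundaries", {
  g <- tibble::tibble(
    variant_id = "v", individual_id = paste0("S", 1:4),
    alt_count = c(1L, 1L, 1L, 1L),
    dp = c(9, 30, 10, 15), gq = c(99, 99, 20, 19)
  )
  masked <- suppressMessages(mask_low_quality_genotypes(g))
  expect_true(is.na(masked$alt_count[1])) # DP 9 < 10
  expect_equal(masked$alt_count[2], 1L) # DP 30, GQ 99
  expect_equal(masked$alt_count[3], 1L) # boundary DP 10, GQ 20 kept
  expect_true(is.na(masked$alt_count[4])) # GQ 19 < 20
  expect_equal(attr(masked, "n_masked"), 2L)
})

test_that("masked counts match a brute-force count and are monotone in thresholds", {
  set.seed(11)
  n <- 500
  g <- tibble::tibble(
    variant_id = sample(paste0("v", 1:10), n, TRUE),
    individual_id = paste0("S", seq_len(n)),
    alt_count = sample(c(0L, 1L, 2L), n, TRUE),
    dp = sample(c(NA, 0:40), n, TRUE),
    gq = sample(c(NA, 0:99), n, TRUE)
  )
  for (th in list(c(10, 20), c(5, 50), c(0, 0))) {
    masked <- suppressMessages(mask_low_quality_genotypes(g, th[1], th[2]))
    brute <- 0
    for (i in seq_len(n)) {
      fails <- (!is.na(g$dp[i]) && g$dp[i] < th[1]) || (!is.na(g$gq[i]) && g$gq[i] < th[2])
      if (fails && !is.na(g$alt_count[i])) brute <- brute + 1
    }
    expect_equal(attr(masked, "n_masked"), brute)
  }
  surviving <- function(min_dp, min_gq) {
    sum(!is.na(suppressMessages(mask_low_quality_genotypes(g, min_dp, min_gq))$alt_count))
  }
  s <- vapply(c(0, 5, 10, 20, 41), function(d) surviving(d, 20), numeric(1))
  expect_true(all(diff(s) <= 0))
  s <- vapply(c(0, 20, 50, 100), function(q) surviving(10, q), numeric(1))
  expect_true(all(diff(s) <= 0))
})

test_that("site missingness filter uses a strict > bound over all samples", {
  n_samples <- 100
  mk <- function(n_missing, vid) {
    tibble::tibble(
      variant_id = vid, individual_id = paste0("S", 1:n_samples),
      alt_count = c(rep(NA_integer_, n_missing), rep(0L, n_samples - n_missing)),
      dp = 30, gq = 99
    )
  }
  g <- dplyr::bind_rows(mk(3, "v3"), mk(2, "v2"), mk(0, "v0"))
  v <- tibble::tibble(variant_id = c("v3", "v2", "v0"))
  out <- drop_high_missingness_sites(v, g, max_missing_fraction = 0.02)
  expect_setequal(out$variants$variant_id, c("v2", "v0")) # 3% dropped, 2% exactly kept
  expect_equal(attr(out$variants, "n_dropped"), 1L)
  expect_false("v3" %in% out$genotypes$variant_id)
})

test_that("masking and missingness filtering are invariant to sample order", {
  set.seed(13)
  n_samples <- 50
  g <- tidyr::expand_grid(
    variant_id = paste0("v", 1:8),
    individual_id = paste0("S", seq_len(n_samples))
  ) |>
    dplyr::mutate(
      alt_count = sample(c(0L, 1L), dplyr::n(), TRUE),
      dp = sample(5:30, dplyr::n(), TRUE),
      gq = sample(10:99, dplyr::n(), TRUE)
    )
  v <- tibble::tibble(variant_id = paste0("v", 1:8))
  run <- function(gg) {
    m <- suppressMessages(mask_low_quality_genotypes(gg))
    out <- drop_high_missingness_sites(v, m, max_missing_fraction = 0.1)
    sort(out$variants$variant_id)
  }
  expect_equal(run(g), run(g[sample(nrow(g)), ]))
})

test_that("rarity filter is strict at 1% and keeps unobserved-in-reference variants", {
  v <- tibble::tibble(
    variant_id = c("a", "b", "c"),
    gnomad_af = c(0.009, 0.01, NA)
  )
  out <- filter_rare(v)
  expect_setequal(out$variant_id, c("a", "c"))
  expect_equal(out$af_absent[out$variant_id == "c"], TRUE)
  expect_equal(out$af_absent[out$variant_id == "a"], FALSE)
})
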