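# On-disk round trip for simulated cohorts: uncompressed VCF + FAM +
# phenotype/annotation/index-SNP/truth TSVs.

#' Write a simulated cohort set to disk
#'
#' Emits `cohort.vcf` (VCF 4.2, GT:DP:GQ, one sample column per individual),
#' `cohort.fam`, `phenotypes.tsv` (with a `cohort_id` column), and
#' `annotations.tsv`, `index_snps.tsv`, `truth_families.tsv`,
#' `truth_variants.tsv`. The VCF is dense: genotype rows absent from the
#' sparse in-memory table are written as homozygous reference with nominal
#' DP/GQ, which is exactly how the classifier interprets them.
#'
#' @param sim A `famseg_sim` object from [simulate_cohorts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- sim$pedigree
  variants <- sim$variants |> arrange(chrom_rank(.data$chrom), .data$pos, .data$alt)
  samples <- ped$individual_id

  gt_map <- sim$genotypes
  key <- paste(gt_map$variant_id, gt_map$individual_id)
  dose <- setNames(gt_map$alt_count, key)
  dp <- setNames(gt_map$dp, key)
  gq <- setNames(gt_map$gq, key)

  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      samples
    ), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    k <- paste(v$variant_id, samples)
    d <- dose[k]
    has <- k %in% key
    gt <- ifelse(!has, "0/0",
      ifelse(is.na(d), "./.", ifelse(d == 0, "0/0", ifelse(d == 1, "0/1", "1/1")))
    )
    dpv <- ifelse(has, dp[k], 30)
    gqv <- ifelse(has, gq[k], 99)
    cells <- paste0(gt, ":", dpv, ":", gqv)
    paste(c(
      v$chrom, v$pos, ".", v$ref, v$alt, ".", v$filter_status, ".", "GT:DP:GQ",
      cells
    ), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), file.path(dir, "cohort.vcf"))

  write_pedigree(ped, file.path(dir, "cohort.fam"), file.path(dir, "phenotypes_plain.tsv"))
  # phenotype TSV with cohort assignment (the FAM format has no cohort field)
  ped |>
    select("cohort_id", "family_id", "individual_id", "affection", "age_years") |>
    mutate(affection = as.character(.data$affection)) |>
    readr::write_tsv(file.path(dir, "phenotypes.tsv"))
  unlink(file.path(dir, "phenotypes_plain.tsv"))

  sim$variants |>
    select("chrom", "pos", "ref", "alt", "gene", "consequence", "cadd_phred", "gnomad_af") |>
    readr::write_tsv(file.path(dir, "annotations.tsv"))
  readr::write_tsv(sim$index_snps, file.path(dir, "index_snps.tsv"))
  readr::write_tsv(sim$truth_families, file.path(dir, "truth_families.tsv"))
  readr::write_tsv(sim$truth_variants, file.path(dir, "truth_variants.tsv"))
  invisible(dir)
}

#' Read a simulated cohort set back from disk
#'
#' Inverse of [write_cohort_files()]: reconstructs the pedigree, variant and
#' genotype tables (dense, as written), annotations, index SNPs and truth
#' records.
#'
#' @param dir Directory written by [write_cohort_files()].
#' @return A list with `pedigree`, `variants`, `genotypes`, `index_snps`,
#'   `truth_families`, `truth_variants`.
#' @export
read_cohort_files <- function(dir) {
  phe <- readr::read_tsv(
    file.path(dir, "phenotypes.tsv"),
    col_types = readr::cols(
      cohort_id = readr::col_character(), family_id = readr::col_character(),
      individual_id = readr::col_character(), affection = readr::col_character(),
      age_years = readr::col_double()
    )
  )
  fam <- utils::read.table(
    file.path(dir, "cohort.fam"),
    header = FALSE, colClasses = "character",
    col.names = c("family_id", "individual_id", "father_id", "mother_id", "sex", "ped_pheno")
  )
  pedigree <- tibble::as_tibble(fam) |>
    mutate(sex = dplyr::case_match(.data$sex, "1" ~ "male", "2" ~ "female", .default = "unknown")) |>
    select(-"ped_pheno") |>
    left_join(phe, by = c("family_id", "individual_id")) |>
    mutate(affection = factor(.data$affection, levels = c("affected", "unaffected", "unknown"))) |>
    relocate("cohort_id")
  validate_pedigree(pedigree)

  vcf <- read_vcf_region(file.path(dir, "cohort.vcf"), regions = NULL)
  variants <- annotate_variants(vcf$variants, file.path(dir, "annotations.tsv"))
  index_snps <- readr::read_tsv(
    file.path(dir, "index_snps.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  truth_families <- readr::read_tsv(
    file.path(dir, "truth_families.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  truth_variants <- readr::read_tsv(
    file.path(dir, "truth_variants.tsv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  list(
    pedigree = pedigree, variants = variants, genotypes = vcf$genotypes,
    index_snps = index_snps, truth_families = truth_families,
    truth_variants = truth_variants
  )
}
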