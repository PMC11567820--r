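#' Read variants and genotypes from a VCF, restricted to candidate loci
#'
#' Loads a (possibly bgzipped) multi-sample VCF and returns a variant table
#' and a long genotype table, keeping only records that overlap the supplied
#' candidate regions. Multi-allelic records are split into one row per
#' alternate allele, with genotypes recoded against that allele (a `1/2` call
#' contributes one alternate allele to each split record); per-genotype DP and
#' GQ are carried over from the original record.
#'
#' VCF coordinates are 1-based inclusive; BED intervals are 0-based
#' half-open, so a BED row `chrom start end` selects positions
#' `start + 1 .. end`.
#'
#' @param vcf_path Path to a VCF (4.2+). The GT FORMAT field is required;
#'   DP and GQ are used when present.
#' @param regions Candidate intervals: a BED file path, a data frame with
#'   columns `chrom`, `start`, `end` (0-based half-open), or `NULL` to keep
#'   every record.
#'
#' @return A list with two tibbles:
#'   * `variants`: `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'     `filter_status`;
#'   * `genotypes`: `variant_id`, `individual_id`, `alt_count` (0/1/2 or NA
#'     for missing), `dp`, `gq`.
#' @export
read_vcf_region <- function(vcf_path, regions = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(list(variants = empty_variants(), genotypes = empty_genotypes()))
  }
  fmt <- vcf@gt[, 1]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    rlang::abort("VCF FORMAT column lacks GT for one or more records")
  }

  keep <- rep(TRUE, nrow(fix))
  if (!is.null(regions)) {
    regions <- read_regions(regions)
    pos <- as.integer(fix$POS)
    keep <- vapply(seq_len(nrow(fix)), function(i) {
      any(regions$chrom == fix$CHROM[i] &
        pos[i] > regions$start & pos[i] <= regions$end)
    }, logical(1))
  }
  if (!any(keep)) {
    return(list(variants = empty_variants(), genotypes = empty_genotypes()))
  }

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
  gq_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ", as.numeric = TRUE))
  samples <- colnames(vcf@gt)[-1]

  rows <- which(keep)
  var_list <- vector("list", length(rows))
  gt_list <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("\\|", "/", gt_raw[i, ]), "/", fixed = TRUE)
    per_alt <- lapply(seq_along(alts), function(k) {
      counts <- vapply(alleles, function(a) {
        if (length(a) == 0 || anyNA(a) || any(a == ".") || all(!nzchar(a))) {
          return(NA_integer_)
        }
        sum(a == as.character(k))
      }, integer(1))
      tibble::tibble(
        variant_id = variant_key(fix$CHROM[i], fix$POS[i], fix$REF[i], alts[k]),
        individual_id = samples,
        alt_count = unname(counts),
        dp = if (is.null(dp_raw)) NA_real_ else unname(dp_raw[i, ]),
        gq = if (is.null(gq_raw)) NA_real_ else unname(gq_raw[i, ])
      )
    })
    gt_list[[j]] <- dplyr::bind_rows(per_alt)
    var_list[[j]] <- tibble::tibble(
      variant_id = variant_key(fix$CHROM[i], fix$POS[i], fix$REF[i], alts),
      chrom = fix$CHROM[i],
      pos = as.integer(fix$POS[i]),
      ref = fix$REF[i],
      alt = alts,
      filter_status = ifelse(is.na(fix$FILTER[i]), ".", fix$FILTER[i])
    )
  }

  variants <- dplyr::bind_rows(var_list)
  bad <- variants$ref == variants$alt
  if (any(bad)) {
    rlang::abort(paste0("ref == alt at ", paste(variants$variant_id[bad], collapse = ", ")))
  }
  list(variants = variants, genotypes = dplyr::bind_rows(gt_list))
}

empty_variants <- function() {
  tibble::tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), filter_status = character()
  )
}

empty_genotypes <- function() {
  tibble::tibble(
    variant_id = character(), individual_id = character(),
    alt_count = integer(), dp = numeric(), gq = numeric()
  )
}

# Accept a BED path or a data frame; return tibble(chrom, start, end).
read_regions <- function(regions) {
  if (is.character(regions) && length(regions) == 1) {
    regions <- utils::read.table(
      regions,
      header = FALSE, sep = "\t",
      colClasses = c("character", "integer", "integer"),
      col.names = c("chrom", "start", "end")
    )
  }
  regions <- tibble::as_tibble(regions)
  if (!all(c("chrom", "start", "end") %in% names(regions))) {
    rlang::abort("regions must have columns chrom, start, end (BED, 0-based half-open)")
  }
  if (any(is.na(regions$start) | is.na(regions$end) | regions$end < regions$start | regions$start < 0)) {
    rlang::abort("malformed region: start/end must satisfy 0 <= start <= end")
  }
  regions
}

#' Attach annotations to a variant table
#'
#' Joins gene symbol, consequence string, CADD phred score and gnomAD allele
#' frequency onto variants by (chrom, pos, ref, alt). Annotation generation
#' (VEP/ANNOVAR/CADD) is upstream of this package; the table is an input.
#'
#' @param variants Variant tibble from [read_vcf_region()].
#' @param annotations A data frame or TSV path with header columns `chrom`,
#'   `pos`, `ref`, `alt`, `gene`, `consequence`, `cadd_phred`, `gnomad_af`.
#' @return The variant tibble with `gene`, `consequence`, `cadd_phred`,
#'   `gnomad_af` columns added (NA where unannotated).
#' @export
annotate_variants <- function(variants, annotations) {
  if (is.character(annotations) && length(annotations) == 1) {
    annotations <- readr::read_tsv(
      annotations,
      col_types = readr::cols(
        chrom = readr::col_character(), pos = readr::col_integer(),
        ref = readr::col_character(), alt = readr::col_character(),
        gene = readr::col_character(), consequence = readr::col_character(),
        cadd_phred = readr::col_double(), gnomad_af = readr::col_double()
      )
    )
  }
  annotations <- tibble::as_tibble(annotations) |>
    select("chrom", "pos", "ref", "alt", "gene", "consequence", "cadd_phred", "gnomad_af")
  left_join(variants, annotations, by = c("chrom", "pos", "ref", "alt"))
}
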