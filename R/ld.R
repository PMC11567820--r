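# Linkage disequilibrium between rare variants and common GWAS index SNPs,
# and index-SNP carrier counts / co-segregation in segregating families.

#' Squared genotype correlation between two loci
#'
#' The default LD measure: squared Pearson correlation between alternate
#' allele dosages over pairwise-complete samples. Invariant to swapping the
#' loci and to relabelling ref/alt at either locus (reflection flips the
#' correlation's sign, not its square).
#'
#' @param dosages_a,dosages_b Dosage vectors in \{0, 1, 2, NA\}, same length.
#' @return A one-row tibble of class `famseg_ld`: `r2`, `n_samples`,
#'   `method = "genotype_corr"`.
#' @export
#' @examples
#' genotype_r2(c(0, 0, 1, 1), c(1, 1, 0, 0)) # perfect anti-correlation, r2 = 1
genotype_r2 <- function(dosages_a, dosages_b) {
  if (length(dosages_a) != length(dosages_b)) {
    rlang::abort("dosage vectors must have equal length")
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]
  b <- dosages_b[ok]
  if (length(a) < 2) {
    rlang::abort("need at least 2 samples with both genotypes non-missing")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    rlang::abort("LD undefined: at least one locus is monomorphic in the complete samples")
  }
  r <- stats::cor(a, b)
  new_ld_result(r2 = r^2, n_samples = length(a), method = "genotype_corr")
}

new_ld_result <- function(r2, n_samples, method, extra = NULL) {
  out <- tibble::tibble(r2 = r2, n_samples = n_samples, method = method)
  if (!is.null(extra)) {
    out <- bind_cols(out, tibble::as_tibble(extra))
  }
  class(out) <- c("famseg_ld", class(out))
  out
}

#' Closed-form r-squared from two-locus haplotype frequencies
#'
#' For haplotype frequencies `(f00, f01, f10, f11)` (allele order: locus A
#' then locus B, 1 = alternate), `r2 = D^2 / (pA (1-pA) pB (1-pB))` with
#' `D = f11 - pA pB`.
#'
#' @param freqs Numeric vector of the four haplotype frequencies, in the
#'   order `f00, f01, f10, f11`; must be non-negative and sum to 1.
#' @return The r-squared value.
#' @export
haplotype_r2 <- function(freqs) {
  stopifnot(length(freqs) == 4)
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-8) {
    rlang::abort("haplotype frequencies must be non-negative and sum to 1")
  }
  pA <- freqs[3] + freqs[4]
  pB <- freqs[2] + freqs[4]
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    rlang::abort("degenerate haplotype frequencies: a locus is monomorphic")
  }
  D <- freqs[4] - pA * pB
  unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' EM estimate of two-locus haplotype frequencies and r-squared
#'
#' Maximum-likelihood haplotype frequencies from unphased genotypes at two
#' biallelic loci. Every genotype pair resolves to a unique pair of
#' haplotypes except the double heterozygote, whose cis/trans split is the
#' E-step; with no double heterozygotes the EM fixed point equals direct
#' haplotype counting. `r2` is the standard `D^2` normalisation.
#'
#' @inheritParams genotype_r2
#' @param tol Convergence tolerance on the largest frequency change.
#' @param max_iter Maximum EM iterations; non-convergence is an error whose
#'   condition carries the last estimate.
#' @return A one-row tibble of class `famseg_ld`: `r2`, `n_samples`,
#'   `method = "em_haplotype"`, the four haplotype frequencies `f00..f11`,
#'   `D`, `iterations`, `converged`.
#' @export
em_haplotype_r2 <- function(dosages_a, dosages_b, tol = 1e-8, max_iter = 1000) {
  if (length(dosages_a) != length(dosages_b)) {
    rlang::abort("dosage vectors must have equal length")
  }
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- as.integer(dosages_a[ok])
  b <- as.integer(dosages_b[ok])
  if (length(a) < 2) {
    rlang::abort("need at least 2 samples with both genotypes non-missing")
  }
  if (all(a == a[1]) || all(b == b[1])) {
    rlang::abort("LD undefined: at least one locus is monomorphic in the complete samples")
  }

  n <- length(a)
  # Fixed haplotype contributions from unambiguous individuals.
  # Haplotype index: 1 = 00, 2 = 01, 3 = 10, 4 = 11 (alleleA, alleleB).
  base <- numeric(4)
  n_dh <- 0
  for (i in seq_len(n)) {
    ga <- a[i]
    gb <- b[i]
    if (ga == 1 && gb == 1) {
      n_dh <- n_dh + 1
    } else {
      # Each locus contributes its alleles independently of phase here.
      ha <- c(rep(0L, 2 - ga), rep(1L, ga))
      hb <- c(rep(0L, 2 - gb), rep(1L, gb))
      # Heterozygous at most one locus: pairing is forced up to exchange.
      base[1 + 2 * ha[1] + hb[1]] <- base[1 + 2 * ha[1] + hb[1]] + 1
      base[1 + 2 * ha[2] + hb[2]] <- base[1 + 2 * ha[2] + hb[2]] + 1
    }
  }

  f <- rep(0.25, 4)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # E-step: split double heterozygotes between cis (00/11) and trans (01/10).
    denom <- f[1] * f[4] + f[2] * f[3]
    w_cis <- if (denom > 0) f[1] * f[4] / denom else 0.5
    counts <- base
    counts[c(1, 4)] <- counts[c(1, 4)] + n_dh * w_cis
    counts[c(2, 3)] <- counts[c(2, 3)] + n_dh * (1 - w_cis)
    f_new <- counts / (2 * n)
    if (max(abs(f_new - f)) < tol) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new
  }
  if (!converged) {
    rlang::abort(
      paste0("EM did not converge after ", max_iter, " iterations"),
      last_estimate = f
    )
  }
  pA <- f[3] + f[4]
  pB <- f[2] + f[4]
  D <- f[4] - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  new_ld_result(
    r2 = r2, n_samples = n, method = "em_haplotype",
    extra = list(
      f00 = f[1], f01 = f[2], f10 = f[3], f11 = f[4],
      D = D, iterations = iter, converged = converged
    )
  )
}

#' LD between index SNPs and qualifying rare variants
#'
#' Computes r-squared for each requested pair of variants across all
#' genotyped individuals (related individuals included; restrict `samples`
#' for a founders-only estimate), and flags pairs with `r2 >= r2_threshold`
#' as "in LD". The threshold is a reporting convenience — the continuous r2
#' is always returned alongside.
#'
#' @param genotypes Long genotype tibble.
#' @param pairs Tibble with columns `variant_a`, `variant_b` (variant keys).
#' @param samples Optional character vector of individual ids to use.
#' @param method `"genotype_corr"` (default) or `"em_haplotype"`.
#' @param r2_threshold Binarisation cutoff for the `in_ld` flag (default 0.2).
#' @return A tibble with one row per pair: `variant_a`, `variant_b`, `r2`,
#'   `n_samples`, `method`, `in_ld`; `r2` is `NA` (with `in_ld = NA`) where
#'   LD is undefined (monomorphic locus).
#' @export
ld_scan <- function(genotypes, pairs, samples = NULL,
                    method = c("genotype_corr", "em_haplotype"),
                    r2_threshold = 0.2) {
  method <- match.arg(method)
  samples <- samples %||% sort(unique(genotypes$individual_id))
  dose <- function(vid) {
    g <- genotypes |> filter(.data$variant_id == vid, .data$individual_id %in% samples)
    out <- g$alt_count[match(samples, g$individual_id)]
    out[!samples %in% g$individual_id] <- 0L
    out
  }
  fun <- if (method == "genotype_corr") genotype_r2 else em_haplotype_r2
  res <- purrr::pmap(pairs, function(variant_a, variant_b, ...) {
    r <- tryCatch(
      fun(dose(variant_a), dose(variant_b)),
      error = function(e) tibble::tibble(r2 = NA_real_, n_samples = NA_integer_, method = method)
    )
    tibble::tibble(
      variant_a = variant_a, variant_b = variant_b,
      r2 = r$r2, n_samples = r$n_samples, method = r$method
    )
  })
  bind_rows(res) |>
    mutate(in_ld = .data$r2 >= r2_threshold)
}

#' Count index-SNP carriers in a family
#'
#' Number of family members, of any affection status, carrying at least one
#' alternate allele of the GWAS index SNP. All-missing genotypes yield 0
#' with a warning.
#'
#' @param dosages Dosage vector for the family's members.
#' @return Integer carrier count.
#' @export
index_carrier_count <- function(dosages) {
  if (length(dosages) > 0 && all(is.na(dosages))) {
    rlang::warn("all index-SNP genotypes missing; carrier count is 0")
    return(0L)
  }
  sum(dosages >= 1, na.rm = TRUE)
}

#' Index-SNP carrier counts per (variant, family) call
#'
#' For each segregation call, counts the members of that family carrying the
#' locus's index SNP.
#'
#' @param seg_calls Segregation calls with `variant_id`, `family_id`.
#' @param pedigree Pedigree tibble.
#' @param genotypes Long genotype tibble containing the index SNPs.
#' @param index_snps Tibble mapping loci to index SNPs: columns
#'   `variant_id` (the rare variant's locus, by gene) are not needed —
#'   supply `gene`-keyed mapping via columns `gene`, `index_variant_id`, and
#'   a `variants` table linking `variant_id` to `gene`.
#' @param variants Variant tibble with `variant_id` and `gene`.
#' @return `seg_calls` with `index_variant_id` and `n_index_carriers` added
#'   (NA where the locus has no index SNP).
#' @export
index_carriers_by_family <- function(seg_calls, pedigree, genotypes, index_snps, variants) {
  # one index SNP per locus: a duplicated gene entry must not fan out calls
  idx <- index_snps |>
    select("gene", "index_variant_id") |>
    distinct(.data$gene, .keep_all = TRUE)
  mapping <- variants |>
    distinct(.data$variant_id, .data$gene) |>
    left_join(idx, by = "gene")
  carriers <- genotypes |>
    filter(!is.na(.data$alt_count), .data$alt_count >= 1) |>
    inner_join(select(pedigree, "family_id", "individual_id"), by = "individual_id") |>
    count(.data$variant_id, .data$family_id, name = "n_index_carriers") |>
    rename(index_variant_id = "variant_id")
  seg_calls |>
    left_join(select(mapping, -"gene"), by = "variant_id") |>
    left_join(carriers, by = c("index_variant_id", "family_id")) |>
    mutate(n_index_carriers = ifelse(
      is.na(.data$index_variant_id), NA_integer_,
      dplyr::coalesce(.data$n_index_carriers, 0L)
    ))
}

#' Does the index SNP co-segregate with a completely segregating variant?
#'
#' True when the GWAS index SNP itself satisfies the complete-segregation
#' rule in the same family as the (COMPLETE) rare-variant call.
#'
#' @param variant_call A one-row segregation call with `status = "COMPLETE"`.
#' @param family Pedigree rows for that family.
#' @param index_dosages Index-SNP dosages for the family (tibble or named
#'   vector, as in [classify_family_segregation()]).
#' @param buffer Age buffer in years.
#' @param onset_reference Onset reference mode.
#' @return Logical scalar.
#' @export
cosegregates_with_index <- function(variant_call, family, index_dosages, buffer = 5,
                                    onset_reference = c("carrier_mean", "family_mean")) {
  onset_reference <- match.arg(onset_reference)
  if (!identical(variant_call$status, "COMPLETE")) {
    rlang::abort("cosegregates_with_index requires a COMPLETE variant call")
  }
  idx <- classify_family_segregation(
    family, index_dosages,
    buffer = buffer, onset_reference = onset_reference
  )
  idx$status == "COMPLETE"
}
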