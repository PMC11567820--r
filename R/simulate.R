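# Synthetic two-cohort family generator with planted segregation structure.
# Carrier status is assigned directly to satisfy the planted patterns;
# Mendelian transmission through the pedigree is not simulated (parent ids
# are cosmetic), because the segregation classifier consumes carrier status
# and ages only.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohorts()]. The
#' defaults emulate the structure of two multiplex late-onset familial AD
#' cohorts: affected onset ages Normal(75.2, 8.0) years, two cohorts of 197
#' and 214 families, and family explanation fractions 17.5% rare-variant
#' explained, 22.6% APOE-only, 59.9% unexplained.
#'
#' @param seed Integer seed; fixes all randomness in [simulate_cohorts()].
#' @param n_families Named integer vector: families per cohort.
#' @param family_size `c(min, max)` members per family.
#' @param n_affected `c(min, max)` affected members per family (min >= 2; at
#'   least one member is left unaffected).
#' @param onset_mean,onset_sd Affected age-at-onset distribution (years).
#' @param unaffected_age_mean,unaffected_age_sd Age at last disease-free
#'   exam for unaffected members (years).
#' @param fractions Named simplex weights `rare_explained`, `apoe_only`,
#'   `unexplained`.
#' @param buffer Age buffer (years) that planted structures are built to
#'   satisfy.
#' @param unaffected_carrier_prob Probability that an unaffected member of a
#'   family with a planted segregating variant is a young qualifying
#'   carrier. Their ages are drawn to straddle the buffer boundary
#'   deliberately (some land exactly on it).
#' @param n_incomplete_variants Cohort-wide incompletely segregating
#'   variants planted per cohort.
#' @param incomplete_affected_carriers Affected carriers (each in a distinct
#'   family) per planted incomplete variant; must be >= 4.
#' @param incomplete_unaffected_carriers Qualifying unaffected carriers per
#'   planted incomplete variant; must be fewer than the affected carriers.
#' @param n_none_variants Planted carried-but-not-segregating variants per
#'   cohort (one affected carrier plus one unaffected carrier too old to
#'   qualify).
#' @param ld_haplotype_freqs Haplotype frequencies `(f00, f01, f10, f11)`
#'   for the planted cohort-wide LD variant pair; defaults give expected
#'   r-squared 0.5.
#' @param index_maf Allele frequency of planted GWAS index SNPs.
#' @param qc_noise Named rates `low_dp`, `low_gq`, `missing` applied to the
#'   planted damaging-variant genotype rows (all 0 by default).
#' @return A validated list of class `famseg_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = c(AD_FBS = 197L, EFIGA = 214L),
                       family_size = c(min = 4L, max = 8L),
                       n_affected = c(min = 2L, max = 4L),
                       onset_mean = 75.2, onset_sd = 8.0,
                       unaffected_age_mean = 71.6, unaffected_age_sd = 9.5,
                       fractions = c(rare_explained = 0.175, apoe_only = 0.226, unexplained = 0.599),
                       buffer = 5,
                       unaffected_carrier_prob = 0.3,
                       n_incomplete_variants = 2L,
                       incomplete_affected_carriers = 5L,
                       incomplete_unaffected_carriers = 2L,
                       n_none_variants = 2L,
                       ld_haplotype_freqs = NULL,
                       index_maf = 0.3,
                       qc_noise = c(low_dp = 0, low_gq = 0, missing = 0)) {
  if (is.null(ld_haplotype_freqs)) {
    # pA = pB = 0.5 with D chosen so D^2 / 0.0625 = 0.5
    d <- sqrt(0.5 * 0.0625)
    ld_haplotype_freqs <- c(f00 = 0.25 + d, f01 = 0.25 - d, f10 = 0.25 - d, f11 = 0.25 + d)
  }
  cfg <- list(
    seed = as.integer(seed), n_families = n_families,
    family_size = family_size, n_affected = n_affected,
    onset_mean = onset_mean, onset_sd = onset_sd,
    unaffected_age_mean = unaffected_age_mean, unaffected_age_sd = unaffected_age_sd,
    fractions = fractions, buffer = buffer,
    unaffected_carrier_prob = unaffected_carrier_prob,
    n_incomplete_variants = as.integer(n_incomplete_variants),
    incomplete_affected_carriers = as.integer(incomplete_affected_carriers),
    incomplete_unaffected_carriers = as.integer(incomplete_unaffected_carriers),
    n_none_variants = as.integer(n_none_variants),
    ld_haplotype_freqs = ld_haplotype_freqs,
    index_maf = index_maf, qc_noise = qc_noise
  )
  validate_sim_config(cfg)
  structure(cfg, class = "famseg_sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    length(cfg$n_families) >= 1, !is.null(names(cfg$n_families)),
    all(cfg$n_families >= 0),
    cfg$onset_sd > 0, cfg$unaffected_age_sd > 0,
    cfg$family_size["min"] >= 3, cfg$family_size["max"] >= cfg$family_size["min"],
    cfg$n_affected["min"] >= 2, cfg$n_affected["max"] >= cfg$n_affected["min"],
    cfg$buffer >= 0,
    cfg$unaffected_carrier_prob >= 0, cfg$unaffected_carrier_prob <= 1,
    all(cfg$qc_noise >= 0), all(cfg$qc_noise <= 1)
  )
  if (cfg$family_size["min"] < cfg$n_affected["min"] + 1) {
    rlang::abort("infeasible config: family_size min must exceed n_affected min (>=1 unaffected member)")
  }
  if (abs(sum(cfg$fractions) - 1) > 1e-6 || any(cfg$fractions < 0)) {
    rlang::abort("infeasible config: fractions must be non-negative and sum to 1")
  }
  if (!setequal(names(cfg$fractions), c("rare_explained", "apoe_only", "unexplained"))) {
    rlang::abort("fractions must be named rare_explained, apoe_only, unexplained")
  }
  if (cfg$n_incomplete_variants > 0 && cfg$incomplete_affected_carriers < 4) {
    rlang::abort("infeasible config: an incomplete variant needs >= 4 affected carriers")
  }
  if (cfg$incomplete_unaffected_carriers >= cfg$incomplete_affected_carriers) {
    rlang::abort("infeasible config: incomplete variants need more affected than unaffected carriers")
  }
  invisible(cfg)
}

# Gene symbols used for planted annotations; cycled as needed.
sim_gene_pool <- function() {
  c(
    "ABCA1", "ABCA7", "ABI3", "ACE", "ADAM10", "ADAMTS1", "ADAMTS20", "AKAP9",
    "ANK3", "BCKDK", "CR1", "CTSB", "DOC2A", "ECHDC3", "EED", "EPHA1",
    "GPR141", "HS3ST5", "IDUA", "IL34", "LILRB2", "MYO15A", "NME8", "NYAP1",
    "PLCG2", "PRDM7", "PRKD3", "PSEN1", "PTK2B", "RBCK1", "SFRP4", "SLC26A1",
    "SNX1", "SORL1", "SPPL2A", "TNIP1", "TPCN1", "TREML2", "TSPOAP1",
    "UNC5CL", "USP6NL", "WDR81"
  )
}

#' Draw a genotype pair with a planted level of linkage disequilibrium
#'
#' Each individual receives two haplotypes drawn independently from the
#' supplied two-locus haplotype frequencies, so the expected r-squared
#' between the two dosage columns equals the closed form
#' [haplotype_r2()] of those frequencies.
#'
#' @param haplotype_freqs Frequencies `(f00, f01, f10, f11)`; non-negative,
#'   summing to 1, with both loci polymorphic.
#' @param n_samples Number of individuals to draw.
#' @return A tibble with `dosage_a`, `dosage_b`; the closed-form r-squared is
#'   attached as attribute `"expected_r2"`.
#' @export
plant_ld_pair <- function(haplotype_freqs, n_samples) {
  expected <- haplotype_r2(haplotype_freqs) # validates, errors on degenerate freqs
  haps <- sample.int(4, 2 * n_samples, replace = TRUE, prob = haplotype_freqs)
  a_allele <- as.integer(haps %in% c(3, 4))
  b_allele <- as.integer(haps %in% c(2, 4))
  out <- tibble::tibble(
    dosage_a = a_allele[seq(1, 2 * n_samples, by = 2)] + a_allele[seq(2, 2 * n_samples, by = 2)],
    dosage_b = b_allele[seq(1, 2 * n_samples, by = 2)] + b_allele[seq(2, 2 * n_samples, by = 2)]
  )
  attr(out, "expected_r2") <- expected
  out
}

#' Simulate two family cohorts with planted segregation structure
#'
#' Generates pedigrees, variant annotations and genotypes for the configured
#' cohorts, planting per family one of three truths: a rare damaging variant
#' in complete segregation (`RARE_EXPLAINED`), APOE epsilon-4 as the only
#' segregating allele (`APOE_ONLY`), or nothing (`UNEXPLAINED`). Each cohort
#' additionally carries planted cohort-wide incompletely segregating
#' variants, carried-but-non-segregating variants, per-gene common index
#' SNPs, and one variant pair with a planted level of LD. Planted structures
#' are verified against the segregation rule before returning; identical
#' configurations (including the seed) give identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `famseg_sim`: `pedigree`, `variants`, `genotypes`,
#'   `index_snps`, `ld_pairs`, `truth_families`, `truth_variants`, `config`.
#' @export
simulate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "famseg_sim_config"))
  with_seed(config$seed, simulate_cohorts_impl(config))
}

simulate_cohorts_impl <- function(cfg) {
  genes <- sim_gene_pool()
  variant_counter <- 0
  index_by_gene <- list()
  ped_list <- list()
  var_list <- list()
  gt_list <- list()
  idx_list <- list()
  ld_list <- list()
  tf_list <- list()
  tv_list <- list()

  new_variant <- function(gene, cohort, kind) {
    variant_counter <<- variant_counter + 1
    chrom <- paste0("chr", 1 + (variant_counter %% 22))
    pos <- 1e6 + variant_counter * 1000 + sample.int(999, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    consequence <- switch(kind,
      damaging = sample(
        c("missense_variant", "stop_gained", "frameshift_variant", "splice_acceptor_variant"),
        1,
        prob = c(0.6, 0.15, 0.15, 0.1)
      ),
      common = "intron_variant"
    )
    cadd <- if (consequence == "missense_variant") {
      runif(1, 21, 45)
    } else if (kind == "damaging") {
      if (runif(1) < 0.3) NA_real_ else runif(1, 15, 50)
    } else {
      runif(1, 0, 10)
    }
    af <- if (kind == "damaging") {
      if (runif(1) < 0.1) NA_real_ else runif(1, 0, 0.009)
    } else {
      runif(1, 0.1, 0.4)
    }
    tibble::tibble(
      variant_id = variant_key(chrom, pos, ref, alt),
      chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
      filter_status = "PASS", gene = gene, consequence = consequence,
      cadd_phred = round(cadd, 2), gnomad_af = signif(af, 3)
    )
  }

  for (cohort in names(cfg$n_families)) {
    n_fam <- cfg$n_families[[cohort]]
    if (n_fam == 0) next

    labels <- sample(
      c("RARE_EXPLAINED", "APOE_ONLY", "UNEXPLAINED"),
      n_fam,
      replace = TRUE,
      prob = cfg$fractions[c("rare_explained", "apoe_only", "unexplained")]
    )

    fams <- vector("list", n_fam)
    for (i in seq_len(n_fam)) {
      size <- sample(seq(cfg$family_size["min"], cfg$family_size["max"]), 1)
      max_aff <- min(cfg$n_affected["max"], size - 1)
      n_aff <- sample(seq(cfg$n_affected["min"], max_aff), 1)
      fid <- sprintf("%s_F%04d", cohort, i)
      iids <- sprintf("%s_I%02d", fid, seq_len(size))
      aff_idx <- sort(sample(size, n_aff))
      affection <- ifelse(seq_len(size) %in% aff_idx, "affected", "unaffected")
      age <- numeric(size)
      age[aff_idx] <- round(pmin(pmax(rnorm(n_aff, cfg$onset_mean, cfg$onset_sd), 45), 110), 1)
      age[-aff_idx] <- round(pmin(pmax(
        rnorm(size - n_aff, cfg$unaffected_age_mean, cfg$unaffected_age_sd), 40
      ), 105), 1)
      fams[[i]] <- tibble::tibble(
        cohort_id = cohort, family_id = fid, individual_id = iids,
        father_id = c("0", "0", rep(iids[1], size - 2)),
        mother_id = c("0", "0", rep(iids[2], size - 2)),
        sex = sample(c("male", "female"), size, replace = TRUE),
        affection = affection, age_years = age
      )
    }

    apoe429 <- list() # individual_id -> dosage at rs429358
    apoe7412 <- list()

    # Force young qualifying ages onto unaffected carriers; some land exactly
    # on the buffer boundary to exercise the >= comparison.
    qualifying_age <- function(onset_ref, n) {
      at_boundary <- runif(n) < 0.2
      age <- onset_ref - cfg$buffer - ifelse(at_boundary, 0, runif(n, 0.5, 8))
      age <- pmax(floor(age * 10) / 10, 40)
      # an age placed exactly on the buffer boundary can fail the >= test by
      # one ulp in binary arithmetic; nudge down until it qualifies as computed
      repeat {
        bad <- (onset_ref - age) < cfg$buffer
        if (!any(bad)) break
        age[bad] <- age[bad] - 0.1
      }
      age
    }

    for (i in seq_len(n_fam)) {
      fam <- fams[[i]]
      aff <- fam$affection == "affected"
      una <- !aff
      label <- labels[i]

      if (label == "RARE_EXPLAINED") {
        v <- new_variant(sample(genes, 1), cohort, "damaging")
        # Guarantee prioritisation: missense CADD > 20 already; make AF rare.
        dos <- integer(nrow(fam))
        dos[aff] <- 1L
        u_carrier <- una & runif(nrow(fam)) < cfg$unaffected_carrier_prob
        if (any(u_carrier)) {
          onset_ref <- mean(fam$age_years[aff])
          fam$age_years[u_carrier] <- qualifying_age(onset_ref, sum(u_carrier))
          dos[u_carrier] <- 1L
        }
        chk <- seg_classify_core(fam$affection, fam$age_years, dos, buffer = cfg$buffer)
        if (chk$status != "COMPLETE") {
          rlang::abort("internal simulator self-check failed for a planted COMPLETE variant")
        }
        var_list[[length(var_list) + 1]] <- v
        gt_list[[length(gt_list) + 1]] <- tibble::tibble(
          variant_id = v$variant_id, individual_id = fam$individual_id,
          alt_count = dos
        )
        tv_list[[length(tv_list) + 1]] <- tibble::tibble(
          cohort_id = cohort, family_id = fam$family_id[1],
          variant_id = v$variant_id, planted_status = "COMPLETE"
        )
        # Index SNP near the locus (one per gene, reused across families),
        # carried at random by family members.
        if (is.null(index_by_gene[[v$gene]])) {
          idx_v <- new_variant(v$gene, cohort, "common")
          index_by_gene[[v$gene]] <- idx_v$variant_id
          idx_list[[length(idx_list) + 1]] <- tibble::tibble(
            gene = v$gene, index_variant_id = idx_v$variant_id
          )
          var_list[[length(var_list) + 1]] <- idx_v
        }
        gt_list[[length(gt_list) + 1]] <- tibble::tibble(
          variant_id = index_by_gene[[v$gene]], individual_id = fam$individual_id,
          alt_count = rbinom(nrow(fam), 2, cfg$index_maf)
        )
        # APOE: either co-segregating, or forced not to segregate.
        if (runif(1) < 0.3) {
          e4 <- plant_apoe_segregation(fam, aff, una, cfg, qualifying_age)
          fam <- e4$fam
          apoe429[[fam$family_id[1]]] <- e4$dosage
          tv_list[[length(tv_list) + 1]] <- tibble::tibble(
            cohort_id = cohort, family_id = fam$family_id[1],
            variant_id = "APOE_e4", planted_status = "COMPLETE"
          )
        } else {
          apoe429[[fam$family_id[1]]] <- plant_apoe_broken(fam, aff)
          tv_list[[length(tv_list) + 1]] <- tibble::tibble(
            cohort_id = cohort, family_id = fam$family_id[1],
            variant_id = "APOE_e4", planted_status = "NONE"
          )
        }
      } else if (label == "APOE_ONLY") {
        e4 <- plant_apoe_segregation(fam, aff, una, cfg, qualifying_age)
        fam <- e4$fam
        apoe429[[fam$family_id[1]]] <- e4$dosage
        tv_list[[length(tv_list) + 1]] <- tibble::tibble(
          cohort_id = cohort, family_id = fam$family_id[1],
          variant_id = "APOE_e4", planted_status = "COMPLETE"
        )
      } else {
        apoe429[[fam$family_id[1]]] <- plant_apoe_broken(fam, aff)
        tv_list[[length(tv_list) + 1]] <- tibble::tibble(
          cohort_id = cohort, family_id = fam$family_id[1],
          variant_id = "APOE_e4", planted_status = "NONE"
        )
      }
      fams[[i]] <- fam
    }

    # Cohort-wide incompletely segregating variants and non-segregating
    # carried variants, planted into disjoint unexplained families so their
    # forced unaffected ages cannot collide with other planted structures.
    unexpl <- sample(which(labels == "UNEXPLAINED"))
    need <- cfg$n_incomplete_variants * cfg$incomplete_affected_carriers + cfg$n_none_variants
    if (length(unexpl) < need) {
      rlang::abort(paste0(
        "infeasible config: cohort ", cohort, " has ", length(unexpl),
        " unexplained families but planted background variants need ", need
      ))
    }
    take <- function(k) {
      out <- unexpl[seq_len(k)]
      unexpl <<- unexpl[-seq_len(k)]
      out
    }
    for (k in seq_len(cfg$n_incomplete_variants)) {
      v <- new_variant(sample(genes, 1), cohort, "damaging")
      fam_idx <- take(cfg$incomplete_affected_carriers)
      rows <- list()
      onset_by_fam <- numeric(0)
      for (fi in fam_idx) {
        fam <- fams[[fi]]
        carrier <- sample(which(fam$affection == "affected"), 1)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variant_id = v$variant_id, individual_id = fam$individual_id[carrier],
          alt_count = 1L
        )
        onset_by_fam[fam$family_id[1]] <- fam$age_years[carrier]
      }
      u_done <- 0
      for (fi in fam_idx) {
        if (u_done >= cfg$incomplete_unaffected_carriers) break
        fam <- fams[[fi]]
        u_idx <- which(fam$affection == "unaffected")
        if (length(u_idx) == 0) next
        u <- u_idx[1]
        fam$age_years[u] <- qualifying_age(onset_by_fam[fam$family_id[1]], 1)
        fams[[fi]] <- fam
        rows[[length(rows) + 1]] <- tibble::tibble(
          variant_id = v$variant_id, individual_id = fam$individual_id[u],
          alt_count = 1L
        )
        u_done <- u_done + 1
      }
      var_list[[length(var_list) + 1]] <- v
      gt_list[[length(gt_list) + 1]] <- bind_rows(rows)
      tv_list[[length(tv_list) + 1]] <- tibble::tibble(
        cohort_id = cohort, family_id = NA_character_,
        variant_id = v$variant_id, planted_status = "INCOMPLETE"
      )
    }
    for (k in seq_len(cfg$n_none_variants)) {
      v <- new_variant(sample(genes, 1), cohort, "damaging")
      fi <- take(1)
      fam <- fams[[fi]]
      carrier <- sample(which(fam$affection == "affected"), 1)
      rows <- tibble::tibble(
        variant_id = v$variant_id, individual_id = fam$individual_id[carrier],
        alt_count = 1L
      )
      u_idx <- which(fam$affection == "unaffected")
      if (length(u_idx) > 0) {
        u <- u_idx[1]
        # Too old to qualify: within the buffer of the carrier's onset age.
        fam$age_years[u] <- round(max(fam$age_years[carrier] - cfg$buffer + 1, 40), 1)
        fams[[fi]] <- fam
        rows <- bind_rows(rows, tibble::tibble(
          variant_id = v$variant_id, individual_id = fam$individual_id[u],
          alt_count = 1L
        ))
      }
      var_list[[length(var_list) + 1]] <- v
      gt_list[[length(gt_list) + 1]] <- rows
      tv_list[[length(tv_list) + 1]] <- tibble::tibble(
        cohort_id = cohort, family_id = fam$family_id[1],
        variant_id = v$variant_id, planted_status = "NONE"
      )
    }

    ped <- bind_rows(fams)

    # APOE genotype rows for every individual. rs7412 (e2) alleles are only
    # placed on rs429358-reference individuals, so no double heterozygotes
    # arise from the background and planted e4 status is unambiguous.
    d429 <- unlist(lapply(unique(ped$family_id), function(f) apoe429[[f]]), use.names = FALSE)
    d7412 <- ifelse(d429 == 0 & runif(length(d429)) < 0.08, 1L, 0L)
    apoe_sites <- apoe_default_sites()
    gt_list[[length(gt_list) + 1]] <- tibble::tibble(
      variant_id = apoe_sites$rs429358, individual_id = ped$individual_id,
      alt_count = as.integer(d429)
    )
    gt_list[[length(gt_list) + 1]] <- tibble::tibble(
      variant_id = apoe_sites$rs7412, individual_id = ped$individual_id,
      alt_count = d7412
    )

    # Cohort-wide LD variant pair with a planted r-squared.
    ld <- plant_ld_pair(cfg$ld_haplotype_freqs, nrow(ped))
    ld_a <- new_variant(sample(genes, 1), cohort, "common")
    ld_b <- new_variant(ld_a$gene, cohort, "common")
    var_list[[length(var_list) + 1]] <- ld_a
    var_list[[length(var_list) + 1]] <- ld_b
    gt_list[[length(gt_list) + 1]] <- tibble::tibble(
      variant_id = ld_a$variant_id, individual_id = ped$individual_id,
      alt_count = ld$dosage_a
    )
    gt_list[[length(gt_list) + 1]] <- tibble::tibble(
      variant_id = ld_b$variant_id, individual_id = ped$individual_id,
      alt_count = ld$dosage_b
    )
    ld_list[[length(ld_list) + 1]] <- tibble::tibble(
      cohort_id = cohort, variant_a = ld_a$variant_id, variant_b = ld_b$variant_id,
      expected_r2 = attr(ld, "expected_r2")
    )

    ped_list[[length(ped_list) + 1]] <- ped
    tf_list[[length(tf_list) + 1]] <- tibble::tibble(
      cohort_id = cohort,
      family_id = vapply(fams, function(f) f$family_id[1], character(1)),
      label = labels
    )
  }

  pedigree <- bind_rows(ped_list)

  # The two APOE coding SNPs as variant records (common missense, low CADD:
  # excluded from the rare-damaging track by the AF filter, but present in
  # the VCF so the on-disk round trip preserves epsilon-4 calls).
  if (nrow(pedigree) > 0) {
    apoe_sites <- apoe_default_sites()
    apoe_coords <- parse_variant_key(c(apoe_sites$rs429358, apoe_sites$rs7412))
    var_list[[length(var_list) + 1]] <- tibble::tibble(
      variant_id = c(apoe_sites$rs429358, apoe_sites$rs7412),
      chrom = apoe_coords$chrom, pos = apoe_coords$pos,
      ref = apoe_coords$ref, alt = apoe_coords$alt,
      filter_status = "PASS", gene = "APOE",
      consequence = "missense_variant", cadd_phred = c(12.4, 16.5),
      gnomad_af = c(0.155, 0.062)
    )
  }

  if (nrow(pedigree) == 0) {
    pedigree <- tibble::tibble(
      cohort_id = character(), family_id = character(), individual_id = character(),
      father_id = character(), mother_id = character(), sex = character(),
      affection = character(), age_years = numeric()
    )
  }
  gt_proto <- tibble::tibble(
    variant_id = character(), individual_id = character(), alt_count = integer()
  )
  var_proto <- tibble::tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), filter_status = character(),
    gene = character(), consequence = character(),
    cadd_phred = numeric(), gnomad_af = numeric()
  )
  genotypes <- bind_rows(c(list(gt_proto), gt_list)) |>
    mutate(
      dp = sample(20:60, dplyr::n(), replace = TRUE),
      gq = sample(30:99, dplyr::n(), replace = TRUE)
    )

  # QC noise on planted damaging-variant rows.
  variants <- bind_rows(c(list(var_proto), var_list))
  noisy_ids <- variants$variant_id[variants$consequence != "intron_variant"]
  target <- genotypes$variant_id %in% noisy_ids
  nz <- cfg$qc_noise
  if (any(nz > 0)) {
    hit_dp <- target & runif(nrow(genotypes)) < nz[["low_dp"]]
    hit_gq <- target & runif(nrow(genotypes)) < nz[["low_gq"]]
    hit_mi <- target & runif(nrow(genotypes)) < nz[["missing"]]
    genotypes$dp[hit_dp] <- sample(0:9, sum(hit_dp), replace = TRUE)
    genotypes$gq[hit_gq] <- sample(0:19, sum(hit_gq), replace = TRUE)
    genotypes$alt_count[hit_mi] <- NA_integer_
  }

  structure(
    list(
      pedigree = pedigree,
      variants = variants,
      genotypes = genotypes,
      index_snps = if (length(idx_list) > 0) distinct(bind_rows(idx_list)) else
        tibble::tibble(gene = character(), index_variant_id = character()),
      ld_pairs = bind_rows(ld_list),
      truth_families = bind_rows(tf_list),
      truth_variants = bind_rows(tv_list),
      config = cfg
    ),
    class = "famseg_sim"
  )
}

# All affected carry one e4 allele; unaffected are non-carriers or young
# qualifying carriers. Returns the updated family (ages may be forced) and
# the rs429358 dosage vector.
plant_apoe_segregation <- function(fam, aff, una, cfg, qualifying_age) {
  dos <- integer(nrow(fam))
  dos[aff] <- 1L
  u_carrier <- una & runif(nrow(fam)) < cfg$unaffected_carrier_prob
  if (any(u_carrier)) {
    onset_ref <- mean(fam$age_years[aff])
    fam$age_years[u_carrier] <- qualifying_age(onset_ref, sum(u_carrier))
    dos[u_carrier] <- 1L
  }
  chk <- seg_classify_core(fam$affection, fam$age_years, dos, buffer = cfg$buffer)
  if (chk$status != "COMPLETE") {
    rlang::abort("internal simulator self-check failed for planted APOE segregation")
  }
  list(fam = fam, dosage = dos)
}

# At least one affected member is forced e4-free, so e4 cannot satisfy the
# all-affected-carry condition; everyone else draws background dosages.
plant_apoe_broken <- function(fam, aff) {
  dos <- rbinom(nrow(fam), 2, 0.15)
  dos[sample(which(aff), 1)] <- 0L
  dos
}

#' @export
print.famseg_sim <- function(x, ...) {
  cat("famseg synthetic cohort simulation\n")
  cat("  cohorts:    ", paste(names(x$config$n_families), collapse = ", "), "\n")
  cat("  families:   ", nrow(x$truth_families), "\n")
  cat("  individuals:", nrow(x$pedigree), "\n")
  cat("  variants:   ", nrow(x$variants), "\n")
  invisible(x)
}
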