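# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Canonical variant key: chrom:pos:ref:alt.
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Split a "chr1:123:A:T" key back into its fields.
parse_variant_key <- function(key) {
  parts <- stringr::str_split_fixed(key, ":", 4)
  tibble::tibble(
    chrom = parts[, 1],
    pos = as.integer(parts[, 2]),
    ref = parts[, 3],
    alt = parts[, 4]
  )
}

# Numeric chromosome order for deterministic sorting (chr1..chr22, chrX, chrY, rest).
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom)
  rank <- suppressWarnings(as.numeric(core))
  rank[core == "X"] <- 23
  rank[core == "Y"] <- 24
  rank[core == "M" | core == "MT"] <- 25
  rank[is.na(rank)] <- 26
  rank
}

# Evaluate code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

path_to_extdata <- function(file) {
  path <- system.file("extdata", file, package = "famseg")
  if (!nzchar(path)) {
    rlang::abort(paste0("packaged reference file not found: ", file))
  }
  path
}
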