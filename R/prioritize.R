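# Consequence classification and damaging-variant prioritisation.

#' Consequence classes recognised by the pipeline
#'
#' Loss-of-function classes are stopgain, stoploss, frameshift and the two
#' canonical splice-site classes; splice-region changes are deliberately not
#' counted as LoF.
#'
#' @format Character vectors of class labels.
#' @name consequence_classes
#' @export
consequence_levels <- c(
  "stopgain", "stoploss", "frameshift",
  "splice_acceptor", "splice_donor", "missense", "other"
)

#' @rdname consequence_classes
#' @export
lof_classes <- c("stopgain", "stoploss", "frameshift", "splice_acceptor", "splice_donor")

default_consequence_synonyms <- c(
  "stop_gained" = "stopgain",
  "stopgain" = "stopgain",
  "stop_gain" = "stopgain",
  "stop_lost" = "stoploss",
  "stoploss" = "stoploss",
  "stop_loss" = "stoploss",
  "frameshift_variant" = "frameshift",
  "frameshift" = "frameshift",
  "frameshift_insertion" = "frameshift",
  "frameshift_deletion" = "frameshift",
  "splice_acceptor_variant" = "splice_acceptor",
  "splice_acceptor" = "splice_acceptor",
  "splice_donor_variant" = "splice_donor",
  "splice_donor" = "splice_donor",
  "missense_variant" = "missense",
  "missense" = "missense",
  "nonsynonymous_snv" = "missense"
)

#' Map annotation spellings onto consequence classes
#'
#' Normalises the consequence strings emitted by common annotators (VEP/
#' ANNOVAR style, e.g. `"stop_gained"`, `"frameshift_variant"`,
#' `"missense_variant"`) onto the pipeline's seven-level class enum. Unknown
#' spellings map to `"other"`; matching is case-insensitive and tolerant of
#' spaces versus underscores. Supply `synonyms` to extend the map for a local
#' annotation dialect (for example, mapping a structural-interaction label to
#' an LoF class).
#'
#' @param x Character vector of annotation consequence strings.
#' @param synonyms Named character vector mapping spellings to class labels;
#'   merged over the built-in map.
#' @return A character vector over [consequence_levels].
#' @export
#' @examples
#' classify_consequence(c("stop_gained", "missense_variant", "synonymous_variant"))
classify_consequence <- function(x, synonyms = NULL) {
  map <- default_consequence_synonyms
  if (!is.null(synonyms)) {
    map[names(synonyms)] <- synonyms
  }
  key <- gsub(" ", "_", tolower(trimws(as.character(x))))
  out <- unname(map[key])
  out[is.na(out) & !is.na(x)] <- "other"
  out
}

#' Call variants damaging
#'
#' A variant is prioritised as damaging when it is loss-of-function
#' (stopgain, stoploss, frameshift, or canonical splice acceptor/donor —
#' regardless of CADD), or missense with CADD phred strictly greater than
#' `cadd_threshold` (default 20). Missense variants with no CADD score are
#' conservatively called `NOT_DAMAGING`, with a warning.
#'
#' @param variants Annotated variant tibble with `consequence` (raw string or
#'   already-classified) and `cadd_phred` columns.
#' @param cadd_threshold Strict CADD phred cutoff for missense variants.
#' @param synonyms Optional consequence synonym map, see
#'   [classify_consequence()].
#' @return The variant tibble with `consequence_class` and `damaging`
#'   (`"LOF"`, `"DAMAGING_MISSENSE"`, `"NOT_DAMAGING"`) columns.
#' @export
is_damaging <- function(variants, cadd_threshold = 20, synonyms = NULL) {
  cls <- classify_consequence(variants$consequence, synonyms = synonyms)
  missense_no_cadd <- cls == "missense" & is.na(variants$cadd_phred)
  if (any(missense_no_cadd, na.rm = TRUE)) {
    rlang::warn(paste0(
      sum(missense_no_cadd, na.rm = TRUE),
      " missense variant(s) without a CADD score called NOT_DAMAGING"
    ))
  }
  variants |>
    mutate(
      consequence_class = cls,
      damaging = dplyr::case_when(
        .data$consequence_class %in% lof_classes ~ "LOF",
        .data$consequence_class == "missense" &
          !is.na(.data$cadd_phred) & .data$cadd_phred > cadd_threshold ~ "DAMAGING_MISSENSE",
        .default = "NOT_DAMAGING"
      )
    )
}
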