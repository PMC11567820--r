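# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort summary
#'
#' Long format: one row per (cohort, statistic).
#'
#' @param x A `famseg_summary` from [summarize_cohorts()].
#' @param ... Ignored.
#' @return A tibble with `cohort_id`, `statistic`, `value`.
#' @exportS3Method generics::tidy
tidy.famseg_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x)) |>
    tidyr::pivot_longer(-"cohort_id", names_to = "statistic", values_to = "value")
}

#' Glance at a cohort summary
#'
#' The combined (pooled) row as a one-row tibble.
#'
#' @param x A `famseg_summary`.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.famseg_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x)) |> filter(.data$cohort_id == "COMBINED")
}

#' Tidy an LD result
#'
#' @param x A `famseg_ld` from [genotype_r2()] or [em_haplotype_r2()].
#' @param ... Ignored.
#' @return The underlying one-row tibble.
#' @exportS3Method generics::tidy
tidy.famseg_ld <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Glance at an LD result
#'
#' @param x A `famseg_ld`.
#' @param ... Ignored.
#' @return A one-row tibble with `r2`, `n_samples`, `method`.
#' @exportS3Method generics::glance
glance.famseg_ld <- function(x, ...) {
  tibble::as_tibble(unclass(x)) |> select("r2", "n_samples", "method")
}
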