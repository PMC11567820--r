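# ggplot2 displays for the main result types.

#' Plot family explanation labels per cohort
#'
#' Stacked bars of rare-variant-explained / APOE-only / unexplained family
#' counts by cohort.
#'
#' @param explanations Output of [classify_family_explanation()].
#' @return A ggplot object.
#' @export
plot_family_explanations <- function(explanations) {
  ggplot2::ggplot(
    explanations,
    ggplot2::aes(x = .data$cohort_id, fill = .data$label)
  ) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(
      x = NULL, y = "families", fill = NULL,
      title = "Family explanation by cohort"
    ) +
    ggplot2::theme_minimal()
}

#' Plot segregation calls
#'
#' Counts of per-family segregation verdicts by cohort.
#'
#' @param seg_calls Output of [segregate_cohort()].
#' @return A ggplot object.
#' @export
plot_segregation_calls <- function(seg_calls) {
  ggplot2::ggplot(
    seg_calls,
    ggplot2::aes(x = .data$cohort_id, fill = .data$status)
  ) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "(variant, family) pairs", fill = NULL,
      title = "Per-family segregation calls"
    ) +
    ggplot2::theme_minimal()
}

#' Plot LD scan results
#'
#' r-squared per variant pair, coloured by the in-LD flag.
#'
#' @param ld Output of [ld_scan()].
#' @return A ggplot object.
#' @export
plot_ld <- function(ld) {
  ld <- ld |> mutate(pair = paste(.data$variant_a, .data$variant_b, sep = " ~ "))
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$r2, y = .data$pair, colour = .data$in_ld)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = expression(r^2), y = NULL, colour = "in LD",
      title = "LD between index SNPs and rare variants"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a cohort summary
#'
#' Percentage of families per explanation class and cohort.
#'
#' @param object A `famseg_summary` from [summarize_cohorts()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.famseg_summary <- function(object, ...) {
  long <- tidy.famseg_summary(object) |>
    filter(stringr::str_starts(.data$statistic, "pct_"))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$cohort_id, y = .data$value, fill = .data$statistic)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "% of families", fill = NULL,
      title = "Family explanation percentages"
    ) +
    ggplot2::theme_minimal()
}
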