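#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_step geom_hline
#'   geom_boxplot geom_jitter labs theme_minimal
#' @export
ggplot2::autoplot

#' Ranked-distance plot for a barcode-gap assessment
#'
#' Ranked pairwise p-distances with a dashed line at the maximum
#' intraspecific divergence; a barcode gap appears as a sudden vertical jump
#' just above the line.
#'
#' @param object A `barcode_gap` from [barcode_gap_assess()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.barcode_gap <- function(object, ...) {
  dat <- tidy(object)
  ggplot(dat, aes(x = .data$rank, y = .data$distance)) +
    geom_step() +
    geom_hline(yintercept = object$d_intra_max, linetype = "dashed") +
    labs(
      x = "ranked pairwise comparisons", y = "p-distance",
      title = if (object$gap_found) "barcode gap found" else "no barcode gap"
    ) +
    theme_minimal()
}

#' Discrimination-rate plot for a combination grid
#'
#' Species-discrimination rate against combination size, one box per method,
#' mirroring the usual multi-method barcode evaluation figure.
#'
#' @param object A `discrimination_report` from [evaluate_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.discrimination_report <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot(dat, aes(x = factor(.data$n_markers), y = .data$rate, fill = .data$method)) +
    geom_boxplot(outlier.size = 0.6, position = "dodge") +
    labs(
      x = "number of combined markers", y = "species discrimination rate (%)",
      fill = "method"
    ) +
    theme_minimal()
}
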