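#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname barcode_gap_assess
#' @param x A `barcode_gap` object.
#' @param ... Unused.
#' @export
tidy.barcode_gap <- function(x, ...) {
  tibble(rank = seq_along(x$ranked), distance = x$ranked)
}

#' @rdname barcode_gap_assess
#' @export
glance.barcode_gap <- function(x, ...) {
  tibble(
    n_distances = length(x$ranked),
    d_intra_max = x$d_intra_max,
    gap_found = x$gap_found,
    gap_lo = if (x$gap_found) x$gap_interval[1] else NA_real_,
    gap_hi = if (x$gap_found) x$gap_interval[2] else NA_real_,
    gap_factor = x$gap_factor
  )
}

#' @rdname abgd_partition
#' @param x An `abgd_partition` object.
#' @param ... Unused.
#' @export
tidy.abgd_partition <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$groups, function(g, i) {
    tibble(individual = g, group = i)
  }))
}

#' @rdname abgd_partition
#' @export
glance.abgd_partition <- function(x, ...) {
  tibble(
    n_groups = length(x$groups),
    prior_P = x$prior_P,
    threshold = x$threshold,
    n_delimited = length(x$delimited_species %||% character(0))
  )
}

#' @rdname evaluate_all
#' @param x A `discrimination_report`.
#' @param ... Unused.
#' @export
glance.discrimination_report <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$method) |>
    summarise(
      n_combinations = dplyr::n(),
      best_rate = max(.data$rate, na.rm = TRUE),
      best_combination = .data$markers[which.max(.data$rate)],
      .groups = "drop"
    )
}
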