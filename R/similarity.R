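#' Leave-self-out top-hit classification
#'
#' Emulates a local similarity search over aligned barcode matrices: the
#' similarity of a query to a reference is the identity fraction over the
#' columns where both carry an unambiguous base (i.e. `1 - p`-distance).
#' Each query individual is ranked against every reference except itself;
#' the query counts as conspecific-matched only when the best score is
#' attained exclusively by conspecific references (any heterospecific tie at
#' the top fails, and is flagged).
#'
#' @param query_aln A [marker_alignment()] of query individuals.
#' @param map A species map tibble covering query and reference individuals.
#' @param ref_aln Reference alignment on compatible column coordinates
#'   (default: the query alignment itself, giving leave-one-out
#'   classification; pass a concatenated multi-marker alignment to query a
#'   pooled reference database).
#' @return A tibble with one row per query: `individual`, `species`,
#'   `best_hit`, `best_score`, `top_conspecific`, `tie`, `unclassifiable`.
#' @export
top_hit_classify <- function(query_aln, map, ref_aln = query_aln) {
  qm <- base_int(unclass(query_aln))
  rm_ <- base_int(unclass(ref_aln))
  if (ncol(qm) != ncol(rm_)) abort("query and reference alignments must share column coordinates")
  qids <- rownames(query_aln); rids <- rownames(ref_aln)
  qsp <- species_of(qids, map); rsp <- species_of(rids, map)

  qv <- !is.na(qm); rv <- !is.na(rm_)
  shared <- tcrossprod(matrix(as.numeric(qv), nrow(qm)), matrix(as.numeric(rv), nrow(rm_)))
  matches <- matrix(0, nrow(qm), nrow(rm_))
  for (b in 1:4) {
    matches <- matches + tcrossprod(
      matrix(as.numeric(qv & qm == b), nrow(qm)),
      matrix(as.numeric(rv & rm_ == b), nrow(rm_))
    )
  }
  sim <- matches / shared
  sim[shared == 0] <- NA_real_

  res <- lapply(seq_along(qids), function(i) {
    s <- sim[i, ]
    s[rids == qids[i]] <- NA_real_ # self excluded
    if (all(is.na(s))) {
      return(tibble(
        individual = qids[i], species = qsp[i], best_hit = NA_character_,
        best_score = NA_real_, top_conspecific = FALSE, tie = FALSE,
        unclassifiable = TRUE
      ))
    }
    best <- max(s, na.rm = TRUE)
    top <- which(s == best)
    top <- top[order(rids[top])]
    tie_sp <- unique(rsp[top])
    conspecific <- identical(tie_sp, qsp[i])
    tibble(
      individual = qids[i], species = qsp[i], best_hit = rids[top[1]],
      best_score = best, top_conspecific = conspecific,
      tie = length(top) > 1L, unclassifiable = FALSE
    )
  })
  dplyr::bind_rows(res)
}

#' Score top-hit results per species
#'
#' A species is identified when every one of its individuals has a
#' conspecific (untied) top hit. Species below `min_individuals` are not
#' eligible: with self-exclusion a singleton can never succeed.
#'
#' @param results Output of [top_hit_classify()].
#' @param min_individuals Minimum individuals for a species to count.
#' @return List with `rate` (percent), `n_identified`, `n_eligible`,
#'   `identified_species`.
#' @export
score_top_hits <- function(results, min_individuals = 2L) {
  per <- results |>
    group_by(.data$species) |>
    summarise(n = dplyr::n(), ok = all(.data$top_conspecific), .groups = "drop") |>
    filter(.data$n >= min_individuals)
  identified <- sort(per$species[per$ok])
  list(
    rate = 100 * length(identified) / max(nrow(per), 1L),
    n_identified = length(identified),
    n_eligible = nrow(per),
    identified_species = identified
  )
}
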