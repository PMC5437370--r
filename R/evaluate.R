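#' Enumerate non-empty marker combinations
#'
#' @param markers Character vector of marker names (1 to 12).
#' @return List of character vectors, ordered by size then lexicographically.
#' @export
#' @examples
#' enumerate_combinations(c("a", "b"))
enumerate_combinations <- function(markers) {
  if (length(markers) < 1L) abort("at least one marker is required")
  if (length(markers) > 12L) abort("more than 12 markers: combination grid too large")
  subsets <- unlist(
    lapply(seq_along(markers), function(k) {
      cols <- utils::combn(sort(markers), k, simplify = FALSE)
      cols[order(vapply(cols, paste, character(1), collapse = "+"))]
    }),
    recursive = FALSE
  )
  subsets
}

#' Concatenate marker alignments
#'
#' Builds a supermatrix over the union of individuals: per-marker blocks in
#' subset order, with individuals missing a marker filled with `?` across
#' that block (pairwise deletion downstream absorbs the missing data).
#'
#' @param alignments Named list of [marker_alignment()]s.
#' @param subset Character vector of marker names to concatenate.
#' @return A [marker_alignment()] with attribute `blocks` (tibble `marker`,
#'   `start`, `end`, 1-based column ranges).
#' @export
concatenate_markers <- function(alignments, subset = names(alignments)) {
  missing <- setdiff(subset, names(alignments))
  if (length(missing) > 0L) {
    abort(paste0("unknown markers: ", paste(missing, collapse = ", ")))
  }
  alns <- alignments[subset]
  all_ids <- sort(unique(unlist(lapply(alns, alignment_ids))))
  blocks <- list()
  pieces <- list()
  at <- 0L
  for (mk in subset) {
    m <- unclass(alns[[mk]])
    L <- ncol(m)
    block <- matrix("?", length(all_ids), L, dimnames = list(all_ids, NULL))
    have <- intersect(all_ids, rownames(m))
    block[have, ] <- m[have, ]
    pieces[[mk]] <- block
    blocks[[mk]] <- tibble(marker = mk, start = at + 1L, end = at + L)
    at <- at + L
  }
  out <- do.call(cbind, pieces)
  structure(
    out,
    class = c("marker_alignment", "matrix"),
    marker_id = paste(subset, collapse = "+"),
    blocks = dplyr::bind_rows(blocks)
  )
}

new_discrimination_report <- function(tab) {
  structure(tab, class = c("discrimination_report", class(tab)))
}

#' Evaluate all marker combinations with the four barcoding methods
#'
#' For every non-empty subset of the supplied markers the requested methods
#' are run on the concatenated supermatrix:
#' \describe{
#'   \item{distance}{ABGD-style partitioning with the observed maximum
#'     intraspecific distance as prior; a species counts when its individuals
#'     form exactly one group alone. All species are eligible.}
#'   \item{similarity}{Leave-self-out top-hit classification; a species
#'     counts when every individual's top hit is conspecific. Eligible:
#'     species with >= 2 individuals.}
#'   \item{character}{Diagnostic logic-formula induction and
#'     self-classification; a species counts when all its individuals are
#'     assigned to it. Eligible: >= 2 individuals (configurable).}
#'   \item{tree}{Neighbor-joining + monophyly; a species counts when its
#'     leaves form a clade. Eligible: >= 2 individuals.}
#' }
#' A method failure on one combination is recorded in `status` and the run
#' continues.
#'
#' @param alignments Named list of [marker_alignment()]s.
#' @param map A species map tibble.
#' @param methods Subset of `c("distance", "similarity", "character", "tree")`.
#' @param combinations List of marker subsets (default: all non-empty).
#' @param min_individuals Eligibility threshold for the similarity, character
#'   and tree methods.
#' @param indel_coding Apply [code_indels()] to each combination before
#'   analysis.
#' @param gap_factor Passed to the distance method's recursion guard.
#' @return A `discrimination_report` tibble: `method`, `markers`,
#'   `n_markers`, `n_identified`, `n_eligible`, `rate` (percent),
#'   `identified_species` (list), `status`.
#' @export
evaluate_all <- function(alignments, map,
                         methods = c("distance", "similarity", "character", "tree"),
                         combinations = enumerate_combinations(names(alignments)),
                         min_individuals = 2L, indel_coding = TRUE, gap_factor = 2) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (subset in combinations) {
    aln <- concatenate_markers(alignments, subset)
    if (indel_coding) aln <- code_indels(aln)$alignment
    dm <- p_distance_matrix(aln)
    label <- paste(subset, collapse = "+")
    for (method in methods) {
      res <- tryCatch(
        run_method(method, aln, dm, map, min_individuals, gap_factor),
        error = function(e) list(
          rate = NA_real_, n_identified = NA_integer_, n_eligible = NA_integer_,
          identified_species = character(0), status = conditionMessage(e)
        )
      )
      rows[[length(rows) + 1L]] <- tibble(
        method = method, markers = label, n_markers = length(subset),
        n_identified = res$n_identified, n_eligible = res$n_eligible,
        rate = res$rate, identified_species = list(res$identified_species),
        status = res$status %||% "ok"
      )
    }
  }
  out <- dplyr::bind_rows(rows) |>
    arrange(.data$method, .data$n_markers, .data$markers)
  new_discrimination_report(out)
}

run_method <- function(method, aln, dm, map, min_individuals, gap_factor) {
  map <- map[map$individual %in% alignment_ids(aln), , drop = FALSE]
  switch(method,
    distance = {
      mask <- conspecific_mask(dm$ids, map)
      intra <- dm$d[mask & upper.tri(mask)]
      intra <- intra[is.finite(intra)]
      prior <- max(c(intra, 0))
      if (prior <= 0) prior <- min(dm$d[upper.tri(dm$d)][dm$d[upper.tri(dm$d)] > 0], 0.001) / 2
      part <- abgd_partition(dm, prior_P = prior, map = map, gap_factor = gap_factor)
      sp <- unique(species_of(dm$ids, map))
      list(
        rate = 100 * length(part$delimited_species) / length(sp),
        n_identified = length(part$delimited_species),
        n_eligible = length(sp),
        identified_species = part$delimited_species
      )
    },
    similarity = {
      hits <- top_hit_classify(aln, map)
      score_top_hits(hits, min_individuals)
    },
    character = {
      formulas <- induce_formulas(aln, map)
      assignments <- classify_with_formulas(formulas, aln)
      score_classification(assignments, map, min_individuals)
    },
    tree = {
      tree <- nj_tree(dm)
      score_tree(tree, map, min_individuals)
    }
  )
}
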