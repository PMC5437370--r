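#' Induce per-species diagnostic logic formulas
#'
#' Character-based barcoding: for every species a formula in disjunctive
#' normal form over (column, state) literals is sought that is satisfied by
#' its individuals and by no others. When pure single-position diagnostics
#' exist (see [find_diagnostic_characters()]) the formula is simply one
#' single-literal disjunct per diagnostic. Otherwise a greedy search grows
#' each conjunction literal by literal, choosing the literal minimizing
#' `pos_weight * positives_excluded + neg_weight * negatives_still_covered`,
#' stopping when no negative satisfies the conjunction or `max_literals` is
#' reached; disjuncts are added until every positive is covered or
#' `max_disjuncts` is reached. The asymmetric default weights make false
#' positives (covered negatives) far more expensive than lost positives.
#'
#' A literal `(c, s)` is satisfied only by an exact unambiguous state match:
#' ambiguity codes, gaps and `?` never satisfy a literal.
#'
#' @param aln A cleaned, typically indel-coded [marker_alignment()].
#' @param map A species map tibble.
#' @param max_literals Maximum literals per conjunction.
#' @param max_disjuncts Maximum disjuncts per species.
#' @param pos_weight,neg_weight Greedy cost weights.
#' @return A `diagnostic_formulas` object: list of per-species entries with
#'   `species`, `dnf` (list of tibbles `column`, `state`), `train_coverage`,
#'   `train_exclusion`, `imperfect`.
#' @export
induce_formulas <- function(aln, map, max_literals = 3L, max_disjuncts = 5L,
                            pos_weight = 50, neg_weight = 800) {
  m <- unclass(aln)
  ids <- rownames(m)
  sp <- species_of(ids, map)
  species <- sort(unique(map$species))
  if (length(setdiff(species, sp)) > 0L) {
    abort(paste0(
      "species absent from alignment: ",
      paste(setdiff(species, sp), collapse = ", ")
    ))
  }
  diags <- find_diagnostic_characters(aln, map)

  formulas <- lapply(species, function(s) {
    pos <- which(sp == s); neg <- which(sp != s)
    ds <- diags[diags$species == s, ]
    if (nrow(ds) > 0L) {
      dnf <- lapply(seq_len(min(nrow(ds), max_disjuncts)), function(i) {
        tibble(column = ds$column[i], state = ds$state[i])
      })
    } else {
      dnf <- greedy_dnf(m, pos, neg, max_literals, max_disjuncts, pos_weight, neg_weight)
    }
    cov <- satisfies_dnf(m, dnf)
    coverage <- mean(cov[pos])
    exclusion <- if (length(neg) > 0L) mean(!cov[neg]) else 1
    list(
      species = s, dnf = dnf,
      train_coverage = coverage, train_exclusion = exclusion,
      imperfect = exclusion < 1 || coverage < 1
    )
  })
  names(formulas) <- species
  structure(formulas, class = "diagnostic_formulas")
}

# rows satisfying a single conjunction (tibble of column/state literals)
satisfies_conj <- function(m, conj) {
  ok <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(conj))) {
    ok <- ok & m[, conj$column[i]] == conj$state[i]
  }
  ok
}

satisfies_dnf <- function(m, dnf) {
  if (length(dnf) == 0L) return(rep(FALSE, nrow(m)))
  Reduce(`|`, lapply(dnf, satisfies_conj, m = m))
}

# Exact search for a perfect two-literal conjunction: literals satisfied by
# every positive, paired so that no negative satisfies both. Vectorized as a
# crossproduct over negative-coverage indicators.
exact_pair <- function(m, pos, neg) {
  cols <- integer(0); states <- character(0)
  covers_neg <- list()
  for (col in seq_len(ncol(m))) {
    vals <- m[pos, col]
    if (!all(vals == vals[1]) || !vals[1] %in% BASES) next
    cols <- c(cols, col); states <- c(states, vals[1])
    covers_neg[[length(covers_neg) + 1L]] <- m[neg, col] == vals[1]
  }
  if (length(cols) < 2L) return(NULL)
  negM <- do.call(cbind, covers_neg) * 1
  joint <- crossprod(negM) # joint[i, j] = negatives satisfying both literals
  hits <- which(joint == 0 & upper.tri(joint), arr.ind = TRUE)
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(cols[hits[, 1]], cols[hits[, 2]]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  tibble(column = cols[c(i, j)], state = states[c(i, j)])
}

greedy_dnf <- function(m, pos, neg, max_literals, max_disjuncts, pos_weight, neg_weight) {
  dnf <- list()
  # a perfect short conjunction, when one exists, beats any greedy growth
  if (max_literals >= 2L && length(neg) > 0L) {
    pair <- exact_pair(m, pos, neg)
    if (!is.null(pair)) return(list(pair))
  }
  uncovered <- pos
  for (d in seq_len(max_disjuncts)) {
    if (length(uncovered) == 0L) break
    conj <- tibble(column = integer(), state = character())
    sat <- rep(TRUE, nrow(m))
    for (l in seq_len(max_literals)) {
      cand_cols <- which(colSums(matrix(m[uncovered, , drop = FALSE] %in% BASES,
                                        length(uncovered))) > 0L)
      best <- NULL; best_full <- NULL
      for (col in cand_cols) {
        col_vals <- m[, col]
        for (b in unique(col_vals[uncovered][col_vals[uncovered] %in% BASES])) {
          new_sat <- sat & col_vals == b
          n_excl <- sum(!new_sat[uncovered])
          cost <- pos_weight * n_excl + neg_weight * sum(new_sat[neg])
          key <- list(cost = cost, col = col, state = b)
          better <- function(old) {
            is.null(old) || cost < old$cost ||
              (cost == old$cost && (col < old$col || (col == old$col && b < old$state)))
          }
          if (better(best)) best <- key
          if (n_excl == 0L && better(best_full)) best_full <- key
        }
      }
      # prefer literals that lose no targeted positive: a perfect conjunction
      # is made of such literals, so this keeps the greedy search aligned
      # with the exhaustive optimum on separable species
      if (!is.null(best_full)) best <- best_full
      if (is.null(best)) break
      conj <- dplyr::bind_rows(conj, tibble(column = best$col, state = best$state))
      sat <- sat & m[, best$col] == best$state
      if (sum(sat[neg]) == 0L) break
    }
    if (nrow(conj) == 0L) break
    dnf[[length(dnf) + 1L]] <- conj
    uncovered <- uncovered[!sat[uncovered]]
  }
  dnf
}

#' @export
print.diagnostic_formulas <- function(x, ...) {
  cat("<diagnostic_formulas for ", length(x), " species>\n", sep = "")
  invisible(x)
}

#' @rdname induce_formulas
#' @param x A `diagnostic_formulas` object.
#' @param ... Unused.
#' @export
tidy.diagnostic_formulas <- function(x, ...) {
  rows <- purrr::imap(unclass(x), function(f, s) {
    if (length(f$dnf) == 0L) {
      return(tibble(
        species = s, disjunct = NA_integer_, literals = NA_character_,
        train_coverage = f$train_coverage, train_exclusion = f$train_exclusion
      ))
    }
    tibble(
      species = s,
      disjunct = seq_along(f$dnf),
      literals = map_chr(f$dnf, function(cj) paste0(cj$column, "=", cj$state, collapse = " & ")),
      train_coverage = f$train_coverage,
      train_exclusion = f$train_exclusion
    )
  })
  dplyr::bind_rows(rows)
}

#' Classify individuals with induced formulas
#'
#' An individual is assigned to species `s` iff it satisfies `s`'s formula
#' and no other species' formula; zero or multiple satisfied formulas leave
#' it unassigned (`NA`).
#'
#' @param formulas A `diagnostic_formulas` object.
#' @param aln A [marker_alignment()] on the same column coordinates.
#' @return Tibble with `individual`, `assigned` (species or `NA`).
#' @export
classify_with_formulas <- function(formulas, aln) {
  m <- unclass(aln)
  sat <- vapply(unclass(formulas), function(f) satisfies_dnf(m, f$dnf), logical(nrow(m)))
  if (is.null(dim(sat))) sat <- matrix(sat, nrow = nrow(m))
  assigned <- apply(sat, 1L, function(row) {
    hits <- names(formulas)[row]
    if (length(hits) == 1L) hits else NA_character_
  })
  tibble(individual = rownames(m), assigned = unname(assigned))
}

#' Score a character-based classification per species
#'
#' A species is identified when all of its individuals are assigned to it.
#'
#' @param assignments Output of [classify_with_formulas()].
#' @param map A species map tibble.
#' @param min_individuals Minimum individuals for eligibility.
#' @return List with `rate` (percent), `n_identified`, `n_eligible`,
#'   `identified_species`.
#' @export
score_classification <- function(assignments, map, min_individuals = 2L) {
  truth <- species_of(assignments$individual, map)
  per <- tibble(species = truth, ok = !is.na(assignments$assigned) & assignments$assigned == truth) |>
    group_by(.data$species) |>
    summarise(n = dplyr::n(), all_ok = all(.data$ok), .groups = "drop") |>
    filter(.data$n >= min_individuals)
  identified <- sort(per$species[per$all_ok])
  list(
    rate = 100 * length(identified) / max(nrow(per), 1L),
    n_identified = length(identified),
    n_eligible = nrow(per),
    identified_species = identified
  )
}
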