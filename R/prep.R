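#' Clean an aligned matrix
#'
#' Drops ambiguous columns and poly-A/T runs before analysis. A column is
#' ambiguous when the fraction of `N`/`?` cells exceeds `max_ambiguous`.
#' A poly-A/T block is a maximal run of >= `polyAT_min` consecutive columns
#' in which at least `polyAT_frac` of the rows are a mononucleotide A run
#' (or T run); the whole block is removed.
#'
#' @param aln A [marker_alignment()].
#' @param max_ambiguous Maximum tolerated fraction of `N`/`?` per column.
#' @param polyAT_min Minimum poly-A/T run length (columns).
#' @param polyAT_frac Minimum fraction of rows that must carry the run.
#' @return The cleaned alignment, with attribute `provenance`: an integer
#'   vector mapping kept columns to original column indices (1-based).
#' @export
clean_alignment <- function(aln, max_ambiguous = 0, polyAT_min = 8L, polyAT_frac = 0.5) {
  m <- unclass(aln)
  amb <- colMeans(m == "N" | m == "?")
  drop <- amb > max_ambiguous

  for (base in c("A", "T")) {
    is_b <- m == base
    # per-row run ids along columns
    run_frac <- colMeans(row_run_at_least(is_b, polyAT_min))
    drop <- drop | run_frac >= polyAT_frac
  }
  keep <- which(!drop)
  if (length(keep) == 0L) abort("cleaning removed every column")
  out <- aln_subset(aln, cols = keep)
  attr(out, "provenance") <- keep
  out
}

# TRUE at cells that belong to a horizontal run of TRUEs of length >= k.
row_run_at_least <- function(mat, k) {
  out <- matrix(FALSE, nrow(mat), ncol(mat))
  for (r in seq_len(nrow(mat))) {
    x <- mat[r, ]
    rl <- rle(x)
    hit <- rl$values & rl$lengths >= k
    out[r, ] <- rep(hit, rl$lengths)
  }
  out
}

#' Simple indel coding
#'
#' Converts gaps to binary characters following the simple indel coding
#' scheme: every distinct maximal gap run (identical start and end across the
#' rows sharing it) becomes one appended binary column, encoded `T` (gap
#' present) / `A` (absent); a row whose own gap strictly contains the span
#' scores `?` for that character. Original gap columns are retained.
#'
#' @param aln A [marker_alignment()].
#' @return List with `alignment` (input plus appended coded columns) and
#'   `characters`: a tibble with `span_start`, `span_end` (1-based inclusive
#'   column range), `presence` (list of logical vectors named by individual),
#'   and `diagnostic_for` filled in by [site_stats()] when a species map is
#'   supplied there (otherwise `NA`).
#' @export
code_indels <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m); L <- ncol(m)
  spans <- list()
  for (r in seq_len(n)) {
    rl <- rle(m[r, ] == "-")
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    gi <- which(rl$values)
    for (g in gi) spans[[length(spans) + 1L]] <- c(starts[g], ends[g])
  }
  spans <- unique(spans)
  if (length(spans) == 0L) {
    return(list(
      alignment = aln,
      characters = tibble(
        span_start = integer(), span_end = integer(),
        presence = list(), diagnostic_for = character()
      )
    ))
  }
  spans <- spans[order(
    vapply(spans, `[`, integer(1), 1L),
    vapply(spans, `[`, integer(1), 2L)
  )]
  coded <- matrix("A", n, length(spans))
  presence <- vector("list", length(spans))
  ids <- rownames(m)
  gap <- m == "-"
  for (s in seq_along(spans)) {
    sp <- spans[[s]]
    cols <- sp[1]:sp[2]
    has_exact <- logical(n)
    for (r in seq_len(n)) {
      g <- gap[r, ]
      all_gap <- all(g[cols])
      exact <- all_gap &&
        (sp[1] == 1L || !g[sp[1] - 1L]) &&
        (sp[2] == L || !g[sp[2] + 1L])
      strict_contain <- all_gap && !exact
      if (exact) {
        coded[r, s] <- "T"; has_exact[r] <- TRUE
      } else if (strict_contain) {
        coded[r, s] <- "?"
      }
    }
    presence[[s]] <- stats::setNames(has_exact, ids)
  }
  out <- cbind(m, coded)
  colnames(out) <- NULL
  list(
    alignment = structure(out, class = c("marker_alignment", "matrix"),
                          marker_id = attr(aln, "marker_id"),
                          n_coded = length(spans)),
    characters = tibble(
      span_start = vapply(spans, `[`, integer(1), 1L),
      span_end = vapply(spans, `[`, integer(1), 2L),
      presence = presence,
      diagnostic_for = NA_character_
    )
  )
}

# Fill the diagnostic_for column of an indel-character table: a character is
# diagnostic for species s iff presence is TRUE for all and only s's rows.
mark_diagnostic_indels <- function(characters, ids, map) {
  if (nrow(characters) == 0L) return(characters)
  sp <- species_of(ids, map)
  characters$diagnostic_for <- vapply(characters$presence, function(pr) {
    pr <- pr[ids]
    have <- unique(sp[pr])
    if (length(have) == 1L && all(pr[sp == have])) have else NA_character_
  }, character(1))
  characters
}

#' Screen ITS rows for likely pseudogenes
#'
#' Flags rows whose GC content falls outside `[gc_min, gc_max]` or that lack
#' any configured conserved 5.8S motif (IUPAC-aware substring match). An
#' empty motif list passes vacuously. Functional nuclear ribosomal ITS
#' copies keep a characteristic GC content and conserved 5.8S core;
#' paralogous pseudogenes drift away from both.
#'
#' @param aln An ITS [marker_alignment()].
#' @param gc_min,gc_max GC-content bounds (percent).
#' @param motifs Character vector of IUPAC motifs to require (each must be
#'   present somewhere in the ungapped row).
#' @return Tibble with `individual`, `gc_percent`, `gc_pass`, `motif_pass`,
#'   `pass`.
#' @export
screen_its <- function(aln, gc_min = 45, gc_max = 70, motifs = character(0)) {
  m <- unclass(aln)
  ids <- rownames(m)
  res <- lapply(seq_len(nrow(m)), function(r) {
    s <- m[r, ]
    s <- s[!(s %in% c("-", "?"))]
    gc <- 100 * sum(s %in% c("G", "C", "S")) / sum(s %in% c(BASES, "S", "W"))
    seqstr <- paste0(s, collapse = "")
    mot <- length(motifs) == 0L ||
      all(vapply(motifs, function(mm) iupac_match(seqstr, mm), logical(1)))
    tibble(
      individual = ids[r], gc_percent = gc,
      gc_pass = gc >= gc_min & gc <= gc_max, motif_pass = mot
    )
  })
  dplyr::bind_rows(res) |> mutate(pass = .data$gc_pass & .data$motif_pass)
}

# IUPAC-aware substring search: does `seq` contain a stretch matching the
# (possibly ambiguous) motif? Both sides expand through IUPAC.
iupac_match <- function(seq, motif) {
  S <- chars(seq); M <- chars(motif)
  n <- length(S); m <- length(M)
  if (m > n) return(FALSE)
  for (i in seq_len(n - m + 1L)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (length(intersect(iupac_expand(S[i + j - 1L]), iupac_expand(M[j]))) == 0L) {
        ok <- FALSE; break
      }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

#' Per-marker site statistics
#'
#' Counts variable and parsimony-informative columns plus indel characters.
#' A column is variable when it shows >= 2 distinct unambiguous bases (gaps
#' and ambiguity codes are not states); parsimony-informative when >= 2
#' states each occur in >= 2 individuals. Indel counts come from
#' [code_indels()]; an indel is diagnostic when its presence pattern matches
#' all and only one species' individuals.
#'
#' @param aln A cleaned [marker_alignment()] (gap columns retained).
#' @param map A species map tibble (see [species_map()]).
#' @return One-row tibble: `marker`, `n_individuals`, `aligned_length`,
#'   `n_variable`, `n_informative`, `n_indels`, `n_diagnostic_indels`.
#' @export
site_stats <- function(aln, map) {
  m <- unclass(aln)
  counts <- apply(m, 2L, function(col) table(factor(col[col %in% BASES], levels = BASES)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 4L)
  n_states <- colSums(counts > 0L)
  n_var <- sum(n_states >= 2L)
  n_inf <- sum(colSums(counts >= 2L) >= 2L & n_states >= 2L)
  ic <- code_indels(aln)
  chars_tab <- mark_diagnostic_indels(ic$characters, rownames(m), map)
  tibble(
    marker = attr(aln, "marker_id"),
    n_individuals = nrow(m),
    aligned_length = ncol(m),
    n_variable = n_var,
    n_informative = n_inf,
    n_indels = nrow(chars_tab),
    n_diagnostic_indels = sum(!is.na(chars_tab$diagnostic_for))
  )
}

#' Find species-diagnostic characters
#'
#' A (column, state) pair is diagnostic for species `s` iff every individual
#' of `s` carries exactly that unambiguous state at the column and no
#' individual of any other species could carry it: an ambiguity code in a
#' non-target individual whose expansion includes the state blocks the
#' diagnosis (conservative rule), while ambiguity in the target species never
#' supplies the state.
#'
#' @param aln A cleaned (and typically indel-coded) [marker_alignment()].
#' @param map A species map tibble.
#' @return Tibble with `species`, `column` (1-based), `state`.
#' @export
find_diagnostic_characters <- function(aln, map) {
  m <- unclass(aln)
  ids <- rownames(m)
  sp <- species_of(ids, map)
  species <- unique(sp)
  res <- list()
  # symbols whose IUPAC expansion contains each base
  containing <- lapply(BASES, function(b) {
    names(IUPAC)[vapply(IUPAC, function(set) b %in% set, logical(1))]
  })
  names(containing) <- BASES
  for (col in seq_len(ncol(m))) {
    cells <- m[, col]
    exact <- lapply(BASES, function(b) cells == b)
    names(exact) <- BASES
    could <- lapply(BASES, function(b) cells %in% containing[[b]])
    names(could) <- BASES
    for (b in BASES) {
      if (!any(exact[[b]])) next
      for (s in species) {
        own <- sp == s
        if (all(exact[[b]][own]) && !any(could[[b]][!own])) {
          res[[length(res) + 1L]] <- tibble(species = s, column = col, state = b)
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble(species = character(), column = integer(), state = character()))
  }
  dplyr::bind_rows(res) |> arrange(.data$species, .data$column)
}
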