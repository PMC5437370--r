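#' Configuration for the synthetic barcode dataset generator
#'
#' The generator emulates a multi-species, multi-marker barcoding study: per
#' marker an ancestral i.i.d. sequence is drawn, each species' consensus is
#' the ancestor mutated per site with probability `d_inter` (uniform over the
#' three alternative bases), and each individual is its species consensus
#' mutated with probability `d_intra`. Per species and marker one reserved
#' column can be forced to a species-unique state (a planted diagnostic);
#' reserved columns are masked from every other stochastic edit so the
#' planted truth stays exact. Species-specific deletions (length 3-10) are
#' planted at distinct coordinates. For plastid markers a whole-haplotype
#' swap emulates chloroplast capture / incomplete lineage sorting: with
#' probability `p_share` an individual's plastid sequence (all plastid
#' markers jointly, as one linked haplotype) is redrawn from a random other
#' species' consensus. Nuclear markers receive IUPAC two-base heterozygote
#' codes at rate `p_het`.
#'
#' @param n_species Number of species.
#' @param n_individuals Individuals per species (scalar or per-species
#'   vector).
#' @param markers Tibble with `marker`, `length`, `inheritance`
#'   (`"plastid"`/`"nuclear"`).
#' @param d_intra,d_inter Per-site substitution probabilities (intra must not
#'   exceed 0.5 and should be below inter for clean presets).
#' @param p_diag Probability a species gets a planted diagnostic per marker.
#' @param indel_rate Per-species, per-marker probability of a planted
#'   species-specific deletion.
#' @param p_share Per-individual probability of a plastid haplotype swap.
#' @param p_het Per-site heterozygosity rate on nuclear markers.
#' @param seed Integer seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 10L, n_individuals = 5L,
                             markers = tibble(
                               marker = c("cpA", "cpB", "nucA"),
                               length = c(600L, 600L, 600L),
                               inheritance = c("plastid", "plastid", "nuclear")
                             ),
                             d_intra = 0.003, d_inter = 0.05,
                             p_diag = 1, indel_rate = 0.2,
                             p_share = 0, p_het = 0.02, seed = 1L) {
  probs <- c(d_intra = d_intra, d_inter = d_inter, p_diag = p_diag,
             indel_rate = indel_rate, p_share = p_share, p_het = p_het)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (d_intra > 0.5) abort("d_intra above 0.5 is not a meaningful mutation rate")
  if (any(markers$length < 50L)) abort("marker length must be at least 50")
  if (!all(markers$inheritance %in% c("plastid", "nuclear"))) {
    abort("inheritance must be 'plastid' or 'nuclear'")
  }
  structure(
    list(
      n_species = n_species, n_individuals = n_individuals, markers = markers,
      d_intra = d_intra, d_inter = d_inter, p_diag = p_diag,
      indel_rate = indel_rate, p_share = p_share, p_het = p_het, seed = seed
    ),
    class = "synthetic_config"
  )
}

#' Study-shaped generator presets
#'
#' `"clean"`: 10 species x 5 individuals, three 600-bp markers (two plastid,
#' one nuclear), `d_intra = 0.003`, `d_inter = 0.05`, planted diagnostics,
#' no haplotype sharing: every method should discriminate perfectly.
#' `"hybrid"`: same but with plastid haplotype sharing `p_share = 0.3`, the
#' regime where distance- and tree-based discrimination collapses while
#' character-based discrimination survives on nuclear diagnostics.
#' `"gapless"`: no indels and no diagnostics planted, for distance-only
#' studies.
#'
#' @param preset `"clean"`, `"hybrid"`, or `"gapless"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
preset_config <- function(preset = c("clean", "hybrid", "gapless"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    clean = list(),
    hybrid = list(p_share = 0.3),
    gapless = list(indel_rate = 0, p_diag = 0)
  )
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  do.call(synthetic_config, args)
}

#' Simulate a multi-marker barcode dataset
#'
#' @param config A [synthetic_config()].
#' @return List with `alignments` (named list of [marker_alignment()]s),
#'   `map` (species map tibble; species `sp01`..., individuals `sp01_1`...),
#'   and `truth`: list with `diagnostics` (tibble `marker`, `species`,
#'   `column`, `state`), `indels` (tibble `marker`, `species`, `start`,
#'   `length`), `shared` (tibble `individual`, `donor_species`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  K <- config$n_species
  ni <- rep(config$n_individuals, length.out = K)
  species <- sprintf("sp%02d", seq_len(K))
  ids <- unlist(lapply(seq_len(K), function(s) paste0(species[s], "_", seq_len(ni[s]))))
  sp_of <- rep(species, ni)
  map <- species_map(ids, sp_of)

  # plastid haplotype sharing decided once per individual (linked markers)
  shared_donor <- rep(NA_character_, length(ids))
  if (config$p_share > 0 && K > 1L) {
    swap <- stats::runif(length(ids)) < config$p_share
    shared_donor[swap] <- vapply(which(swap), function(i) {
      sample(setdiff(species, sp_of[i]), 1L)
    }, character(1))
  }

  diags <- list(); indels <- list()
  alignments <- list()
  for (r in seq_len(nrow(config$markers))) {
    mk <- config$markers$marker[r]
    L <- config$markers$length[r]
    plastid <- config$markers$inheritance[r] == "plastid"

    ancestor <- sample(BASES, L, replace = TRUE)
    # one reserved column per species, kept clear of all stochastic edits
    reserved <- sample.int(L, K)
    consensus <- matrix(rep(ancestor, K), nrow = K, byrow = TRUE)
    for (s in seq_len(K)) {
      mut <- stats::runif(L) < config$d_inter
      mut[reserved] <- FALSE
      idx <- which(mut)
      if (length(idx) > 0L) {
        consensus[s, idx] <- vapply(consensus[s, idx], function(b) {
          sample(setdiff(BASES, b), 1L)
        }, character(1))
      }
    }
    for (s in seq_len(K)) {
      if (stats::runif(1) < config$p_diag) {
        col <- reserved[s]
        taken <- unique(consensus[-s, col])
        free <- setdiff(BASES, taken)
        if (length(free) > 0L) {
          state <- sample(free, 1L)
          consensus[s, col] <- state
          diags[[length(diags) + 1L]] <-
            tibble(marker = mk, species = species[s], column = col, state = state)
        }
      }
    }
    # species-specific deletion spans at distinct coordinates, off reserved
    del_spans <- list()
    for (s in seq_len(K)) {
      if (stats::runif(1) < config$indel_rate) {
        len <- sample(3:10, 1L)
        for (try in 1:50) {
          start <- sample.int(L - len, 1L)
          cols <- start:(start + len - 1L)
          clash <- any(cols %in% reserved) ||
            any(vapply(del_spans, function(x) any(cols %in% x$cols), logical(1)))
          if (!clash) {
            del_spans[[length(del_spans) + 1L]] <- list(species = s, cols = cols)
            indels[[length(indels) + 1L]] <-
              tibble(marker = mk, species = species[s], start = start, length = len)
            break
          }
        }
      }
    }

    rows <- matrix("", length(ids), L)
    for (i in seq_along(ids)) {
      s <- match(sp_of[i], species)
      src <- s
      if (plastid && !is.na(shared_donor[i])) src <- match(shared_donor[i], species)
      seqv <- consensus[src, ]
      mut <- stats::runif(L) < config$d_intra
      mut[reserved] <- FALSE
      idx <- which(mut)
      if (length(idx) > 0L) {
        seqv[idx] <- vapply(seqv[idx], function(b) sample(setdiff(BASES, b), 1L), character(1))
      }
      if (!plastid && config$p_het > 0) {
        het <- which(stats::runif(L) < config$p_het)
        het <- setdiff(het, reserved)
        for (h in het) {
          other <- sample(setdiff(BASES, seqv[h]), 1L)
          seqv[h] <- iupac_code(seqv[h], other)
        }
      }
      # deletions apply to the *species* of the individual (nuclear and
      # plastid alike; a swapped plastid haplotype carries the donor's gaps)
      del_src <- if (plastid) src else s
      for (dsp in del_spans) {
        if (dsp$species == del_src) seqv[dsp$cols] <- "-"
      }
      rows[i, ] <- seqv
    }
    rownames(rows) <- ids
    alignments[[mk]] <- structure(
      rows, class = c("marker_alignment", "matrix"), marker_id = mk
    )
  }

  truth <- list(
    diagnostics = dplyr::bind_rows(diags) %0%
      tibble(marker = character(), species = character(), column = integer(), state = character()),
    indels = dplyr::bind_rows(indels) %0%
      tibble(marker = character(), species = character(), start = integer(), length = integer()),
    shared = tibble(individual = ids[!is.na(shared_donor)],
                    donor_species = shared_donor[!is.na(shared_donor)])
  )
  list(alignments = alignments, map = map, truth = truth)
}

# two-base IUPAC code for a heterozygous site
iupac_code <- function(a, b) {
  pair <- sort(c(a, b))
  codes <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  codes[[paste0(pair, collapse = "")]]
}

#' Expected pairwise p-distance under the generator's mutation model
#'
#' Each mutation step (probability `d`, uniform over the three alternatives)
#' is a Jukes-Cantor-like kernel with identity eigenvalue `1 - 4d/3`; for
#' two lineages with total eigenvalues `lam_1`, `lam_2` from their common
#' ancestor the expected p-distance is `3/4 (1 - lam_1 lam_2)`. Conspecific
#' pairs take one `d_intra` step each from the consensus; heterospecific
#' pairs take a `d_inter` then a `d_intra` step on each side.
#'
#' @param config A [synthetic_config()].
#' @param relation `"intra"` or `"inter"`.
#' @return Expected p-distance.
#' @export
expected_pairwise_distance <- function(config, relation = c("intra", "inter")) {
  relation <- match.arg(relation)
  lam <- function(d) 1 - 4 * d / 3
  l_branch <- switch(relation,
    intra = lam(config$d_intra),
    inter = lam(config$d_intra) * lam(config$d_inter)
  )
  3 / 4 * (1 - l_branch^2)
}
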