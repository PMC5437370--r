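#' Nucleotide diversity (pi)
#'
#' Mean pairwise p-distance (pairwise deletion) over all unordered pairs of
#' the given individuals.
#'
#' @param aln A [marker_alignment()].
#' @param ids Individuals to include (default: all rows). At least two.
#' @return A single numeric value in `[0, 1]`.
#' @export
nucleotide_diversity <- function(aln, ids = alignment_ids(aln)) {
  if (length(ids) < 2L) abort("nucleotide diversity needs at least two individuals")
  dm <- p_distance_matrix(aln_subset(aln, rows = ids))
  d <- dm$d[lower.tri(dm$d)]
  mean(d, na.rm = TRUE)
}

#' Per-species nucleotide diversity
#'
#' @param aln A [marker_alignment()].
#' @param map A species map tibble.
#' @return List with `per_species` (tibble `species`, `n`, `pi`; species with
#'   fewer than two individuals get `NA`) and `mean_pi` (unweighted mean over
#'   species with >= 2 individuals).
#' @export
diversity_by_species <- function(aln, map) {
  ids <- alignment_ids(aln)
  sp <- species_of(ids, map)
  per <- tibble(species = unique(sp)) |>
    mutate(
      n = map_int(.data$species, ~ sum(sp == .x)),
      pi = map_dbl(.data$species, function(s) {
        if (sum(sp == s) < 2L) return(NA_real_)
        nucleotide_diversity(aln, ids[sp == s])
      })
    )
  list(per_species = per, mean_pi = mean(per$pi[per$n >= 2L]))
}

#' Deletion-insertion polymorphism (DIP)
#'
#' Each distinct gap span defines a multiallelic indel locus whose alleles
#' are the distinct (presence, length) states among the chosen individuals.
#' Per-locus diversity is the unbiased multiallelic heterozygosity
#' `h = n/(n-1) * (1 - sum(p_i^2))`.
#'
#' @param aln A [marker_alignment()] containing gaps.
#' @param ids Individuals to include (default: all rows).
#' @return List with `per_locus` (tibble `span_start`, `span_end`,
#'   `n_alleles`, `h`) and `mean_dip` (mean over loci; `NA` when there are no
#'   indel loci).
#' @export
dip_statistic <- function(aln, ids = alignment_ids(aln)) {
  sub <- aln_subset(aln, rows = ids)
  m <- unclass(sub)
  n <- nrow(m)
  # locus = maximal union of overlapping gap spans; allele = the exact gap
  # pattern (start, length) of each row within the locus ("" = no gap)
  gap_any <- colSums(m == "-") > 0L
  if (!any(gap_any)) {
    return(list(
      per_locus = tibble(
        span_start = integer(), span_end = integer(),
        n_alleles = integer(), h = double()
      ),
      mean_dip = NA_real_
    ))
  }
  rl <- rle(gap_any)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  loci <- which(rl$values)
  per <- lapply(loci, function(g) {
    cols <- starts[g]:ends[g]
    alleles <- apply(m[, cols, drop = FALSE] == "-", 1L, function(x) paste0(as.integer(x), collapse = ""))
    p <- table(alleles) / n
    h <- n / (n - 1) * (1 - sum(p^2))
    tibble(
      span_start = starts[g], span_end = ends[g],
      n_alleles = length(p), h = h
    )
  })
  per <- dplyr::bind_rows(per)
  list(per_locus = per, mean_dip = mean(per$h))
}

#' Unbiased multiallelic diversity from allele counts
#'
#' `h = n/(n-1) * (1 - sum((k_i/n)^2))` for allele counts `k_i`.
#'
#' @param counts Integer vector of allele counts.
#' @return The diversity value.
#' @export
#' @examples
#' allele_diversity(c(6, 3)) # 0.5
allele_diversity <- function(counts) {
  n <- sum(counts)
  if (n < 2L) abort("need at least two observations")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

#' Screen markers for phylogeographic use
#'
#' A marker is selected when its mean per-species nucleotide diversity
#' exceeds `pi_threshold` and its (observed, supplied) amplification success
#' is at least `success_threshold`.
#'
#' @param markers Tibble with columns `marker`, `mean_pi`,
#'   `amplification_success` (fraction in `[0, 1]`).
#' @param pi_threshold Diversity cut-off.
#' @param success_threshold Amplification cut-off.
#' @return The input with logical columns `pi_pass`, `success_pass`,
#'   `selected`.
#' @export
screen_markers <- function(markers, pi_threshold = 5e-4, success_threshold = 0.8) {
  markers |>
    mutate(
      pi_pass = .data$mean_pi > pi_threshold,
      success_pass = .data$amplification_success >= success_threshold,
      selected = .data$pi_pass & .data$success_pass
    )
}
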