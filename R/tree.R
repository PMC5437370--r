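#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a p-distance matrix: at each step the pair
#' minimizing `Q(i,j) = (n-2) d(i,j) - R_i - R_j` is joined (ties broken by
#' the lexicographically smallest id pair), branch lengths come from the
#' standard three-point formulas, and negative branch lengths are clamped to
#' zero with the deficit transferred to the sister branch so path lengths are
#' preserved.
#'
#' @param dm A `p_distance_matrix` with no `NA` off-diagonal entries and at
#'   least three individuals.
#' @return An unrooted [ape::phylo] tree with the alignment ids as tips.
#' @export
nj_tree <- function(dm) {
  D <- dm$d
  n <- nrow(D)
  if (n < 3L) abort("neighbor joining needs at least three individuals")
  if (any(is.na(D[upper.tri(D)]))) {
    abort("distance matrix contains NA; impute or drop the affected individuals first")
  }
  labels <- dm$ids
  # active clusters carry a Newick fragment
  frag <- labels
  repeat {
    k <- nrow(D)
    if (k == 3L) break
    R <- rowSums(D)
    Q <- (k - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie-break on the pair of cluster labels
    key <- paste(pmin(labels[cand[, 1]], labels[cand[, 2]]),
                 pmax(labels[cand[, 1]], labels[cand[, 2]]))
    pick <- cand[order(key)[1L], ]
    i <- pick[[1]]; j <- pick[[2]]
    vi <- 0.5 * D[i, j] + (R[i] - R[j]) / (2 * (k - 2))
    vj <- D[i, j] - vi
    cl <- clamp_pair(vi, vj)
    newfrag <- paste0("(", frag[i], ":", fmt(cl[1]), ",", frag[j], ":", fmt(cl[2]), ")")
    newlab <- min(labels[i], labels[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(k), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    labels <- c(labels[keep], newlab)
    frag <- c(frag[keep], newfrag)
  }
  # final three-point join
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- clamp_triple(c(v1, v2, v3))
  nwk <- paste0(
    "(", frag[1], ":", fmt(v[1]), ",", frag[2], ":", fmt(v[2]),
    ",", frag[3], ":", fmt(v[3]), ");"
  )
  ape::read.tree(text = nwk)
}

fmt <- function(x) sprintf("%.12g", x)

# clamp negatives to zero, moving the deficit to the sister branch
clamp_pair <- function(vi, vj) {
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- vi + vj; vj <- 0 }
  c(max(vi, 0), max(vj, 0))
}

clamp_triple <- function(v) {
  for (i in 1:3) {
    if (v[i] < 0) {
      others <- setdiff(1:3, i)
      v[others] <- v[others] + v[i] / 2
      v[i] <- 0
    }
  }
  pmax(v, 0)
}

# Bipartition keys for every edge of an unrooted tree: each edge splits the
# tips in two; the key is the sorted side not containing the smallest tip
# label (canonical), collapsed with '|'. Non-trivial splits only by default.
bipartitions <- function(tree, trivial = FALSE) {
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1]
  sets <- descendant_sets_by_node(tree)
  sets <- sets[setdiff(seq_along(sets), n + 1L)] # root carries no edge
  keys <- vapply(sets, function(s) {
    side <- if (anchor %in% s) setdiff(tips, s) else s
    paste(sort(side), collapse = "|")
  }, character(1))
  sizes <- vapply(sets, length, integer(1))
  if (!trivial) keys <- keys[sizes > 1L & sizes < n - 1L]
  unique(keys[keys != ""])
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Columns are resampled with replacement `n_boot` times; the support of an
#' internal edge of the original-data tree is the percentage of replicate
#' trees containing the same bipartition. Replicate `r` is seeded with
#' `seed + r`, so supports are reproducible.
#'
#' @param aln A [marker_alignment()].
#' @param n_boot Number of replicates.
#' @param seed Integer seed.
#' @return The original-data tree with `node.label` carrying integer supports
#'   (root label empty).
#' @export
bootstrap_support <- function(aln, n_boot = 1000L, seed = 1L) {
  tree <- nj_tree(p_distance_matrix(aln))
  keys <- bipartitions(tree, trivial = FALSE)
  counts <- stats::setNames(numeric(length(keys)), keys)
  L <- ncol(aln)
  for (r in seq_len(n_boot)) {
    set.seed(seed + r)
    cols <- sample.int(L, L, replace = TRUE)
    rdm <- p_distance_matrix(aln_subset(aln, cols = cols))
    if (any(is.na(rdm$d[upper.tri(rdm$d)]))) next
    rkeys <- bipartitions(nj_tree(rdm), trivial = FALSE)
    hit <- keys %in% rkeys
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / n_boot)
  # map supports onto internal nodes
  n <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  labs <- character(tree$Nnode)
  all_sets <- descendant_sets_by_node(tree)
  for (nd in seq_len(tree$Nnode)) {
    node <- n + nd
    if (node == n + 1L) { labs[nd] <- ""; next }
    s <- all_sets[[node]]
    side <- if (anchor %in% s) setdiff(tree$tip.label, s) else s
    key <- paste(sort(side), collapse = "|")
    labs[nd] <- if (key %in% names(support)) as.character(support[[key]]) else ""
  }
  tree$node.label <- labs
  tree
}

# descendant tip sets indexed by node number (root included)
descendant_sets_by_node <- function(tree) {
  n <- length(tree$tip.label)
  out <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) out[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; c_ <- tree$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[c_]])
  }
  out
}

#' Per-species monophyly on an unrooted tree
#'
#' A species is monophyletic when removing a single edge separates exactly
#' its leaves from all others; species with fewer than `min_individuals`
#' leaves are reported but flagged ineligible.
#'
#' @param tree An [ape::phylo] tree.
#' @param map A species map tibble covering the tips.
#' @param min_individuals Minimum leaves for eligibility.
#' @return Tibble with `species`, `n`, `eligible`, `monophyletic`.
#' @export
monophyly <- function(tree, map, min_individuals = 2L) {
  tips <- tree$tip.label
  sp <- species_of(tips, map)
  sets <- descendant_sets_by_node(tree)
  keys <- unique(vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1)))
  comp_keys <- unique(vapply(sets, function(s) paste(sort(setdiff(tips, s)), collapse = "|"), character(1)))
  tibble(species = unique(sp)) |>
    mutate(
      n = map_int(.data$species, ~ sum(sp == .x)),
      eligible = .data$n >= min_individuals,
      monophyletic = map_lgl(.data$species, function(s) {
        key <- paste(sort(tips[sp == s]), collapse = "|")
        key %in% keys || key %in% comp_keys
      })
    )
}

#' Score tree-based species discrimination
#'
#' @param tree An [ape::phylo] tree.
#' @param map A species map tibble.
#' @param min_individuals Minimum leaves for a species to be eligible;
#'   singletons are excluded from the denominator and reported separately.
#' @return List with `rate` (percent), `n_identified`, `n_eligible`,
#'   `identified_species`, `singleton_species`.
#' @export
score_tree <- function(tree, map, min_individuals = 2L) {
  mono <- monophyly(tree, map, min_individuals)
  elig <- mono[mono$eligible, ]
  identified <- sort(elig$species[elig$monophyletic])
  list(
    rate = 100 * length(identified) / max(nrow(elig), 1L),
    n_identified = length(identified),
    n_eligible = nrow(elig),
    identified_species = identified,
    singleton_species = sort(mono$species[!mono$eligible])
  )
}
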