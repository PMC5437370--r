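#' Pairwise p-distance matrix with pairwise deletion
#'
#' For each pair of rows only the columns where both carry an unambiguous
#' `A/C/G/T` are compared; the distance is mismatches over compared columns.
#' Pairs sharing no such column get `NA`. Appended indel-coded columns (which
#' use an `A`/`T` encoding) participate automatically.
#'
#' @param aln A [marker_alignment()].
#' @return A `p_distance_matrix`: list with `ids`, `d` (symmetric numeric
#'   matrix, zero diagonal), and `shared_sites` (integer matrix of compared
#'   columns per pair).
#' @export
p_distance_matrix <- function(aln) {
  m <- base_int(unclass(aln))
  ids <- rownames(aln)
  valid <- !is.na(m)
  vnum <- matrix(as.numeric(valid), nrow(m))
  shared <- tcrossprod(vnum)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) {
    hit <- matrix(as.numeric(valid & m == b), nrow(m))
    matches <- matches + tcrossprod(hit)
  }
  d <- (shared - matches) / shared
  d[shared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  storage.mode(shared) <- "integer"
  dimnames(shared) <- list(ids, ids)
  structure(list(ids = ids, d = d, shared_sites = shared), class = "p_distance_matrix")
}

#' @export
print.p_distance_matrix <- function(x, ...) {
  cat("<p_distance_matrix: ", length(x$ids), " individuals>\n", sep = "")
  invisible(x)
}

#' @rdname p_distance_matrix
#' @param x A `p_distance_matrix`.
#' @param ... Unused.
#' @export
tidy.p_distance_matrix <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(lower.tri(x$d), arr.ind = TRUE)
  tibble(
    id1 = x$ids[idx[, 2]], id2 = x$ids[idx[, 1]],
    distance = x$d[idx], shared_sites = x$shared_sites[idx]
  )
}

# subset a distance matrix to a set of ids
dm_subset <- function(dm, ids) {
  keep <- match(ids, dm$ids)
  structure(
    list(
      ids = ids,
      d = dm$d[keep, keep, drop = FALSE],
      shared_sites = dm$shared_sites[keep, keep, drop = FALSE]
    ),
    class = "p_distance_matrix"
  )
}

# logical matrix marking conspecific pairs (diagonal FALSE)
conspecific_mask <- function(ids, map) {
  sp <- species_of(ids, map)
  mask <- outer(sp, sp, "==")
  diag(mask) <- FALSE
  mask
}

#' Maximum intraspecific divergence with bootstrap standard error
#'
#' The statistic is the maximum p-distance over all conspecific pairs; its
#' standard error is the standard deviation of the statistic across
#' column-resampled alignments.
#'
#' @param dm A `p_distance_matrix` for `aln`'s rows.
#' @param map A species map tibble.
#' @param aln The alignment the matrix came from (used for resampling).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `d_intra_max` and `se`.
#' @export
max_intraspecific <- function(dm, map, aln, n_boot = 1000L, seed = 1L) {
  mask <- conspecific_mask(dm$ids, map)
  if (!any(mask)) abort("no conspecific pair: every species has a single individual")
  d_max <- max(dm$d[mask], na.rm = TRUE)

  # per conspecific pair: per-column mismatch / validity indicators
  m <- base_int(unclass(aln))[dm$ids, , drop = FALSE]
  pairs <- which(mask & upper.tri(mask), arr.ind = TRUE)
  L <- ncol(m)
  mis <- matrix(FALSE, nrow(pairs), L)
  val <- matrix(FALSE, nrow(pairs), L)
  for (p in seq_len(nrow(pairs))) {
    a <- m[pairs[p, 1], ]; b <- m[pairs[p, 2], ]
    ok <- !is.na(a) & !is.na(b)
    val[p, ] <- ok
    mis[p, ok] <- a[ok] != b[ok]
  }
  set.seed(seed)
  stat <- vapply(seq_len(n_boot), function(r) {
    cols <- sample.int(L, L, replace = TRUE)
    num <- rowSums(mis[, cols, drop = FALSE])
    den <- rowSums(val[, cols, drop = FALSE])
    max(num / den, na.rm = TRUE)
  }, numeric(1))
  list(d_intra_max = d_max, se = stats::sd(stat))
}

#' Barcode-gap assessment
#'
#' Ranks all finite pairwise distances and asks whether a sudden increase
#' occurs at the maximum intraspecific divergence: a gap is found when the
#' consecutive pair `(d_k, d_k+1)` straddling `d_intra_max` jumps by more
#' than `gap_factor` times `d_k` itself (scale-free suddenness: the jump must
#' dwarf the distances below it; when `d_k` is zero the median positive
#' consecutive difference is the fallback scale).
#'
#' @param dm A `p_distance_matrix`.
#' @param map A species map tibble.
#' @param gap_factor Multiplier quantifying "sudden increase".
#' @return A `barcode_gap` list: `ranked`, `d_intra_max`, `gap_found`,
#'   `gap_interval` (NULL when not found), `gap_factor`.
#' @export
barcode_gap_assess <- function(dm, map, gap_factor = 2) {
  mask <- conspecific_mask(dm$ids, map)
  intra <- dm$d[mask & upper.tri(mask)]
  intra <- intra[is.finite(intra)]
  if (length(intra) == 0L) abort("no conspecific pair available")
  d_intra_max <- max(intra)
  ranked <- sort(dm$d[upper.tri(dm$d)])
  steps <- diff(ranked)
  pos <- steps[steps > 0]
  k <- findInterval(d_intra_max, ranked) # last index with ranked <= d_intra_max
  gap_found <- FALSE; interval <- NULL
  if (k >= 1L && k < length(ranked)) {
    jump <- ranked[k + 1L] - ranked[k]
    scale <- if (ranked[k] > 0) ranked[k] else if (length(pos) > 0L) stats::median(pos) else 0
    if (ranked[k + 1L] > d_intra_max && jump > gap_factor * scale) {
      gap_found <- TRUE
      interval <- c(ranked[k], ranked[k + 1L])
    }
  }
  structure(
    list(
      ranked = ranked, d_intra_max = d_intra_max,
      gap_found = gap_found, gap_interval = interval, gap_factor = gap_factor
    ),
    class = "barcode_gap"
  )
}

#' @export
print.barcode_gap <- function(x, ...) {
  cat(
    "<barcode_gap: ", length(x$ranked), " distances, d_intra_max = ",
    signif(x$d_intra_max, 4), ", gap ",
    if (x$gap_found) "FOUND" else "absent", ">\n",
    sep = ""
  )
  invisible(x)
}

#' Single-linkage components under a distance threshold
#'
#' Individuals are linked when their distance is <= `threshold`; groups are
#' the connected components. `NA` distances never link.
#'
#' @param dm A `p_distance_matrix`.
#' @param threshold Linking threshold.
#' @return List of character vectors (the groups), ordered by first member.
#' @export
single_linkage_components <- function(dm, threshold) {
  n <- length(dm$ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- which(dm$d <= threshold & upper.tri(dm$d), arr.ind = TRUE)
  for (e in seq_len(nrow(link))) {
    a <- find(link[e, 1]); b <- find(link[e, 2])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(dm$ids, match(roots, unique(roots))))
}

#' ABGD-style recursive partitioning
#'
#' Simplified deterministic re-implementation of automatic barcode gap
#' discovery: given a prior maximum intraspecific divergence `P`, the
#' threshold is the lower edge of the widest consecutive gap in the ranked
#' distances whose upper edge exceeds `P` (or `P` itself when no distance
#' exceeds the prior); groups are single-linkage components at that
#' threshold. When `recursive`, each group is re-examined over `n_steps`
#' geometrically spaced priors in `[P/10, P]` and split further only when the
#' within-group gap is also sudden (wider than `gap_factor` times the median
#' positive step), until the partition stabilizes.
#'
#' @param dm A `p_distance_matrix` without `NA` (NA pairs never link).
#' @param prior_P Prior maximum intraspecific divergence (> 0).
#' @param map Optional species map; when supplied, delimited species are
#'   scored (a species is delimited iff its individuals form exactly one
#'   group with no other individuals).
#' @param n_steps Number of recursion priors.
#' @param recursive Recurse into groups.
#' @param gap_factor Suddenness multiplier for recursive splits.
#' @return An `abgd_partition` list: `groups`, `prior_P`, `threshold`,
#'   `delimited_species`.
#' @export
abgd_partition <- function(dm, prior_P, map = NULL, n_steps = 100L,
                           recursive = TRUE, gap_factor = 2) {
  if (!is.numeric(prior_P) || prior_P <= 0) abort("prior_P must be positive")
  thr <- gap_threshold(dm$d[upper.tri(dm$d)], prior_P, require_sudden = FALSE, gap_factor = gap_factor)
  groups <- single_linkage_components(dm, thr)
  if (recursive) {
    priors <- geom_seq(prior_P / 10, prior_P, n_steps)
    repeat {
      nxt <- list()
      changed <- FALSE
      for (g in groups) {
        if (length(g) <= 2L) { nxt[[length(nxt) + 1L]] <- g; next }
        sub <- dm_subset(dm, g)
        split_found <- FALSE
        for (p in sort(priors, decreasing = TRUE)) {
          t2 <- gap_threshold(sub$d[upper.tri(sub$d)], p, require_sudden = TRUE, gap_factor = gap_factor)
          if (is.na(t2)) next
          comps <- single_linkage_components(sub, t2)
          if (length(comps) > 1L) {
            nxt <- c(nxt, comps)
            split_found <- TRUE; changed <- TRUE
            break
          }
        }
        if (!split_found) nxt[[length(nxt) + 1L]] <- g
      }
      groups <- nxt
      if (!changed) break
    }
  }
  groups <- groups[order(vapply(groups, function(g) g[[1]], character(1)))]
  delimited <- NULL
  if (!is.null(map)) delimited <- delimited_species(groups, dm$ids, map)
  structure(
    list(groups = groups, prior_P = prior_P, threshold = thr, delimited_species = delimited),
    class = "abgd_partition"
  )
}

# Widest-gap threshold above a prior. Candidate gaps are consecutive pairs in
# the ranked list whose upper edge exceeds the prior; the threshold is the
# lower edge of the widest candidate (ties -> smallest lower edge). With
# require_sudden the widest candidate must also be sudden *relative to the
# distances below it* (width > gap_factor * lower edge), otherwise NA (no
# split): a composite group hiding interspecific structure shows a jump that
# dwarfs its intra-cluster distances, while the spread inside a genuine
# conspecific cluster never does.
gap_threshold <- function(dvec, prior, require_sudden, gap_factor) {
  dvec <- sort(dvec[is.finite(dvec)])
  if (length(dvec) < 2L) return(if (require_sudden) NA_real_ else prior)
  if (max(dvec) <= prior) return(if (require_sudden) NA_real_ else prior)
  steps <- diff(dvec)
  cand <- which(dvec[-1L] > prior & steps > 0)
  if (length(cand) == 0L) return(if (require_sudden) NA_real_ else prior)
  best <- cand[order(-steps[cand], dvec[cand])][1L]
  if (require_sudden && steps[best] <= gap_factor * dvec[best]) return(NA_real_)
  dvec[best]
}

delimited_species <- function(groups, ids, map) {
  sp <- species_of(ids, map)
  ok <- character(0)
  for (s in unique(sp)) {
    members <- sort(ids[sp == s])
    hit <- vapply(groups, function(g) identical(sort(g), members), logical(1))
    if (sum(hit) == 1L) ok <- c(ok, s)
  }
  sort(ok)
}

#' @export
print.abgd_partition <- function(x, ...) {
  cat(
    "<abgd_partition: ", length(x$groups), " groups at prior ",
    signif(x$prior_P, 4), ">\n",
    sep = ""
  )
  invisible(x)
}

#' Intra- vs interspecific divergence tests
#'
#' Welch's t test and the Wilcoxon rank-sum test (normal approximation,
#' tie-corrected) comparing intraspecific against interspecific p-distances.
#' In `pooled` mode all conspecific pairs are compared against all
#' heterospecific pairs (optionally restricted to pairs within the same
#' section or group); in `per_species` mode the per-species maximum
#' intraspecific distance is compared against the per-species minimum
#' interspecific distance.
#'
#' @param dm A `p_distance_matrix`.
#' @param map A species map tibble.
#' @param grouping `"all"`, `"section"`, or `"group"`: restrict pairs to the
#'   same taxon partition.
#' @param mode `"pooled"` or `"per_species"`.
#' @return One-row tibble: `t_stat`, `t_p`, `w_stat` (rank-sum W of the
#'   intraspecific sample), `w_p`, `mode`, `n_intra`, `n_inter`.
#' @export
intra_inter_tests <- function(dm, map, grouping = c("all", "section", "group"),
                              mode = c("pooled", "per_species")) {
  grouping <- match.arg(grouping)
  mode <- match.arg(mode)
  ids <- dm$ids
  sp <- species_of(ids, map)
  same_sp <- outer(sp, sp, "==")
  keep <- upper.tri(dm$d)
  if (grouping != "all") {
    gv <- map[[grouping]][match(ids, map$individual)]
    if (all(is.na(gv))) abort(paste0("species map carries no '", grouping, "' column values"))
    keep <- keep & outer(gv, gv, "==")
  }
  if (mode == "pooled") {
    intra <- dm$d[keep & same_sp]
    inter <- dm$d[keep & !same_sp]
  } else {
    intra <- c(); inter <- c()
    for (s in unique(sp)) {
      own <- sp == s
      di <- dm$d[own, own][upper.tri(dm$d[own, own])]
      dx <- dm$d[own, !own]
      if (grouping != "all") {
        gv <- map[[grouping]][match(ids, map$individual)]
        dx <- dm$d[own, !own & gv == gv[own][1], drop = FALSE]
      }
      if (length(di) > 0L) intra <- c(intra, max(di, na.rm = TRUE))
      if (length(dx) > 0L) inter <- c(inter, min(dx, na.rm = TRUE))
    }
  }
  intra <- intra[is.finite(intra)]
  inter <- inter[is.finite(inter)]
  if (length(intra) == 0L || length(inter) == 0L) {
    abort(paste0("empty intra or inter distance set for grouping '", grouping, "'"))
  }
  out <- divergence_tests(intra, inter)
  out$mode <- mode
  out
}

#' Two-sample divergence tests on raw distance vectors
#'
#' @param intra,inter Numeric vectors.
#' @return One-row tibble with `t_stat`, `t_p`, `w_stat`, `w_p`, `n_intra`,
#'   `n_inter`.
#' @export
divergence_tests <- function(intra, inter) {
  tt <- tryCatch(
    stats::t.test(intra, inter),
    error = function(e) {
      # degenerate zero-variance samples: infinite separation or none
      delta <- mean(intra) - mean(inter)
      list(
        statistic = c(t = if (delta == 0) 0 else sign(delta) * Inf),
        p.value = if (delta == 0) 1 else 0
      )
    }
  )
  wt <- suppressWarnings(stats::wilcox.test(intra, inter, exact = FALSE, correct = TRUE))
  n1 <- length(intra)
  tibble(
    t_stat = unname(tt$statistic), t_p = tt$p.value,
    w_stat = unname(wt$statistic) + n1 * (n1 + 1) / 2, # rank-sum W
    w_p = wt$p.value,
    n_intra = n1, n_inter = length(inter)
  )
}
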