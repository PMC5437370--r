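# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive: per-column loops, all-pairs scans, exhaustive
# enumeration. The package implementations are checked against these.

random_alignment <- function(n = 6L, L = 40L, alphabet = c("A", "C", "G", "T"),
                             gap_p = 0, amb_p = 0, marker_id = "rnd") {
  m <- matrix(sample(alphabet, n * L, replace = TRUE), n, L)
  if (gap_p > 0) m[runif(n * L) < gap_p] <- "-"
  if (amb_p > 0) m[runif(n * L) < amb_p] <- sample(c("N", "R", "Y", "W"), 1)
  rownames(m) <- sprintf("ind%02d", seq_len(n))
  marker_alignment(m, marker_id = marker_id)
}

# per-pair, per-column p-distance with pairwise deletion
oracle_pdist <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sh <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mm <- 0L; cc <- 0L
    for (col in seq_len(ncol(m))) {
      a <- m[i, col]; b <- m[j, col]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T")) {
        cc <- cc + 1L
        if (a != b) mm <- mm + 1L
      }
    }
    d[i, j] <- if (cc == 0L) NA_real_ else mm / cc
    sh[i, j] <- cc
  }
  list(d = d, shared = sh)
}

# per-column recount of variable / parsimony-informative sites
oracle_site_counts <- function(aln) {
  m <- unclass(aln)
  nv <- 0L; ni <- 0L
  for (col in seq_len(ncol(m))) {
    obs <- m[, col]
    obs <- obs[obs %in% c("A", "C", "G", "T")]
    tab <- table(obs)
    if (length(tab) >= 2L) {
      nv <- nv + 1L
      if (sum(tab >= 2L) >= 2L) ni <- ni + 1L
    }
  }
  list(variable = nv, informative = ni)
}

# all-pairs maximal forward repeats (O(n^2 L)); 0-based positions
oracle_forward_repeats <- function(seq, min_len, max_len) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  hits <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (s[i] != s[j]) next
    if (i > 1L && s[i - 1L] == s[j - 1L]) next # not left-maximal
    L <- 0L
    while (i + L <= n && j + L <= n && s[i + L] == s[j + L]) L <- L + 1L
    if (L < min_len || L > max_len) next
    unit <- paste0(s[i:(i + L - 1L)], collapse = "")
    if (length(unique(s[i:(i + L - 1L)])) == 1L) next
    if (grepl("N", unit, fixed = TRUE)) next
    hits[[length(hits) + 1L]] <- c(i - 1L, j - 1L, L)
  }
  if (length(hits) == 0L) {
    return(data.frame(pos1 = integer(), pos2 = integer(), length = integer()))
  }
  out <- unique(as.data.frame(do.call(rbind, hits)))
  names(out) <- c("pos1", "pos2", "length")
  out[order(-out$length, out$pos1, out$pos2), ]
}

# all-pairs maximal palindromic (reverse-complement) repeats, disjoint only
oracle_palindromic_repeats <- function(seq, min_len, max_len) {
  s <- strsplit(seq, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  n <- length(s)
  hits <- list()
  # match condition: s[i + t] == comp(s[j + L - 1 - t]); extension to the
  # right of i pairs with extension to the left of j
  for (i in seq_len(n)) for (jend in seq_len(n)) {
    # jend = j + L - 1 anchored; start minimal pair (L = 1): s[i] vs comp(s[jend])
    if (s[i] != comp[[s[jend]]]) next
    # left-maximal: cannot extend with i-1 and jend+1
    if (i > 1L && jend < n && s[i - 1L] == comp[[s[jend + 1L]]]) next
    L <- 0L
    while (i + L <= n && jend - L >= 1L && s[i + L] == comp[[s[jend - L]]]) L <- L + 1L
    j <- jend - L + 1L
    if (L < min_len || L > max_len) next
    if (i + L - 1L >= j) next # overlapping arms: self-palindrome, not a pair
    if (j <= i) next
    unit <- paste0(s[i:(i + L - 1L)], collapse = "")
    if (length(unique(strsplit(unit, "")[[1]])) == 1L) next
    if (grepl("N", unit, fixed = TRUE)) next
    hits[[length(hits) + 1L]] <- c(i - 1L, j - 1L, L)
  }
  if (length(hits) == 0L) {
    return(data.frame(pos1 = integer(), pos2 = integer(), length = integer()))
  }
  out <- unique(as.data.frame(do.call(rbind, hits)))
  names(out) <- c("pos1", "pos2", "length")
  out[order(-out$length, out$pos1, out$pos2), ]
}

# monophyly by explicit edge removal and flood fill over the tree graph
oracle_monophyletic <- function(tree, tips_in_group) {
  edges <- tree$edge
  ntip <- length(tree$tip.label)
  nodes <- sort(unique(as.vector(edges)))
  adj <- lapply(seq_len(max(nodes)), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  target <- sort(tips_in_group)
  for (e in seq_len(nrow(edges))) {
    # flood from child side without crossing edge e
    start <- edges[e, 2]
    seen <- rep(FALSE, max(nodes))
    stack <- start; seen[start] <- TRUE
    while (length(stack) > 0L) {
      v <- stack[[1]]; stack <- stack[-1]
      for (w in adj[[v]]) {
        if (seen[w]) next
        if ((v == edges[e, 1] && w == edges[e, 2]) ||
            (v == edges[e, 2] && w == edges[e, 1])) next
        seen[w] <- TRUE; stack <- c(stack, w)
      }
    }
    side <- sort(tree$tip.label[which(seen[seq_len(ntip)])])
    other <- sort(setdiff(tree$tip.label, side))
    if (identical(side, target) || identical(other, target)) return(TRUE)
  }
  FALSE
}

# exhaustive search for a perfect 1- or 2-literal conjunction separating one
# species from the rest (matrix of single characters, exact state match)
oracle_perfect_conjunction_exists <- function(m, pos, neg, max_literals = 2L) {
  lits <- list()
  for (col in seq_len(ncol(m))) {
    for (b in unique(m[pos, col])) {
      if (!b %in% c("A", "C", "G", "T")) next
      lits[[length(lits) + 1L]] <- c(col, b)
    }
  }
  sat <- function(litset) {
    ok <- rep(TRUE, nrow(m))
    for (l in litset) ok <- ok & m[, as.integer(l[1])] == l[2]
    ok
  }
  for (a in seq_along(lits)) {
    s <- sat(lits[a])
    if (all(s[pos]) && !any(s[neg])) return(TRUE)
  }
  if (max_literals >= 2L && length(lits) >= 2L) {
    for (a in seq_along(lits)) for (b in seq_along(lits)) {
      if (b <= a) next
      s <- sat(lits[c(a, b)])
      if (all(s[pos]) && !any(s[neg])) return(TRUE)
    }
  }
  FALSE
}

# additive distance matrix from a random tree, as a p_distance_matrix
additive_dm <- function(tree) {
  D <- ape::cophenetic.phylo(tree)
  ids <- rownames(D)
  structure(
    list(ids = ids, d = D,
         shared_sites = matrix(1000L, length(ids), length(ids),
                               dimnames = list(ids, ids))),
    class = "p_distance_matrix"
  )
}

# species map for ids named like "sp01_3"
map_from_ids <- function(ids) species_map(ids, sub("_[0-9]+$", "", ids))

# tiny GenBank flat file fixture written to a temp path
write_genbank_fixture <- function(seq, id = "TEST01", features = TRUE) {
  path <- tempfile(fileext = ".gb")
  n <- nchar(seq)
  lines <- c(
    sprintf("LOCUS       %s             %d bp    DNA     circular PLN 01-JAN-2020", id, n),
    sprintf("DEFINITION  synthetic fixture record %s.", id),
    "FEATURES             Location/Qualifiers",
    if (features) c(
      sprintf("     source          1..%d", n),
      "     gene            3..10",
      "                     /gene=\"demo\"",
      sprintf("     repeat_region   complement(5..%d)", min(12L, n)),
      "                     /rpt_type=\"inverted\""
    ),
    "ORIGIN"
  )
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    block <- substr(seq, s, min(n, s + 59L))
    chunks <- regmatches(block, gregexpr(".{1,10}", block))[[1]]
    lines <- c(lines, sprintf("%9d %s", s, paste(tolower(chunks), collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}
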