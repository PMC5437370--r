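#' Locate the inverted repeat pair and derive the quadripartite map
#'
#' Plastomes carry two large inverted repeats (IRa/IRb) separating the large
#' and small single-copy regions (LSC/SSC). The pair is found by seeding
#' shared k-mers between the sequence and its reverse complement, extending
#' each seed run maximally with zero mismatches along its anti-diagonal, and
#' keeping the longest pair at least `min_ir_len` long. Among equal-length
#' maxima the pair with the smallest IRa start wins. If the record carries
#' `repeat_region` annotations and `source = "annotated"`, those intervals
#' are used instead (validated against the reverse-complement invariant with
#' 1% mismatch tolerance).
#'
#' @param genome A `genome_record` from [read_genbank()] or
#'   [synthetic_plastome()].
#' @param min_ir_len Minimum inverted-repeat length in bp.
#' @param source `"computed"` (default) or `"annotated"`.
#' @param k Seed k-mer size.
#' @return A `quadripartite_map` tibble with one row per region
#'   (`lsc`, `ira`, `ssc`, `irb`), 0-based half-open `start`/`end` (the last
#'   region may wrap past the origin on circular records, indicated by
#'   `start > end`), `length`, and a `source` attribute.
#' @export
locate_inverted_repeats <- function(genome, min_ir_len = 1000, source = c("computed", "annotated"), k = 25L) {
  source <- match.arg(source)
  n <- nchar(genome$seq)
  if (n <= 4 * min_ir_len) abort("genome too short for the requested min_ir_len")

  if (source == "annotated") {
    ann <- genome$annotations
    irs <- ann[ann$feature == "repeat_region", , drop = FALSE]
    if (nrow(irs) != 2L) abort("annotated source requires exactly two repeat_region features")
    irs <- irs[order(irs$start), ]
    a <- c(irs$start[1], irs$end[1]); b <- c(irs$start[2], irs$end[2])
    validate_ir_pair(genome$seq, a, b)
    return(build_quadripartite(n, a, b, source = "annotated"))
  }

  hit <- best_ir_pair(genome$seq, k = k)
  if (is.null(hit) || hit$len < min_ir_len) {
    abort(paste0("no inverted repeat of length >= ", min_ir_len, " found (no-IR)"))
  }
  a <- c(hit$i, hit$i + hit$len)
  b <- c(hit$j, hit$j + hit$len)
  build_quadripartite(n, a, b, source = "computed")
}

# Longest reverse-complement segment pair via k-mer seeding. A seed
# (i, j) means seq[i, i+k) == revcomp(seq[j, j+k)); extensions keep i + j
# constant, so maximal hits are runs of consecutive i on one anti-diagonal.
# Coordinates here are 0-based.
best_ir_pair <- function(seq, k = 25L) {
  n <- nchar(seq)
  rc <- revcomp(seq)
  starts <- seq_len(n - k + 1L)
  kms <- substring(seq, starts, starts + k - 1L)
  kmr <- substring(rc, starts, starts + k - 1L)
  shared <- intersect(unique(kms), unique(kmr))
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (length(shared) == 0L) return(NULL)
  pos_f <- split(starts[kms %in% shared] - 1L, kms[kms %in% shared])
  pos_r <- split(starts[kmr %in% shared] - 1L, kmr[kmr %in% shared])
  pos_r <- pos_r[names(pos_f)]
  # vectorized per-kmer cross product of forward and reverse-side positions
  ni <- lengths(pos_f); nj <- lengths(pos_r)
  seeds_i <- rep(unlist(pos_f, use.names = FALSE), times = rep(nj, times = ni))
  seeds_j <- unlist(pos_r[rep(seq_along(pos_r), ni)], use.names = FALSE)
  # rc position p corresponds to forward segment starting at n - p - k
  seeds_j <- n - seeds_j - k
  keep <- seeds_i < seeds_j
  seeds_i <- seeds_i[keep]; seeds_j <- seeds_j[keep]
  if (length(seeds_i) == 0L) return(NULL)
  d <- seeds_i + seeds_j
  best <- NULL
  for (dd in unique(d)) {
    ii <- sort(unique(seeds_i[d == dd]))
    runs <- split(ii, cumsum(c(1L, diff(ii) != 1L)))
    for (r in runs) {
      len <- length(r) + k - 1L
      i0 <- r[[1]]
      j0 <- dd - (r[[length(r)]]) # start of the partner segment
      if (i0 + len > j0) next # overlapping self-palindrome, not an IR pair
      cand <- list(i = i0, j = j0, len = len)
      if (is.null(best) || len > best$len ||
          (len == best$len && i0 < best$i)) {
        best <- cand
      }
    }
  }
  best
}

validate_ir_pair <- function(seq, a, b, tol = 0.01) {
  la <- a[2] - a[1]; lb <- b[2] - b[1]
  if (la != lb) abort("IR intervals differ in length")
  sa <- substr(seq, a[1] + 1L, a[2])
  sb <- revcomp(substr(seq, b[1] + 1L, b[2]))
  mism <- sum(chars(sa) != chars(sb))
  if (mism > tol * la) {
    abort("annotated IR intervals are not reverse complements at >= 99% identity")
  }
  invisible(TRUE)
}

build_quadripartite <- function(n, a, b, source) {
  inner <- c(a[2], b[1])             # between IRa end and IRb start
  outer <- c(b[2] %% n, a[1])        # wraps past the origin when b[2] < n
  len_inner <- inner[2] - inner[1]
  len_outer <- (a[1] - (b[2] %% n)) %% n
  if (len_outer == 0L) len_outer <- n - (b[2] - a[1]) # degenerate, no wrap gap
  if (len_inner >= len_outer) {
    lsc <- inner; ssc <- outer; llen <- len_inner; slen <- len_outer
    regions <- tibble(
      region = c("lsc", "ira", "ssc", "irb"),
      start = c(NA_integer_, a[1], NA_integer_, b[1]),
      end = c(NA_integer_, a[2], NA_integer_, b[2])
    )
    regions$start[regions$region == "lsc"] <- lsc[1]
    regions$end[regions$region == "lsc"] <- lsc[2]
    regions$start[regions$region == "ssc"] <- ssc[1]
    regions$end[regions$region == "ssc"] <- ssc[2]
    lens <- c(llen, a[2] - a[1], slen, b[2] - b[1])
  } else {
    regions <- tibble(
      region = c("lsc", "ira", "ssc", "irb"),
      start = c(outer[1], a[1], inner[1], b[1]),
      end = c(outer[2], a[2], inner[2], b[2])
    )
    lens <- c(len_outer, a[2] - a[1], len_inner, b[2] - b[1])
  }
  regions$length <- as.integer(lens)
  out <- structure(regions, class = c("quadripartite_map", class(regions)))
  attr(out, "source") <- source
  stopifnot(sum(out$length) == n)
  out
}

#' Extract the sequence of one quadripartite region
#'
#' @param genome A `genome_record`.
#' @param map A `quadripartite_map`.
#' @param region One of `"lsc"`, `"ira"`, `"ssc"`, `"irb"`.
#' @return The region sequence as a single string (wrapping regions are
#'   concatenated across the origin).
#' @export
region_seq <- function(genome, map, region) {
  row <- map[map$region == region, ]
  if (nrow(row) != 1L) abort(paste0("unknown region: ", region))
  n <- nchar(genome$seq)
  s <- row$start; e <- row$end
  if (s <= e && !(s == e && row$length == n)) {
    if (e - s != row$length) { # wrap with end stored < start impossible here
      abort("inconsistent region interval")
    }
    substr(genome$seq, s + 1L, e)
  } else {
    paste0(substr(genome$seq, s + 1L, n), substr(genome$seq, 1L, e))
  }
}

#' Summarize a genome and its quadripartite structure
#'
#' @param genome A `genome_record`.
#' @param map A `quadripartite_map` for that genome.
#' @param repeats Optional repeat table from [find_repeats()].
#' @return A one-row tibble: `id`, `total_bp`, `lsc_bp`, `ssc_bp`, `ir_bp`,
#'   `gc_percent` (two decimals; computed over A/C/G/T ignoring N),
#'   `n_repeats`.
#' @export
genome_summary <- function(genome, map, repeats = NULL) {
  n <- nchar(genome$seq)
  stopifnot(sum(map$length) == n)
  cnt <- table(factor(chars(genome$seq), levels = c(BASES, "N")))
  acgt <- sum(cnt[BASES])
  gc <- round(100 * sum(cnt[c("G", "C")]) / acgt, 2)
  tibble(
    id = genome$id,
    total_bp = n,
    lsc_bp = map$length[map$region == "lsc"],
    ssc_bp = map$length[map$region == "ssc"],
    ir_bp = map$length[map$region == "ira"],
    gc_percent = gc,
    n_repeats = if (is.null(repeats)) NA_integer_ else nrow(repeats)
  )
}

#' Scan a genome for maximal exact repeats
#'
#' Finds all maximal exact repeated pairs (forward and, optionally,
#' palindromic i.e. reverse-complement) with unit length between `min_len`
#' and `max_len`, excluding mononucleotide units. Pairs are deduplicated by
#' (unit, sorted positions) and sorted by length descending then first
#' position. Regions listed in `exclude` (e.g. the inverted repeats) are
#' skipped.
#'
#' @param genome A `genome_record` or a plain sequence string.
#' @param min_len,max_len Repeat unit length bounds in bp.
#' @param include_palindromic Also report reverse-complement pairs.
#' @param exclude Optional `quadripartite_map`; hits overlapping its `ira`
#'   or `irb` rows are dropped.
#' @return Tibble with columns `kind`, `pos1`, `pos2` (0-based starts),
#'   `length`, `unit`.
#' @export
find_repeats <- function(genome, min_len = 8L, max_len = 50L,
                         include_palindromic = TRUE, exclude = NULL) {
  if (min_len < 2L) abort("min_len must be at least 2")
  seq <- if (inherits(genome, "genome_record")) genome$seq else genome
  fwd <- maximal_repeat_pairs(seq, seq, min_len, max_len, self = TRUE)
  fwd$kind <- rep("forward", nrow(fwd))
  out <- fwd
  if (include_palindromic) {
    pal <- maximal_repeat_pairs(seq, revcomp(seq), min_len, max_len, self = FALSE)
    if (nrow(pal) > 0L) {
      n <- nchar(seq)
      # convert partner coordinate from revcomp back to forward strand
      pal$pos2 <- n - pal$pos2 - pal$length
      swap <- pal$pos2 < pal$pos1
      tmp <- pal$pos1[swap]; pal$pos1[swap] <- pal$pos2[swap]; pal$pos2[swap] <- tmp
      # a palindromic *pair* must occupy two disjoint locations; maximal
      # extensions that fold onto themselves are self-palindromes, not pairs
      pal <- pal[pal$pos1 + pal$length <= pal$pos2, ]
      if (nrow(pal) > 0L) {
        pal$unit <- substring(seq, pal$pos1 + 1L, pal$pos1 + pal$length)
        pal$kind <- rep("palindromic", nrow(pal))
        out <- dplyr::bind_rows(out, pal)
      }
    }
  }
  if (nrow(out) == 0L) {
    return(tibble(
      kind = character(), pos1 = integer(), pos2 = integer(),
      length = integer(), unit = character()
    ))
  }
  # drop mononucleotide units and N-containing units
  mono <- vapply(out$unit, function(u) length(unique(chars(u))) == 1L, logical(1))
  out <- out[!mono & !grepl("N", out$unit, fixed = TRUE), ]
  if (!is.null(exclude)) {
    irs <- exclude[exclude$region %in% c("ira", "irb"), ]
    hit_ir <- rep(FALSE, nrow(out))
    for (r in seq_len(nrow(irs))) {
      s <- irs$start[r]; e <- irs$end[r]
      hit_ir <- hit_ir |
        (out$pos1 < e & out$pos1 + out$length > s) |
        (out$pos2 < e & out$pos2 + out$length > s)
    }
    out <- out[!hit_ir, ]
  }
  out <- dplyr::distinct(out, .data$kind, .data$pos1, .data$pos2, .data$length, .keep_all = TRUE)
  out |>
    arrange(desc(.data$length), .data$pos1, .data$pos2) |>
    select("kind", "pos1", "pos2", "length", "unit") |>
    as_tibble()
}

# All maximal exact matching pairs between seqA and seqB with length in
# [min_len, max_len]. Seeds are min_len-mers; runs of diagonal-consecutive
# seeds are collapsed into maximal matches. 0-based positions.
maximal_repeat_pairs <- function(seqA, seqB, min_len, max_len, self) {
  k <- as.integer(min_len)
  nA <- nchar(seqA); nB <- nchar(seqB)
  if (nA < k || nB < k) {
    return(tibble(pos1 = integer(), pos2 = integer(), length = integer(), unit = character()))
  }
  sA <- seq_len(nA - k + 1L); sB <- seq_len(nB - k + 1L)
  kA <- substring(seqA, sA, sA + k - 1L)
  kB <- substring(seqB, sB, sB + k - 1L)
  shared <- intersect(kA, kB)
  if (length(shared) == 0L) {
    return(tibble(pos1 = integer(), pos2 = integer(), length = integer(), unit = character()))
  }
  posA <- split(sA[kA %in% shared] - 1L, kA[kA %in% shared])
  posB <- split(sB[kB %in% shared] - 1L, kB[kB %in% shared])
  posB <- posB[names(posA)]
  # vectorized per-kmer cross product
  ni <- lengths(posA); nj <- lengths(posB)
  ii <- rep(unlist(posA, use.names = FALSE), times = rep(nj, times = ni))
  jj <- unlist(posB[rep(seq_along(posB), ni)], use.names = FALSE)
  if (self) {
    keep <- ii < jj
    ii <- ii[keep]; jj <- jj[keep]
  }
  if (length(ii) == 0L) {
    return(tibble(pos1 = integer(), pos2 = integer(), length = integer(), unit = character()))
  }
  # collapse diagonal-consecutive seeds into maximal runs, fully vectorized
  dg <- jj - ii
  ord <- order(dg, ii)
  dgo <- dg[ord]; iio <- ii[ord]
  n_seed <- length(iio)
  newrun <- c(TRUE, dgo[-1L] != dgo[-n_seed] | iio[-1L] != iio[-n_seed] + 1L)
  grp <- cumsum(newrun)
  run_len <- tabulate(grp)
  first <- which(newrun)
  res_i <- iio[first]
  res_j <- res_i + dgo[first]
  res_l <- run_len + k - 1L
  keep <- res_l <= max_len
  # runs longer than max_len fall outside the configured unit-length bounds
  out <- tibble(pos1 = res_i[keep], pos2 = res_j[keep], length = res_l[keep])
  out$unit <- if (nrow(out) == 0L) character(0) else {
    substring(seqA, out$pos1 + 1L, out$pos1 + out$length)
  }
  out
}

#' Compare single-copy regions of two plastomes
#'
#' Aligns LSC with LSC and SSC with SSC (inverted repeats removed), using a
#' collinear chain of unique shared k-mer blocks as anchors and a banded
#' global alignment of the inter-anchor segments (band width
#' `2 * |len_a - len_b| + 16`). Mismatch columns are counted as SNPs and each
#' maximal run of gap columns as one gap event.
#'
#' @param genome_a,genome_b `genome_record`s.
#' @param map_a,map_b Their `quadripartite_map`s.
#' @param k Anchor k-mer size.
#' @return A one-row tibble: `snp_count`, `gap_event_count`,
#'   `anchored_fraction` (reference bases inside anchor blocks / reference
#'   length).
#' @export
compare_single_copy_regions <- function(genome_a, genome_b, map_a, map_b, k = 20L) {
  tot <- list(snp = 0L, gaps = 0L, anch = 0, len = 0L)
  for (region in c("lsc", "ssc")) {
    ra <- region_seq(genome_a, map_a, region)
    rb <- region_seq(genome_b, map_b, region)
    cmp <- anchored_compare(ra, rb, k = k)
    tot$snp <- tot$snp + cmp$snp_count
    tot$gaps <- tot$gaps + cmp$gap_event_count
    tot$anch <- tot$anch + cmp$anchored_fraction * nchar(ra)
    tot$len <- tot$len + nchar(ra)
  }
  frac <- tot$anch / tot$len
  if (frac < 0.5) abort("divergent-genomes: anchored fraction below 0.5, anchoring unreliable")
  tibble(snp_count = tot$snp, gap_event_count = tot$gaps, anchored_fraction = frac)
}

#' Anchor-chained comparison of two homologous sequences
#'
#' @param seq_a Reference sequence (string).
#' @param seq_b Alternate sequence (string).
#' @param k Anchor k-mer size.
#' @param error Error out (as [compare_single_copy_regions()]) when the
#'   anchored fraction falls below 0.5.
#' @return One-row tibble with `snp_count`, `gap_event_count`,
#'   `anchored_fraction`, plus an `alignment` attribute holding the two
#'   gapped strings.
#' @export
anchored_compare <- function(seq_a, seq_b, k = 20L, error = TRUE) {
  blocks <- anchor_chain(seq_a, seq_b, k)
  cov <- if (nrow(blocks) == 0L) 0 else sum(blocks$len) / nchar(seq_a)
  if (cov < 0.5) {
    if (error) abort("divergent-genomes: anchored fraction below 0.5, anchoring unreliable")
    return(tibble(snp_count = NA_integer_, gap_event_count = NA_integer_, anchored_fraction = cov))
  }
  ga <- character(0); gb <- character(0)
  pa <- 0L; pb <- 0L
  for (r in seq_len(nrow(blocks))) {
    seg <- banded_align(
      substr(seq_a, pa + 1L, blocks$a[r]),
      substr(seq_b, pb + 1L, blocks$b[r])
    )
    ga <- c(ga, seg$a); gb <- c(gb, seg$b)
    blk <- substr(seq_a, blocks$a[r] + 1L, blocks$a[r] + blocks$len[r])
    ga <- c(ga, blk); gb <- c(gb, blk)
    pa <- blocks$a[r] + blocks$len[r]
    pb <- blocks$b[r] + blocks$len[r]
  }
  seg <- banded_align(substr(seq_a, pa + 1L, nchar(seq_a)), substr(seq_b, pb + 1L, nchar(seq_b)))
  ga <- c(ga, seg$a); gb <- c(gb, seg$b)
  A <- chars(paste0(ga, collapse = "")); B <- chars(paste0(gb, collapse = ""))
  isgap <- A == "-" | B == "-"
  snp <- sum(!isgap & A != B)
  gap_events <- sum(diff(c(FALSE, isgap)) == 1L)
  out <- tibble(snp_count = snp, gap_event_count = gap_events, anchored_fraction = cov)
  attr(out, "alignment") <- list(a = paste0(A, collapse = ""), b = paste0(B, collapse = ""))
  out
}

# Longest collinear chain of unique shared k-mer blocks. Returns 0-based
# block starts in a and b plus block length, non-overlapping and increasing
# in both coordinates.
anchor_chain <- function(seq_a, seq_b, k) {
  nA <- nchar(seq_a); nB <- nchar(seq_b)
  empty <- tibble(a = integer(), b = integer(), len = integer())
  if (nA < k || nB < k) return(empty)
  sA <- seq_len(nA - k + 1L); sB <- seq_len(nB - k + 1L)
  kA <- substring(seq_a, sA, sA + k - 1L)
  kB <- substring(seq_b, sB, sB + k - 1L)
  uA <- kA %in% names(which(table(kA) == 1L))
  uB <- kB %in% names(which(table(kB) == 1L))
  shared <- intersect(kA[uA], kB[uB])
  if (length(shared) == 0L) return(empty)
  ia <- sA[match(shared, kA)] - 1L
  ib <- sB[match(shared, kB)] - 1L
  ord <- order(ia)
  ia <- ia[ord]; ib <- ib[ord]
  # collapse diagonal runs into blocks
  dd <- ib - ia
  newblk <- c(TRUE, !(diff(ia) == 1L & diff(dd) == 0L))
  grp <- cumsum(newblk)
  blk <- tibble(
    a = tapply(ia, grp, min)[order(unique(grp))],
    len = as.integer(tapply(ia, grp, function(x) max(x) - min(x) + k)),
    b = tapply(ib, grp, min)[order(unique(grp))]
  )
  blk <- blk[order(blk$a), ]
  # longest increasing chain in b weighted by block length (O(m^2), m small)
  m <- nrow(blk)
  score <- blk$len; prev <- rep(0L, m)
  for (i in seq_len(m)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      ok <- blk$a[j] + blk$len[j] <= blk$a[i] && blk$b[j] + blk$len[j] <= blk$b[i]
      if (ok && score[j] + blk$len[i] > score[i]) {
        score[i] <- score[j] + blk$len[i]
        prev[i] <- j
      }
    }
  }
  at <- which.max(score)
  chain <- integer(0)
  while (at != 0L) { chain <- c(at, chain); at <- prev[at] }
  blk[chain, c("a", "b", "len")]
}

# Banded global alignment with affine gap costs (Gotoh): mismatch 1, gap
# open 3, gap extend 0.5. The high open cost keeps each indel event one
# contiguous run, so planted edit scripts are recovered as written instead of
# being fragmented to buy back single mismatches. Returns gapped strings.
banded_align <- function(a, b, mismatch = 1, open = 3, ext = 0.5) {
  A <- chars(a); B <- chars(b)
  n <- length(A); m <- length(B)
  if (n == 0L && m == 0L) return(list(a = character(0), b = character(0)))
  if (n == 0L) return(list(a = strrep("-", m), b = b))
  if (m == 0L) return(list(a = a, b = strrep("-", n)))
  band <- 2L * abs(n - m) + 16L
  INF <- 1e18
  M <- matrix(INF, n + 1L, m + 1L) # last column pair aligned
  P <- matrix(INF, n + 1L, m + 1L) # last column gap in b (a consumed)
  Q <- matrix(INF, n + 1L, m + 1L) # last column gap in a (b consumed)
  M[1, 1] <- 0
  for (j in seq_len(min(m, band))) Q[1, j + 1L] <- open + ext * j
  for (i in seq_len(min(n, band))) P[i + 1L, 1L] <- open + ext * i
  for (i in seq_len(n)) {
    jlo <- max(1L, i - band); jhi <- min(m, i + band)
    for (j in jlo:jhi) {
      sub <- mismatch * (A[i] != B[j])
      M[i + 1L, j + 1L] <- min(M[i, j], P[i, j], Q[i, j]) + sub
      P[i + 1L, j + 1L] <- min(M[i, j + 1L] + open, P[i, j + 1L],
                               Q[i, j + 1L] + open) + ext
      Q[i + 1L, j + 1L] <- min(M[i + 1L, j] + open, Q[i + 1L, j],
                               P[i + 1L, j] + open) + ext
    }
  }
  # traceback with explicit state
  i <- n; j <- m
  state <- which.min(c(M[n + 1L, m + 1L], P[n + 1L, m + 1L], Q[n + 1L, m + 1L]))
  ra <- character(n + m); rb <- character(n + m); at <- n + m
  eq <- function(x, y) abs(x - y) < 1e-9
  while (i > 0L || j > 0L) {
    if (state == 1L) {
      sub <- mismatch * (A[i] != B[j])
      val <- M[i + 1L, j + 1L]
      ra[at] <- A[i]; rb[at] <- B[j]
      state <- if (eq(val, M[i, j] + sub)) 1L else if (eq(val, P[i, j] + sub)) 2L else 3L
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      val <- P[i + 1L, j + 1L]
      ra[at] <- A[i]; rb[at] <- "-"
      state <- if (eq(val, P[i, j + 1L] + ext)) 2L else if (eq(val, M[i, j + 1L] + open + ext)) 1L else 3L
      i <- i - 1L
    } else {
      val <- Q[i + 1L, j + 1L]
      ra[at] <- "-"; rb[at] <- B[j]
      state <- if (eq(val, Q[i + 1L, j] + ext)) 3L else if (eq(val, M[i + 1L, j] + open + ext)) 1L else 2L
      j <- j - 1L
    }
    at <- at - 1L
    if (i == 0L && j > 0L) state <- 3L
    if (j == 0L && i > 0L) state <- 2L
  }
  keep <- seq.int(at + 1L, n + m)
  list(a = paste0(ra[keep], collapse = ""), b = paste0(rb[keep], collapse = ""))
}

#' Build a synthetic reference plastome
#'
#' Constructs a random circular-convention plastome with the canonical
#' LSC + IRa + SSC + revcomp(IRa) architecture, for exercising the
#' quadripartite locator and genome summaries at realistic scale without any
#' sequence download. Defaults use the region lengths and GC content typical
#' of a Fagaceae plastome.
#'
#' @param lsc_bp,ssc_bp,ir_bp Region lengths in bp.
#' @param gc Target GC proportion.
#' @param seed Integer seed.
#' @return A `genome_record` with id `"synthetic_plastome"`.
#' @export
synthetic_plastome <- function(lsc_bp = 91121L, ssc_bp = 20150L, ir_bp = 25051L,
                               gc = 0.3679, seed = 1L) {
  set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  draw <- function(n) paste0(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
  lsc <- draw(lsc_bp); ir <- draw(ir_bp); ssc <- draw(ssc_bp)
  # pin the IR/SSC boundary: if the SSC termini are complementary the IR pair
  # would extend one step into the SSC and shift the recovered boundaries
  first <- substr(ssc, 1L, 1L)
  last <- substr(ssc, ssc_bp, ssc_bp)
  if (identical(revcomp(last), first)) {
    repl <- sample(setdiff(BASES, last), 1L)
    if (identical(revcomp(repl), first)) repl <- sample(setdiff(BASES, c(last, repl)), 1L)
    substr(ssc, ssc_bp, ssc_bp) <- repl
  }
  seq <- paste0(lsc, ir, ssc, revcomp(ir))
  new_genome_record("synthetic_plastome", seq, circular = TRUE,
                    annotations = empty_annotations())
}
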