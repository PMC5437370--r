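#' Primer melting temperature
#'
#' Wallace rule `2(A+T) + 4(G+C)` or the GC formula
#' `64.9 + 41 (GC - 16.4) / len`. The conventional split — Wallace for short
#' oligos, GC formula above 20 nt — is applied by [pick_primer_windows()].
#'
#' @param seq Primer sequence over `{A,C,G,T}`, length >= 8.
#' @param method `"wallace"` or `"gc"`.
#' @return Melting temperature in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AAAATTTTGGGGCCCC") # 48
melting_temperature <- function(seq, method = c("wallace", "gc")) {
  method <- match.arg(method)
  ch <- chars(toupper(seq))
  if (!all(ch %in% BASES)) abort("primer sequences must be unambiguous A/C/G/T")
  if (length(ch) < 8L) abort("primer too short for a meaningful Tm")
  gc <- sum(ch %in% c("G", "C"))
  at <- sum(ch %in% c("A", "T"))
  switch(method,
    wallace = 2 * at + 4 * gc,
    gc = 64.9 + 41 * (gc - 16.4) / length(ch)
  )
}

default_tm <- function(seq) {
  melting_temperature(seq, if (nchar(seq) <= 20L) "wallace" else "gc")
}

#' Select conserved-flank primer windows around variable cores
#'
#' Scans a pairwise-aligned region of two genomes for primer-sized windows
#' that are identical (and ungapped) in both sequences and satisfy the
#' length and melting-temperature constraints, then pairs windows that
#' bracket at least one variant column at a product length within bounds.
#' Tiling is greedy left-to-right and prefers non-overlapping products, the
#' classical recipe for designing universal markers from a two-genome
#' comparison.
#'
#' @param ref_aligned,alt_aligned Equal-length aligned strings (gaps as `-`)
#'   of the reference and alternate genome region.
#' @param primer_len Length bounds for each primer.
#' @param tm_range Melting-temperature bounds (degrees Celsius).
#' @param product_len Product-length bounds (alignment columns between and
#'   including the primers).
#' @param region_label Label attached to emitted candidates.
#' @return Tibble of candidate markers: `region_label`, `fwd`, `rev` (5'->3'
#'   on the reverse strand), `tm_fwd`, `tm_rev`, `product_start`,
#'   `product_end` (0-based half-open on the alignment), `n_variant_sites`.
#' @export
pick_primer_windows <- function(ref_aligned, alt_aligned,
                                primer_len = c(18L, 24L),
                                tm_range = c(50, 65),
                                product_len = c(400L, 1100L),
                                region_label = "region") {
  A <- chars(toupper(ref_aligned)); B <- chars(toupper(alt_aligned))
  if (length(A) != length(B)) abort("aligned region strings must have equal length")
  L <- length(A)
  variant <- A != B
  conserved <- A == B & A %in% BASES

  # candidate windows: maximal runs of conserved columns >= min primer length
  win_len <- primer_len[1]
  ok_window <- function(start) {
    # grow to the longest primer within bounds that satisfies Tm; prefer the
    # shortest length whose Tm fits
    for (len in primer_len[1]:primer_len[2]) {
      e <- start + len - 1L
      if (e > L || !all(conserved[start:e])) return(NULL)
      p <- paste0(A[start:e], collapse = "")
      tm <- default_tm(p)
      if (tm >= tm_range[1] && tm <= tm_range[2]) {
        return(list(start = start, end = e, seq = p, tm = tm))
      }
    }
    NULL
  }

  out <- list()
  pos <- 1L
  while (pos + product_len[1] - 1L <= L) {
    fwd <- ok_window(pos)
    if (is.null(fwd)) { pos <- pos + 1L; next }
    placed <- FALSE
    # try the smallest product first so tiling stays dense
    for (pend in seq(fwd$start + product_len[1] - 1L, min(L, fwd$start + product_len[2] - 1L))) {
      rev_start <- pend - primer_len[1] + 1L
      if (rev_start <= fwd$end) next
      rv <- ok_window_rev(A, conserved, rev_start, pend, primer_len, tm_range)
      if (is.null(rv) || rv$start <= fwd$end + 1L) next
      nvar <- sum(variant[(fwd$end + 1L):(rv$start - 1L)])
      if (nvar < 1L) next
      fwd_seq <- fwd$seq; fwd_tm <- fwd$tm; fwd_start <- fwd$start
      out[[length(out) + 1L]] <- tibble(
        region_label = region_label,
        fwd = fwd_seq, rev = rv$seq,
        tm_fwd = fwd_tm, tm_rev = rv$tm,
        product_start = fwd_start - 1L, product_end = pend,
        n_variant_sites = nvar
      )
      pos <- pend + 1L # non-overlapping products preferred
      placed <- TRUE
      break
    }
    if (!placed) pos <- pos + 1L
  }
  dplyr::bind_rows(out) %0% tibble(
    region_label = character(), fwd = character(), rev = character(),
    tm_fwd = double(), tm_rev = double(),
    product_start = integer(), product_end = integer(),
    n_variant_sites = integer()
  )
}

# reverse primer anchored at product end: window [start, end] conserved, Tm
# in range; returned 5'->3' on the reverse strand
ok_window_rev <- function(A, conserved, start, end, primer_len, tm_range) {
  L <- length(A)
  for (len in primer_len[1]:primer_len[2]) {
    s <- end - len + 1L
    if (s < 1L || !all(conserved[s:end])) return(NULL)
    p <- revcomp(paste0(A[s:end], collapse = ""))
    tm <- default_tm(p)
    if (tm >= tm_range[1] && tm <= tm_range[2]) {
      return(list(start = s, end = end, seq = p, tm = tm))
    }
  }
  NULL
}
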