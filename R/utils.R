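#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr unnest pivot_longer
#' @importFrom purrr map map_dbl map_chr map_lgl map_int imap
NULL

# IUPAC nucleotide ambiguity expansion. '-' and '?' expand to nothing: a gap
# or missing cell can never match or block a base state.
IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  `-` = character(0), `?` = character(0)
)

BASES <- c("A", "C", "G", "T")

iupac_expand <- function(x) {
  out <- IUPAC[[x]]
  if (is.null(out)) abort(paste0("unknown sequence symbol '", x, "'"))
  out
}

#' Reverse complement of a nucleotide string
#'
#' Complements IUPAC ambiguity codes correctly; gaps and `?` pass through.
#'
#' @param seq Single character string over the IUPAC alphabet.
#' @return The reverse complement as a single string.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", U = "A",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", V = "B", D = "H", H = "D", N = "N", `-` = "-", `?` = "?"
  )
  ch <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- comp[ch]
  if (anyNA(out)) abort("sequence contains symbols outside the IUPAC alphabet")
  paste0(out, collapse = "")
}

# Split a string into a character vector of single characters.
chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Map A/C/G/T to 1..4, everything else (gaps, ?, ambiguity) to NA. Used by
# all pairwise-deletion distance code: only unambiguous bases are states.
base_int <- function(m) {
  out <- match(m, BASES)
  dim(out) <- dim(m)
  dimnames(out) <- dimnames(m)
  out
}

# Deterministic geometric sequence from `hi` down to `lo`.
geom_seq <- function(lo, hi, n) exp(seq(log(hi), log(lo), length.out = n))

`%0%` <- function(x, y) if (length(x) == 0L) y else x
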