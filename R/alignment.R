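#' Marker alignment container
#'
#' A `marker_alignment` is a character matrix with one row per individual and
#' one column per alignment position, all cells single characters over
#' `{A,C,G,T,-,?}` plus IUPAC ambiguity codes. Row names are the individual
#' identifiers and must be unique.
#'
#' @param seqs Character vector of equal-length aligned sequences, or a
#'   character matrix of single characters.
#' @param ids Individual identifiers (defaults to names of `seqs`).
#' @param marker_id Marker label carried as an attribute.
#' @return A `marker_alignment` object.
#' @export
#' @examples
#' marker_alignment(c(a = "ACGT", b = "AC-T"), marker_id = "demo")
marker_alignment <- function(seqs, ids = NULL, marker_id = "marker") {
  if (is.matrix(seqs)) {
    m <- seqs
    if (!is.null(ids)) rownames(m) <- ids
  } else {
    ids <- ids %||% names(seqs)
    if (is.null(ids)) abort("individual ids are required")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      bad <- ids[lens != stats::median(lens)]
      abort(paste0(
        "aligned sequences must have equal length; offending ids: ",
        paste(bad, collapse = ", ")
      ))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- ids
  }
  if (ncol(m) == 0L) abort("alignment must have at least one column")
  if (anyDuplicated(rownames(m))) {
    abort(paste0(
      "duplicate individual ids: ",
      paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")
    ))
  }
  m[m == "U"] <- "T"
  m[m == "."] <- "-"
  bad <- setdiff(unique(as.vector(m)), names(IUPAC))
  if (length(bad) > 0L) {
    abort(paste0("alignment contains non-IUPAC symbols: ", paste(bad, collapse = " ")))
  }
  structure(m, class = c("marker_alignment", "matrix"), marker_id = marker_id)
}

#' @export
print.marker_alignment <- function(x, ...) {
  cat(
    "<marker_alignment '", attr(x, "marker_id"), "': ",
    nrow(x), " individuals x ", ncol(x), " columns>\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname marker_alignment
#' @param x A `marker_alignment`.
#' @export
alignment_ids <- function(x) rownames(x)

#' @rdname marker_alignment
#' @export
marker_id <- function(x) attr(x, "marker_id")

# Collapse rows back to strings (used by writers and the generator).
alignment_strings <- function(x) {
  stats::setNames(apply(unclass(x), 1L, paste0, collapse = ""), rownames(x))
}

# Subset rows/columns without losing class or marker_id.
aln_subset <- function(x, rows = NULL, cols = NULL) {
  m <- unclass(x)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) m <- m[, cols, drop = FALSE]
  structure(m, class = c("marker_alignment", "matrix"), marker_id = attr(x, "marker_id"))
}
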