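#' Read a GenBank flat file or single-record FASTA as a genome record
#'
#' Minimal reader for annotated plastome records. GenBank 1-based closed
#' feature coordinates are converted to 0-based half-open on read; the
#' declared LOCUS length is checked against the parsed sequence. Lowercase
#' sequence and `U` are normalized to uppercase `T`-alphabet.
#'
#' @param path Path to a GenBank flat file (`LOCUS ... ORIGIN ... //`) or a
#'   single-record FASTA file.
#' @return A `genome_record`: list with `id`, `seq` (single uppercase string),
#'   `circular`, and `annotations` (tibble with `feature`, `start`, `end`,
#'   `strand`, `label`).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort(paste0("empty file: ", path))
  if (startsWith(lines[[1]], ">")) {
    return(read_fasta_genome(lines, path))
  }
  if (!grepl("^LOCUS", lines[[1]])) {
    abort(paste0(path, ":1: expected LOCUS or '>' header"))
  }
  locus <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  id <- locus[2]
  declared <- suppressWarnings(as.integer(locus[grep("^[0-9]+$", locus)][1]))
  if (is.na(declared)) abort(paste0(path, ":1: LOCUS line carries no length"))
  circular <- any(grepl("circular", lines[[1]], ignore.case = TRUE))

  origin_at <- grep("^ORIGIN", lines)[1]
  if (is.na(origin_at)) abort(paste0(path, ": no ORIGIN section"))
  end_at <- grep("^//", lines)[1] %0% (length(lines) + 1L)
  seq_lines <- lines[(origin_at + 1L):(end_at - 1L)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  seq <- gsub("U", "T", seq)
  if (nchar(seq) == 0L) abort(paste0(path, ":", origin_at, ": empty ORIGIN"))
  if (nchar(seq) != declared) {
    abort(paste0(
      path, ": LOCUS declares ", declared, " bp but ORIGIN has ", nchar(seq)
    ))
  }

  annotations <- parse_genbank_features(lines, origin_at, path)
  new_genome_record(id, seq, circular, annotations)
}

read_fasta_genome <- function(lines, path) {
  headers <- grep("^>", lines)
  if (length(headers) > 1L) {
    abort(paste0(path, ": multi-record FASTA not supported for genome input"))
  }
  id <- sub("^>\\s*", "", lines[[1]])
  id <- strsplit(id, "\\s+")[[1]][1]
  seq <- toupper(paste0(lines[-1], collapse = ""))
  seq <- gsub("U", "T", gsub("\\s", "", seq))
  if (nchar(seq) == 0L) abort(paste0(path, ": empty sequence"))
  new_genome_record(id, seq, circular = FALSE, annotations = empty_annotations())
}

empty_annotations <- function() {
  tibble(
    feature = character(), start = integer(), end = integer(),
    strand = character(), label = character()
  )
}

parse_genbank_features <- function(lines, origin_at, path) {
  feat_at <- grep("^FEATURES", lines)[1]
  if (is.na(feat_at) || feat_at > origin_at) return(empty_annotations())
  block <- lines[(feat_at + 1L):(origin_at - 1L)]
  # Feature headers sit at column 6; qualifiers at column 22.
  hdr <- grepl("^\\s{4,6}\\S", block) & !grepl("^\\s{10,}", block)
  rows <- list()
  current <- NULL
  for (i in seq_along(block)) {
    ln <- block[[i]]
    if (hdr[[i]]) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) < 2L) {
        abort(paste0(path, ":", feat_at + i, ": malformed feature line"))
      }
      loc <- parts[2]
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1]]
      if (length(nums) == 0L) {
        abort(paste0(path, ":", feat_at + i, ": unparseable location '", loc, "'"))
      }
      start1 <- as.integer(nums[1])
      end1 <- as.integer(nums[length(nums)])
      current <- list(
        feature = parts[1],
        start = start1 - 1L, # to 0-based half-open
        end = end1,
        strand = strand, label = NA_character_
      )
      rows[[length(rows) + 1L]] <- current
    } else if (!is.null(current) && is.na(rows[[length(rows)]]$label)) {
      q <- regmatches(ln, regexec('/(gene|label|note|rpt_type)="?([^"]+)"?', ln))[[1]]
      if (length(q) == 3L) rows[[length(rows)]]$label <- q[3]
    }
  }
  if (length(rows) == 0L) return(empty_annotations())
  dplyr::bind_rows(lapply(rows, as_tibble))
}

new_genome_record <- function(id, seq, circular, annotations) {
  if (!grepl("^[ACGTN]*$", seq)) {
    extra <- setdiff(unique(chars(seq)), c("A", "C", "G", "T", "N"))
    abort(paste0("genome sequence contains unexpected symbols: ", paste(extra, collapse = " ")))
  }
  n <- nchar(seq)
  if (nrow(annotations) > 0L &&
      any(annotations$start < 0L | annotations$end > n | annotations$start >= annotations$end)) {
    abort("annotation intervals fall outside the sequence")
  }
  structure(
    list(id = id, seq = seq, circular = circular, annotations = annotations),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(
    "<genome_record ", x$id, ": ", nchar(x$seq), " bp, ",
    if (x$circular) "circular" else "linear", ", ",
    nrow(x$annotations), " annotations>\n",
    sep = ""
  )
  invisible(x)
}

#' Read an aligned FASTA file as a marker alignment
#'
#' All records must have equal length; `U` is converted to `T` and `.` to
#' `-`. Record order is preserved. IUPAC ambiguity codes are kept verbatim.
#'
#' @param path Path to an aligned FASTA file.
#' @param marker_id Marker label (defaults to the file base name).
#' @return A [marker_alignment()].
#' @export
read_fasta_alignment <- function(path, marker_id = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  marker_id <- marker_id %||% sub("\\.[^.]*$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  marker_alignment(seqs, marker_id = marker_id)
}

#' Write a marker alignment as aligned FASTA
#'
#' @param aln A [marker_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- alignment_strings(aln)
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}

#' Read an individual-to-species map
#'
#' Expects a TSV with header columns `individual` and `species`, plus
#' optional `section` and `group`. Unknown columns are ignored with a
#' warning. Duplicate individuals and blank species are errors.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `individual`, `species`, `section`, `group`.
#' @export
read_species_map <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  need <- c("individual", "species")
  if (!all(need %in% names(tab))) {
    abort("species map needs 'individual' and 'species' columns")
  }
  extra <- setdiff(names(tab), c(need, "section", "group"))
  if (length(extra) > 0L) {
    warn(paste0("ignoring unknown species-map columns: ", paste(extra, collapse = ", ")))
  }
  if (anyDuplicated(tab$individual)) {
    abort(paste0(
      "individuals mapped more than once: ",
      paste(unique(tab$individual[duplicated(tab$individual)]), collapse = ", ")
    ))
  }
  if (any(is.na(tab$species) | trimws(tab$species) == "")) {
    abort("species map contains blank species cells")
  }
  species_map(
    tab$individual, tab$species,
    section = if ("section" %in% names(tab)) tab$section else NA_character_,
    group = if ("group" %in% names(tab)) tab$group else NA_character_
  )
}

#' Construct a species map in code
#'
#' @param individual,species Character vectors of equal length.
#' @param section,group Optional character vectors (recycled).
#' @return A tibble with one row per individual.
#' @export
species_map <- function(individual, species, section = NA_character_, group = NA_character_) {
  if (anyDuplicated(individual)) abort("duplicate individuals in species map")
  if (any(is.na(species) | species == "")) abort("species names must be non-empty")
  tibble(
    individual = as.character(individual), species = as.character(species),
    section = as.character(section), group = as.character(group)
  )
}

# species vector aligned with a set of ids, with validation
species_of <- function(ids, map) {
  sp <- map$species[match(ids, map$individual)]
  if (anyNA(sp)) {
    abort(paste0(
      "individuals missing from species map: ",
      paste(ids[is.na(sp)], collapse = ", ")
    ))
  }
  sp
}

#' Write a tree in Newick format
#'
#' Bootstrap supports stored in `node.label` are written as integer internal
#' edge labels. Leaf names containing whitespace are underscored.
#'
#' @param tree An [ape::phylo] tree (as returned by [nj_tree()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- gsub("\\s+", "_", tree$tip.label)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a discrimination report
#'
#' Rows are ordered by method, then combination size, then marker labels, so
#' repeated writes of the same report are byte-identical.
#'
#' @param report A discrimination report tibble from [evaluate_all()].
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- report |>
    mutate(identified_species = map_chr(.data$identified_species, paste, collapse = ";")) |>
    arrange(.data$method, .data$n_markers, .data$markers)
  if (format == "tsv") {
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    recs <- purrr::pmap(out, function(method, markers, n_markers, n_identified,
                                      n_eligible, rate, identified_species, ...) {
      list(
        method = method, markers = strsplit(markers, "+", fixed = TRUE)[[1]],
        rate = rate, n_identified = n_identified, n_eligible = n_eligible,
        identified = strsplit(identified_species, ";", fixed = TRUE)[[1]] %0% character(0)
      )
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a discrimination report written by [write_report()]
#'
#' @param path Path to a TSV report.
#' @return The report tibble with `identified_species` restored as a list
#'   column.
#' @export
read_report <- function(path) {
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      method = "c", markers = "c", n_markers = "i", n_identified = "i",
      n_eligible = "i", rate = "d", identified_species = "c"
    ),
    progress = FALSE
  )
  tab$identified_species <- lapply(
    tab$identified_species,
    function(s) if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  )
  new_discrimination_report(tab)
}
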