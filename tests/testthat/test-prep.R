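test_that("cleaning drops ambiguous columns and poly-A/T blocks with provenance", {
  rows <- c(
    a = "ACGTNAAAAAAAAAGC",
    b = "ACGTNAAAAAAAAAGC",
    c = "ACCTNAAAAAAAAAGC"
  )
  aln <- marker_alignment(rows, marker_id = "m")
  out <- clean_alignment(aln)
  # column 5 is all-N, columns 6..14 are a 9-long poly-A run in every row
  expect_identical(attr(out, "provenance"), c(1:4, 15:16))
  expect_identical(ncol(out), 6L)

  no_change <- marker_alignment(c(a = "ACGTAC", b = "ACCTAC"), marker_id = "m")
  kept <- clean_alignment(no_change)
  expect_identical(alignment_strings(kept), alignment_strings(no_change))
  expect_identical(attr(kept, "provenance"), 1:6)

  all_n <- marker_alignment(c(a = "NNN", b = "NNN"), marker_id = "m")
  expect_error(clean_alignment(all_n), "every column")
})

test_that("simple indel coding appends one binary column per distinct span", {
  aln <- marker_alignment(
    c(r1 = "AC--GT", r2 = "ACTTGT", r3 = "AC--GT"),
    marker_id = "m"
  )
  out <- code_indels(aln)
  expect_identical(nrow(out$characters), 1L)
  expect_identical(out$characters$span_start, 3L)
  expect_identical(out$characters$span_end, 4L)
  expect_identical(unname(out$characters$presence[[1]]), c(TRUE, FALSE, TRUE))
  expect_identical(ncol(out$alignment), 7L)
  expect_identical(unname(unclass(out$alignment)[, 7]), c("T", "A", "T"))
})

test_that("strictly containing gaps score '?' for the contained character", {
  aln <- marker_alignment(
    c(r1 = "AC----GT", r2 = "ACT--TGT", r3 = "ACTAGTGT"),
    marker_id = "m"
  )
  out <- code_indels(aln)
  expect_identical(nrow(out$characters), 2L)
  coded <- unclass(out$alignment)[, 9:10]
  # span [3,6] present only in r1; span [4,5] contained within r1's gap -> '?'
  wide <- which(out$characters$span_start == 3L)
  narrow <- which(out$characters$span_start == 4L)
  expect_identical(unname(coded[, wide]), c("T", "A", "A"))
  expect_identical(unname(coded[, narrow]), c("?", "T", "A"))
})

test_that("gap-free alignments code to zero characters unchanged", {
  aln <- random_alignment(4, 20)
  out <- code_indels(aln)
  expect_identical(nrow(out$characters), 0L)
  expect_identical(unclass(out$alignment), unclass(aln))
})

test_that("indel coding then decoding recovers the gap topology", {
  set.seed(41)
  for (case in 1:20) {
    aln <- random_alignment(n = 6, L = 30)
    m <- unclass(aln)
    # plant 1-3 gap runs at random rows/positions
    for (g in seq_len(sample(1:3, 1))) {
      r <- sample(6, 1); start <- sample(1:25, 1); len <- sample(2:5, 1)
      m[r, start:(start + len - 1)] <- "-"
    }
    aln2 <- marker_alignment(m, marker_id = "m")
    out <- code_indels(aln2)
    # distinct exact spans in the matrix == appended characters
    spans <- unique(unlist(lapply(seq_len(nrow(m)), function(r) {
      rl <- rle(unclass(aln2)[r, ] == "-")
      e <- cumsum(rl$lengths); s <- e - rl$lengths + 1
      paste(s[rl$values], e[rl$values])
    })))
    expect_identical(nrow(out$characters), length(spans))
    # presence vectors reproduce exactly which rows carry each exact span
    for (i in seq_len(nrow(out$characters))) {
      sp <- c(out$characters$span_start[i], out$characters$span_end[i])
      truth <- vapply(seq_len(nrow(m)), function(r) {
        g <- unclass(aln2)[r, ] == "-"
        all(g[sp[1]:sp[2]]) &&
          (sp[1] == 1 || !g[sp[1] - 1]) && (sp[2] == ncol(m) || !g[sp[2] + 1])
      }, logical(1))
      expect_identical(unname(out$characters$presence[[i]]), truth)
    }
  }
})

test_that("site statistics match a per-column recount on random matrices", {
  set.seed(42)
  for (case in 1:100) {
    aln <- random_alignment(
      n = sample(4:8, 1), L = sample(10:40, 1),
      gap_p = 0.05, amb_p = 0.03
    )
    map <- species_map(alignment_ids(aln),
                       rep(c("x", "y"), length.out = nrow(aln)))
    got <- site_stats(aln, map)
    exp <- oracle_site_counts(aln)
    expect_identical(got$n_variable, exp$variable)
    expect_identical(got$n_informative, exp$informative)
  }
})

test_that("site statistics count diagnostic indels per species", {
  rows <- c(
    x1 = "AAC--GGTT", x2 = "AAC--GGTT",
    y1 = "AACTAGGTT", y2 = "AACTAGG--"
  )
  aln <- marker_alignment(rows, marker_id = "m")
  map <- species_map(names(rows), c("x", "x", "y", "y"))
  s <- site_stats(aln, map)
  expect_identical(s$n_indels, 2L)
  expect_identical(s$n_diagnostic_indels, 1L) # [4,5] in all/only x; [8,9] only y2
})

test_that("hand-built examples reproduce textbook variable/informative counts", {
  a1 <- marker_alignment(c(a = "AAAA", b = "AAAT", c = "AAAA"), marker_id = "m")
  m1 <- species_map(c("a", "b", "c"), c("s1", "s1", "s2"))
  s1 <- site_stats(a1, m1)
  expect_identical(c(s1$n_variable, s1$n_informative), c(1L, 0L))
  a2 <- marker_alignment(c(a = "AAT", b = "AAT", c = "CCA", d = "CCA"), marker_id = "m")
  m2 <- species_map(letters[1:4], c("s1", "s1", "s2", "s2"))
  s2 <- site_stats(a2, m2)
  expect_identical(c(s2$n_variable, s2$n_informative), c(3L, 3L))
})

test_that("diagnostic characters follow the conservative ambiguity rule", {
  rows <- c(
    x1 = "TTAAC", x2 = "TTAAC",
    y1 = "CTAAC", y2 = "CTAAC"
  )
  aln <- marker_alignment(rows, marker_id = "m")
  map <- species_map(names(rows), c("x", "x", "y", "y"))
  d <- find_diagnostic_characters(aln, map)
  expect_identical(nrow(d), 2L) # column 1: T diagnostic for x, C for y
  expect_identical(d$state[d$species == "x"], "T")

  # heterozygous Y (C/T) in a y individual blocks x's T at that column
  rows2 <- rows; rows2[["y1"]] <- "YTAAC"
  d2 <- find_diagnostic_characters(marker_alignment(rows2, marker_id = "m"), map)
  expect_false(any(d2$species == "x"))
  # and ambiguity never supplies a state: y loses its C diagnostic too
  expect_false(any(d2$species == "y"))

  # a species with mixed states has no diagnostic
  rows3 <- rows; rows3[["x2"]] <- "CTAAC"
  d3 <- find_diagnostic_characters(marker_alignment(rows3, marker_id = "m"), map)
  expect_identical(nrow(d3), 0L)
})

test_that("ITS screening flags GC outliers and honors motif lists", {
  rows <- c(
    ok = "GCGCGCATGCGCGTACGCAT",  # GC 65%
    low = "ATATATATATATATATATAT", # GC 0%
    mot = "GCGCGCATGCGCGTACGCAT"
  )
  aln <- marker_alignment(rows, marker_id = "ITS")
  flags <- screen_its(aln)
  expect_true(flags$pass[flags$individual == "ok"])
  expect_false(flags$pass[flags$individual == "low"])
  # empty motif list passes vacuously
  expect_true(all(flags$motif_pass))
  with_motif <- screen_its(aln, motifs = "ATGYGCG") # Y matches C in 'ok'
  expect_true(with_motif$motif_pass[with_motif$individual == "ok"])
  with_absent <- screen_its(aln, motifs = "AAAAAAA")
  expect_false(any(with_absent$motif_pass))
})
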