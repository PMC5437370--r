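test_that("neighbor joining is consistent on random additive matrices", {
  set.seed(91)
  for (case in 1:100) {
    tr <- ape::rtree(8, br = function(n) stats::runif(n, 0.2, 2))
    tr <- ape::unroot(tr)
    dm <- additive_dm(tr)
    est <- nj_tree(dm)
    # topology identical
    expect_equal(as.numeric(ape::dist.topo(est, tr)), 0)
    # path lengths reproduce the input distances exactly
    got <- ape::cophenetic.phylo(est)[dm$ids, dm$ids]
    expect_equal(got, dm$d, tolerance = 1e-8)
  }
})

test_that("three-taxon trees use the three-point formulas and ties are deterministic", {
  ids <- c("A", "B", "C")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(ids, ids))
  dm <- structure(list(ids = ids, d = d,
                       shared_sites = matrix(10L, 3, 3, dimnames = list(ids, ids))),
                  class = "p_distance_matrix")
  tr <- nj_tree(dm)
  expect_identical(ape::Ntip(tr), 3L)
  expect_identical(tr$Nnode, 1L)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))

  # equidistant 4 taxa: same result on repeated runs
  ids4 <- c("a", "b", "c", "d")
  d4 <- matrix(1, 4, 4, dimnames = list(ids4, ids4)); diag(d4) <- 0
  dm4 <- structure(list(ids = ids4, d = d4,
                        shared_sites = matrix(10L, 4, 4, dimnames = list(ids4, ids4))),
                   class = "p_distance_matrix")
  t1 <- nj_tree(dm4); t2 <- nj_tree(dm4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_error(
    nj_tree(structure(list(ids = ids4, d = {
      dna <- d4; dna[1, 2] <- dna[2, 1] <- NA; dna
    }, shared_sites = dm4$shared_sites), class = "p_distance_matrix")),
    "NA"
  )
})

test_that("clamped branch lengths stay non-negative", {
  set.seed(92)
  for (case in 1:20) {
    aln <- random_alignment(n = 8, L = 60, gap_p = 0.02)
    dm <- p_distance_matrix(aln)
    if (any(is.na(dm$d[upper.tri(dm$d)]))) next
    tr <- nj_tree(dm)
    expect_true(all(tr$edge.length >= 0))
    expect_identical(sort(tr$tip.label), sort(dm$ids))
  }
})

test_that("monophyly agrees with brute-force edge removal on random trees", {
  set.seed(93)
  for (case in 1:100) {
    tr <- ape::unroot(ape::rtree(12))
    tr$tip.label <- sprintf("sp%02d_%d", sample(rep(1:4, 3)), 1:12)
    map <- map_from_ids(tr$tip.label)
    got <- monophyly(tr, map)
    for (s in got$species) {
      tips <- tr$tip.label[startsWith(tr$tip.label, paste0(s, "_"))]
      expect_identical(
        got$monophyletic[got$species == s],
        oracle_monophyletic(tr, tips)
      )
    }
  }
})

test_that("textbook monophyly cases behave", {
  t1 <- ape::read.tree(text = "((a_1:1,a_2:1):1,(b_1:1,b_2:1):1);")
  m1 <- monophyly(t1, map_from_ids(t1$tip.label))
  expect_true(all(m1$monophyletic))
  t2 <- ape::read.tree(text = "((a_1:1,b_1:1):1,(a_2:1,b_2:1):1);")
  m2 <- monophyly(t2, map_from_ids(t2$tip.label))
  expect_false(any(m2$monophyletic))
  s <- score_tree(t2, map_from_ids(t2$tip.label))
  expect_equal(s$rate, 0)
  expect_identical(s$n_eligible, 2L)
})

test_that("tree scoring excludes singletons and reports them", {
  tr <- ape::read.tree(text = "((a_1:1,a_2:1):1,(b_1:1,c_1:1):1);")
  s <- score_tree(tr, map_from_ids(tr$tip.label))
  expect_identical(s$n_eligible, 1L)
  expect_identical(s$identified_species, "a")
  expect_identical(s$singleton_species, c("b", "c"))
  expect_equal(s$rate, 100)
})

test_that("bootstrap supports are high across a strong split, low on noise, reproducible", {
  set.seed(94)
  # two clusters separated by 50 fixed differences
  base <- sample(c("A", "C", "G", "T"), 300, TRUE)
  other <- base
  flip <- sample(300, 50)
  other[flip] <- vapply(base[flip], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                        character(1))
  mutate_few <- function(x) {
    i <- sample(300, 2)
    x[i] <- vapply(x[i], function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1))
    x
  }
  m <- rbind(
    g1_1 = base, g1_2 = mutate_few(base), g1_3 = mutate_few(base),
    g2_1 = other, g2_2 = mutate_few(other), g2_3 = mutate_few(other)
  )
  aln <- marker_alignment(m, marker_id = "m")
  tree <- bootstrap_support(aln, n_boot = 200, seed = 5)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup <- sup[!is.na(sup)]
  expect_gte(max(sup), 99)
  # determinism
  tree2 <- bootstrap_support(aln, n_boot = 200, seed = 5)
  expect_identical(tree$node.label, tree2$node.label)
  expect_identical(ape::write.tree(tree), ape::write.tree(tree2))

  # pure noise: median internal support < 50
  noise <- random_alignment(n = 10, L = 100)
  tn <- bootstrap_support(noise, n_boot = 100, seed = 6)
  sn <- suppressWarnings(as.numeric(tn$node.label))
  sn <- sn[!is.na(sn)]
  expect_lt(stats::median(sn), 50)
})
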