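test_that("p-distance matrix matches the per-column brute force", {
  set.seed(61)
  for (case in 1:100) {
    aln <- random_alignment(
      n = sample(3:6, 1), L = sample(15:50, 1),
      gap_p = 0.08, amb_p = 0.04
    )
    got <- p_distance_matrix(aln)
    exp <- oracle_pdist(aln)
    expect_equal(got$d, exp$d)
    expect_equal(unname(got$shared_sites - diag(diag(got$shared_sites))),
                 unname(exp$shared))
    expect_true(all(diag(got$d) == 0))
    expect_equal(got$d, t(got$d))
  }
})

test_that("hand examples: gap exclusion and NA on empty overlap", {
  aln <- marker_alignment(c(a = "ACGT", b = "ACGA"), marker_id = "m")
  expect_equal(p_distance_matrix(aln)$d["a", "b"], 0.25)
  aln2 <- marker_alignment(c(a = "AC-T", b = "ACGT"), marker_id = "m")
  got <- p_distance_matrix(aln2)
  expect_equal(got$d["a", "b"], 0)
  expect_identical(got$shared_sites["a", "b"], 3L)
  aln3 <- marker_alignment(c(a = "AC--", b = "--GT"), marker_id = "m")
  expect_true(is.na(p_distance_matrix(aln3)$d["a", "b"]))
})

test_that("maximum intraspecific divergence and its bootstrap SE behave", {
  sim <- simulate_dataset(preset_config("clean", seed = 6,
                                        n_species = 4L, n_individuals = 4L))
  aln <- concatenate_markers(sim$alignments)
  dm <- p_distance_matrix(aln)
  res <- max_intraspecific(dm, sim$map, aln, n_boot = 200, seed = 2)
  mask <- barcodeval:::conspecific_mask(dm$ids, sim$map)
  expect_equal(res$d_intra_max, max(dm$d[mask]))
  expect_gt(res$se, 0)
  # identical sequences give (0, 0)
  same <- marker_alignment(stats::setNames(rep(strrep("ACGT", 10), 4), paste0("s1_", 1:4)),
                           marker_id = "m")
  dm0 <- p_distance_matrix(same)
  r0 <- max_intraspecific(dm0, map_from_ids(alignment_ids(same)), same,
                          n_boot = 50, seed = 1)
  expect_equal(r0$d_intra_max, 0)
  expect_equal(r0$se, 0)
  # determinism under a fixed seed
  r1 <- max_intraspecific(dm, sim$map, aln, n_boot = 100, seed = 7)
  r2 <- max_intraspecific(dm, sim$map, aln, n_boot = 100, seed = 7)
  expect_identical(r1$se, r2$se)
})

test_that("barcode gap is found between well-separated clusters and not in a smear", {
  sim <- simulate_dataset(preset_config("clean", seed = 7))
  aln <- concatenate_markers(sim$alignments)
  dm <- p_distance_matrix(aln)
  gap <- barcode_gap_assess(dm, sim$map)
  expect_true(gap$gap_found)
  expect_gte(gap$gap_interval[1], gap$d_intra_max - 1e-12)
  expect_lt(gap$gap_interval[1], gap$gap_interval[2])

  # uniformly spread distances: no jump exceeds twice the median step
  n <- 10
  ids <- paste0("sp", sprintf("%02d", 1:n), "_1")
  ids[2] <- "sp01_2" # one conspecific pair so d_intra_max exists
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- seq(0.01, 0.01 + 0.001 * (choose(n, 2) - 1), by = 0.001)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  dm2 <- structure(list(ids = ids, d = d,
                        shared_sites = matrix(100L, n, n, dimnames = list(ids, ids))),
                   class = "p_distance_matrix")
  gap2 <- barcode_gap_assess(dm2, map_from_ids(ids))
  expect_false(gap2$gap_found)
})

test_that("single-linkage partitioning is monotone in the threshold", {
  set.seed(62)
  sim <- simulate_dataset(preset_config("clean", seed = 8,
                                        n_species = 5L, n_individuals = 4L))
  dm <- p_distance_matrix(concatenate_markers(sim$alignments))
  singletons <- single_linkage_components(dm, -1)
  expect_identical(length(singletons), length(dm$ids))
  everyone <- single_linkage_components(dm, 1)
  expect_identical(length(everyone), 1L)
  thr <- sort(unique(dm$d[upper.tri(dm$d)]))
  sizes <- vapply(thr, function(t) length(single_linkage_components(dm, t)), integer(1))
  expect_true(all(diff(sizes) <= 0)) # coarsens as the threshold grows
})

test_that("ABGD partition delimits planted clusters and respects the prior", {
  sim <- simulate_dataset(preset_config("clean", seed = 9,
                                        n_species = 3L, n_individuals = 5L))
  dm <- p_distance_matrix(concatenate_markers(sim$alignments))
  part <- abgd_partition(dm, prior_P = 0.02, map = sim$map)
  expect_identical(length(part$groups), 3L)
  expect_identical(length(part$delimited_species), 3L)
  expect_error(abgd_partition(dm, prior_P = 0), "positive")

  # all distances below the prior: one group, nothing delimited
  ids <- c("a_1", "a_2", "b_1", "b_2")
  d <- matrix(0.001, 4, 4, dimnames = list(ids, ids)); diag(d) <- 0
  dm2 <- structure(list(ids = ids, d = d,
                        shared_sites = matrix(10L, 4, 4, dimnames = list(ids, ids))),
                   class = "p_distance_matrix")
  p2 <- abgd_partition(dm2, prior_P = 0.05, map = species_map(ids, sub("_.*", "", ids)))
  expect_identical(length(p2$groups), 1L)
  expect_identical(length(p2$delimited_species), 0L)

  # an over-split species (two distant haplotype clusters) is not delimited
  ids3 <- c("a_1", "a_2", "a_3", "a_4", "b_1", "b_2")
  d3 <- matrix(0.30, 6, 6, dimnames = list(ids3, ids3))
  d3[1:2, 1:2] <- 0.001; d3[3:4, 3:4] <- 0.001; d3[5:6, 5:6] <- 0.001
  diag(d3) <- 0
  dm3 <- structure(list(ids = ids3, d = d3,
                        shared_sites = matrix(10L, 6, 6, dimnames = list(ids3, ids3))),
                   class = "p_distance_matrix")
  p3 <- abgd_partition(dm3, prior_P = 0.01, map = species_map(ids3, sub("_.*", "", ids3)))
  expect_identical(length(p3$groups), 3L)
  expect_identical(p3$delimited_species, "b")
})

test_that("divergence tests separate shifted distributions and keep level under the null", {
  # strong separation
  res <- divergence_tests(rep(0, 30), rep(0.5, 30))
  expect_lt(res$t_p, 1e-6)
  expect_lt(res$w_p, 1e-6)
  # power at a one-sd shift with n = 50 per group
  set.seed(63)
  hits <- sum(vapply(1:200, function(i) {
    divergence_tests(rnorm(50), rnorm(50, 1))$t_p < 0.05
  }, logical(1)))
  expect_gt(hits / 200, 0.99)
})

test_that("intra/inter tests extract the right pairs and support both modes", {
  sim <- simulate_dataset(preset_config("clean", seed = 10,
                                        n_species = 4L, n_individuals = 4L))
  dm <- p_distance_matrix(concatenate_markers(sim$alignments))
  pooled <- intra_inter_tests(dm, sim$map, mode = "pooled")
  expect_equal(pooled$n_intra, 4 * choose(4, 2))
  expect_equal(pooled$n_inter, choose(16, 2) - 4 * choose(4, 2))
  # clean data: inter far above intra, so both tests reject decisively
  expect_lt(pooled$t_p, 1e-6)
  per_sp <- intra_inter_tests(dm, sim$map, mode = "per_species")
  expect_identical(per_sp$n_intra, 4L)
  expect_identical(per_sp$n_inter, 4L)
  # grouping without values errors cleanly
  expect_error(intra_inter_tests(dm, sim$map, grouping = "section"), "section")
})
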