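test_that("trivial linkage cases collapse or stay apart for any fraction", {
  m <- random_dist_matrix(6, seed = 1)
  for (f in c(0, 0.5, 1)) {
    expect_length(fraction_linkage_cluster(m, threshold = 1.01, fraction = f), 1L)
    expect_length(fraction_linkage_cluster(m, threshold = -1, fraction = f), 6L)
  }
})

test_that("F = 0 equals single linkage and F = 1 has the complete-linkage property", {
  for (k in 1:50) {
    n <- sample(5:15, 1)
    m <- random_dist_matrix(n, seed = 1000 + k)
    th <- stats::runif(1, 0.2, 0.6)

    got0 <- fraction_linkage_cluster(m, th, fraction = 0)
    oracle <- components_oracle(m, th)
    expect_identical(got0[order(vapply(got0, min, character(1)))],
                     oracle[order(vapply(oracle, min, character(1)))])

    got1 <- fraction_linkage_cluster(m, th, fraction = 1)
    for (cl in got1) {
      if (length(cl) >= 2)
        expect_true(all(unclass(m)[cl, cl][upper.tri(diag(length(cl)))] <= th))
    }
  }
})

test_that("clusters always partition the strains, monotonically in T and F", {
  for (k in 1:10) {
    m <- random_dist_matrix(10, seed = 2000 + k)
    ths <- c(0.2, 0.4, 0.6, 0.8)
    sizes <- vapply(ths, function(th)
      length(fraction_linkage_cluster(m, th, 0.5)), integer(1))
    expect_true(all(diff(sizes) <= 0))  # more linking, fewer clusters
    for (th in ths) {
      cl0 <- fraction_linkage_cluster(m, th, 0)
      cl1 <- fraction_linkage_cluster(m, th, 1)
      expect_gte(length(cl1), length(cl0))
      expect_setequal(unlist(cl1), rownames(m))
      expect_identical(anyDuplicated(unlist(cl1)), 0L)
    }
    # determinism
    expect_identical(fraction_linkage_cluster(m, 0.4, 0.5),
                     fraction_linkage_cluster(m, 0.4, 0.5))
  }
})

test_that("type-radius affiliation flags ambiguities and novel candidates", {
  labs <- c("T1", "T2", "s1", "s2", "s3")
  m <- matrix(0, 5, 5, dimnames = list(labs, labs))
  m["T1", "s1"] <- m["s1", "T1"] <- 75
  m["T1", "s2"] <- m["s2", "T1"] <- 72
  m["T2", "s2"] <- m["s2", "T2"] <- 71
  diag(m) <- 100
  lm <- labeled_matrix(m, "dDDH")
  aff <- type_radius_affiliate(lm, c(T1 = 70, T2 = 70))
  expect_identical(aff$affiliation$s1, "T1")
  expect_setequal(aff$affiliation$s2, c("T1", "T2"))
  expect_identical(aff$ambiguities$strain, "s2")
  expect_identical(aff$novel_candidates, "s3")
  expect_error(type_radius_affiliate(lm, c(TX = 70)), "unknown type")

  # all off-type similarities zero: everyone novel, no ambiguities
  m0 <- matrix(0, 5, 5, dimnames = list(labs, labs)); diag(m0) <- 100
  aff0 <- type_radius_affiliate(labeled_matrix(m0, "dDDH"), c(T1 = 70, T2 = 70))
  expect_setequal(aff0$novel_candidates, c("s1", "s2", "s3"))
  expect_identical(nrow(aff0$ambiguities), 0L)
})

test_that("species delineation recovers the planted partition without conflicts", {
  sim <- small_complex()
  m <- small_anib()
  part <- delineate_species(m, sim$metadata, threshold = 96, fraction = 0.5)
  expect_s3_class(part, "species_partition")
  expect_setequal(unlist(part$clusters), names(sim$genomes))
  expect_identical(anyDuplicated(unlist(part$clusters)), 0L)
  cmp <- compare_partitions(part, sim$truth$species_of)
  expect_true(cmp$exact_match)
  expect_equal(cmp$adjusted_rand, 1)
  expect_identical(nrow(part$ambiguities), 0L)
  # novel clusters are exactly the species without described types
  n_described <- sum(sim$metadata$is_type)
  expect_identical(sum(part$novel), length(part$clusters) - n_described)
  expect_length(part$putative_types, sum(part$novel))
  # a putative type's radius captures its whole cluster
  for (i in which(part$novel)) {
    pt <- part$types[[i]]
    cl <- part$clusters[[i]]
    expect_true(all(unclass(m)[pt, cl] >= 96))
  }
})

test_that("subspecies delineation refines the species partition", {
  sim <- small_complex()
  m <- small_anib()
  part <- delineate_species(m, sim$metadata, threshold = 96)
  cut <- equivalent_cutoff(sim$truth, "subspecies")
  sub <- delineate_subspecies(m, part, cutoff = cut)
  expect_s3_class(sub, "subspecies_partition")
  cmp <- compare_partitions(sub, sim$truth$subspecies_of)
  expect_true(cmp$exact_match)
  # refinement: every sub-cluster is inside one species cluster
  species_of <- partition_membership(part)
  for (cl in sub$clusters)
    expect_length(unique(species_of[cl]), 1L)
  # a species whose strains are all within the cutoff stays undivided
  tight <- labeled_matrix(
    matrix(c(100, 99, 99, 100), 2, dimnames = list(c("a", "b"), c("a", "b"))),
    "dDDH")
  sub2 <- delineate_subspecies(tight, list(g1 = c("a", "b")), cutoff = 79)
  expect_length(sub2$by_species$g1, 1L)
  expect_identical(sub2$nontrivial_count, 0L)
})

test_that("threshold sweep counts clusters and ambiguities per threshold", {
  labs <- c("a", "b")
  m <- matrix(c(100, 95, 95, 100), 2, dimnames = list(labs, labs))
  lm <- labeled_matrix(m, "ANIb")
  sw <- threshold_sweep(lm, NULL, thresholds = c(94, 96))
  expect_identical(sw$n_clusters, c(1L, 2L))
  expect_error(threshold_sweep(lm, NULL, thresholds = numeric()), "threshold")

  sim <- small_complex()
  sw2 <- threshold_sweep(small_anib(), sim$metadata, thresholds = c(94, 96),
                         reference = sim$truth$species_of)
  expect_true(sw2$exact_match[sw2$threshold == 96])
})

test_that("partition comparison matches a pair-counting oracle", {
  a <- c(x1 = "A", x2 = "A", x3 = "B", x4 = "B")
  expect_equal(compare_partitions(a, a)$adjusted_rand, 1)
  expect_true(compare_partitions(a, a)$exact_match)

  singletons <- stats::setNames(letters[1:4], names(a))
  lump <- stats::setNames(rep("z", 4), names(a))
  expect_equal(compare_partitions(singletons, lump)$adjusted_rand, 0)

  # random partitions vs brute-force pair confusion ARI
  set.seed(77)
  for (k in 1:5) {
    n <- 12
    ids <- sprintf("s%02d", 1:n)
    pa <- stats::setNames(sample(letters[1:4], n, replace = TRUE), ids)
    pb <- stats::setNames(sample(letters[1:3], n, replace = TRUE), ids)
    got <- compare_partitions(pa, pb)$adjusted_rand
    # oracle: count agreeing/disagreeing pairs
    same_a <- outer(pa, pa, "==")[upper.tri(diag(n))]
    same_b <- outer(pb, pb, "==")[upper.tri(diag(n))]
    n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
    n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
    ri_exp <- ((n11 + n10) * (n11 + n01) + (n00 + n10) * (n00 + n01)) /
      choose(n, 2)
    ari_oracle <- (n11 + n00 - ri_exp) / (choose(n, 2) - ri_exp)
    expect_equal(got, ari_oracle, tolerance = 1e-12)
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(got, mclust::adjustedRandIndex(pa, pb), tolerance = 1e-12)
  }
  expect_error(compare_partitions(a, singletons[1:3]), "different strain sets")
})
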