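test_that("tetranucleotide counts match a sliding-window oracle", {
  set.seed(21)
  s <- random_genome(1000, gc = 0.55)
  prof <- tetra_profile(s)
  expect_length(prof$z, 256)
  expect_identical(names(prof$z)[1], "AAAA")
  expect_identical(names(prof$z)[256], "TTTT")
  expect_true(all(is.finite(prof$z)))

  # independent oracle: count every window of s and its reverse complement
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  oracle <- table(factor(
    c(substring(s, 1:997, 4:1000), substring(rc, 1:997, 4:1000)),
    levels = names(prof$z)))
  expect_equal(prof$n_tetramers, as.numeric(sum(oracle)))

  # recompute z from oracle counts through the Markov expectation
  n3 <- table(factor(c(substring(s, 1:998, 3:1000),
                       substring(rc, 1:998, 3:1000)),
                     levels = tetra_words_oracle(3)))
  n2 <- table(factor(c(substring(s, 1:999, 2:1000),
                       substring(rc, 1:999, 2:1000)),
                     levels = tetra_words_oracle(2)))
  w <- names(prof$z)
  E <- as.numeric(n3[substr(w, 1, 3)]) * as.numeric(n3[substr(w, 2, 4)]) /
    as.numeric(n2[substr(w, 2, 3)])
  v <- E * (as.numeric(n2[substr(w, 2, 3)]) - as.numeric(n3[substr(w, 1, 3)])) *
    (as.numeric(n2[substr(w, 2, 3)]) - as.numeric(n3[substr(w, 2, 4)])) /
    as.numeric(n2[substr(w, 2, 3)])^2
  z <- ifelse(v > 0, (as.numeric(oracle) - E) / sqrt(v), 0)
  expect_equal(unname(prof$z), z, tolerance = 1e-12)
})

test_that("tetra profile is strand-symmetric and handles degenerate input", {
  set.seed(22)
  s <- random_genome(2000)
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  expect_equal(tetra_profile(s)$z, tetra_profile(rc)$z)

  polyA <- tetra_profile(strrep("A", 500))
  expect_true(all(is.finite(polyA$z)))
  expect_error(tetra_profile("ACG"), "shorter than 4")
  flat <- structure(list(genome_id = "flat",
                         z = stats::setNames(rep(0, 256), names(polyA$z)),
                         n_tetramers = 0),
                    class = "tetra_profile")
  expect_error(tetra_correlation(flat, flat), "zero-variance")
})

test_that("tetra correlation separates related from unrelated genomes", {
  # composition is stable under point mutation at full genome size (200 kb):
  # a within-species pair stays above the strict 0.999 screen
  sim <- fixture("tetra_pair", function() simulate_species_complex(
    simulation_config(n_species = 1, cluster_sizes = 2, genome_length = 200000,
                      n_contigs = 1, n_described = 0, seed = 301)))
  prof <- lapply(sim$genomes, tetra_profile)
  expect_equal(tetra_correlation(prof[[1]], prof[[1]]), 1.0)
  expect_gt(tetra_correlation(prof[[1]], prof[[2]]), 0.999)  # band 0.03 pair

  set.seed(30)
  r1 <- tetra_profile(random_genome(200000, 0.63))
  r2 <- tetra_profile(random_genome(200000, 0.63))
  expect_lt(tetra_correlation(r1, r2), 0.99)  # independent genomes
})

test_that("fragmentation keeps terminal fragments >= 100 bp", {
  g <- c(strrep("ACGT", 300), strrep("A", 1150))  # 1200 + 1150 bp contigs
  fr <- fragment_genome(g, fragment_len = 1020L)
  expect_identical(unname(nchar(fr)), c(1020L, 180L, 1020L, 130L))
  fr2 <- fragment_genome(strrep("ACGT", 256), fragment_len = 1020L)
  expect_identical(unname(nchar(fr2)), 1020L)  # 4 bp tail dropped
})

test_that("fragment-ANI self-comparison is exact and mutation lands on target", {
  sim <- small_complex()
  g <- sim$genomes[[1]]
  self <- anib(g, g)
  expect_equal(self$ani, 100.0)
  expect_gt(self$aligned_fraction, 0.97)
  expect_equal(self$n_fragments_retained, self$n_fragments_total)

  whole <- paste(g, collapse = "")
  mut <- mutate_sequence(whole, 0.02, seed = 77)
  res <- anib(whole, mut)
  expect_gte(res$ani, 97.5)
  expect_lte(res$ani, 98.5)

  set.seed(31)
  other <- random_genome(30000, gc = 0.63)
  expect_error(anib(substr(whole, 1, 30000), other), "no-homology")
})

test_that("the all-vs-all ANI matrix agrees with per-pair calls", {
  sim <- small_complex()
  m <- small_anib()
  expect_s3_class(m, "labeled_matrix")
  expect_identical(rownames(m), names(sim$genomes))
  expect_equal(unclass(m), t(unclass(m)))
  p <- band_pairs()
  direct <- (anib(sim$genomes[[p$anchor]], sim$genomes[[p$other_sub]])$ani +
             anib(sim$genomes[[p$other_sub]], sim$genomes[[p$anchor]])$ani) / 2
  expect_lt(abs(m[p$anchor, p$other_sub] - direct), 0.3)
})

test_that("approximate alignment ANI tracks fragment ANI within a point", {
  sim <- small_complex()
  p <- band_pairs()
  g <- sim$genomes
  am <- anim_approx(g[[p$anchor]], g[[p$other_sub]])
  expect_true(am$approximate)
  expect_lt(abs(am$ani - small_anib()[p$anchor, p$other_sub]), 1.0)
  self <- anim_approx(g[[1]], g[[1]])
  expect_equal(self$ani, 100.0)

  set.seed(33)
  expect_error(anim_approx(random_genome(20000), random_genome(20000)),
               "no-homology")
})

test_that("genome-BLAST distance is zero on self and monotone across bands", {
  sim <- small_complex()
  p <- band_pairs()
  g <- sim$genomes
  self <- gbdp_distance(g[[1]], g[[1]], seed = 4)
  expect_equal(self$d, 0)
  expect_equal(self$ddh_like, 100)
  expect_length(self$replicate_d, 100)

  ds <- vapply(c(p$same_sub, p$other_sub, p$other_sp), function(id)
    gbdp_distance(g[[p$anchor]], g[[id]], seed = 4)$d, numeric(1))
  expect_true(all(diff(ds) > 0))  # 0.005 -> 0.03 -> 0.10 planted bands

  r1 <- gbdp_distance(g[[p$anchor]], g[[p$other_sub]], seed = 9)
  r2 <- gbdp_distance(g[[p$anchor]], g[[p$other_sub]], seed = 9)
  expect_identical(r1$replicate_d, r2$replicate_d)  # seeded bootstrap

  expect_warning(
    out <- genospec:::gbdp_from_hsps(empty_hits_frame(), a_id = "x", b_id = "y"),
    "no HSPs")
  expect_equal(out$d, 1)
})

test_that("trimming never double-counts query positions", {
  # two overlapping synthetic HSPs: the weaker one is truncated
  hits <- empty_hits_frame()
  hits[1, ] <- list("q", "s", 100, 1000, 1000, 1, 1000, 1, 1000, 2000, 5000)
  hits[2, ] <- list("q", "s", 90, 1000, 900, 501, 1500, 2001, 3000, 1500, 5000)
  res <- genospec:::gbdp_from_hsps(hits, n_replicates = 10, seed = 1)
  # overlap 500 of the weaker HSP removed: lengths 1000 + 500, idents 1000 + 450
  expect_equal(res$d, 1 - (1000 + 450) / (1000 + 500))
  res_untrimmed <- genospec:::gbdp_from_hsps(hits, trimming = FALSE,
                                  n_replicates = 10, seed = 1)
  expect_equal(res_untrimmed$d, 1 - 1900 / 2000)
})
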