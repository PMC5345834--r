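block2 <- function(a, b, locus = "gyrB")
  alignment_block(c(s1 = a, s2 = b), locus)

test_that("pairwise identity follows the gap policy", {
  expect_equal(pairwise_identity(block2("ACGT", "ACGA"))["s1", "s2"], 75)
  g <- block2("AC-T", "ACGT")
  expect_equal(pairwise_identity(g, "gaps-are-differences")["s1", "s2"], 75)
  expect_equal(pairwise_identity(g, "exclude-pairwise")["s1", "s2"], 100)
  # shared all-gap columns dropped under the default policy
  both <- block2("AC--", "AC-T")
  expect_equal(pairwise_identity(both)["s1", "s2"], 100 * 2 / 3)
})

test_that("identity matrix equals a brute-force column counter and is symmetric", {
  set.seed(5)
  n <- 10; len <- 500
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T", "-"), len, replace = TRUE,
                 prob = c(0.23, 0.23, 0.23, 0.23, 0.08)), collapse = ""),
    character(1))
  names(seqs) <- sprintf("t%02d", seq_len(n))
  blk <- alignment_block(seqs, "MLSA")
  m <- pairwise_identity(blk)
  chars <- strsplit(seqs, "")
  for (i in 1:3) for (j in (i + 1):4) {   # spot-check a subset of pairs
    a <- chars[[i]]; b <- chars[[j]]
    keep <- !(a == "-" & b == "-")
    expect_equal(m[i, j], 100 * sum(a[keep] == b[keep]) / sum(keep))
  }
  expect_equal(unclass(m), t(unclass(m)))
  expect_true(all(diag(unclass(m)) == 100))
})

test_that("K2P distance matches the closed form and a per-site oracle", {
  same <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(same$P, 0); expect_equal(same$Q, 0); expect_equal(same$d, 0)

  # constructed pair with exactly P = 0.1 (transitions) and Q = 0.05:
  # 100 sites, 10 A->G, 5 A->C
  a <- strsplit(strrep("A", 100), "")[[1]]
  b <- a
  b[1:10] <- "G"; b[11:15] <- "C"
  est <- k2p_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(est$P, 0.1)
  expect_equal(est$Q, 0.05)
  expect_equal(est$d, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_lt(abs(est$d - 0.17018), 1e-4)

  # random pair: P, Q match independent per-site classification
  set.seed(11)
  x <- sample(c("A", "C", "G", "T"), 100, replace = TRUE)
  y <- x; flip <- sample(100, 20)
  y[flip] <- sample(c("A", "C", "G", "T"), 20, replace = TRUE)
  sx <- paste(x, collapse = ""); sy <- paste(y, collapse = "")
  est2 <- k2p_distance(sx, sy)
  purine <- c("A", "G")
  diffs <- x != y
  ti <- sum(diffs & ((x %in% purine) == (y %in% purine)))
  tv <- sum(diffs) - ti
  expect_equal(est2$P, ti / 100)
  expect_equal(est2$Q, tv / 100)

  # gaps and N excluded from comparable sites
  est3 <- k2p_distance("ACGTN-", "ACGAAC")
  expect_equal(est3$n_sites, 4L)

  expect_error(k2p_distance(strrep("A", 10), strrep("G", 10)), "saturated")
  expect_error(k2p_distance("----", "AAAA"), "zero comparable")
})

test_that("K2P agrees with an established implementation and bounds p-distance", {
  set.seed(3)
  x <- sample(c("A", "C", "G", "T"), 2000, replace = TRUE)
  y <- x
  flip <- sample(2000, 300)
  y[flip] <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  sx <- paste(x, collapse = ""); sy <- paste(y, collapse = "")
  est <- k2p_distance(sx, sy)
  bin <- ape::as.DNAbin(list(a = tolower(x), b = tolower(y)))
  ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(est$d, ref, tolerance = 1e-12)
  p <- mean(x != y)
  expect_gte(est$d, p)  # multiple-hit correction can only inflate
})

test_that("alignment statistics count polymorphic columns and G+C", {
  flat <- block2("ACGT", "ACGT")
  s <- alignment_stats(flat)
  expect_equal(s$pct_polymorphic, 0)
  expect_equal(s$mean_d, 0)
  expect_equal(s$mean_gc, 50)

  poly <- block2("ACGT", "ACGA")
  expect_equal(alignment_stats(poly)$pct_polymorphic, 25)

  # N is not a state: A/N column is not polymorphic
  amb <- block2("ANGT", "AAGT")
  expect_equal(alignment_stats(amb)$pct_polymorphic, 0)
})

test_that("locus concatenation uses the canonical order and validates strains", {
  b1 <- alignment_block(c(x = "AAA", y = "CCC"), "atpD")
  b2 <- alignment_block(c(x = "GGGG", y = "TTTT"), "clpA")
  cat1 <- concatenate_loci(list(b1, b2))
  expect_identical(cat1$locus, "MLSA")
  expect_identical(unname(nchar(cat1$seqs)), c(7L, 7L))
  expect_identical(unname(cat1$seqs["x"]), "GGGGAAA")  # clpA before atpD

  cat2 <- concatenate_loci(list(b2, b1))  # order of supply irrelevant
  expect_identical(cat1$seqs, cat2$seqs)

  b3 <- alignment_block(c(x = "AA", z = "CC"), "gyrB")
  expect_error(concatenate_loci(list(b1, b3)), "y.*gyrB|gyrB.*y")
})

test_that("concatenating the Table-1-length loci yields the 12,283 bp alignment", {
  lens <- default_locus_lengths()
  hk <- setdiff(names(lens), "16S")
  set.seed(2)
  blocks <- lapply(hk, function(locus) {
    s <- paste(sample(c("A", "C", "G", "T"), lens[[locus]], replace = TRUE),
               collapse = "")
    alignment_block(c(u = s, v = s), locus)
  })
  mlsa <- concatenate_loci(blocks)
  expect_identical(unique(unname(nchar(mlsa$seqs))), 12283L)
})

test_that("concatenated identity equals the length-weighted identity of loci", {
  set.seed(8)
  mk <- function(locus, len) {
    base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    alt <- base
    flip <- sample(len, round(len * 0.1))
    alt[flip] <- sample(c("A", "C", "G", "T"), length(flip), replace = TRUE)
    alignment_block(c(p = paste(base, collapse = ""),
                      q = paste(alt, collapse = "")), locus)
  }
  blocks <- list(mk("clpA", 300), mk("atpD", 200), mk("gyrB", 500))
  cat_id <- pairwise_identity(concatenate_loci(blocks))["p", "q"]
  per <- vapply(blocks, function(b) pairwise_identity(b)["p", "q"], numeric(1))
  lens <- vapply(blocks, function(b) nchar(b$seqs[[1]]), numeric(1))
  expect_equal(cat_id, sum(per * lens) / sum(lens))
})

test_that("species and genus screens apply the published bounds", {
  expect_identical(mlsa_species_screen(99.0)$verdict, "same-species")
  expect_identical(mlsa_species_screen(97.5)$verdict, "different-species")
  expect_identical(mlsa_species_screen(98.0)$verdict, "grey-zone")
  expect_error(mlsa_species_screen(101), "out of")

  labs <- c("a1", "a2", "b1", "b2")
  m <- matrix(100, 4, 4, dimnames = list(labs, labs))
  m[c("a1", "a2"), c("b1", "b2")] <- 90
  m[c("b1", "b2"), c("a1", "a2")] <- 90
  r <- genus_boundary_screen(labeled_matrix(m, "16S-identity"),
                             c("a1", "a2"), c("b1", "b2"))
  expect_identical(r$verdict, "separate-genera-supported")
  expect_equal(r$mean, 90)

  m2 <- matrix(100, 4, 4, dimnames = list(labs, labs))
  r2 <- genus_boundary_screen(labeled_matrix(m2, "16S-identity"),
                              c("a1", "a2"), c("b1", "b2"))
  expect_identical(r2$verdict, "same-genus-supported")

  expect_error(genus_boundary_screen(labeled_matrix(m2, "16S-identity"),
                                     c("a1"), c("a1", "b1")), "overlap")
})
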