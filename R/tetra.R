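tetra_words <- function(k) {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(rep(list(b), k), stringsAsFactors = FALSE)
  # lexicographic order: first position is the slowest-varying index
  apply(g[do.call(order, g), , drop = FALSE], 1L, paste, collapse = "")
}

count_words <- function(seqs, k) {
  words <- tetra_words(k)
  counts <- stats::setNames(numeric(length(words)), words)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    w <- substring(s, 1:(n - k + 1L), k:n)
    w <- w[!grepl("[^ACGT]", w)]
    if (!length(w)) next
    tb <- table(w)
    counts[names(tb)] <- counts[names(tb)] + as.numeric(tb)
  }
  counts
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                       collapse = ""), character(1L),
                USE.NAMES = FALSE))
}

#' Tetranucleotide z-score profile of a genome
#'
#' Counts all overlapping tetranucleotides on both strands of every contig
#' (windows containing N are skipped) and converts them to z-scores against
#' the maximal-order Markov expectation
#' `E(n1n2n3n4) = N(n1n2n3) * N(n2n3n4) / N(n2n3)`, with the approximate
#' variance `E * (N(n2n3) - N(n1n2n3)) * (N(n2n3) - N(n2n3n4)) / N(n2n3)^2`.
#' Cells with zero variance get z = 0. Profiles of a genome and its reverse
#' complement are identical by construction.
#'
#' @param genome character vector of contig sequences (a single string is
#'   accepted), or the named list element produced by
#'   [simulate_species_complex()].
#' @param genome_id label stored in the profile.
#' @return object of class `tetra_profile`: list with `genome_id`, `z`
#'   (256 values named by tetramer, lexicographic AAAA..TTTT) and
#'   `n_tetramers`.
#' @export
tetra_profile <- function(genome, genome_id = "genome") {
  seqs <- unlist(genome, use.names = FALSE)
  if (sum(nchar(seqs)) < 4L) stop("genome shorter than 4 bp")
  both <- c(seqs, revcomp(seqs))
  n4 <- count_words(both, 4L)
  n3 <- count_words(both, 3L)
  n2 <- count_words(both, 2L)
  w4 <- names(n4)
  pre <- substr(w4, 1L, 3L)
  suf <- substr(w4, 2L, 4L)
  mid <- substr(w4, 2L, 3L)
  N123 <- n3[pre]; N234 <- n3[suf]; N23 <- n2[mid]
  E <- ifelse(N23 > 0, N123 * N234 / N23, 0)
  v <- ifelse(N23 > 0, E * (N23 - N123) * (N23 - N234) / N23^2, 0)
  z <- ifelse(v > 0, (n4 - E) / sqrt(v), 0)
  structure(list(genome_id = genome_id, z = stats::setNames(z, w4),
                 n_tetramers = sum(n4)),
            class = "tetra_profile")
}

#' Correlation between two tetranucleotide profiles
#'
#' Pearson correlation over the 256 z-scores; the alignment-free genome
#' similarity signal. Published species thresholds are 0.989 (permissive)
#' and 0.999 (strict).
#'
#' @param a,b [tetra_profile()] objects.
#' @return correlation in \[-1, 1\].
#' @export
tetra_correlation <- function(a, b) {
  stopifnot(inherits(a, "tetra_profile"), inherits(b, "tetra_profile"))
  if (stats::sd(a$z) == 0 || stats::sd(b$z) == 0)
    stop("zero-variance tetranucleotide profile")
  stats::cor(a$z, b$z)
}

#' Pairwise TETRA correlation matrix of a genome set
#'
#' @param genomes named list of genomes (character vectors of contigs).
#' @return a [labeled_matrix()] of kind `"TETRA"`.
#' @export
tetra_matrix <- function(genomes) {
  ids <- names(genomes)
  profs <- lapply(ids, function(id) tetra_profile(genomes[[id]], id))
  names(profs) <- ids
  n <- length(ids)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- tetra_correlation(profs[[i]], profs[[j]])
    m[i, j] <- r; m[j, i] <- r
  }
  labeled_matrix(m, kind = "TETRA", symmetrize = FALSE)
}
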