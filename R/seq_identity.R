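#' Pairwise sequence identity matrix of an alignment
#'
#' Identity is the percentage of compared alignment columns at which two
#' sequences agree. Under the default `"gaps-are-differences"` policy (the
#' number-of-differences convention used for the multilocus screen) every
#' column where the two sequences differ — including gap-vs-base — counts as
#' a difference; columns gapped in *both* sequences are dropped. Under
#' `"exclude-pairwise"` any column with a gap in either sequence is dropped
#' before counting.
#'
#' @param block an [alignment_block()].
#' @param gap_policy `"gaps-are-differences"` or `"exclude-pairwise"`.
#' @return a [labeled_matrix()] of identities in percent.
#' @export
pairwise_identity <- function(block,
                              gap_policy = c("gaps-are-differences",
                                             "exclude-pairwise")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(block, "alignment_block"))
  m <- do.call(rbind, strsplit(block$seqs, "", fixed = TRUE))
  rownames(m) <- names(block$seqs)
  n <- nrow(m)
  out <- matrix(100, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- m[i, ]; b <- m[j, ]
      keep <- if (gap_policy == "gaps-are-differences")
        !(a == "-" & b == "-")
      else
        a != "-" & b != "-"
      nc <- sum(keep)
      if (nc == 0L)
        stop("zero compared columns between ", rownames(m)[i], " and ",
             rownames(m)[j])
      id <- 100 * sum(a[keep] == b[keep]) / nc
      out[i, j] <- id
      out[j, i] <- id
    }
  }
  kind <- if (identical(block$locus, "16S")) "16S-identity" else "MLSA-identity"
  labeled_matrix(out, kind = kind, symmetrize = FALSE)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Classifies every comparable site pair (no gap or N in either sequence)
#' as identical, transition (A<->G, C<->T) or transversion, and evaluates
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` where `P` and `Q` are the
#' transition and transversion proportions.
#'
#' @param seqA,seqB aligned nucleotide strings of equal length.
#' @return list of class `k2p_estimate` with elements `P`, `Q`, `d`,
#'   `n_sites`.
#' @export
k2p_distance <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB)) stop("sequences differ in length")
  a <- strsplit(toupper(seqA), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seqB), "", fixed = TRUE)[[1L]]
  acgt <- c("A", "C", "G", "T")
  keep <- a %in% acgt & b %in% acgt
  n <- sum(keep)
  if (n == 0L) stop("zero comparable sites")
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  purine <- c("A", "G")
  is_ti <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(is_ti) / n
  Q <- sum(diff & !is_ti) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("saturated divergence: Kimura-2P distance undefined (P=",
         format(P), ", Q=", format(Q), ")")
  d <- -0.5 * log(w1 * sqrt(w2))
  structure(list(P = P, Q = Q, d = d, n_sites = n), class = "k2p_estimate")
}

#' @export
print.k2p_estimate <- function(x, ...) {
  cat(sprintf("K2P distance d = %.6f (P = %.4f, Q = %.4f, %d sites)\n",
              x$d, x$P, x$Q, x$n_sites))
  invisible(x)
}

#' Summary statistics of a marker-gene alignment
#'
#' Length, percentage of polymorphic columns (columns with at least two
#' observed states among A, C, G, T; gap/N-only variation does not count),
#' mean G+C content across sequences, and the minimum/maximum/mean pairwise
#' Kimura-2P distance. Saturated pairs are dropped from the distance
#' summaries with a warning count.
#'
#' @param block an [alignment_block()].
#' @return list of class `alignment_stats`.
#' @export
alignment_stats <- function(block) {
  stopifnot(inherits(block, "alignment_block"))
  m <- do.call(rbind, strsplit(block$seqs, "", fixed = TRUE))
  acgt <- c("A", "C", "G", "T")
  n_states <- apply(m, 2L, function(col) length(unique(col[col %in% acgt])))
  pct_poly <- 100 * sum(n_states >= 2L) / ncol(m)
  gc <- apply(m, 1L, function(s) {
    base <- s[s %in% acgt]
    100 * sum(base %in% c("G", "C")) / length(base)
  })
  n <- nrow(m)
  ds <- c(); n_saturated <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      est <- tryCatch(k2p_distance(block$seqs[[i]], block$seqs[[j]]),
                      error = function(e) NULL)
      if (is.null(est)) n_saturated <- n_saturated + 1L else ds <- c(ds, est$d)
    }
  }
  if (n_saturated > 0L)
    warning(n_saturated, " saturated pair(s) dropped from K2P summaries")
  structure(list(locus = block$locus, length = ncol(m),
                 pct_polymorphic = pct_poly, mean_gc = mean(gc),
                 min_d = min(ds), max_d = max(ds), mean_d = mean(ds),
                 n_saturated = n_saturated),
            class = "alignment_stats")
}

#' @export
print.alignment_stats <- function(x, ...) {
  cat(sprintf(
    "%s: %d bp, %.2f%% polymorphic, G+C %.2f%%, K2P d in [%.4f, %.4f], mean %.4f\n",
    x$locus, x$length, x$pct_polymorphic, x$mean_gc, x$min_d, x$max_d, x$mean_d))
  invisible(x)
}

#' Concatenate housekeeping loci into the multilocus alignment
#'
#' Loci are concatenated in the fixed order clpA, atpD, gyrB, rpoH, secF,
#' dnaJ, rpoD, rpoS (see [mlsa_locus_order()]) regardless of the order they
#' are supplied in; a subset of the housekeeping loci is allowed, any
#' supplied 16S block is ignored. All loci must cover the identical strain
#' set.
#'
#' @param blocks list of [alignment_block()]s of housekeeping loci.
#' @return an [alignment_block()] with locus `"MLSA"`.
#' @export
concatenate_loci <- function(blocks) {
  names(blocks) <- vapply(blocks, `[[`, character(1L), "locus")
  order <- intersect(mlsa_locus_order(), names(blocks))
  if (!length(order)) stop("no housekeeping locus blocks supplied")
  strains <- sort(names(blocks[[order[1L]]]$seqs))
  for (locus in order) {
    have <- names(blocks[[locus]]$seqs)
    gone <- setdiff(strains, have)
    if (length(gone))
      stop("strain(s) ", paste(gone, collapse = ", "),
           " missing from locus ", locus)
    if (!setequal(have, strains))
      stop("locus ", locus, " has extra strains: ",
           paste(setdiff(have, strains), collapse = ", "))
  }
  seqs <- stats::setNames(rep("", length(strains)), strains)
  for (locus in order)
    seqs <- paste0(seqs, blocks[[locus]]$seqs[strains])
  names(seqs) <- strains
  alignment_block(seqs, "MLSA")
}

#' Multilocus identity screen for species affiliation
#'
#' Fast pre-genome assessment of whether two strains belong to the same
#' genomic species from their concatenated housekeeping-gene identity:
#' above 98.13% the strains have always fallen in the same genomic species,
#' below 97.77% never, and values in between are a grey zone where
#' whole-genome measures must decide.
#'
#' @param identity multilocus identity in percent.
#' @param same_species_above,different_species_below screen bounds.
#' @return list with `verdict` (`"same-species"`, `"different-species"` or
#'   `"grey-zone"`) and `identity`.
#' @export
mlsa_species_screen <- function(identity, same_species_above = 98.13,
                                different_species_below = 97.77) {
  if (identity < 0 || identity > 100) stop("identity out of [0, 100]")
  verdict <- if (identity > same_species_above) "same-species"
    else if (identity < different_species_below) "different-species"
    else "grey-zone"
  list(verdict = verdict, identity = identity)
}

#' 16S-identity screen for genus separation
#'
#' Compares all inter-group 16S rRNA identities of two strain groups against
#' the proposed minimal genus-separation identity of 94.8% (± 0.25
#' tolerance band). Separation is supported when even the largest inter-group
#' identity stays below the band.
#'
#' @param identity_matrix a 16S identity [labeled_matrix()].
#' @param groupA,groupB disjoint, non-empty strain label sets.
#' @param boundary,tolerance genus boundary and its tolerance (percent).
#' @return list with `min`, `max`, `mean` inter-group identity and `verdict`
#'   (`"separate-genera-supported"`, `"within-band"`, `"same-genus-supported"`).
#' @export
genus_boundary_screen <- function(identity_matrix, groupA, groupB,
                                  boundary = 94.8, tolerance = 0.25) {
  stopifnot(inherits(identity_matrix, "labeled_matrix"))
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  if (length(intersect(groupA, groupB))) stop("groups overlap")
  miss <- setdiff(c(groupA, groupB), rownames(identity_matrix))
  if (length(miss)) stop("strain(s) not in matrix: ", paste(miss, collapse = ", "))
  vals <- unclass(identity_matrix)[groupA, groupB, drop = FALSE]
  lo <- boundary - tolerance
  hi <- boundary + tolerance
  verdict <- if (max(vals) < lo) "separate-genera-supported"
    else if (any(vals >= lo & vals <= hi)) "within-band"
    else "same-genus-supported"
  list(min = min(vals), max = max(vals), mean = mean(vals), verdict = verdict)
}
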