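#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering; the returned tree is ultrametric
#' with leaf depth equal to half the cophenetic distance. Labels are sorted
#' before clustering so equal-height merges break ties lexicographically and
#' the output is deterministic.
#'
#' @param dist a distance [labeled_matrix()] (or symmetric labeled matrix).
#' @return a `phylo` tree.
#' @export
upgma <- function(dist) {
  m <- unclass(dist)
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  ape::as.phylo(hc)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining; on an additive matrix the generating topology
#' and branch lengths are recovered exactly. Optionally rooted on an
#' outgroup.
#'
#' @param dist a distance [labeled_matrix()] with at least three taxa.
#' @param root_on optional character vector of outgroup tip labels.
#' @return a `phylo` tree (unrooted unless `root_on` is given).
#' @export
nj_tree <- function(dist, root_on = NULL) {
  m <- unclass(dist)
  if (nrow(m) < 3L) stop("neighbor joining needs >= 3 taxa")
  tr <- ape::nj(stats::as.dist(m))
  if (!is.null(root_on)) {
    miss <- setdiff(root_on, tr$tip.label)
    if (length(miss)) stop("outgroup label(s) absent: ",
                           paste(miss, collapse = ", "))
    tr <- ape::root(tr, outgroup = root_on, resolve.root = TRUE)
  }
  tr
}

#' Attach replicate-based branch support to a reference tree
#'
#' Support of an internal branch is the percentage of replicate trees (e.g.
#' trees inferred from resampled-HSP distance replicates) containing the
#' same bipartition; the pseudo-bootstrap of distance-based phylogenomics.
#'
#' @param reference the point-estimate `phylo` tree.
#' @param replicates list of `phylo` trees on the identical leaf set.
#' @return `reference` with `node.label` set to integer percent support
#'   (`NA` on the root).
#' @export
replicate_support <- function(reference, replicates) {
  if (!length(replicates)) stop("no replicate trees")
  for (tr in replicates)
    if (!setequal(tr$tip.label, reference$tip.label))
      stop("replicate tree leaf set differs from reference")
  counts <- ape::prop.clades(reference, replicates, rooted = FALSE)
  support <- round(100 * counts / length(replicates))
  reference$node.label <- as.character(support)
  reference
}

#' Is a tree ultrametric?
#'
#' @param tree a `phylo` object.
#' @param tol maximum allowed spread of root-to-leaf depths.
#' @return logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  diff(range(depths)) < tol
}
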