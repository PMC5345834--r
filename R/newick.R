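#' Serialize a tree to Newick text
#'
#' Writes an `ape` `phylo` object as standard Newick, with branch lengths
#' formatted to six decimals and (when present) integer support values as
#' internal-node labels. Labels containing characters outside
#' `[A-Za-z0-9_.|-]` are single-quoted. Output round-trips through
#' [ape::read.tree()].
#'
#' @param tree a `phylo` object; `tree$node.label` (if any) is emitted as
#'   internal-node labels.
#' @param path optional file path; when given the text is written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  parent <- tree$edge[, 1L]
  child <- tree$edge[, 2L]
  if (anyDuplicated(child))
    stop("invalid tree: node with more than one parent (cyclic structure?)")
  kids <- split(seq_along(child), parent)  # edge index by parent node
  lens <- tree$edge.length
  nlab <- tree$node.label

  fmt_label <- function(lab) {
    if (grepl("^[A-Za-z0-9_.|-]+$", lab)) lab
    else paste0("'", gsub("'", "''", lab), "'")
  }
  rec <- function(node, depth) {
    if (depth > ntip + nnode + 1L) stop("cyclic structure in tree")
    if (node <= ntip) return(fmt_label(tree$tip.label[node]))
    eidx <- kids[[as.character(node)]]
    if (is.null(eidx)) stop("internal node ", node, " has no children")
    parts <- vapply(eidx, function(e) {
      s <- rec(child[e], depth + 1L)
      if (!is.null(lens)) s <- sprintf("%s:%.6f", s, lens[e])
      s
    }, character(1L))
    lab <- ""
    if (!is.null(nlab)) {
      l <- nlab[node - ntip]
      if (!is.na(l) && nzchar(l)) lab <- fmt_label(as.character(l))
    }
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  root <- setdiff(parent, child)[1L]
  txt <- paste0(rec(root, 1L), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that validates the result.
#'
#' @param path file containing one Newick tree.
#' @return a `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  tr
}
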