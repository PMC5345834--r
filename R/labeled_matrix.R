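#' Labeled pairwise similarity/distance matrices
#'
#' A `labeled_matrix` is the currency of the whole pipeline: a square numeric
#' matrix of pairwise values between strains, carrying the strain labels, the
#' kind of measure it holds, and the value expected on the diagonal
#' (100 for percent similarities, 1 for tetranucleotide correlations, 0 for
#' distances).
#'
#' @param values square numeric matrix; `dimnames` give the strain labels
#'   (row and column labels must match as sets).
#' @param kind one of `"ANIb"`, `"ANIm"`, `"TETRA"`, `"dDDH"`,
#'   `"MLSA-identity"`, `"16S-identity"`, `"distance"`.
#' @param symmetrize average `M[i,j]` and `M[j,i]` before validation.
#'   Asymmetries larger than 0.5 (on the percent scale; 0.005 for TETRA and
#'   distances) are treated as data corruption and rejected.
#'
#' @return an object of class `labeled_matrix`: the numeric matrix with
#'   attributes `kind` and `scale` (the declared diagonal value).
#' @export
labeled_matrix <- function(values, kind, symmetrize = TRUE) {
  kind <- match.arg(kind, c("ANIb", "ANIm", "TETRA", "dDDH",
                            "MLSA-identity", "16S-identity", "distance"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("matrix is not square: ", nrow(values), " x ", ncol(values))
  labs <- rownames(values)
  if (is.null(labs) || is.null(colnames(values)))
    stop("matrix must have row and column labels")
  if (anyDuplicated(labs))
    stop("duplicate strain labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  if (!setequal(labs, colnames(values)))
    stop("row and column label sets differ")
  values <- values[, labs, drop = FALSE]  # align column order to rows

  scale <- matrix_scale(kind)
  tol <- if (scale == 100) 0.5 else 0.005
  if (symmetrize) {
    asym <- abs(values - t(values))
    if (max(asym, na.rm = TRUE) > tol)
      stop("asymmetry exceeds tolerance (max |M[i,j]-M[j,i]| = ",
           format(max(asym, na.rm = TRUE)), "); refusing to symmetrize")
    values <- (values + t(values)) / 2
  } else if (max(abs(values - t(values)), na.rm = TRUE) > 1e-9) {
    stop("matrix is not symmetric")
  }
  diag(values) <- scale

  rng <- switch(kind,
    TETRA = c(-1, 1),
    distance = c(0, Inf),
    c(0, 100))
  off <- values[row(values) != col(values)]
  if (any(off < rng[1] - 1e-9 | off > rng[2] + 1e-9, na.rm = TRUE))
    stop("values out of range [", rng[1], ", ", rng[2], "] for kind ", kind)

  structure(values, kind = kind, scale = scale, class = "labeled_matrix")
}

matrix_scale <- function(kind) {
  switch(kind, TETRA = 1, distance = 0, 100)
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat(sprintf("labeled_matrix [%s], %d strains, diagonal = %s\n",
              attr(x, "kind"), nrow(x), format(attr(x, "scale"))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x))),
                   drop = FALSE], ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
`[.labeled_matrix` <- function(x, i, j, ...) {
  out <- unclass(x)[i, j, ...]
  if (is.matrix(out) && nrow(out) == ncol(out) &&
      identical(rownames(out), colnames(out))) {
    structure(out, kind = attr(x, "kind"), scale = attr(x, "scale"),
              class = "labeled_matrix")
  } else out
}

#' Read a labeled pairwise matrix from a delimited text file
#'
#' Accepts comma- or tab-separated tables whose first row and first column
#' are strain labels (the layout supplementary-material spreadsheets export
#' to). Asymmetric pairs are symmetrized by arithmetic mean; the diagonal is
#' forced to the declared scale of `kind`.
#'
#' @param path file path.
#' @param kind matrix kind, see [labeled_matrix()].
#' @return a [labeled_matrix()].
#' @export
read_labeled_matrix <- function(path, kind) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("matrix body is not numeric in ", path)
  labeled_matrix(m, kind = kind, symmetrize = TRUE)
}

#' Write a labeled matrix as tab-separated text
#'
#' @param x a [labeled_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(x, path) {
  stopifnot(inherits(x, "labeled_matrix"))
  df <- data.frame(strain = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Convert a percent similarity to a distance
#'
#' The trivial conversion used throughout: subtract from 100% and divide by
#' 100, so the 70% hybridization threshold becomes distance 0.30 and the 96%
#' nucleotide-identity threshold becomes 0.04. Tetranucleotide correlations
#' use `1 - r` instead (see [tetra_correlation()]).
#'
#' @param s similarity in percent, in \[0, 100\].
#' @return distance in \[0, 1\].
#' @export
similarity_to_distance <- function(s) {
  if (any(s < 0 | s > 100, na.rm = TRUE))
    stop("similarity out of [0, 100]")
  (100 - s) / 100
}

#' Convert a similarity matrix to a distance matrix
#'
#' @param x a similarity [labeled_matrix()] (percent kinds or TETRA).
#' @return a [labeled_matrix()] of kind `"distance"`.
#' @export
as_distance_matrix <- function(x) {
  stopifnot(inherits(x, "labeled_matrix"))
  kind <- attr(x, "kind")
  d <- switch(kind,
    distance = return(x),
    TETRA = 1 - unclass(x),
    similarity_to_distance(unclass(x)))
  labeled_matrix(d, kind = "distance", symmetrize = FALSE)
}

#' Convert a stated similarity threshold to the distance scale
#'
#' @param threshold threshold on the similarity scale of `kind`.
#' @param kind the scale the threshold was stated on.
#' @return the equivalent distance threshold.
#' @export
threshold_to_distance <- function(threshold, kind) {
  if (identical(kind, "TETRA")) {
    if (threshold < -1 || threshold > 1) stop("TETRA threshold out of [-1, 1]")
    1 - threshold
  } else if (identical(kind, "distance")) {
    threshold
  } else {
    similarity_to_distance(threshold)
  }
}
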