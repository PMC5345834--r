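#' Read sequences from a FASTA file
#'
#' Sequences are returned as a named character vector of upper-case
#' nucleotide strings ('U' is normalized to 'T'); names are the FASTA ids
#' (first whitespace-delimited token), full header lines are kept in the
#' `"descriptions"` attribute. Genomic sequences must not contain gap
#' characters; aligned input must have equal lengths.
#'
#' @param path FASTA file.
#' @param aligned if `TRUE`, enforce equal sequence lengths and allow `-`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  seqs <- toupper(as.character(set))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (any(!nzchar(ids))) stop("empty sequence id in ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ok <- if (aligned) "^[ACGTN-]+$" else "^[ACGTN]+$"
  bad <- !grepl(ok, seqs)
  if (any(bad))
    stop("invalid characters (alphabet is A,C,G,T,N",
         if (aligned) ",-", ") in: ", paste(ids[bad], collapse = ", "))
  if (aligned) {
    len <- nchar(seqs)
    if (length(unique(len)) != 1L)
      stop("aligned sequences differ in length: ",
           paste(sprintf("%s=%d", ids[len != len[1L]], len[len != len[1L]]),
                 collapse = ", "))
  }
  names(seqs) <- ids
  attr(seqs, "descriptions") <- headers
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 80L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Alignment block of one locus
#'
#' Bundles equal-length aligned sequences with the locus name. Valid locus
#' names are the 16S rRNA gene, the eight housekeeping genes used for
#' multilocus analysis, and `"MLSA"` for the concatenation.
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (>= 2 records).
#' @param locus locus name.
#' @return object of class `alignment_block` with elements `seqs` and `locus`.
#' @export
alignment_block <- function(seqs, locus) {
  locus <- match.arg(locus, c(mlsa_locus_order(), "16S", "MLSA"))
  if (length(seqs) < 2L) stop("alignment needs >= 2 sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences differ in length for locus ", locus)
  structure(list(seqs = seqs, locus = locus), class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block '%s': %d sequences x %d columns\n",
              x$locus, length(x$seqs), nchar(x$seqs[[1L]])))
  invisible(x)
}

#' Concatenation order of the housekeeping loci
#'
#' The fixed gene order used when building the multilocus (MLSA)
#' concatenation: clpA, atpD, gyrB, rpoH, secF, dnaJ, rpoD, rpoS.
#'
#' @return character vector of the eight locus names, in order.
#' @export
mlsa_locus_order <- function() {
  c("clpA", "atpD", "gyrB", "rpoH", "secF", "dnaJ", "rpoD", "rpoS")
}

#' Read strain metadata
#'
#' Tab- or comma-separated table with columns `strain_id`, `is_type`,
#' `species_name`, `region` and optionally `is_putative_type`. Every type
#' strain must carry a species name.
#'
#' @param path file path.
#' @return data.frame with one row per strain.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- sniff_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "")
  validate_metadata(df)
}

#' Write strain metadata as TSV
#'
#' @param metadata data.frame as from [read_metadata()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  metadata <- validate_metadata(metadata)
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_metadata <- function(df) {
  need <- c("strain_id", "is_type", "species_name", "region")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!"is_putative_type" %in% names(df)) df$is_putative_type <- FALSE
  df$is_type <- as.logical(df$is_type)
  df$is_putative_type <- as.logical(df$is_putative_type)
  df$species_name[is.na(df$species_name)] <- ""
  df$region[is.na(df$region) | !nzchar(df$region)] <- "unknown"
  if (anyDuplicated(df$strain_id))
    stop("duplicate strain_id in metadata")
  bad <- df$is_type & !nzchar(df$species_name)
  if (any(bad))
    stop("type strain(s) without species_name: ",
         paste(df$strain_id[bad], collapse = ", "))
  df
}
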