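blast_available <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

require_blast <- function() {
  if (!blast_available())
    stop("BLAST+ (blastn/makeblastdb) not found on PATH; ",
         "fragment-ANI and GBDP distances need it")
}

as_contigs <- function(genome, id = "g") {
  seqs <- unlist(genome, use.names = FALSE)
  if (is.null(seqs) || !length(seqs) || !sum(nchar(seqs)))
    stop("empty genome")
  stats::setNames(seqs, sprintf("%s|ctg%d", id, seq_along(seqs)))
}

make_blast_db <- function(contigs, dir) {
  ref_fa <- file.path(dir, "ref.fa")
  write_fasta(contigs, ref_fa)
  out <- suppressWarnings(system2("makeblastdb",
    c("-in", ref_fa, "-dbtype", "nucl", "-out", file.path(dir, "refdb")),
    stdout = TRUE, stderr = TRUE))
  if (!file.exists(file.path(dir, "refdb.nsq")) &&
      !file.exists(file.path(dir, "refdb.00.nsq")))
    stop("makeblastdb failed: ", paste(out, collapse = "\n"))
  file.path(dir, "refdb")
}

blastn_tab <- function(query, db, dir, extra = character(),
                       task = "blastn") {
  q_fa <- file.path(dir, "query.fa")
  write_fasta(query, q_fa)
  out_tab <- file.path(dir, "hits.tsv")
  fields <- c("qseqid", "sseqid", "pident", "length", "nident",
              "qstart", "qend", "sstart", "send", "bitscore", "qlen")
  scoring <- if (task == "blastn")
    c("-reward", "1", "-penalty", "-1", "-gapopen", "5", "-gapextend", "2",
      "-xdrop_gap_final", "150") else character()
  args <- c("-task", task, "-query", q_fa, "-db", db, scoring,
            "-dust", "no", "-evalue", "1e-15",
            "-outfmt", shQuote(paste(c("6", fields), collapse = " ")),
            "-out", out_tab, extra)
  msg <- suppressWarnings(system2("blastn", args, stdout = TRUE, stderr = TRUE))
  if (!file.exists(out_tab))
    stop("blastn failed: ", paste(msg, collapse = "\n"))
  if (file.size(out_tab) == 0L)
    return(stats::setNames(data.frame(matrix(nrow = 0L, ncol = length(fields))),
                           fields))
  hits <- utils::read.table(out_tab, sep = "\t", stringsAsFactors = FALSE)
  names(hits) <- fields
  hits
}

#' Cut a genome into consecutive fragments
#'
#' Each contig is cut into consecutive windows of `fragment_len`; the
#' terminal fragment of a contig is kept when at least `min_tail` bp long.
#'
#' @param genome character vector of contigs.
#' @param fragment_len fragment length in bp.
#' @param min_tail minimum length of the terminal fragment.
#' @return named character vector of fragments.
#' @export
fragment_genome <- function(genome, fragment_len = 1020L, min_tail = 100L) {
  seqs <- unlist(genome, use.names = FALSE)
  frags <- character(); k <- 0L
  for (s in seqs) {
    n <- nchar(s)
    starts <- seq.int(1L, n, by = fragment_len)
    for (st in starts) {
      en <- min(st + fragment_len - 1L, n)
      if (en - st + 1L >= min_tail || st == 1L) {
        k <- k + 1L
        frags[sprintf("frag%06d", k)] <- substr(s, st, en)
      }
    }
  }
  frags[nchar(frags) >= min(min_tail, fragment_len)]
}

ani_result <- function(query_id, ref_id, ani, n_total, n_retained,
                       aligned_fraction, approximate = FALSE) {
  structure(list(query_id = query_id, ref_id = ref_id, ani = ani,
                 n_fragments_total = n_total, n_fragments_retained = n_retained,
                 aligned_fraction = aligned_fraction,
                 approximate = approximate),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("ANI %s vs %s: %.3f%% (%d/%d fragments, aligned fraction %.3f%s)\n",
              x$query_id, x$ref_id, x$ani, x$n_fragments_retained,
              x$n_fragments_total, x$aligned_fraction,
              if (isTRUE(x$approximate)) ", approximate" else ""))
  invisible(x)
}

#' Fragment-based average nucleotide identity (BLAST flavour)
#'
#' The query is cut into consecutive 1020 bp fragments, each fragment is
#' locally aligned against the reference with `blastn`, and a fragment is
#' retained when its best alignment has at least 30% identity over at least
#' 70% of the fragment length. The reported ANI is the mean identity of the
#' retained fragments. These retention rules are the conventional defaults
#' of the BLAST-based ANI as popularized by JSpecies.
#'
#' @param query,ref genomes as character vectors of contigs.
#' @param fragment_len fragment length (bp).
#' @param min_identity minimum percent identity for a fragment to count.
#' @param min_coverage minimum aligned fraction of the fragment length.
#' @param query_id,ref_id labels for the result.
#' @return an `ani_result`; error with message "no-homology" when no
#'   fragment is retained.
#' @export
anib <- function(query, ref, fragment_len = 1020L, min_identity = 30,
                 min_coverage = 0.7, query_id = "query", ref_id = "ref") {
  require_blast()
  frags <- fragment_genome(query, fragment_len)
  dir <- tempfile("anib"); dir.create(dir); on.exit(unlink(dir, recursive = TRUE))
  db <- make_blast_db(as_contigs(ref, ref_id), dir)
  hits <- blastn_tab(frags, db, dir)
  summarize_anib(hits, frags, query_id, ref_id, min_identity, min_coverage)
}

summarize_anib <- function(hits, frags, query_id, ref_id,
                           min_identity, min_coverage) {
  n_total <- length(frags)
  if (nrow(hits)) {
    hits <- hits[order(-hits$bitscore), ]
    hits <- hits[!duplicated(hits$qseqid), ]  # best HSP per fragment
    keep <- hits$pident >= min_identity &
      hits$length >= min_coverage * hits$qlen
    hits <- hits[keep, , drop = FALSE]
  }
  if (!nrow(hits))
    stop("no-homology: no retained fragments between ", query_id,
         " and ", ref_id)
  ani_result(query_id, ref_id,
             ani = mean(hits$pident),
             n_total = n_total, n_retained = nrow(hits),
             aligned_fraction = sum(nchar(frags[hits$qseqid])) /
               sum(nchar(frags)))
}

#' All-vs-all fragment-ANI matrix
#'
#' Computes the BLAST-based fragment ANI for every ordered genome pair using
#' a single combined BLAST database and query set, then symmetrizes by
#' averaging the two directions. Pairs with no retained fragments get
#' similarity 0 (with a warning); the diagonal is 100. The default seeding
#' task is `"megablast"`, appropriate down to roughly 85% identity; switch
#' to `task = "blastn"` (the sensitive per-pair default of [anib()]) when
#' genuinely distant genomes must still align.
#'
#' @inheritParams anib
#' @param genomes named list of genomes.
#' @param task BLAST seeding task, `"megablast"` or `"blastn"`.
#' @return a [labeled_matrix()] of kind `"ANIb"`.
#' @export
anib_matrix <- function(genomes, fragment_len = 1020L, min_identity = 30,
                        min_coverage = 0.7, task = "megablast") {
  require_blast()
  ids <- names(genomes)
  dir <- tempfile("anibm"); dir.create(dir); on.exit(unlink(dir, recursive = TRUE))
  all_contigs <- unlist(lapply(ids, function(id)
    as_contigs(genomes[[id]], id)))
  db <- make_blast_db(all_contigs, dir)
  frag_sets <- lapply(ids, function(id) {
    f <- fragment_genome(genomes[[id]], fragment_len)
    stats::setNames(f, sprintf("%s|%s", id, names(f)))
  })
  names(frag_sets) <- ids
  frags <- unlist(unname(frag_sets))
  hits <- blastn_tab(frags, db, dir,
                     extra = c("-max_target_seqs", "500"), task = task)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 100
  if (nrow(hits)) {
    hits$qstrain <- sub("\\|.*$", "", hits$qseqid)
    hits$tstrain <- sub("\\|.*$", "", hits$sseqid)
    hits <- hits[hits$qstrain != hits$tstrain, , drop = FALSE]
    hits <- hits[order(-hits$bitscore), ]
    hits <- hits[!duplicated(paste(hits$qseqid, hits$tstrain)), , drop = FALSE]
    keep <- hits$pident >= min_identity & hits$length >= min_coverage * hits$qlen
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits)) {
      agg <- stats::aggregate(pident ~ qstrain + tstrain, hits, mean)
      for (r in seq_len(nrow(agg)))
        m[agg$qstrain[r], agg$tstrain[r]] <- agg$pident[r]
    }
  }
  miss <- is.na(m)
  if (any(miss)) {
    warning(sum(miss[upper.tri(miss)] & t(miss)[upper.tri(miss)]),
            " pair(s) with no homology; similarity set to 0")
    m[miss] <- 0
  }
  labeled_matrix(m, kind = "ANIb", symmetrize = TRUE)
}

#' Approximate whole-genome-alignment ANI
#'
#' An approximate, exact-match-anchored stand-in for whole-genome-aligner
#' ANI: all maximal exact matches of at least `min_match` bp between query
#' and reference are located via a k-mer index, anchors on the same diagonal
#' are chained gap-free (gaps up to `max_gap` bp), and the identity of each
#' chained block is computed by direct base comparison. The reported ANI is
#' the length-weighted mean identity over chained blocks. Results are
#' flagged `approximate = TRUE`.
#'
#' @param query,ref genomes as character vectors of contigs.
#' @param min_match anchor (k-mer) length.
#' @param max_gap largest anchor gap bridged within one gap-free block.
#' @param query_id,ref_id labels.
#' @return an `ani_result` with `approximate = TRUE`.
#' @export
anim_approx <- function(query, ref, min_match = 20L, max_gap = 200L,
                        query_id = "query", ref_id = "ref") {
  qseqs <- unlist(query, use.names = FALSE)
  rcat <- paste(unlist(ref, use.names = FALSE), collapse = strrep("X", min_match))
  if (!nchar(rcat) || !sum(nchar(qseqs))) stop("empty genome")
  nr <- nchar(rcat)
  rk <- substring(rcat, 1:(nr - min_match + 1L), min_match:nr)
  total_len <- 0; total_ident <- 0; covered <- 0
  for (qs in qseqs) {
    nq <- nchar(qs)
    if (nq < min_match) next
    qk <- substring(qs, 1:(nq - min_match + 1L), min_match:nq)
    hit <- match(qk, rk)
    idx <- which(!is.na(hit))
    if (!length(idx)) next
    diagid <- idx - hit[idx]
    for (dg in unique(diagid)) {
      qpos <- idx[diagid == dg]
      brk <- c(0L, which(diff(qpos) > max_gap), length(qpos))
      for (b in seq_len(length(brk) - 1L)) {
        run <- qpos[(brk[b] + 1L):brk[b + 1L]]
        qs1 <- run[1L]; qe1 <- run[length(run)] + min_match - 1L
        rs1 <- qs1 - dg; re1 <- qe1 - dg
        if (rs1 < 1L || re1 > nr) next
        a <- utf8ToInt(substr(qs, qs1, qe1))
        bb <- utf8ToInt(substr(rcat, rs1, re1))
        len <- length(a)
        ident <- sum(a == bb)
        total_len <- total_len + len
        total_ident <- total_ident + ident
        covered <- covered + len
      }
    }
  }
  if (total_len == 0)
    stop("no-homology: no exact-match anchors between ", query_id,
         " and ", ref_id)
  ani_result(query_id, ref_id, ani = 100 * total_ident / total_len,
             n_total = NA_integer_, n_retained = NA_integer_,
             aligned_fraction = covered / sum(nchar(qseqs)),
             approximate = TRUE)
}
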