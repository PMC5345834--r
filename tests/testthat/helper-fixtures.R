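# Shared fixtures, computed once per test run. The small planted complex is
# reused by the distance/clustering/tree tests; the expensive objects (ANI
# matrix) are memoized.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

small_complex <- function() {
  fixture("small_complex", function() {
    simulate_species_complex(simulation_config(
      n_species = 3, cluster_sizes = c(4, 3, 2), genome_length = 60000,
      n_contigs = 3, seed = 101))
  })
}

small_anib <- function() {
  fixture("small_anib", function() anib_matrix(small_complex()$genomes))
}

# strains at the three planted divergence bands relative to sp01_st01:
# same subspecies (st02), same species/other subspecies (st03 or st04),
# other species (sp02_st01)
band_pairs <- function() {
  sim <- small_complex()
  sub <- sim$truth$subspecies_of
  anchor <- "sp01_st01"
  same_sub <- setdiff(names(sub)[sub == sub[anchor]], anchor)[1L]
  other_sub <- names(sub)[startsWith(names(sub), "sp01") &
                            sub != sub[anchor]][1L]
  other_sp <- "sp02_st01"
  list(anchor = anchor, same_sub = same_sub, other_sub = other_sub,
       other_sp = other_sp)
}

# deterministic random distance matrix with labels a..; values in [0, 1]
random_dist_matrix <- function(n, seed) {
  set.seed(seed)
  labs <- sprintf("s%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  v <- stats::runif(n * (n - 1) / 2)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  labeled_matrix(m, "distance", symmetrize = FALSE)
}

# independent single-linkage oracle: connected components of the link graph
components_oracle <- function(m, threshold) {
  labs <- rownames(m)
  link <- unclass(m) <= threshold
  diag(link) <- FALSE
  comp <- seq_along(labs)
  repeat {
    changed <- FALSE
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (link[i, j] && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(labs, comp), sort))
}

tetra_words_oracle <- function(k) {
  b <- c("A", "C", "G", "T")
  sort(apply(expand.grid(rep(list(b), k)), 1, paste, collapse = ""))
}

empty_hits_frame <- function() {
  data.frame(qseqid = character(), sseqid = character(), pident = numeric(),
             length = numeric(), nident = numeric(), qstart = numeric(),
             qend = numeric(), sstart = numeric(), send = numeric(),
             bitscore = numeric(), qlen = numeric(), stringsAsFactors = FALSE)
}

write_tmp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
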