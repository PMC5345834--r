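#' Simulation configuration for a planted species complex
#'
#' Defaults describe the study conditions the package is validated under:
#' about twenty genomes of 200 kb in species clusters of one to twelve
#' strains, with pairwise divergence bands (substitutions/site) of 0.005
#' within subspecies, 0.03 within species, 0.10 between species and 0.25
#' between genera. With these bands fragment-ANI of within-species pairs
#' lands above the 96% species boundary and between-species pairs fall well
#' below 94%, so the planted structure straddles the conventional
#' delineation thresholds.
#'
#' @param n_species number of species clusters.
#' @param cluster_sizes strains per species (each in 1..12).
#' @param genome_length chromosome length in bp before contig splitting.
#' @param n_contigs contigs per genome (chromosome cut at random breakpoints).
#' @param gc_target genomic G+C fraction.
#' @param band_within_subspecies,band_within_species,band_between_species,band_between_genus
#'   target pairwise divergence (substitutions/site) for strain pairs at each
#'   level of the planted hierarchy; must be strictly increasing.
#' @param ti_tv_ratio transition:transversion ratio of the substitution model.
#' @param subspecies_sizes `"auto"` (species with >= 4 strains are split into
#'   two subspecies), `NULL` (no planted subspecies) or a list with one
#'   integer vector per species summing to its cluster size.
#' @param n_described number of species treated as already described (they
#'   get a species name and a designated type strain); defaults to half,
#'   rounded up.
#' @param seed integer seed; recorded in the output.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 6,
                              cluster_sizes = c(6, 4, 4, 3, 2, 1),
                              genome_length = 200000,
                              n_contigs = 5,
                              gc_target = 0.63,
                              band_within_subspecies = 0.005,
                              band_within_species = 0.03,
                              band_between_species = 0.10,
                              band_between_genus = 0.25,
                              ti_tv_ratio = 2.0,
                              subspecies_sizes = "auto",
                              n_described = ceiling(n_species / 2),
                              seed = 1L) {
  if (length(cluster_sizes) != n_species)
    stop("cluster_sizes must have length n_species")
  if (any(cluster_sizes < 1 | cluster_sizes > 12))
    stop("cluster sizes must be in 1..12")
  if (genome_length < 1000) stop("genome_length too small")
  bands <- c(band_within_subspecies, band_within_species,
             band_between_species, band_between_genus)
  if (any(diff(bands) <= 0))
    stop("divergence bands must be strictly increasing")
  # a subspecies is a set of strains diverging by band_within_subspecies;
  # strains in different subspecies of one species diverge by
  # band_within_species. "auto" groups species of >= 4 strains into two
  # subspecies and leaves smaller species unstructured (one trivial
  # subspecies per strain); NULL plants no subspecies structure at all.
  if (identical(subspecies_sizes, "auto")) {
    subspecies_sizes <- lapply(cluster_sizes, function(k) {
      if (k >= 4) c(ceiling(k / 2), floor(k / 2)) else rep(1L, k)
    })
  } else if (is.null(subspecies_sizes)) {
    subspecies_sizes <- lapply(cluster_sizes, function(k) rep(1L, k))
  }
  if (!all(vapply(seq_along(subspecies_sizes),
                  function(i) sum(subspecies_sizes[[i]]) == cluster_sizes[i],
                  logical(1L))))
    stop("subspecies_sizes must sum to cluster_sizes per species")
  structure(list(
    n_species = n_species, cluster_sizes = cluster_sizes,
    genome_length = genome_length, n_contigs = n_contigs,
    gc_target = gc_target,
    band_within_subspecies = band_within_subspecies,
    band_within_species = band_within_species,
    band_between_species = band_between_species,
    band_between_genus = band_between_genus,
    ti_tv_ratio = ti_tv_ratio,
    subspecies_sizes = subspecies_sizes,
    n_described = n_described, seed = as.integer(seed)
  ), class = "simulation_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Draw a random genome sequence
#'
#' With `order = 0` bases are drawn independently at the target G+C. With
#' `order = 3` the sequence is sampled from a random third-order Markov
#' chain whose transition rows are Dirichlet draws centred on the base
#' composition: this plants a genome-specific oligonucleotide signature
#' (tetramer usage not predictable from trimers), the property that makes
#' tetranucleotide z-score correlations of real genomes informative. Lower
#' `concentration` gives a stronger signature.
#'
#' @param length sequence length in bp.
#' @param gc G+C fraction.
#' @param order Markov order of the composition model (0 or 3).
#' @param concentration Dirichlet concentration multiplier for `order = 3`.
#' @return a single nucleotide string.
#' @export
random_genome <- function(length, gc = 0.5, order = 0L, concentration = 1.5) {
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  if (order == 0L)
    return(paste(sample(bases, length, replace = TRUE, prob = p),
                 collapse = ""))
  if (order != 3L) stop("order must be 0 or 3")
  # 64 trimer contexts x 4 next-base probabilities, Dirichlet(4 * conc * p)
  alpha <- 4 * concentration * p
  trans <- matrix(stats::rgamma(64L * 4L, shape = rep(alpha, each = 64L)),
                  64L, 4L)
  trans <- trans / rowSums(trans)
  cum <- t(apply(trans, 1L, cumsum))
  out <- integer(length)
  out[1:3] <- sample.int(4L, 3L, replace = TRUE, prob = p)
  u <- stats::runif(length)
  state <- (out[1L] - 1L) * 16L + (out[2L] - 1L) * 4L + out[3L]
  for (i in 4:length) {
    b <- findInterval(u[i], cum[state, ]) + 1L
    out[i] <- b
    state <- ((state - 1L) %% 16L) * 4L + b
  }
  paste(bases[out], collapse = "")
}

#' Mutate a sequence under a two-parameter substitution model
#'
#' Each site is substituted independently with probability `rate`; a
#' substituted site receives a transition (A<->G, C<->T) with probability
#' `ti_tv_ratio / (ti_tv_ratio + 1)` and otherwise one of the two possible
#' transversions, uniformly. Length is preserved; `N` and gap characters are
#' never touched. No indels are introduced: downstream identity statistics
#' treat gaps as differences, and a substitution-only model keeps the
#' divergence/ANI calibration transparent.
#'
#' @param seq nucleotide string.
#' @param rate per-site substitution probability, in \[0, 0.75).
#' @param ti_tv_ratio transitions per transversion.
#' @param seed optional seed applied locally.
#' @return mutated nucleotide string of the same length.
#' @export
mutate_sequence <- function(seq, rate, ti_tv_ratio = 2.0, seed = NULL) {
  if (rate < 0 || rate >= 0.75) stop("rate must be in [0, 0.75)")
  if (!is.null(seed)) return(with_seed(seed,
    mutate_sequence(seq, rate, ti_tv_ratio)))
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate & chars %in% c("A", "C", "G", "T"))
  if (length(hit)) {
    p_ti <- ti_tv_ratio / (ti_tv_ratio + 1)
    is_ti <- stats::runif(length(hit)) < p_ti
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    old <- chars[hit]
    new <- ifelse(is_ti, transition[old],
                  ifelse(stats::runif(length(hit)) < 0.5, tv1[old], tv2[old]))
    chars[hit] <- new
  }
  paste(chars, collapse = "")
}

#' Simulate a genome set with planted species and subspecies structure
#'
#' One ancestral chromosome is drawn at random; species ancestors,
#' subspecies ancestors and finally strains are evolved from it with
#' per-branch substitution rates chosen so that the *pairwise* divergence of
#' strain pairs matches the configured band of their level: within-subspecies
#' pairs diverge by about `band_within_subspecies`, within-species pairs by
#' `band_within_species`, and between-species pairs by
#' `band_between_species`. Chromosomes are then cut at uniform random
#' breakpoints into `n_contigs` contigs. The first `n_described` species are
#' flagged as described, with their first strain as the nomenclatural type.
#'
#' @param config a [simulation_config()].
#' @return list with `genomes` (named list of contig character vectors),
#'   `truth` (class `planted_truth`: species/subspecies membership, type
#'   strains, the divergence bands and the seed) and `metadata` (strain
#'   table as in [read_metadata()]).
#' @export
simulate_species_complex <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    cfg <- config
    n_strains <- sum(cfg$cluster_sizes)
    root <- random_genome(cfg$genome_length, cfg$gc_target, order = 3L)

    # per-branch rates: each level adds half the band increment so that the
    # pairwise (leaf-to-leaf) divergence matches the band of that level
    r_strain <- cfg$band_within_subspecies / 2
    r_subsp <- (cfg$band_within_species - cfg$band_within_subspecies) / 2
    r_species <- (cfg$band_between_species - cfg$band_within_species) / 2

    genomes <- list(); species_of <- integer(); subspecies_of <- character()
    regions <- character()
    vocab <- c("Kulunda Steppe", "Kenya", "Egypt (Wadi Natrun)", "Mongolia",
               "California (Mono, Searles)", "Buriatia")
    home <- vocab[((seq_len(cfg$n_species) - 1L) %% length(vocab)) + 1L]
    for (sp in seq_len(cfg$n_species)) {
      anc <- mutate_sequence(root, r_species, cfg$ti_tv_ratio)
      subs <- cfg$subspecies_sizes[[sp]]
      st <- 0L
      for (ss in seq_along(subs)) {
        subanc <- mutate_sequence(anc, r_subsp, cfg$ti_tv_ratio)
        for (k in seq_len(subs[ss])) {
          st <- st + 1L
          id <- sprintf("sp%02d_st%02d", sp, st)
          g <- mutate_sequence(subanc, r_strain, cfg$ti_tv_ratio)
          genomes[[id]] <- split_contigs(g, cfg$n_contigs)
          species_of[id] <- sp
          subspecies_of[id] <- sprintf("%d.%d", sp, ss)
          regions[id] <- if (stats::runif(1) < 0.15)
            sample(setdiff(vocab, home[sp]), 1L) else home[sp]
        }
      }
    }

    ids <- names(genomes)
    described <- seq_len(min(cfg$n_described, cfg$n_species))
    type_strains <- vapply(described, function(sp)
      ids[species_of == sp][1L], character(1L))
    metadata <- data.frame(
      strain_id = ids,
      is_type = ids %in% type_strains,
      species_name = ifelse(species_of[ids] %in% described,
                            sprintf("Species_%02d", species_of[ids]), ""),
      region = regions[ids],
      is_putative_type = FALSE,
      stringsAsFactors = FALSE
    )
    truth <- structure(list(
      species_of = species_of,
      subspecies_of = subspecies_of,
      type_strains = type_strains,
      bands = c(within_subspecies = cfg$band_within_subspecies,
                within_species = cfg$band_within_species,
                between_species = cfg$band_between_species,
                between_genus = cfg$band_between_genus),
      seed = cfg$seed
    ), class = "planted_truth")
    list(genomes = genomes, truth = truth, metadata = validate_metadata(metadata))
  })
}

split_contigs <- function(seq, n_contigs) {
  n <- nchar(seq)
  if (n_contigs <= 1L || n < 2L * n_contigs) return(stats::setNames(seq, "ctg1"))
  cuts <- sort(sample(seq_len(n - 1L), n_contigs - 1L))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  stats::setNames(substring(seq, starts, ends),
                  sprintf("ctg%d", seq_len(n_contigs)))
}

#' Similarity cutoff equivalent to a planted divergence boundary
#'
#' The conventional 70%/79% hybridization cutoffs live on the calibrated
#' digital-hybridization scale, which the default surrogate backend does not
#' reproduce. For synthetic runs the equivalent cutoff on a percent-identity
#' scale is defined from the planted bands themselves: the similarity
#' halfway between the two divergence bands the boundary separates.
#'
#' @param truth a `planted_truth` object.
#' @param level `"species"` (between within-species and between-species
#'   bands) or `"subspecies"`.
#' @return cutoff in percent similarity.
#' @export
equivalent_cutoff <- function(truth, level = c("species", "subspecies")) {
  level <- match.arg(level)
  b <- truth$bands
  mid <- if (level == "species")
    mean(c(b[["within_species"]], b[["between_species"]]))
  else
    mean(c(b[["within_subspecies"]], b[["within_species"]]))
  100 * (1 - mid)
}

#' Default marker-gene locus lengths
#'
#' Alignment lengths (bp) of the 16S rRNA gene and the eight housekeeping
#' loci used for multilocus analysis; the housekeeping lengths sum to the
#' 12,283 bp concatenation.
#'
#' @return named integer vector.
#' @export
default_locus_lengths <- function() {
  c("16S" = 1360L, atpD = 1380L, clpA = 2299L, dnaJ = 1162L, gyrB = 2457L,
    rpoD = 1960L, rpoH = 897L, rpoS = 1156L, secF = 972L)
}

#' Simulate gap-free marker-gene alignments on a planted hierarchy
#'
#' Each locus is evolved along the same species/subspecies hierarchy as the
#' genomes, with a per-locus rate multiplier. The 16S rRNA gene is far more
#' conserved than the housekeeping genes (multiplier 0.15 vs 1.0 by
#' default), reproducing the qualitative contrast between ribosomal and
#' multilocus divergence in real data.
#'
#' @param truth a `planted_truth` from [simulate_species_complex()].
#' @param loci named integer vector of locus lengths; names must be known
#'   loci (see [default_locus_lengths()]).
#' @param multipliers named numeric vector of per-locus rate multipliers;
#'   unlisted loci default to 1 (0.15 for `"16S"`).
#' @param gc G+C fraction of the simulated genes.
#' @param seed integer seed.
#' @return named list of [alignment_block()]s, one per locus.
#' @export
simulate_marker_alignments <- function(truth, loci = default_locus_lengths(),
                                       multipliers = c("16S" = 0.15),
                                       gc = 0.6, seed = truth$seed + 1L) {
  if (length(loci) == 0L) stop("empty loci list")
  known <- names(default_locus_lengths())
  bad <- setdiff(names(loci), known)
  if (length(bad)) stop("unknown locus name(s): ", paste(bad, collapse = ", "))
  if (any(loci <= 0)) stop("locus lengths must be positive")
  b <- truth$bands
  r_strain <- b[["within_subspecies"]] / 2
  r_subsp <- (b[["within_species"]] - b[["within_subspecies"]]) / 2
  r_species <- (b[["between_species"]] - b[["within_species"]]) / 2
  species <- truth$species_of
  subsp <- truth$subspecies_of
  with_seed(seed, {
    out <- list()
    for (locus in names(loci)) {
      mult <- if (locus %in% names(multipliers)) multipliers[[locus]] else 1
      rootg <- random_genome(loci[[locus]], gc)
      seqs <- character()
      for (sp in unique(species)) {
        anc <- mutate_sequence(rootg, r_species * mult)
        for (ss in unique(subsp[species == sp])) {
          subanc <- mutate_sequence(anc, r_subsp * mult)
          for (id in names(subsp)[subsp == ss & species == sp]) {
            seqs[id] <- mutate_sequence(subanc, r_strain * mult)
          }
        }
      }
      out[[locus]] <- alignment_block(seqs[names(species)], locus)
    }
    out
  })
}
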