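#' Pipeline configuration
#'
#' Bundles inputs, thresholds and the seed for an end-to-end run. Default
#' thresholds are the conventional delineation values: species radius 70 on
#' the hybridization scale (confidence-interval variants 67 and 73), 94/95/96
#' on the nucleotide-identity scale, 0.989/0.999 for tetranucleotide
#' correlation, subspecies cutoff 79, linkage fraction 0.5.
#'
#' @param mode `"simulate"` (generate a planted species complex),
#'   `"genomes"` (FASTA files in `genomes_dir`) or `"matrices"` (a
#'   precomputed similarity matrix at `matrix_path`).
#' @param out_dir run directory (created).
#' @param sim a [simulation_config()] (simulate mode).
#' @param genomes_dir directory of `*.fasta` genome files (genomes mode).
#' @param matrix_path,matrix_kind precomputed matrix and its kind
#'   (matrices mode).
#' @param metadata_path optional strain metadata table.
#' @param measures genome measures to compute from genomes
#'   (subset of `"ANIb"`, `"TETRA"`, `"GBDP"`).
#' @param ddh_radius,ddh_ci,ani_radii,tetra_radii,subspecies_cutoff,fraction
#'   delineation thresholds.
#' @param seed integer seed, recorded in every output.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "genomes", "matrices"),
                            out_dir = tempfile("genospec_run"),
                            sim = simulation_config(seed = seed),
                            genomes_dir = NULL,
                            matrix_path = NULL, matrix_kind = "dDDH",
                            metadata_path = NULL,
                            measures = c("ANIb", "TETRA"),
                            ddh_radius = 70, ddh_ci = c(67, 73),
                            ani_radii = c(94, 95, 96),
                            tetra_radii = c(0.989, 0.999),
                            subspecies_cutoff = 79,
                            fraction = 0.5, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "genomes" && is.null(genomes_dir))
    stop("genomes mode needs 'genomes_dir'")
  if (mode == "matrices" && is.null(matrix_path))
    stop("matrices mode needs 'matrix_path'")
  structure(list(mode = mode, out_dir = out_dir, sim = sim,
                 genomes_dir = genomes_dir, matrix_path = matrix_path,
                 matrix_kind = matrix_kind, metadata_path = metadata_path,
                 measures = measures, ddh_radius = ddh_radius,
                 ddh_ci = ddh_ci, ani_radii = ani_radii,
                 tetra_radii = tetra_radii,
                 subspecies_cutoff = subspecies_cutoff,
                 fraction = fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the delineation pipeline end to end
#'
#' Depending on the mode: simulates (or reads) genomes, computes the
#' requested pairwise measures, delineates species by type radius plus
#' fraction-linkage clustering, delineates subspecies, builds a UPGMA
#' dendrogram of the primary matrix, classifies biogeographic distribution,
#' and writes every stage product into the run directory: `*.tsv` matrices,
#' `partition.json`, `*.nwk` trees, `biogeo.tsv`, and `report.tsv`
#' tabulating cluster / novel / ambiguity counts per measure and threshold.
#' In simulate mode the planted truth is written to `truth.json` and the
#' recovery (adjusted Rand index) is included in the report.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the main in-memory products: `matrices`,
#'   `partition`, `subspecies`, `report`, `biogeo`, and (simulate mode)
#'   `truth` and `recovery`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                    sprintf(...)),
                            file = log_path, append = TRUE)
  logf("mode=%s seed=%d", config$mode, config$seed)

  truth <- NULL; metadata <- NULL; genomes <- NULL
  matrices <- list(); thresholds <- list()

  if (config$mode == "simulate") {
    sim <- simulate_species_complex(config$sim)
    genomes <- sim$genomes; truth <- sim$truth; metadata <- sim$metadata
    gdir <- file.path(config$out_dir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    for (id in names(genomes))
      write_fasta(stats::setNames(genomes[[id]],
                                  paste0(id, "|", names(genomes[[id]]))),
                  file.path(gdir, paste0(id, ".fasta")))
    jsonlite::write_json(
      list(species_of = as.list(truth$species_of),
           subspecies_of = as.list(truth$subspecies_of),
           type_strains = truth$type_strains,
           bands = as.list(truth$bands), seed = truth$seed),
      file.path(config$out_dir, "truth.json"), auto_unbox = TRUE)
    write_metadata(metadata, file.path(config$out_dir, "metadata.tsv"))
  } else if (config$mode == "genomes") {
    files <- list.files(config$genomes_dir, "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files in ", config$genomes_dir)
    genomes <- lapply(files, read_fasta)
    names(genomes) <- sub("\\.(fa|fasta|fna)$", "", basename(files))
  }
  if (!is.null(config$metadata_path))
    metadata <- read_metadata(config$metadata_path)

  if (!is.null(genomes)) {
    if ("ANIb" %in% config$measures) {
      logf("computing fragment-ANI matrix for %d genomes", length(genomes))
      matrices$ANIb <- anib_matrix(genomes)
      thresholds$ANIb <- config$ani_radii
    }
    if ("TETRA" %in% config$measures) {
      logf("computing tetranucleotide correlation matrix")
      matrices$TETRA <- tetra_matrix(genomes)
      thresholds$TETRA <- config$tetra_radii
    }
    if ("GBDP" %in% config$measures) {
      logf("computing GBDP distance matrix")
      g <- gbdp_matrix(genomes, seed = config$seed)
      matrices$dDDH <- g$ddh
      thresholds$dDDH <- c(config$ddh_radius, config$ddh_ci)
    }
  } else {
    matrices[[config$matrix_kind]] <-
      read_labeled_matrix(config$matrix_path, config$matrix_kind)
    thresholds[[config$matrix_kind]] <-
      if (config$matrix_kind == "dDDH") c(config$ddh_radius, config$ddh_ci)
      else if (config$matrix_kind == "TETRA") config$tetra_radii
      else config$ani_radii
  }
  for (kind in names(matrices))
    write_labeled_matrix(matrices[[kind]],
                         file.path(config$out_dir,
                                   paste0("matrix_", kind, ".tsv")))

  # primary measure for the headline partition: highest-resolution available
  primary_kind <- intersect(c("dDDH", "ANIb", "ANIm", "TETRA",
                              names(matrices)), names(matrices))[1L]
  primary <- matrices[[primary_kind]]
  primary_threshold <- if (config$mode %in% c("simulate", "genomes") &&
                           primary_kind %in% c("ANIb", "ANIm")) {
    max(config$ani_radii)
  } else thresholds[[primary_kind]][1L]

  report <- list(); recovery <- NULL
  ref_membership <- if (!is.null(truth)) truth$species_of else NULL
  for (kind in names(matrices)) {
    sweep <- threshold_sweep(matrices[[kind]], metadata,
                             thresholds = thresholds[[kind]],
                             fraction = config$fraction,
                             reference = ref_membership)
    sweep <- cbind(measure = kind, sweep)
    report[[kind]] <- sweep
  }
  report <- do.call(rbind, report)
  report$seed <- config$seed
  utils::write.table(report, file.path(config$out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  partition <- delineate_species(primary, metadata,
                                 threshold = primary_threshold,
                                 fraction = config$fraction)
  sub_cutoff <- if (!is.null(truth) && primary_kind %in% c("ANIb", "ANIm"))
    equivalent_cutoff(truth, "subspecies") else config$subspecies_cutoff
  subspecies <- delineate_subspecies(primary, partition,
                                     cutoff = sub_cutoff,
                                     fraction = config$fraction)
  jsonlite::write_json(
    list(params = partition$params,
         clusters = partition$clusters,
         novel = as.list(partition$novel),
         putative_types = partition$putative_types,
         ambiguities = partition$ambiguities,
         subspecies = subspecies$clusters,
         nontrivial_subspecies = subspecies$nontrivial_count,
         seed = config$seed),
    file.path(config$out_dir, "partition.json"), auto_unbox = TRUE)

  tree <- upgma(as_distance_matrix(primary))
  write_newick(tree, file.path(config$out_dir,
                               paste0("upgma_", primary_kind, ".nwk")))

  biogeo <- NULL
  if (!is.null(metadata)) {
    known <- unique(c(names(default_macroregion_map()), "unknown"))
    map <- default_macroregion_map()
    extra <- setdiff(unique(metadata$region), known)
    if (length(extra)) map[extra] <- extra  # unmapped regions are their own macro-region
    biogeo <- classify_distribution(partition, metadata, region_map = map)
    utils::write.table(biogeo, file.path(config$out_dir, "biogeo.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(truth)) {
    recovery <- list(
      species = compare_partitions(partition, truth$species_of),
      subspecies = compare_partitions(subspecies, truth$subspecies_of))
    logf("species ARI=%.3f subspecies ARI=%.3f",
         recovery$species$adjusted_rand, recovery$subspecies$adjusted_rand)
  }
  logf("done")
  invisible(list(matrices = matrices, partition = partition,
                 subspecies = subspecies, report = report, biogeo = biogeo,
                 truth = truth, recovery = recovery,
                 out_dir = config$out_dir))
}
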