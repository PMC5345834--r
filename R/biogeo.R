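#' Default macro-region map for isolation sites
#'
#' Maps the isolation regions of the soda-lake strain collections to
#' macro-regions: the Central Asian steppe lakes, East African and North
#' African lake districts, the North American alkaline lakes, and engineered
#' (bioreactor) systems. Override by passing your own named vector to
#' [classify_distribution()].
#'
#' @return named character vector (region -> macro-region).
#' @export
default_macroregion_map <- function() {
  c("Kulunda Steppe" = "Central Asia",
    "Buriatia" = "Central Asia",
    "Transbaikal" = "Central Asia",
    "Mongolia" = "Central Asia",
    "Kenya" = "East Africa",
    "Egypt (Wadi Natrun)" = "North Africa",
    "California (Mono, Searles)" = "North America",
    "bioreactor" = "Engineered")
}

#' Classify the biogeographic distribution of genomic species
#'
#' A species cluster whose located members all come from one macro-region is
#' a *candidate endemic*; members from two or more macro-regions make it a
#' *candidate disjunct*. Strains with region `"unknown"` are excluded from
#' the verdict; clusters with fewer than `min_confident` located strains
#' keep their provisional verdict but are flagged not confident (too few
#' isolates to say anything about dispersion).
#'
#' @param species a `species_partition` (or named list of clusters).
#' @param metadata strain table as in [read_metadata()].
#' @param region_map named vector region -> macro-region.
#' @param min_confident minimum located strains for a confident verdict.
#' @return data.frame with one row per cluster: `cluster`, `n_strains`,
#'   `n_located`, `macro_regions`, `verdict`, `confident`.
#' @export
classify_distribution <- function(species, metadata,
                                  region_map = default_macroregion_map(),
                                  min_confident = 4L) {
  clusters <- if (inherits(species, "species_partition"))
    species$clusters else species
  metadata <- validate_metadata(metadata)
  region <- stats::setNames(metadata$region, metadata$strain_id)
  bad <- setdiff(unique(region), c(names(region_map), "unknown"))
  if (length(bad))
    stop("region(s) not in region map: ", paste(bad, collapse = ", "))
  rows <- lapply(names(clusters), function(cl) {
    members <- sort(clusters[[cl]])
    regs <- region[members]
    located <- regs[regs != "unknown" & !is.na(regs)]
    macros <- sort(unique(unname(region_map[located])))
    verdict <- if (!length(macros)) "insufficient-data"
      else if (length(macros) == 1L) "candidate-endemic"
      else "candidate-disjunct"
    data.frame(cluster = cl,
               n_strains = length(members),
               n_located = length(located),
               macro_regions = paste(macros, collapse = "/"),
               verdict = verdict,
               confident = length(located) >= min_confident,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
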