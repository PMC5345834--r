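#' Threshold-linkage clustering with a linkage fraction
#'
#' Two strains are *linked* when their pairwise distance is smaller than or
#' equal to the threshold `T`. Starting from singletons, the procedure
#' repeatedly merges the pair of clusters A, B with the largest inter-cluster
#' link fraction `f(A,B) = links(A,B) / (|A| * |B|)`, provided `f >= F` and
#' `f > 0`; ties are broken by the smaller mean inter-cluster distance, then
#' by the lexicographically smallest pair of cluster label minima, so the
#' result is fully deterministic. At `F = 0` the result equals the connected
#' components of the link graph (single linkage: one link suffices); at
#' `F = 1` every intra-cluster pair of the result is a link
#' (complete-linkage behaviour).
#'
#' @param dist a distance [labeled_matrix()] (or plain symmetric labeled
#'   numeric matrix).
#' @param threshold distance threshold `T` (convert stated similarity
#'   thresholds with [threshold_to_distance()] first).
#' @param fraction required link fraction `F` in \[0, 1\].
#' @return list of character vectors (cluster members, each sorted), ordered
#'   by their smallest label.
#' @export
fraction_linkage_cluster <- function(dist, threshold, fraction = 0.5) {
  m <- unclass(dist)
  if (!is.matrix(m) || is.null(rownames(m)))
    stop("'dist' must be a labeled square matrix")
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix is not symmetric")
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  labs <- rownames(m)
  link <- m <= threshold
  diag(link) <- FALSE
  clusters <- as.list(labs)

  repeat {
    k <- length(clusters)
    if (k < 2L) break
    best <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        A <- clusters[[i]]; B <- clusters[[j]]
        nl <- sum(link[A, B, drop = FALSE])
        f <- nl / (length(A) * length(B))
        if (f <= 0 || f < fraction) next
        md <- mean(m[A, B, drop = FALSE])
        key <- paste(sort(c(min(A), min(B))), collapse = "\r")
        if (is.null(best) ||
            f > best$f + 1e-12 ||
            (abs(f - best$f) <= 1e-12 && md < best$md - 1e-12) ||
            (abs(f - best$f) <= 1e-12 && abs(md - best$md) <= 1e-12 &&
             key < best$key)) {
          best <- list(i = i, j = j, f = f, md = md, key = key)
        }
      }
    }
    if (is.null(best)) break
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- clusters[-c(best$i, best$j)]
    clusters <- c(clusters, list(merged))
  }
  clusters <- lapply(clusters, sort)
  clusters[order(vapply(clusters, min, character(1L)))]
}

#' Affiliate strains to type-strain radii
#'
#' A strain is affiliated to a type strain when its similarity to the type
#' is at least the type's radius threshold (equivalently, distance at most
#' the converted radius). Strains inside two or more radii are ambiguities;
#' strains inside none are candidates for novel species.
#'
#' @param matrix a similarity [labeled_matrix()].
#' @param types named numeric vector: names are type strain ids (must be
#'   matrix labels), values the radius threshold on the matrix scale.
#' @return list with `affiliation` (named list: strain -> type ids whose
#'   radius contains it), `ambiguities` (data.frame `strain`, `types`) and
#'   `novel_candidates` (strains in no radius).
#' @export
type_radius_affiliate <- function(matrix, types) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  if (is.null(names(types)) || !length(types)) stop("'types' must be named")
  miss <- setdiff(names(types), rownames(matrix))
  if (length(miss)) stop("unknown type id(s): ", paste(miss, collapse = ", "))
  labs <- rownames(matrix)
  sim <- unclass(matrix)
  aff <- lapply(labs, function(s) {
    names(types)[sim[s, names(types)] >= types]
  })
  names(aff) <- labs
  amb_strains <- labs[vapply(aff, length, integer(1L)) >= 2L]
  ambiguities <- data.frame(
    strain = amb_strains,
    types = vapply(aff[amb_strains], paste, character(1L), collapse = "/"),
    stringsAsFactors = FALSE
  )
  list(affiliation = aff,
       ambiguities = ambiguities,
       novel_candidates = labs[vapply(aff, length, integer(1L)) == 0L])
}

#' Delineate genomic species by type radius plus de-novo clustering
#'
#' Three steps. (1) Every strain is tested against the radius of each
#' described type strain; strains inside at least one radius are assigned to
#' the most similar type. (2) The unaffiliated strains are de-novo clustered
#' by [fraction_linkage_cluster()] at the same threshold with linkage
#' fraction `fraction`; each resulting cluster is a putative novel species.
#' (3) Within each novel cluster one member is retained as the putative type
#' (PT) — preferentially a strain whose radius captures exactly its own
#' cluster, otherwise the strain with the largest within-cluster minimum
#' similarity, lowest label on ties — and the radius affiliation is re-run
#' over all strains with described types plus retained PTs; strains inside
#' two or more radii are recorded as ambiguities.
#'
#' @param matrix a similarity [labeled_matrix()] (hybridization-scale,
#'   percent-identity or tetranucleotide-correlation kinds).
#' @param metadata strain table as in [read_metadata()]; `is_type` rows are
#'   the described types. May be `NULL` for fully de-novo clustering.
#' @param threshold species radius on the similarity scale of the matrix
#'   (e.g. 70 for the hybridization scale, 96 for nucleotide identity,
#'   0.999 for tetranucleotide correlation).
#' @param fraction linkage fraction `F` for the de-novo step.
#' @return object of class `species_partition`: list with `clusters` (named
#'   list of member vectors), `novel` (logical per cluster), `types` (type
#'   or putative type anchoring each cluster; `NA` for anchorless clusters),
#'   `putative_types`, `affiliation`, `ambiguities`, `params`.
#' @export
delineate_species <- function(matrix, metadata = NULL, threshold,
                              fraction = 0.5) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  labs <- rownames(matrix)
  sim <- unclass(matrix)
  kind <- attr(matrix, "kind")
  described <- character()
  if (!is.null(metadata)) {
    metadata <- validate_metadata(metadata)
    miss <- setdiff(metadata$strain_id, labs)
    if (length(miss))
      stop("metadata strain(s) not in matrix: ", paste(miss, collapse = ", "))
    described <- metadata$strain_id[metadata$is_type]
  }
  if (!length(labs)) stop("empty matrix")

  # step 1: affiliation to described types
  if (length(described)) {
    aff1 <- type_radius_affiliate(matrix,
                                  stats::setNames(rep(threshold,
                                                      length(described)),
                                                  described))
    unaffiliated <- aff1$novel_candidates
    assigned <- setdiff(labs, unaffiliated)
  } else {
    unaffiliated <- labs
    assigned <- character()
  }

  # step 2: de-novo clustering of the unaffiliated strains
  novel_clusters <- list()
  if (length(unaffiliated) == 1L) {
    novel_clusters <- list(unaffiliated)
  } else if (length(unaffiliated)) {
    dsub <- as_distance_matrix(matrix[unaffiliated, unaffiliated])
    novel_clusters <- fraction_linkage_cluster(
      dsub, threshold_to_distance(threshold, kind), fraction)
  }

  # step 3: putative type per novel cluster, then full re-affiliation
  ptypes <- vapply(novel_clusters, function(cl) {
    captured <- lapply(cl, function(s) labs[sim[s, ] >= threshold])
    exact <- vapply(captured, function(cap) setequal(cap, cl), logical(1L))
    cand <- cl[exact]
    if (!length(cand)) {
      minsim <- vapply(cl, function(s) min(sim[s, cl]), numeric(1L))
      cand <- cl[minsim == max(minsim)]
    }
    sort(cand)[1L]
  }, character(1L))

  anchors <- c(described, ptypes)
  if (!length(anchors)) stop("no described types and no strains to cluster")
  aff <- type_radius_affiliate(matrix,
                               stats::setNames(rep(threshold, length(anchors)),
                                               anchors))

  # final partition: affiliated strains go to their most similar anchor;
  # novel-cluster members stay with their de-novo cluster
  member_of <- stats::setNames(rep(NA_character_, length(labs)), labs)
  for (cl_i in seq_along(novel_clusters))
    member_of[novel_clusters[[cl_i]]] <- ptypes[cl_i]
  for (s in assigned) {
    within <- intersect(aff$affiliation[[s]], described)
    if (!length(within)) within <- described
    member_of[s] <- within[which.max(sim[s, within])]
  }

  anchor_order <- c(sort(described), sort(ptypes))
  clusters <- lapply(anchor_order, function(a)
    sort(names(member_of)[member_of == a]))
  keep <- vapply(clusters, length, integer(1L)) > 0L
  clusters <- clusters[keep]; anchor_order <- anchor_order[keep]
  names(clusters) <- sprintf("cluster_%02d", seq_along(clusters))

  structure(list(
    clusters = clusters,
    types = stats::setNames(anchor_order, names(clusters)),
    novel = stats::setNames(anchor_order %in% ptypes, names(clusters)),
    putative_types = ptypes,
    affiliation = aff$affiliation,
    ambiguities = aff$ambiguities,
    params = list(kind = kind, threshold = threshold, fraction = fraction)
  ), class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  cat(sprintf(
    "species_partition: %d clusters (%d novel), %d strains, %d ambiguous strain(s)\n",
    length(x$clusters), sum(x$novel),
    length(unlist(x$clusters)), nrow(x$ambiguities)))
  cat(sprintf("  [%s radius %s, linkage fraction %s]\n",
              x$params$kind, format(x$params$threshold),
              format(x$params$fraction)))
  invisible(x)
}

#' @export
summary.species_partition <- function(object, ...) {
  sizes <- vapply(object$clusters, length, integer(1L))
  df <- data.frame(cluster = names(object$clusters),
                   anchor = unname(object$types),
                   novel = unname(object$novel),
                   n_strains = unname(sizes),
                   members = vapply(object$clusters, paste, character(1L),
                                    collapse = ","),
                   stringsAsFactors = FALSE, row.names = NULL)
  print(object)
  df
}

#' Cluster membership as a named vector
#'
#' @param partition a `species_partition`, `subspecies_partition`, a named
#'   list of member vectors, or an already-named membership vector.
#' @return named vector mapping strain to cluster id.
#' @export
partition_membership <- function(partition) {
  if (inherits(partition, "species_partition") ||
      inherits(partition, "subspecies_partition"))
    partition <- partition$clusters
  if (is.list(partition)) {
    if (is.null(names(partition)))
      names(partition) <- sprintf("cluster_%02d", seq_along(partition))
    out <- rep(names(partition), lengths(partition))
    names(out) <- unlist(partition)
    return(out)
  }
  if (is.null(names(partition))) stop("membership vector must be named")
  partition
}

#' Delineate subspecies within genomic species
#'
#' Within every species cluster of two or more strains, the strains are
#' re-clustered by [fraction_linkage_cluster()] at the subspecies cutoff
#' (79 on the hybridization-like percent scale by convention). Singleton
#' sub-clusters are recorded but never counted, and an undivided species
#' contributes no subspecies: `nontrivial_count` is the number of
#' sub-clusters with at least two strains inside species that are actually
#' subdivided.
#'
#' @param matrix similarity [labeled_matrix()] on the scale of `cutoff`.
#' @param species a `species_partition` (or named list of clusters).
#' @param cutoff subspecies similarity cutoff.
#' @param fraction linkage fraction.
#' @return object of class `subspecies_partition`: list with `by_species`
#'   (list of sub-cluster lists), `clusters` (flat named list),
#'   `nontrivial_count`.
#' @export
delineate_subspecies <- function(matrix, species, cutoff = 79,
                                 fraction = 0.5) {
  stopifnot(inherits(matrix, "labeled_matrix"))
  clusters <- if (inherits(species, "species_partition"))
    species$clusters else species
  miss <- setdiff(unlist(clusters), rownames(matrix))
  if (length(miss))
    stop("strain(s) missing from matrix: ", paste(miss, collapse = ", "))
  kind <- attr(matrix, "kind")
  tdist <- threshold_to_distance(cutoff, kind)
  by_species <- lapply(clusters, function(cl) {
    if (length(cl) < 2L) return(list(cl))
    dsub <- as_distance_matrix(matrix[cl, cl])
    fraction_linkage_cluster(dsub, tdist, fraction)
  })
  nontrivial <- sum(vapply(by_species, function(subs) {
    if (length(subs) < 2L) return(0L)
    sum(lengths(subs) >= 2L)
  }, integer(1L)))
  flat <- list(); k <- 0L
  for (sp in names(by_species)) for (i in seq_along(by_species[[sp]])) {
    k <- k + 1L
    flat[[sprintf("%s.%d", sp, i)]] <- by_species[[sp]][[i]]
  }
  structure(list(by_species = by_species, clusters = flat,
                 nontrivial_count = nontrivial,
                 params = list(kind = kind, cutoff = cutoff,
                               fraction = fraction)),
            class = "subspecies_partition")
}

#' @export
print.subspecies_partition <- function(x, ...) {
  cat(sprintf(
    "subspecies_partition: %d sub-clusters in %d species; %d non-trivial subspecies\n",
    length(x$clusters), length(x$by_species), x$nontrivial_count))
  invisible(x)
}

#' Sweep delineation thresholds
#'
#' Runs [delineate_species()] at each threshold and tabulates cluster,
#' novel-cluster and ambiguous-strain counts, plus agreement with an
#' optional reference partition.
#'
#' @inheritParams delineate_species
#' @param thresholds numeric vector of similarity thresholds.
#' @param reference optional reference partition (any form accepted by
#'   [partition_membership()]).
#' @return data.frame with one row per threshold.
#' @export
threshold_sweep <- function(matrix, metadata = NULL, thresholds,
                            fraction = 0.5, reference = NULL) {
  if (!length(thresholds)) stop("need at least one threshold")
  rows <- lapply(thresholds, function(th) {
    p <- delineate_species(matrix, metadata, threshold = th,
                           fraction = fraction)
    row <- data.frame(threshold = th,
                      n_clusters = length(p$clusters),
                      n_novel = sum(p$novel),
                      n_ambiguous_strains = nrow(p$ambiguities))
    if (!is.null(reference)) {
      cmp <- compare_partitions(p, reference)
      row$exact_match <- cmp$exact_match
      row$adjusted_rand <- cmp$adjusted_rand
    }
    row
  })
  do.call(rbind, rows)
}

#' Compare two partitions of the same strain set
#'
#' Exact equality as set-of-sets, the adjusted Rand index by the standard
#' contingency-table formula, and the strains whose co-membership pattern
#' differs between the two partitions.
#'
#' @param a,b partitions in any form accepted by [partition_membership()].
#' @return list with `exact_match`, `adjusted_rand`, `discordant_strains`.
#' @export
compare_partitions <- function(a, b) {
  ma <- partition_membership(a)
  mb <- partition_membership(b)
  if (!setequal(names(ma), names(mb)))
    stop("partitions cover different strain sets")
  mb <- mb[names(ma)]
  tab <- table(ma, mb)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- length(ma)
  expected <- ai * bj / choose(n, 2)
  maxi <- (ai + bj) / 2
  ari <- if (abs(maxi - expected) < 1e-12) 1 else
    (nij - expected) / (maxi - expected)
  sets_a <- lapply(split(names(ma), ma), sort)
  sets_b <- lapply(split(names(mb), mb), sort)
  exact <- length(sets_a) == length(sets_b) &&
    all(vapply(sets_a, function(s)
      any(vapply(sets_b, identical, logical(1L), s)), logical(1L)))
  disc <- character()
  if (!exact && n > 1L) {
    same_a <- outer(ma, ma, "==")
    same_b <- outer(mb, mb, "==")
    bad <- same_a != same_b
    disc <- sort(names(ma)[rowSums(bad) > 0L])
  }
  list(exact_match = exact, adjusted_rand = unname(ari),
       discordant_strains = disc)
}
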