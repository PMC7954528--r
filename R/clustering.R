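#' @include skeleton.R
NULL

#' Pairwise along-neurite distances between synapses
#'
#' Entry (i, j) is the path distance between the attachment nodes of
#' synapses i and j, measured along the neurites.  Synapses sharing a node
#' have distance 0 (and therefore always co-cluster at any positive d_nn).
#'
#' @param skeleton a [Skeleton-class].
#' @param table a [SynapseTable-class].
#' @return symmetric numeric matrix (um) with synapse ids as dimnames.
#' @export
pairwiseDistances <- function(skeleton, table) {
  stopifnot(is(table, "SynapseTable"))
  r <- table@records
  .checkNodes(skeleton, r$attach_node)
  un <- unique(r$attach_node)
  d <- .pathDistances(skeleton, un, un)
  m <- d[as.character(r$attach_node), as.character(r$attach_node),
         drop = FALSE]
  dimnames(m) <- list(r$synapse_id, r$synapse_id)
  diag(m) <- 0
  m
}

.checkDistanceMatrix <- function(distances) {
  if (!is.matrix(distances) || nrow(distances) != ncol(distances))
    stop("distances must be a square matrix")
  if (nrow(distances) && is.null(rownames(distances)))
    stop("distances must carry synapse ids as dimnames")
  if (nrow(distances) && (any(distances < 0) ||
      max(abs(distances - t(distances))) > 1e-8 ||
      any(diag(distances) != 0)))
    stop("distances must be symmetric, nonnegative, with zero diagonal")
  invisible(TRUE)
}

#' Constrained single-linkage clustering of synapses
#'
#' Agglomerative single-linkage clustering under the along-neurite metric
#' with two constraints: clusters are only joined while the single-linkage
#' distance between their most proximal elements is at most \code{d_nn}
#' (maximum nearest-neighbor distance) and the merged cluster's extent
#' (maximum pairwise distance) is at most \code{d_ext}.  Starting from
#' singletons, the admissible pair with minimal linkage is merged each step;
#' if the globally minimal pair would exceed \code{d_ext} it is skipped and
#' the next admissible pair is merged.  Aggregation stops when no admissible
#' pair remains.  Ties in linkage are broken deterministically towards the
#' pair whose smallest member synapse (in the row order of
#' \code{distances}) is lowest, then the second.
#'
#' @param distances symmetric matrix of pairwise path distances (um) with
#'   synapse ids as dimnames, e.g. from [pairwiseDistances()].
#' @param d_nn maximum allowed nearest-neighbor distance (um), > 0.
#' @param d_ext maximum overall cluster extent (um), > 0.
#' @return a [ClusterSet-class]; the clusters partition the input synapses.
#' @examples
#' d <- as.matrix(dist(c(0, 4, 9, 15)))
#' dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
#' clusterSynapses(d, d_nn = 5, d_ext = 10)
#' @export
clusterSynapses <- function(distances, d_nn, d_ext) {
  stopifnot(length(d_nn) == 1, length(d_ext) == 1, d_nn > 0, d_ext > 0)
  .checkDistanceMatrix(distances)
  params <- c(d_nn = as.numeric(d_nn), d_ext = as.numeric(d_ext))
  if (nrow(distances) == 0L)
    return(new("ClusterSet", members = list(), extents = numeric(0),
               params = params,
               mergeLog = data.frame(linkage = numeric(0),
                                     extent = numeric(0))))
  res <- .slink_constrained_cpp(distances, d_nn, d_ext)
  ids <- rownames(distances)
  members <- split(ids, res$assign)
  names(members) <- NULL
  new("ClusterSet", members = members, extents = as.numeric(res$extent),
      params = params,
      mergeLog = data.frame(linkage = res$merge_linkage,
                            extent = res$merge_extent))
}

# partners per cluster as list of character vectors (distinct per cluster)
.clusterPartners <- function(clusters, table) {
  r <- table@records
  pmap <- setNames(r$partner_id, r$synapse_id)
  lapply(clusters@members, function(ids) unique(unname(pmap[ids])))
}

.subsetClusterSet <- function(clusters, keep) {
  new("ClusterSet", members = clusters@members[keep],
      extents = clusters@extents[keep], params = clusters@params,
      mergeLog = clusters@mergeLog)
}

#' Filter clusters for the F-ratio analysis
#'
#' Removes clusters with synapses from only one presynaptic partner or with
#' a single synapse; retained clusters have at least two synapses and at
#' least two distinct partners.
#'
#' @param clusters a [ClusterSet-class].
#' @param table the [SynapseTable-class] resolving partner ids.
#' @return the filtered [ClusterSet-class].
#' @export
filterForFRatio <- function(clusters, table) {
  stopifnot(is(clusters, "ClusterSet"), is(table, "SynapseTable"))
  np <- lengths(.clusterPartners(clusters, table))
  keep <- lengths(clusters@members) >= 2L & np >= 2L
  .subsetClusterSet(clusters, keep)
}

#' Keep only multi-synapse clusters
#'
#' Clusters comprising a single synapse are dropped (used for the
#' cluster-size tabulations).
#'
#' @param clusters a [ClusterSet-class].
#' @return the filtered [ClusterSet-class].
#' @export
filterMultiSynapse <- function(clusters) {
  stopifnot(is(clusters, "ClusterSet"))
  .subsetClusterSet(clusters, lengths(clusters@members) >= 2L)
}

#' Frequency table of cluster sizes
#'
#' One row per observed synapse count: how many clusters have that many
#' synapses, and the multiset of distinct-partner counts among them,
#' formatted like \code{"1 (6x), 2 (3x)"}.
#'
#' @param clusters a (typically filtered) [ClusterSet-class].
#' @param table the [SynapseTable-class] resolving partner ids.
#' @return data.frame with columns \code{synapse_count}, \code{frequency},
#'   \code{partner_counts}.
#' @export
clusterSizeTable <- function(clusters, table) {
  stopifnot(is(clusters, "ClusterSet"), is(table, "SynapseTable"))
  sizes <- lengths(clusters@members)
  if (!length(sizes))
    return(data.frame(synapse_count = integer(0), frequency = integer(0),
                      partner_counts = character(0)))
  np <- lengths(.clusterPartners(clusters, table))
  out <- lapply(sort(unique(sizes)), function(s) {
    sel <- sizes == s
    tab <- table(np[sel])
    data.frame(synapse_count = s, frequency = sum(sel),
               partner_counts = paste(sprintf("%s (%dx)", names(tab),
                                              as.integer(tab)),
                                      collapse = ", "))
  })
  do.call(rbind, out)
}
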