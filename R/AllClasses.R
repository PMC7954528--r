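#' @include synarbor-package.R
NULL

.VALENCES <- c("excitatory", "inhibitory", "unknown")
.BEHAVIORS <- c("swim", "crawl", "local_bend")
.NODE_TAGS <- c("soma", "neurite", "axon_exit")

# ---------------------------------------------------------------------------
# Skeleton
# ---------------------------------------------------------------------------

#' Skeleton: a rooted tree tracing of a neuron
#'
#' Nodes carry 3D positions in micrometres; every non-root node has a parent
#' and an edge length equal to the Euclidean distance between the node and
#' its parent.  The root is the soma; at most one node may be tagged
#' \code{axon_exit} (the point where the axon leaves the ganglion), which
#' anchors the primary neurite.
#'
#' @slot nodes data.frame with columns \code{node_id} (integer),
#'   \code{parent_id} (integer, \code{NA} for the root), \code{x},\code{y},
#'   \code{z} (micrometres), \code{radius} (micrometres, may be \code{NA}),
#'   \code{tag} (one of \code{soma}, \code{neurite}, \code{axon_exit}).
#' @slot edgeLengths named numeric; one entry per non-root node (name =
#'   node id), the distance to its parent in micrometres.  All positive.
#'
#' @seealso [readSWC()], [Skeleton()], [cableLength()], [pathDistance()]
#' @exportClass Skeleton
setClass("Skeleton",
         representation(nodes = "data.frame", edgeLengths = "numeric"))

setValidity("Skeleton", function(object) {
  nd <- object@nodes
  need <- c("node_id", "parent_id", "x", "y", "z", "radius", "tag")
  if (!all(need %in% names(nd)))
    return(paste("nodes must have columns:", paste(need, collapse = ", ")))
  if (nrow(nd) == 0L) return("skeleton has no nodes")
  if (anyDuplicated(nd$node_id)) return("duplicate node ids")
  roots <- which(is.na(nd$parent_id))
  if (length(roots) != 1L)
    return(sprintf("skeleton must have exactly one root, found %d",
                   length(roots)))
  if (nd$tag[roots] != "soma") return("the root node must be tagged 'soma'")
  if (sum(nd$tag == "soma") != 1L)
    return("exactly one node may be tagged 'soma'")
  if (sum(nd$tag == "axon_exit") > 1L)
    return("at most one node may be tagged 'axon_exit'")
  if (!all(nd$tag %in% .NODE_TAGS))
    return("node tags must be one of soma/neurite/axon_exit")
  kids <- nd$node_id[-roots]
  pars <- nd$parent_id[-roots]
  if (length(kids) && !all(pars %in% nd$node_id))
    return("dangling parent references")
  el <- object@edgeLengths
  if (length(el) != nrow(nd) - 1L)
    return("edgeLengths must have one entry per non-root node")
  if (length(el)) {
    if (is.null(names(el)) || !setequal(names(el), as.character(kids)))
      return("edgeLengths names must be the non-root node ids")
    if (any(!is.finite(el)) || any(el <= 0))
      return("all edge lengths must be positive and finite")
  }
  # acyclicity / connectivity: walking parent pointers from every node must
  # reach the root without revisiting
  idx <- match(nd$parent_id, nd$node_id)
  depth <- rep(NA_integer_, nrow(nd)); depth[roots] <- 0L
  remaining <- TRUE; guard <- 0L
  while (remaining && guard <= nrow(nd)) {
    newly <- which(is.na(depth) & !is.na(depth[idx]))
    if (!length(newly)) remaining <- FALSE else depth[newly] <- depth[idx[newly]] + 1L
    guard <- guard + 1L
  }
  if (anyNA(depth)) return("skeleton is not a single connected tree (cycle or orphan)")
  TRUE
})

#' Construct a Skeleton from a node table
#'
#' @param nodes data.frame with columns node_id, parent_id, x, y, z and
#'   optionally radius and tag (default tag: root = soma, others = neurite).
#' @return a validated [Skeleton-class] object; edge lengths are computed as
#'   Euclidean distances between each node and its parent.
#' @examples
#' sk <- Skeleton(data.frame(node_id = 1:3, parent_id = c(NA, 1, 2),
#'                           x = c(0, 1, 2), y = 0, z = 0))
#' cableLength(sk)
#' @export
Skeleton <- function(nodes) {
  nodes <- as.data.frame(nodes)
  if (!"radius" %in% names(nodes)) nodes$radius <- NA_real_
  if (!"tag" %in% names(nodes)) {
    nodes$tag <- ifelse(is.na(nodes$parent_id), "soma", "neurite")
  }
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  for (cc in c("x", "y", "z", "radius")) nodes[[cc]] <- as.numeric(nodes[[cc]])
  nodes$tag <- as.character(nodes$tag)
  nonroot <- !is.na(nodes$parent_id)
  pidx <- match(nodes$parent_id[nonroot], nodes$node_id)
  el <- sqrt((nodes$x[nonroot] - nodes$x[pidx])^2 +
             (nodes$y[nonroot] - nodes$y[pidx])^2 +
             (nodes$z[nonroot] - nodes$z[pidx])^2)
  names(el) <- as.character(nodes$node_id[nonroot])
  new("Skeleton", nodes = nodes, edgeLengths = el)
}

# ---------------------------------------------------------------------------
# SynapseTable
# ---------------------------------------------------------------------------

#' SynapseTable: annotated input synapses on a skeleton
#'
#' Each record ties one synapse to its attachment node on the postsynaptic
#' skeleton, the identity of the presynaptic partner, and optional valence
#' and behavior annotations.
#'
#' @slot records data.frame with columns \code{synapse_id} (unique),
#'   \code{attach_node} (integer node id), \code{partner_id} (nonempty),
#'   \code{valence} (excitatory/inhibitory/unknown) and
#'   \code{behavior_label} (swim/crawl/local_bend/unassigned).
#' @seealso [SynapseTable()], [readSynapseTable()], [pairwiseDistances()]
#' @exportClass SynapseTable
setClass("SynapseTable", representation(records = "data.frame"))

setValidity("SynapseTable", function(object) {
  r <- object@records
  need <- c("synapse_id", "attach_node", "partner_id", "valence",
            "behavior_label")
  if (!all(need %in% names(r)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$synapse_id)) return("synapse ids must be unique")
  if (any(is.na(r$partner_id) | !nzchar(r$partner_id)))
    return("partner_id must be nonempty for every synapse")
  if (!all(r$valence %in% .VALENCES))
    return("valence must be excitatory/inhibitory/unknown")
  if (!all(r$behavior_label %in% c(.BEHAVIORS, "unassigned")))
    return("behavior_label must be swim/crawl/local_bend/unassigned")
  TRUE
})

#' Construct a SynapseTable
#'
#' @param records data.frame with columns synapse_id, attach_node,
#'   partner_id, and optionally valence and behavior_label.
#' @param skeleton optional [Skeleton-class]; if given, attachment nodes are
#'   checked to exist on it.
#' @return a validated [SynapseTable-class].
#' @export
SynapseTable <- function(records, skeleton = NULL) {
  records <- as.data.frame(records)
  if (!"valence" %in% names(records)) records$valence <- "unknown"
  if (!"behavior_label" %in% names(records)) records$behavior_label <- "unassigned"
  records$synapse_id <- as.character(records$synapse_id)
  records$attach_node <- as.integer(records$attach_node)
  records$partner_id <- as.character(records$partner_id)
  obj <- new("SynapseTable", records = records)
  if (!is.null(skeleton)) {
    bad <- setdiff(records$attach_node, skeleton@nodes$node_id)
    if (length(bad))
      stop("attach_node not on skeleton: ", paste(head(bad, 5), collapse = ", "))
  }
  obj
}

# ---------------------------------------------------------------------------
# Spectral types
# ---------------------------------------------------------------------------

#' SpectralOptions: multitaper settings
#'
#' @slot timeBandwidth time-bandwidth product NW (dimensionless, > 1).
#' @slot nTapers number of Slepian tapers K, with K <= 2NW - 1.
#' @slot detrendOrder polynomial order removed before spectral analysis
#'   (captures bleaching trends; 0 = mean only).
#' @slot searchBand numeric length 2, (f_lo, f_hi) in Hz, the band searched
#'   for the reference cell's dominant frequency.
#' @seealso [spectralOptions()], [multitaperPSD()], [coherenceAt()]
#' @exportClass SpectralOptions
setClass("SpectralOptions",
         representation(timeBandwidth = "numeric", nTapers = "integer",
                        detrendOrder = "integer", searchBand = "numeric"))

setValidity("SpectralOptions", function(object) {
  if (object@timeBandwidth <= 1) return("timeBandwidth must exceed 1")
  if (object@nTapers < 1L) return("nTapers must be positive")
  if (object@nTapers > 2 * object@timeBandwidth - 1)
    return("nTapers must not exceed 2*timeBandwidth - 1")
  if (object@detrendOrder < 0L) return("detrendOrder must be >= 0")
  b <- object@searchBand
  if (length(b) != 2 || !(b[1] >= 0 && b[1] < b[2]))
    return("searchBand must be (f_lo, f_hi) with 0 <= f_lo < f_hi")
  TRUE
})

#' Multitaper spectral options
#'
#' Defaults bracket the rhythms of the three fictive behaviors (the swim
#' rhythm runs near 2 Hz; crawling is more than an order of magnitude
#' slower).  Behavior-specific dominant-frequency search bands are available
#' through [defaultSearchBand()].
#'
#' @param timeBandwidth time-bandwidth product NW (default 4).
#' @param nTapers number of Slepian tapers (default 7 = 2NW - 1).
#' @param detrendOrder polynomial detrend order (default 2).
#' @param searchBand frequency band (Hz) searched for the dominant peak.
#' @return a [SpectralOptions-class] object.
#' @export
spectralOptions <- function(timeBandwidth = 4, nTapers = 7L,
                            detrendOrder = 2L, searchBand = c(0.5, 3)) {
  new("SpectralOptions", timeBandwidth = as.numeric(timeBandwidth),
      nTapers = as.integer(nTapers), detrendOrder = as.integer(detrendOrder),
      searchBand = as.numeric(searchBand))
}

#' Default dominant-frequency search band per behavior
#'
#' @param behavior one of "swim", "crawl", "local_bend".
#' @return numeric length 2, (f_lo, f_hi) in Hz.
#' @export
defaultSearchBand <- function(behavior = c("swim", "crawl", "local_bend")) {
  behavior <- match.arg(behavior)
  switch(behavior,
         swim = c(0.5, 3),
         crawl = c(0.02, 0.5),
         local_bend = c(0.05, 2))
}

#' TrialRecording: one optical-imaging trial
#'
#' @slot trialId identifier.
#' @slot behavior one of swim/crawl/local_bend.
#' @slot dt sample interval in seconds.
#' @slot traces numeric matrix, samples x cells, column names = cell ids;
#'   values are relative fluorescence change (dimensionless).
#' @slot referenceCell the hub cell against which coherence is computed.
#' @seealso [trialRecording()], [coherenceMap()]
#' @exportClass TrialRecording
setClass("TrialRecording",
         representation(trialId = "character", behavior = "character",
                        dt = "numeric", traces = "matrix",
                        referenceCell = "character"))

setValidity("TrialRecording", function(object) {
  if (object@dt <= 0) return("dt must be positive")
  if (!object@behavior %in% .BEHAVIORS)
    return("behavior must be swim/crawl/local_bend")
  tr <- object@traces
  if (is.null(colnames(tr)) || anyDuplicated(colnames(tr)))
    return("traces must have unique column names (cell ids)")
  if (!object@referenceCell %in% colnames(tr))
    return("referenceCell must be one of the trace columns")
  if (anyNA(tr)) return("traces must not contain NA")
  if (nrow(tr) < 8) return("traces are too short")
  TRUE
})

#' Construct a TrialRecording
#'
#' @param traces samples x cells numeric matrix with cell ids as column
#'   names.
#' @param dt sample interval (s).
#' @param referenceCell cell id of the reference (hub) cell.
#' @param behavior behavior label.
#' @param trialId trial identifier.
#' @return a validated [TrialRecording-class].
#' @export
trialRecording <- function(traces, dt, referenceCell,
                           behavior = "swim", trialId = "trial1") {
  new("TrialRecording", trialId = as.character(trialId),
      behavior = as.character(behavior), dt = as.numeric(dt),
      traces = as.matrix(traces), referenceCell = as.character(referenceCell))
}

# ---------------------------------------------------------------------------
# Clustering types
# ---------------------------------------------------------------------------

#' ClusterSet: a partition of synapses into spatial clusters
#'
#' Produced by [clusterSynapses()]; before filtering, the clusters partition
#' the input synapses.  Extents are tree-metric diameters (maximum pairwise
#' along-neurite distance among member synapses); a singleton has extent 0.
#'
#' @slot members list of character vectors of synapse ids.
#' @slot extents numeric, tree-metric diameter of each cluster (um).
#' @slot params named numeric c(d_nn=, d_ext=) that produced the set.
#' @slot mergeLog data.frame with one row per accepted merge: the
#'   single-linkage distance \code{linkage} and the extent of the merged
#'   cluster \code{extent}.
#' @seealso [clusterSynapses()], [filterForFRatio()], [clusterSizeTable()]
#' @exportClass ClusterSet
setClass("ClusterSet",
         representation(members = "list", extents = "numeric",
                        params = "numeric", mergeLog = "data.frame"))

setValidity("ClusterSet", function(object) {
  if (length(object@members) != length(object@extents))
    return("one extent per cluster required")
  ids <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(ids)) return("a synapse may not belong to two clusters")
  if (!all(c("d_nn", "d_ext") %in% names(object@params)))
    return("params must be named c(d_nn=, d_ext=)")
  if (any(object@params <= 0)) return("d_nn and d_ext must be positive")
  if (length(object@extents) &&
      any(object@extents > object@params[["d_ext"]] + 1e-9))
    return("cluster extent exceeds d_ext")
  TRUE
})

#' FRatioResult: complex-coherence F-ratio, optionally with permutation p
#'
#' Holds the observed F together with its sum-of-squares decomposition
#' (ssTotal = ssWithin + ssBetween), and, after [permutationP()], the
#' exceedance count m and the empirical p-value (m+1)/(nShuffles+1).
#'
#' @slot f the F-ratio, ssTotal/ssWithin; >= 1 up to floating error.
#' @slot ssTotal,ssWithin,ssBetween sums of absolute squared deviations.
#' @slot pHat empirical p-value, NA before permutation.
#' @slot m exceedance count (shuffled F >= observed F), NA before permutation.
#' @slot nShuffles,seed permutation settings (NA before permutation).
#' @slot degenerate "" or a flag: "zero_within" (F = +Inf sentinel) or
#'   "zero_total" (all values identical, F defined as 1).
#' @seealso [complexFRatio()], [permutationP()]
#' @exportClass FRatioResult
setClass("FRatioResult",
         representation(f = "numeric", ssTotal = "numeric",
                        ssWithin = "numeric", ssBetween = "numeric",
                        pHat = "numeric", m = "numeric",
                        nShuffles = "numeric", seed = "numeric",
                        degenerate = "character"))

#' FRatioGrid: F-ratio and empirical p over the clustering parameter grid
#'
#' @slot trialId identifier of the trial whose coherence values were used.
#' @slot grid data.frame with columns d_nn, d_ext, f, p_hat, n_clusters,
#'   n_values (memberships entering the F-ratio) and degenerate (logical).
#' @slot nShuffles,seed permutation settings of the sweep.
#' @seealso [runSweep()], [bestDnnProfile()], [significantPairs()]
#' @exportClass FRatioGrid
setClass("FRatioGrid",
         representation(trialId = "character", grid = "data.frame",
                        nShuffles = "numeric", seed = "numeric"))

setValidity("FRatioGrid", function(object) {
  g <- object@grid
  need <- c("d_nn", "d_ext", "f", "p_hat", "n_clusters", "n_values",
            "degenerate")
  if (!all(need %in% names(g)))
    return(paste("grid must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(g[c("d_nn", "d_ext")])) return("duplicated grid cells")
  TRUE
})

#' GaussianFit: peak localization along the cluster-extent axis
#'
#' The model is F = 1 + A * exp(-(d_ext - mu)^2 / (2 sigma^2)), fitted by
#' nonlinear least squares to the F-vs-d_ext profile at the best d_nn.
#'
#' @slot a amplitude A (dimensionless).
#' @slot mu peak location (um).
#' @slot sigma peak width (um).
#' @slot seMu standard error of mu from the least-squares covariance (um).
#' @slot converged logical; FALSE when the fit failed or the profile is
#'   non-identifiable (flat).
#' @slot message diagnostic string.
#' @seealso [fitPeak()]
#' @exportClass GaussianFit
setClass("GaussianFit",
         representation(a = "numeric", mu = "numeric", sigma = "numeric",
                        seMu = "numeric", converged = "logical",
                        message = "character"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "Skeleton", function(object) {
  nd <- object@nodes
  ax <- nd$node_id[nd$tag == "axon_exit"]
  cat(sprintf("Skeleton: %d nodes, cable %.1f um, root (soma) node %d%s\n",
              nrow(nd), sum(object@edgeLengths),
              nd$node_id[is.na(nd$parent_id)],
              if (length(ax)) sprintf(", axon exit node %d", ax) else ""))
})

setMethod("show", "SynapseTable", function(object) {
  r <- object@records
  cat(sprintf("SynapseTable: %d synapses from %d partners (%s)\n",
              nrow(r), length(unique(r$partner_id)),
              paste(sprintf("%s %d", names(table(r$valence)),
                            as.integer(table(r$valence))), collapse = ", ")))
})

setMethod("show", "TrialRecording", function(object) {
  cat(sprintf(
    "TrialRecording '%s' (%s): %d cells x %d samples, dt %.4g s, ref '%s'\n",
    object@trialId, object@behavior, ncol(object@traces),
    nrow(object@traces), object@dt, object@referenceCell))
})

setMethod("show", "SpectralOptions", function(object) {
  cat(sprintf(
    "SpectralOptions: NW %.3g, %d tapers, detrend order %d, band %.3g-%.3g Hz\n",
    object@timeBandwidth, object@nTapers, object@detrendOrder,
    object@searchBand[1], object@searchBand[2]))
})

setMethod("show", "ClusterSet", function(object) {
  n <- lengths(object@members)
  cat(sprintf(
    "ClusterSet: %d clusters of %d synapses (d_nn %.3g, d_ext %.3g um)\n",
    length(n), sum(n), object@params[["d_nn"]], object@params[["d_ext"]]))
  if (length(n))
    cat(sprintf("  sizes: %s; extents up to %.1f um\n",
                paste(sort(unique(n)), collapse = ", "), max(object@extents)))
})

setMethod("show", "FRatioResult", function(object) {
  cat(sprintf("FRatioResult: F = %.4g (ss_total %.4g, ss_within %.4g)%s\n",
              object@f, object@ssTotal, object@ssWithin,
              if (nzchar(object@degenerate))
                sprintf(" [degenerate: %s]", object@degenerate) else ""))
  if (!is.na(object@pHat))
    cat(sprintf("  permutation p = %.4g (m = %d of %d shuffles)\n",
                object@pHat, as.integer(object@m),
                as.integer(object@nShuffles)))
})

setMethod("show", "FRatioGrid", function(object) {
  g <- object@grid
  cat(sprintf(
    "FRatioGrid '%s': %d cells (%d degenerate), F up to %.4g\n",
    object@trialId, nrow(g), sum(g$degenerate),
    suppressWarnings(max(g$f[!g$degenerate], na.rm = TRUE))))
})

setMethod("show", "GaussianFit", function(object) {
  if (object@converged)
    cat(sprintf("GaussianFit: mu = %.2f +/- %.2f um, sigma = %.2f, A = %.3g\n",
                object@mu, object@seMu, object@sigma, object@a))
  else cat(sprintf("GaussianFit: not converged (%s)\n", object@message))
})

# ---------------------------------------------------------------------------
# accessors
# ---------------------------------------------------------------------------

#' Accessors for synarbor classes
#'
#' @param x the object.
#' @name accessors
#' @return \code{skeletonNodes}: the node data.frame; \code{synapseRecords}:
#'   the synapse data.frame; \code{clusterMembers}: list of synapse-id
#'   vectors; \code{clusterExtents}: numeric extents (um);
#'   \code{clusterParams}: named c(d_nn, d_ext); \code{gridTable}: the sweep
#'   results data.frame; \code{trialTraces}: the samples x cells matrix.
NULL

#' @rdname accessors
#' @export
skeletonNodes <- function(x) { stopifnot(is(x, "Skeleton")); x@nodes }

#' @rdname accessors
#' @export
synapseRecords <- function(x) { stopifnot(is(x, "SynapseTable")); x@records }

#' @rdname accessors
#' @export
clusterMembers <- function(x) { stopifnot(is(x, "ClusterSet")); x@members }

#' @rdname accessors
#' @export
clusterExtents <- function(x) { stopifnot(is(x, "ClusterSet")); x@extents }

#' @rdname accessors
#' @export
clusterParams <- function(x) { stopifnot(is(x, "ClusterSet")); x@params }

#' @rdname accessors
#' @export
gridTable <- function(x) { stopifnot(is(x, "FRatioGrid")); x@grid }

#' @rdname accessors
#' @export
trialTraces <- function(x) { stopifnot(is(x, "TrialRecording")); x@traces }

#' Number of clusters in a ClusterSet
#' @param x a [ClusterSet-class]
#' @export
setMethod("length", "ClusterSet", function(x) length(x@members))
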