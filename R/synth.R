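#' @include sweep.R coherence.R
NULL

#' SynthConfig: settings of the synthetic-data generator
#'
#' Defaults emulate the study conditions the pipeline targets: an arbor of
#' roughly 6,000 um total cable, about 450 input synapses from 50
#' presynaptic partners, partner coherences forming Gaussian clusters in the
#' complex plane, and swim-like ~2 Hz oscillatory traces with a bleaching
#' trend.
#'
#' @slot seed master seed; every generator output is a pure function of the
#'   configuration including this seed.
#' @slot nBranchPoints,meanSegmentUm,targetCableUm skeleton growth: expected
#'   number of branch points, mean exponential segment length (um), and the
#'   cable length (um) at which growth stops.
#' @slot nPartners,nSynapses presynaptic partner and synapse counts.
#' @slot placementMode "uniform" (over cable) or "clustered" (planted).
#' @slot plantedExtentUm,plantedNClusters clustered mode: tree-metric extent
#'   of each planted cluster (um) and the number of clusters.
#' @slot nFunctionalGroups,groupPhases,groupMagnitudes,zNoiseSd functional
#'   structure of partner coherences: group centroids m_g exp(i phi_g) plus
#'   complex Gaussian noise (per-axis sd).
#' @slot signalCoupling "aligned" (each planted cluster draws partners from
#'   a single functional group) or "independent" (partners drawn regardless
#'   of cluster).
#' @slot unmatchedFraction fraction of partners without an optical match
#'   (emulates out-of-volume inputs; default 0).
#' @slot rhythmHz,trialS,dt,snr,bleachFraction trace generation: rhythm
#'   frequency (Hz), trial length (s), sample interval (s), amplitude
#'   signal-to-noise ratio, and fractional bleaching amplitude over the
#'   trial.
#' @seealso [synthConfig()], [synthSkeleton()], [synthSynapses()],
#'   [synthCoherence()], [synthTimeseries()]
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
  seed = "integer", nBranchPoints = "integer", meanSegmentUm = "numeric",
  targetCableUm = "numeric", nPartners = "integer", nSynapses = "integer",
  placementMode = "character", plantedExtentUm = "numeric",
  plantedNClusters = "integer", nFunctionalGroups = "integer",
  groupPhases = "numeric", groupMagnitudes = "numeric", zNoiseSd = "numeric",
  signalCoupling = "character", unmatchedFraction = "numeric",
  rhythmHz = "numeric", trialS = "numeric", dt = "numeric", snr = "numeric",
  bleachFraction = "numeric"))

setValidity("SynthConfig", function(object) {
  if (object@nPartners < 1 || object@nSynapses < 1 ||
      object@nFunctionalGroups < 1 || object@plantedNClusters < 1 ||
      object@nBranchPoints < 1)
    return("all counts must be positive")
  if (!object@placementMode %in% c("uniform", "clustered"))
    return("placementMode must be 'uniform' or 'clustered'")
  if (!object@signalCoupling %in% c("aligned", "independent"))
    return("signalCoupling must be 'aligned' or 'independent'")
  if (object@plantedExtentUm <= 0)
    return("plantedExtentUm must be positive")
  if (any(object@groupMagnitudes < 0 | object@groupMagnitudes > 1))
    return("groupMagnitudes must lie in [0, 1]")
  if (length(object@groupPhases) != object@nFunctionalGroups ||
      length(object@groupMagnitudes) != object@nFunctionalGroups)
    return("groupPhases/groupMagnitudes must have one entry per group")
  if (object@unmatchedFraction < 0 || object@unmatchedFraction >= 1)
    return("unmatchedFraction must lie in [0, 1)")
  if (object@meanSegmentUm <= 0 || object@targetCableUm <= 0 ||
      object@rhythmHz <= 0 || object@trialS <= 0 || object@dt <= 0 ||
      object@snr <= 0 || object@bleachFraction < 0)
    return("scale parameters must be positive (bleachFraction >= 0)")
  TRUE
})

#' Create a synthetic-data configuration
#'
#' @param seed master seed (integer).
#' @param nBranchPoints expected branch points of the grown arbor.
#' @param meanSegmentUm mean exponential segment length (um).
#' @param targetCableUm cable length at which growth stops (um).
#' @param nPartners number of presynaptic partners.
#' @param nSynapses number of synapses.
#' @param placementMode "uniform" or "clustered".
#' @param plantedExtentUm extent of each planted cluster (um).
#' @param plantedNClusters number of planted clusters.
#' @param nFunctionalGroups number of functional groups.
#' @param groupPhases phases of the group centroids (radians); default:
#'   evenly spaced around the circle.
#' @param groupMagnitudes magnitudes of the group centroids in [0, 1];
#'   recycled.
#' @param zNoiseSd per-axis sd of the complex Gaussian coherence noise.
#' @param signalCoupling "aligned" or "independent".
#' @param unmatchedFraction fraction of partners with no optical match.
#' @param rhythmHz rhythm frequency (Hz; the swim rhythm runs near 2 Hz).
#' @param trialS trial duration (s).
#' @param dt sample interval (s).
#' @param snr amplitude signal-to-noise ratio of the traces.
#' @param bleachFraction fractional bleaching trend amplitude.
#' @return a validated [SynthConfig-class].
#' @export
synthConfig <- function(seed = 1L, nBranchPoints = 60L, meanSegmentUm = 30,
                        targetCableUm = 6000, nPartners = 50L,
                        nSynapses = 450L,
                        placementMode = c("uniform", "clustered"),
                        plantedExtentUm = 60, plantedNClusters = 8L,
                        nFunctionalGroups = 3L, groupPhases = NULL,
                        groupMagnitudes = 0.6, zNoiseSd = 0.1,
                        signalCoupling = c("aligned", "independent"),
                        unmatchedFraction = 0, rhythmHz = 2, trialS = 30,
                        dt = 0.02, snr = 10, bleachFraction = 0.2) {
  placementMode <- match.arg(placementMode)
  signalCoupling <- match.arg(signalCoupling)
  G <- as.integer(nFunctionalGroups)
  if (is.null(groupPhases)) groupPhases <- 2 * pi * (seq_len(G) - 1) / G
  new("SynthConfig", seed = as.integer(seed),
      nBranchPoints = as.integer(nBranchPoints),
      meanSegmentUm = as.numeric(meanSegmentUm),
      targetCableUm = as.numeric(targetCableUm),
      nPartners = as.integer(nPartners), nSynapses = as.integer(nSynapses),
      placementMode = placementMode,
      plantedExtentUm = as.numeric(plantedExtentUm),
      plantedNClusters = as.integer(plantedNClusters),
      nFunctionalGroups = G,
      groupPhases = as.numeric(groupPhases),
      groupMagnitudes = rep_len(as.numeric(groupMagnitudes), G),
      zNoiseSd = as.numeric(zNoiseSd), signalCoupling = signalCoupling,
      unmatchedFraction = as.numeric(unmatchedFraction),
      rhythmHz = as.numeric(rhythmHz), trialS = as.numeric(trialS),
      dt = as.numeric(dt), snr = as.numeric(snr),
      bleachFraction = as.numeric(bleachFraction))
}

.partnerIds <- function(config) sprintf("P%03d", seq_len(config@nPartners))

# round-robin partner -> functional group map
.partnerGroups <- function(config) {
  setNames(rep_len(seq_len(config@nFunctionalGroups), config@nPartners),
           .partnerIds(config))
}

#' Grow a random skeleton
#'
#' Random rooted tree grown segment by segment: a random open tip is
#' extended by an exponential segment (directional persistence plus jitter),
#' occasionally branching so that the expected number of branch points
#' matches the configuration.  Growth stops as soon as the cable length
#' first reaches \code{targetCableUm}.  One random leaf is flagged as the
#' axon exit.  Deterministic given the configuration seed.
#'
#' @param config a [SynthConfig-class].
#' @return a [Skeleton-class].
#' @export
synthSkeleton <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  withr::with_seed(.subSeed(config@seed, 1, 0), {
    pBranch <- min(0.45, config@nBranchPoints /
                     max(1, config@targetCableUm / config@meanSegmentUm))
    pos <- list(c(0, 0, 0))
    parent <- NA_integer_
    nodes <- data.frame(node_id = 1L, parent_id = NA_integer_,
                        x = 0, y = 0, z = 0, radius = 2, tag = "soma")
    tips <- list(list(id = 1L, dir = c(1, 0, 0)))
    cable <- 0
    nid <- 1L
    while (cable < config@targetCableUm) {
      ti <- sample.int(length(tips), 1)
      tip <- tips[[ti]]
      len <- max(0.5, rexp(1, 1 / config@meanSegmentUm))
      dir <- tip$dir + 0.6 * rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      nid <- nid + 1L
      p <- as.numeric(nodes[nodes$node_id == tip$id, c("x", "y", "z")])
      q <- p + len * dir
      nodes <- rbind(nodes, data.frame(node_id = nid, parent_id = tip$id,
                                       x = q[1], y = q[2], z = q[3],
                                       radius = 0.5, tag = "neurite"))
      cable <- cable + len
      if (cable < config@targetCableUm && runif(1) < pBranch) {
        d2 <- dir + 0.9 * rnorm(3); d2 <- d2 / sqrt(sum(d2^2))
        tips[[ti]] <- list(id = nid, dir = dir)
        tips[[length(tips) + 1L]] <- list(id = nid, dir = d2)
      } else {
        tips[[ti]] <- list(id = nid, dir = dir)
      }
    }
    sk <- Skeleton(nodes)
    leaves <- setdiff(nodes$node_id, nodes$parent_id)
    leaves <- setdiff(leaves, .rootId(sk))
    ax <- if (length(leaves) == 1) leaves else sample(leaves, 1)
    nodes$tag[nodes$node_id == ax] <- "axon_exit"
    Skeleton(nodes)
  })
}

# Attach synapses at cable positions given as (child node id, offset from
# that child's parent along the edge).  Degree-2 nodes are inserted where
# needed (interpolated coordinates, so the tree metric is preserved
# exactly); offsets at the ends of an edge reuse the endpoint node.
# Returns list(skeleton =, attach = integer node id per input row).
.attachAtPositions <- function(skeleton, child, offset, eps = 1e-6) {
  nd <- skeleton@nodes
  el <- skeleton@edgeLengths
  attach <- integer(length(child))
  nextId <- max(nd$node_id) + 1L
  for (cid in unique(child)) {
    rows <- which(child == cid)
    len <- el[[as.character(cid)]]
    off <- pmin(pmax(offset[rows], 0), len)
    pid <- nd$parent_id[nd$node_id == cid]
    ord <- order(off)
    prev <- pid; prevOff <- 0
    for (r in rows[ord]) {
      o <- min(max(offset[r], 0), len)
      if (o <= eps) { attach[r] <- pid; next }
      if (o >= len - eps) { attach[r] <- cid; next }
      if (o - prevOff <= eps && prev != pid) { attach[r] <- prev; next }
      # interpolate between the ORIGINAL endpoints
      p <- as.numeric(nd[nd$node_id == pid, c("x", "y", "z")])
      q <- as.numeric(nd[nd$node_id == cid, c("x", "y", "z")])
      t <- o / len
      newPos <- p + t * (q - p)
      nd <- rbind(nd, data.frame(node_id = nextId, parent_id = prev,
                                 x = newPos[1], y = newPos[2], z = newPos[3],
                                 radius = 0.5, tag = "neurite"))
      nd$parent_id[nd$node_id == cid] <- nextId
      attach[r] <- nextId
      prev <- nextId; prevOff <- o
      nextId <- nextId + 1L
    }
  }
  list(skeleton = Skeleton(nd), attach = attach)
}

# map global cable coordinates (in [0, cable)) to (child, offset); edges
# ordered by child node id
.cableToEdge <- function(skeleton, s) {
  el <- skeleton@edgeLengths
  ord <- order(as.integer(names(el)))
  lens <- unname(el[ord])
  starts <- cumsum(c(0, lens[-length(lens)]))
  idx <- findInterval(s, starts)
  idx[idx < 1] <- 1L
  idx[idx > length(lens)] <- length(lens)
  list(child = as.integer(names(el)[ord][idx]), offset = s - starts[idx])
}

#' Place synthetic synapses on a skeleton
#'
#' Uniform mode draws attachment positions uniformly over the cable.
#' Clustered mode plants \code{plantedNClusters} centers (uniform over
#' cable, re-drawn until centers are mutually separated by at least 1.5x the
#' planted extent along the tree) and attaches each synapse within path
#' distance \code{plantedExtentUm / 2} of its cluster's center, so the
#' tree-metric extent of each planted cluster is at most
#' \code{plantedExtentUm}.  Partners are assigned per synapse: with aligned
#' coupling every planted cluster draws partners from a single functional
#' group (clusters cycle through the groups); with independent coupling (or
#' uniform placement) partners are drawn from all partners regardless of
#' position.  A node is inserted at every synapse position.
#'
#' @param skeleton a [Skeleton-class], e.g. from [synthSkeleton()].
#' @param config a [SynthConfig-class].
#' @return list: \code{skeleton} (with inserted nodes), \code{table} (a
#'   [SynapseTable-class]) and \code{truth} (list: synapse -> planted
#'   cluster map, partner -> group map, planted extent, cluster -> group
#'   map).
#' @export
synthSynapses <- function(skeleton, config) {
  stopifnot(is(skeleton, "Skeleton"), is(config, "SynthConfig"))
  cable <- cableLength(skeleton)
  if (config@placementMode == "clustered" &&
      config@plantedExtentUm > cable)
    stop("plantedExtentUm exceeds the skeleton cable length")
  withr::with_seed(.subSeed(config@seed, 2, 0), {
    partners <- .partnerIds(config)
    groups <- .partnerGroups(config)
    n <- config@nSynapses
    if (config@placementMode == "uniform") {
      s <- runif(n) * cable
      pos <- .cableToEdge(skeleton, s)
      att <- .attachAtPositions(skeleton, pos$child, pos$offset)
      partner <- sample(partners, n, replace = TRUE)
      clusterOf <- rep(NA_integer_, n)
      clusterGroup <- integer(0)
      sk2 <- att$skeleton
      attach <- att$attach
    } else {
      K <- config@plantedNClusters
      r <- config@plantedExtentUm / 2
      # centers: uniform over cable, mutually separated along the tree
      centers <- NULL
      for (try in 1:500) {
        sc <- runif(K) * cable
        cp <- .cableToEdge(skeleton, sc)
        attc <- .attachAtPositions(skeleton, cp$child, cp$offset)
        D <- .pathDistances(attc$skeleton, attc$attach, attc$attach)
        if (K == 1 || min(D[upper.tri(D)]) >= 1.5 * config@plantedExtentUm) {
          centers <- attc
          break
        }
      }
      if (is.null(centers))
        stop("could not place ", K, " planted clusters separated by 1.5x ",
             config@plantedExtentUm, " um on ", round(cable), " um of cable")
      sk2 <- centers$skeleton
      clusterGroup <- rep_len(seq_len(config@nFunctionalGroups), K)
      clusterOf <- rep_len(seq_len(K), n)
      attach <- integer(n)
      for (k in seq_len(K)) {
        sel <- which(clusterOf == k)
        # reachable cable within r of the center, per edge
        nd <- sk2@nodes
        el <- sk2@edgeLengths
        dcen <- .pathDistances(sk2, nd$node_id, centers$attach[k])[, 1]
        childIds <- as.integer(names(el))
        dp <- dcen[as.character(nd$parent_id[match(childIds, nd$node_id)])]
        dc <- dcen[as.character(childIds)]
        nearest <- pmin(dp, dc)
        avail <- pmax(pmin(r - nearest, unname(el)), 0)
        ok <- which(avail > 0)
        if (!length(ok)) stop("no cable within planted radius")
        ei <- ok[sample.int(length(ok), length(sel), replace = TRUE,
                            prob = avail[ok])]
        u <- runif(length(sel)) * avail[ei]
        # offset measured from the parent: if the parent is the nearer end
        # walk forward from it, otherwise back from the child
        fromParent <- dp[ei] <= dc[ei]
        off <- ifelse(fromParent, u, unname(el)[ei] - u)
        att <- .attachAtPositions(sk2, childIds[ei], off)
        sk2 <- att$skeleton
        attach[sel] <- att$attach
      }
      partner <- character(n)
      for (k in seq_len(K)) {
        sel <- which(clusterOf == k)
        pool <- if (config@signalCoupling == "aligned")
          partners[groups == clusterGroup[k]] else partners
        partner[sel] <- sample(pool, length(sel), replace = TRUE)
      }
    }
    valence <- sample(c("excitatory", "inhibitory", "unknown"), n,
                      replace = TRUE, prob = c(0.25, 0.15, 0.6))
    tab <- SynapseTable(data.frame(
      synapse_id = sprintf("syn%04d", seq_len(n)),
      attach_node = attach, partner_id = partner, valence = valence,
      behavior_label = "unassigned"), skeleton = sk2)
    list(skeleton = sk2, table = tab,
         truth = list(synapseCluster = setNames(clusterOf,
                                                tab@records$synapse_id),
                      partnerGroup = groups,
                      clusterGroup = clusterGroup,
                      plantedExtentUm = config@plantedExtentUm))
  })
}

#' Draw per-partner complex coherence values
#'
#' A partner in functional group g receives z = m_g exp(i phi_g) plus
#' complex Gaussian noise (independent per-axis sd \code{zNoiseSd}); values
#' with |z| > 1 are rescaled onto the unit circle (coherence magnitudes
#' cannot exceed 1).  Partners beyond the matched fraction are dropped from
#' the returned map (no optical match).  Deterministic given the seed.
#'
#' @param config a [SynthConfig-class].
#' @param groups optional named partner -> group integer map (default:
#'   round-robin as used by [synthSynapses()]).
#' @return named complex vector of coherence values for matched partners;
#'   attributes \code{groups} (the map) and \code{centers} (group
#'   centroids).
#' @export
synthCoherence <- function(config, groups = NULL) {
  stopifnot(is(config, "SynthConfig"))
  if (is.null(groups)) groups <- .partnerGroups(config)
  withr::with_seed(.subSeed(config@seed, 3, 0), {
    centers <- config@groupMagnitudes * exp(1i * config@groupPhases)
    z <- centers[groups] +
      complex(real = rnorm(length(groups), 0, config@zNoiseSd),
              imaginary = rnorm(length(groups), 0, config@zNoiseSd))
    big <- Mod(z) > 1
    z[big] <- z[big] / Mod(z[big])
    names(z) <- names(groups)
    nMatched <- ceiling((1 - config@unmatchedFraction) * length(z))
    z <- z[seq_len(nMatched)]
    attr(z, "groups") <- groups
    attr(z, "centers") <- centers
    z
  })
}

#' Generate an oscillatory multi-cell trial
#'
#' Each cell's trace is A cos(2 pi f t - phi_cell) plus an exponential
#' bleaching trend (amplitude \code{bleachFraction}, decaying over the
#' trial) and white noise with amplitude set by \code{snr} (RMS signal over
#' RMS noise).  The reference cell has phase 0, so a cell with planted
#' phase phi lags the reference by phi / (2 pi f) seconds, matching the
#' phase-sign convention of [coherenceAt()].  Deterministic given the seed.
#'
#' @param config a [SynthConfig-class].
#' @param cellPhases named numeric vector of planted phases (radians) for
#'   the non-reference cells; default: each matched partner at its
#'   functional group's phase.
#' @param referenceCell name of the added reference cell (default "ref").
#' @param behavior behavior label of the trial (default "swim").
#' @return a [TrialRecording-class]; the planted phases are stored in
#'   attribute \code{phases}.
#' @export
synthTimeseries <- function(config, cellPhases = NULL,
                            referenceCell = "ref", behavior = "swim") {
  stopifnot(is(config, "SynthConfig"))
  if (is.null(cellPhases)) {
    g <- .partnerGroups(config)
    nMatched <- ceiling((1 - config@unmatchedFraction) * length(g))
    g <- g[seq_len(nMatched)]
    cellPhases <- setNames(config@groupPhases[g], names(g))
  }
  withr::with_seed(.subSeed(config@seed, 4, 0), {
    t <- seq(0, config@trialS - config@dt, by = config@dt)
    phases <- c(setNames(0, referenceCell), cellPhases)
    A <- 1
    noiseSd <- (A / sqrt(2)) / config@snr
    bleach <- config@bleachFraction * exp(-2 * t / config@trialS)
    traces <- vapply(phases, function(ph)
      A * cos(2 * pi * config@rhythmHz * t - ph) + bleach +
        rnorm(length(t), 0, noiseSd),
      numeric(length(t)))
    colnames(traces) <- names(phases)
    tr <- trialRecording(traces, dt = config@dt,
                         referenceCell = referenceCell,
                         behavior = behavior,
                         trialId = sprintf("synth-%d", config@seed))
    attr(tr, "phases") <- phases
    tr
  })
}
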