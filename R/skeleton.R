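#' @include AllClasses.R
NULL

# weighted undirected igraph of the skeleton; vertex names = node ids
.skelGraph <- function(skeleton) {
  nd <- skeleton@nodes
  child <- nd$node_id[!is.na(nd$parent_id)]
  parent <- nd$parent_id[!is.na(nd$parent_id)]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(parent), to = as.character(child),
               weight = unname(skeleton@edgeLengths[as.character(child)])),
    directed = FALSE,
    vertices = data.frame(name = as.character(nd$node_id)))
  g
}

.rootId <- function(skeleton) {
  nd <- skeleton@nodes
  nd$node_id[is.na(nd$parent_id)]
}

.checkNodes <- function(skeleton, ids) {
  bad <- setdiff(ids, skeleton@nodes$node_id)
  if (length(bad))
    stop("unknown node id(s): ", paste(head(bad, 5), collapse = ", "))
  invisible(TRUE)
}

#' Read a neuron skeleton from an SWC file
#'
#' Standard 7-column SWC: id, type, x, y, z, radius, parent (parent -1 for
#' the root), whitespace-separated, '#' comments.  The root is tagged as the
#' soma.  SWC has no concept of an axon-exit point, so one node may be
#' flagged by SWC type code 2, or designated explicitly via
#' \code{axonExitId} (which overrides type codes).
#'
#' @param path SWC file path.
#' @param axonExitId optional node id to tag as the axon exit.
#' @return a validated [Skeleton-class].
#' @examples
#' f <- tempfile(fileext = ".swc")
#' writeLines(c("1 1 0 0 0 1 -1", "2 0 1 0 0 1 1", "3 0 2 0 0 1 2"), f)
#' readSWC(f)
#' @export
readSWC <- function(path, axonExitId = NULL) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  raw <- tryCatch(
    read.table(path, comment.char = "#", col.names = c(
      "id", "type", "x", "y", "z", "radius", "parent"),
      colClasses = c("integer", "integer", "numeric", "numeric", "numeric",
                     "numeric", "integer")),
    error = function(e) stop("malformed SWC file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (anyDuplicated(raw$id))
    stop("SWC parse error: duplicate node id ",
         raw$id[duplicated(raw$id)][1])
  roots <- which(raw$parent == -1L)
  if (length(roots) == 0L) stop("SWC parse error: no root node (parent -1)")
  if (length(roots) > 1L)
    stop("SWC parse error: multiple roots at nodes ",
         paste(raw$id[roots], collapse = ", "))
  dangling <- which(raw$parent != -1L & !(raw$parent %in% raw$id))
  if (length(dangling))
    stop("SWC parse error: node ", raw$id[dangling[1]],
         " references absent parent ", raw$parent[dangling[1]],
         " (line ", dangling[1], " of data)")
  tag <- rep("neurite", nrow(raw))
  tag[roots] <- "soma"
  if (!is.null(axonExitId)) {
    if (!axonExitId %in% raw$id)
      stop("axonExitId ", axonExitId, " is not a node in the file")
    tag[raw$id == axonExitId] <- "axon_exit"
  } else {
    ax <- which(raw$type == 2L & raw$parent != -1L)
    if (length(ax) > 1L)
      stop("SWC has ", length(ax), " nodes with type code 2; pass ",
           "axonExitId to designate the axon-exit node explicitly")
    if (length(ax) == 1L) tag[ax] <- "axon_exit"
  }
  nodes <- data.frame(node_id = raw$id,
                      parent_id = ifelse(raw$parent == -1L, NA_integer_,
                                         raw$parent),
                      x = raw$x, y = raw$y, z = raw$z, radius = raw$radius,
                      tag = tag)
  sk <- tryCatch(Skeleton(nodes), error = function(e)
    stop("SWC validation failed for '", path, "': ", conditionMessage(e),
         call. = FALSE))
  ok <- validObject(sk, test = TRUE)
  if (!isTRUE(ok)) stop("SWC validation failed for '", path, "': ", ok)
  sk
}

#' Write a skeleton to an SWC file
#'
#' Inverse of [readSWC()]: the root gets type 1 and parent -1; an axon-exit
#' node gets type 2; other nodes type 0.
#'
#' @param skeleton a [Skeleton-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSWC <- function(skeleton, path) {
  nd <- skeleton@nodes
  type <- ifelse(nd$tag == "soma", 1L, ifelse(nd$tag == "axon_exit", 2L, 0L))
  out <- data.frame(id = nd$node_id, type = type,
                    x = nd$x, y = nd$y, z = nd$z,
                    radius = ifelse(is.na(nd$radius), 1, nd$radius),
                    parent = ifelse(is.na(nd$parent_id), -1L, nd$parent_id))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC skeleton written by synarbor", con)
  write.table(format(out, digits = 12, scientific = FALSE, trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total cable length of a skeleton
#'
#' Sum of all edge lengths (Euclidean node-to-parent distances), in
#' micrometres.
#'
#' @param skeleton a [Skeleton-class].
#' @return cable length in um.
#' @export
cableLength <- function(skeleton) {
  stopifnot(is(skeleton, "Skeleton"))
  sum(skeleton@edgeLengths)
}

#' Along-neurite path distance between two nodes
#'
#' Length of the unique tree path, in micrometres.  All analysis distances
#' in this package are measured along the neurites, never by the Euclidean
#' metric through the volume.
#'
#' @param skeleton a [Skeleton-class].
#' @param nodeA,nodeB node ids.
#' @return distance in um (0 iff nodeA == nodeB).
#' @export
pathDistance <- function(skeleton, nodeA, nodeB) {
  .checkNodes(skeleton, c(nodeA, nodeB))
  if (nodeA == nodeB) return(0)
  g <- .skelGraph(skeleton)
  as.numeric(igraph::distances(g, v = as.character(nodeA),
                               to = as.character(nodeB)))
}

# path distances from a set of nodes to a set of nodes (matrix), one graph
.pathDistances <- function(skeleton, from, to = from) {
  g <- .skelGraph(skeleton)
  d <- igraph::distances(g, v = as.character(from), to = as.character(to))
  dimnames(d) <- list(as.character(from), as.character(to))
  d
}

#' Along-neurite distance from synapses to the soma
#'
#' @param skeleton a [Skeleton-class].
#' @param table a [SynapseTable-class] (or a vector of attachment node ids).
#' @return named numeric vector of distances (um), one per synapse.
#' @export
distanceToSoma <- function(skeleton, table) {
  nodes <- if (is(table, "SynapseTable")) table@records$attach_node
           else as.integer(table)
  .checkNodes(skeleton, nodes)
  root <- .rootId(skeleton)
  d <- .pathDistances(skeleton, unique(nodes), root)[, 1]
  out <- unname(d[as.character(nodes)])
  if (is(table, "SynapseTable")) names(out) <- table@records$synapse_id
  out
}

#' The primary neurite: soma-to-axon-exit node path
#'
#' The path between the soma (root) and the designated point where the axon
#' leaves the ganglion.
#'
#' @param skeleton a [Skeleton-class] with one node tagged axon_exit.
#' @return integer vector of node ids, root first.
#' @export
primaryNeurite <- function(skeleton) {
  nd <- skeleton@nodes
  exit <- nd$node_id[nd$tag == "axon_exit"]
  if (length(exit) != 1L)
    stop("no axon-exit node designated; flag one node as the axon exit ",
         "(SWC type code 2 or the axonExitId argument of readSWC)")
  # walk parent pointers from the exit to the root
  pmap <- setNames(nd$parent_id, as.character(nd$node_id))
  path <- exit
  cur <- exit
  while (!is.na(pmap[[as.character(cur)]])) {
    cur <- pmap[[as.character(cur)]]
    path <- c(path, cur)
  }
  rev(path)
}

#' Along-neurite distance from synapses to the primary neurite
#'
#' Minimum path distance from each synapse's attachment node to any node on
#' the primary-neurite path (0 for synapses attached on the path).  Always
#' less than or equal to the distance to the soma, because the soma lies on
#' the primary neurite.
#'
#' @param skeleton a [Skeleton-class] with an axon-exit node.
#' @param table a [SynapseTable-class] (or vector of attachment node ids).
#' @return named numeric vector of distances (um).
#' @export
distanceToPrimaryNeurite <- function(skeleton, table) {
  nodes <- if (is(table, "SynapseTable")) table@records$attach_node
           else as.integer(table)
  .checkNodes(skeleton, nodes)
  pn <- primaryNeurite(skeleton)
  d <- .pathDistances(skeleton, unique(nodes), pn)
  mind <- apply(d, 1, min)
  out <- unname(mind[as.character(nodes)])
  if (is(table, "SynapseTable")) names(out) <- table@records$synapse_id
  out
}
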