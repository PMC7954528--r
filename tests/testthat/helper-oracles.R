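# Independent oracles and fixture builders used across the suite.  These
# deliberately avoid the package's own code paths (igraph shortest paths,
# the C++ clustering, the vectorised F-ratio) so the tests are dual-route.

# --- fixture builders -------------------------------------------------------

# chain skeleton along the x axis with the given edge lengths
chainSkeleton <- function(edges, tagTip = NULL) {
  n <- length(edges) + 1L
  nodes <- data.frame(node_id = seq_len(n),
                      parent_id = c(NA, seq_len(n - 1L)),
                      x = cumsum(c(0, edges)), y = 0, z = 0)
  sk <- Skeleton(nodes)
  if (!is.null(tagTip)) {
    nd <- skeletonNodes(sk)
    nd$tag[nd$node_id == n] <- "axon_exit"
    sk <- Skeleton(nd)
  }
  sk
}

# random tree: each node's parent drawn among earlier nodes, random coords
randomSkeleton <- function(n, seed, axonExitLeaf = FALSE) {
  withr::with_seed(seed, {
    nodes <- data.frame(node_id = seq_len(n),
                        parent_id = c(NA, vapply(2:n, function(i)
                          sample.int(i - 1L, 1), integer(1))),
                        x = runif(n, 0, 100), y = runif(n, 0, 100),
                        z = runif(n, 0, 100))
    if (axonExitLeaf) {
      leaves <- setdiff(nodes$node_id, nodes$parent_id)
      leaves <- setdiff(leaves, 1L)
      nodes$tag <- ifelse(is.na(nodes$parent_id), "soma", "neurite")
      nodes$tag[nodes$node_id == sample(leaves, 1)] <- "axon_exit"
    }
    Skeleton(nodes)
  })
}

simpleSynapseTable <- function(attachNodes, partners = NULL,
                               valence = "unknown") {
  n <- length(attachNodes)
  if (is.null(partners)) partners <- paste0("P", seq_len(n))
  SynapseTable(data.frame(synapse_id = paste0("s", seq_len(n)),
                          attach_node = attachNodes, partner_id = partners,
                          valence = valence))
}

# distance matrix from 1D positions with synapse ids
lineDistances <- function(pos, ids = paste0("s", seq_along(pos))) {
  d <- as.matrix(dist(pos))
  dimnames(d) <- list(ids, ids)
  d
}

# --- path-distance oracle (parent pointers + LCA; no igraph) ---------------

oracleDepths <- function(sk) {
  nd <- skeletonNodes(sk)
  el <- sk@edgeLengths
  depth <- setNames(rep(NA_real_, nrow(nd)), nd$node_id)
  depth[as.character(nd$node_id[is.na(nd$parent_id)])] <- 0
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    for (i in todo) {
      p <- nd$parent_id[match(as.integer(names(depth)[i]), nd$node_id)]
      if (!is.na(depth[as.character(p)]))
        depth[i] <- depth[as.character(p)] +
          el[[names(depth)[i]]]
    }
  }
  depth
}

oracleAncestors <- function(sk, v) {
  nd <- skeletonNodes(sk)
  pmap <- setNames(nd$parent_id, nd$node_id)
  anc <- v
  while (!is.na(pmap[[as.character(v)]])) {
    v <- pmap[[as.character(v)]]
    anc <- c(anc, v)
  }
  anc
}

oraclePathDistance <- function(sk, a, b) {
  depth <- oracleDepths(sk)
  ancA <- oracleAncestors(sk, a)
  ancB <- oracleAncestors(sk, b)
  lca <- ancA[ancA %in% ancB][1]
  unname(depth[as.character(a)] + depth[as.character(b)] -
           2 * depth[as.character(lca)])
}

# --- brute-force constrained single-linkage (rescans all pairs) -------------

bruteSlink <- function(D, dnn, dext) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  linkages <- numeric(0)
  repeat {
    best <- NULL
    nc <- length(clusters)
    if (nc >= 2) for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
      link <- min(D[clusters[[i]], clusters[[j]]])
      if (link > dnn) next
      allm <- c(clusters[[i]], clusters[[j]])
      ext <- max(D[allm, allm])
      if (ext > dext) next
      k1 <- min(min(clusters[[i]]), min(clusters[[j]]))
      k2 <- max(min(clusters[[i]]), min(clusters[[j]]))
      if (is.null(best) || link < best$link ||
          (link == best$link && (k1 < best$k1 ||
                                 (k1 == best$k1 && k2 < best$k2))))
        best <- list(i = i, j = j, link = link, k1 = k1, k2 = k2)
    }
    if (is.null(best)) break
    linkages <- c(linkages, best$link)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(clusters = clusters, linkages = linkages)
}

# canonical form of a partition over synapse ids: sorted list of sorted sets
canonicalPartition <- function(memberList) {
  out <- lapply(memberList, sort)
  out[order(vapply(out, `[`, character(1), 1))]
}

# --- direct-formula complex F-ratio (plain loops) ---------------------------

oracleFRatio <- function(clusterValues) {
  z <- unlist(clusterValues)
  z0 <- mean(z)
  sst <- 0; ssw <- 0
  for (zz in clusterValues) {
    zk0 <- mean(zz)
    for (v in zz) {
      sst <- sst + abs(v - z0)^2
      ssw <- ssw + abs(v - zk0)^2
    }
  }
  sst / ssw
}

# three 2D-Gaussian clouds in the complex plane, centroids mutually
# displaced by one standard deviation in different directions
displacedGaussianClusters <- function(nPer = 100, sdAxis = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- sdAxis * exp(2i * pi * (0:2) / 3)  # pairwise distance = sd
    centers <- centers / abs(centers[1] - centers[2]) * sdAxis
    lapply(centers, function(cc)
      cc + complex(real = rnorm(nPer, 0, sdAxis),
                   imaginary = rnorm(nPer, 0, sdAxis)))
  })
}
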