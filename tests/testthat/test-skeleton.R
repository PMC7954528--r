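# Morphology: SWC round trips, validation, and along-neurite metrics.

test_that("SWC reading parses a chain and validates structure", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 1 -1", "2 0 1 0 0 1 1",
               "3 0 2 0 0 1 2"), f)
  sk <- readSWC(f)
  expect_equal(length(sk@edgeLengths), 2)
  expect_equal(unname(sk@edgeLengths), c(1, 1))
  expect_equal(cableLength(sk), 2)

  # dangling parent names the offending node
  writeLines(c("1 1 0 0 0 1 -1", "5 0 1 0 0 1 99"), f)
  expect_error(readSWC(f), "node 5.*absent parent 99")

  # multiple roots
  writeLines(c("1 1 0 0 0 1 -1", "2 1 1 0 0 1 -1"), f)
  expect_error(readSWC(f), "multiple roots")

  # cyclic parent links cannot reach the root
  writeLines(c("1 1 0 0 0 1 -1", "2 0 1 0 0 1 3", "3 0 2 0 0 1 2"), f)
  expect_error(readSWC(f), "tree")
})

test_that("write/read SWC round trip preserves topology and coordinates", {
  sk <- randomSkeleton(40, seed = 11, axonExitLeaf = TRUE)
  f <- withr::local_tempfile(fileext = ".swc")
  writeSWC(sk, f)
  sk2 <- readSWC(f)
  nd1 <- skeletonNodes(sk); nd2 <- skeletonNodes(sk2)
  expect_equal(nd2$node_id, nd1$node_id)
  expect_equal(nd2$parent_id, nd1$parent_id)
  expect_equal(nd2$tag, nd1$tag)
  expect_lt(max(abs(nd2$x - nd1$x), abs(nd2$y - nd1$y),
                abs(nd2$z - nd1$z)), 1e-6)
})

test_that("cable length sums edges and is zero for a bare root", {
  expect_equal(cableLength(chainSkeleton(c(2, 3))), 5)
  root <- Skeleton(data.frame(node_id = 1, parent_id = NA, x = 0, y = 0,
                              z = 0))
  expect_equal(cableLength(root), 0)
  sk <- randomSkeleton(50, seed = 3)
  nd <- skeletonNodes(sk)
  pidx <- match(nd$parent_id, nd$node_id)
  ok <- !is.na(pidx)
  oracle <- sum(sqrt((nd$x[ok] - nd$x[pidx[ok]])^2 +
                     (nd$y[ok] - nd$y[pidx[ok]])^2 +
                     (nd$z[ok] - nd$z[pidx[ok]])^2))
  expect_equal(cableLength(sk), oracle)
})

test_that("path distance matches the LCA oracle and is a tree metric", {
  sk <- chainSkeleton(c(2, 3))
  expect_equal(pathDistance(sk, 1, 1), 0)
  expect_equal(pathDistance(sk, 1, 3), 5)
  expect_error(pathDistance(sk, 1, 99), "unknown node")

  sk <- randomSkeleton(30, seed = 5)
  ids <- skeletonNodes(sk)$node_id
  for (a in ids[c(1, 7, 13)]) for (b in ids[c(2, 19, 30)]) {
    d <- pathDistance(sk, a, b)
    expect_equal(d, oraclePathDistance(sk, a, b), tolerance = 1e-10)
    expect_equal(d, pathDistance(sk, b, a))           # symmetry
    expect_true(d >= 0)
  }
  # triangle equality along a path: c on the a-b path
  anc <- oracleAncestors(sk, 30)
  if (length(anc) >= 3) {
    a <- anc[1]; cmid <- anc[2]; b <- anc[length(anc)]
    expect_equal(pathDistance(sk, a, b),
                 pathDistance(sk, a, cmid) + pathDistance(sk, cmid, b))
  }
})

test_that("distance to soma follows path distance to the root", {
  sk <- chainSkeleton(c(2, 3))
  tab <- simpleSynapseTable(c(1, 3))
  d <- distanceToSoma(sk, tab)
  expect_equal(unname(d), c(0, 5))
  expect_named(d, c("s1", "s2"))

  sk <- randomSkeleton(40, seed = 9)
  nodes <- sample(skeletonNodes(sk)$node_id, 12)
  d <- distanceToSoma(sk, simpleSynapseTable(nodes))
  oracle <- vapply(nodes, function(v) oraclePathDistance(sk, v, 1),
                   numeric(1))
  expect_equal(unname(d), oracle, tolerance = 1e-10)
})

test_that("primary neurite is the unique root-to-exit path", {
  sk <- chainSkeleton(c(1, 1, 1), tagTip = TRUE)
  expect_equal(primaryNeurite(sk), 1:4)

  # Y tree: root 1 - 2, then branches 3 (left, exit) and 4 (right)
  nodes <- data.frame(node_id = 1:4, parent_id = c(NA, 1, 2, 2),
                      x = c(0, 1, 2, 2), y = c(0, 0, 1, -1), z = 0,
                      tag = c("soma", "neurite", "axon_exit", "neurite"))
  sk <- Skeleton(nodes)
  expect_equal(primaryNeurite(sk), c(1, 2, 3))

  expect_error(primaryNeurite(chainSkeleton(c(1, 1))), "axon-exit")

  sk <- randomSkeleton(35, seed = 21, axonExitLeaf = TRUE)
  exit <- skeletonNodes(sk)$node_id[skeletonNodes(sk)$tag == "axon_exit"]
  expect_equal(primaryNeurite(sk), rev(oracleAncestors(sk, exit)))
})

test_that("distance to primary neurite is a min over path nodes", {
  # side branch of length 7 off a tagged chain
  nodes <- data.frame(node_id = 1:4, parent_id = c(NA, 1, 2, 2),
                      x = c(0, 5, 10, 5), y = c(0, 0, 0, 7), z = 0,
                      tag = c("soma", "neurite", "axon_exit", "neurite"))
  sk <- Skeleton(nodes)
  d <- distanceToPrimaryNeurite(sk, simpleSynapseTable(c(2, 4)))
  expect_equal(unname(d), c(0, 7))

  sk <- randomSkeleton(35, seed = 33, axonExitLeaf = TRUE)
  pn <- primaryNeurite(sk)
  nodes <- sample(skeletonNodes(sk)$node_id, 10)
  tab <- simpleSynapseTable(nodes)
  d <- distanceToPrimaryNeurite(sk, tab)
  oracle <- vapply(nodes, function(v)
    min(vapply(pn, function(p) oraclePathDistance(sk, v, p), numeric(1))),
    numeric(1))
  expect_equal(unname(d), oracle, tolerance = 1e-10)
  # soma lies on the primary path
  expect_true(all(d <= distanceToSoma(sk, tab) + 1e-12))
})
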