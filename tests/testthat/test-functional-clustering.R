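mkAvg <- function(labels, ..., metric = metricSpec("pearson")) {
  V <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(V) <- 1
  K <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  diag(K) <- 1L
  for (w in list(...)) {
    V[w[[1]], w[[2]]] <- V[w[[2]], w[[1]]] <- as.numeric(w[[3]])
    K[w[[1]], w[[2]]] <- K[w[[2]], w[[1]]] <- 1L
  }
  new("AveragedMatrix", values = V, counts = K, metric = metric,
      nAnimals = 1L)
}

test_that("node-max thresholding keeps every neuron's strongest link", {
  avg <- mkAvg(c("n1", "n2", "n3"),
               list("n1", "n2", 0.9), list("n1", "n3", 0.4),
               list("n2", "n3", 0.7))
  net <- thresholdMatrix(avg)
  ## per-node maxima (0.9, 0.9, 0.7) -> tau = 0.7
  keys <- paste(net@edges$from, net@edges$to)
  expect_setequal(keys, c("n1 n2", "n2 n3"))
  expect_identical(net@nComponents, 1L)
  ## all weights equal: complete graph survives
  avg2 <- mkAvg(c("a", "b", "c"), list("a", "b", 0.5), list("a", "c", 0.5),
                list("b", "c", 0.5))
  expect_identical(nrow(thresholdMatrix(avg2)@edges), 3L)
  ## two neurons, one defined pair
  avg3 <- mkAvg(c("a", "b"), list("a", "b", 0.3))
  expect_identical(nrow(thresholdMatrix(avg3)@edges), 1L)
})

test_that("percolation thresholding stops at one component", {
  avg <- mkAvg(c("a", "b", "c", "d"),
               list("a", "b", 0.9), list("c", "d", 0.8),
               list("b", "c", 0.6), list("a", "d", 0.5),
               list("a", "c", 0.4))
  net <- thresholdMatrix(avg, rule = "percolation")
  keys <- paste(net@edges$from, net@edges$to)
  ## added in decreasing weight until connected: 0.9, 0.8, then 0.6 joins
  expect_setequal(keys, c("a b", "c d", "b c"))
  expect_identical(net@nComponents, 1L)
  expect_identical(net@rule, "percolation")
})

test_that("thresholding rejects an all-undefined matrix", {
  V <- matrix(NA_real_, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  K <- matrix(0L, 2, 2, dimnames = dimnames(V))
  avg <- new("AveragedMatrix", values = V, counts = K,
             metric = metricSpec("pearson"), nAnimals = 1L)
  expect_error(thresholdMatrix(avg), "all entries undefined")
})

mkNet <- function(labels, ...) {
  e <- do.call(rbind, lapply(list(...), function(w)
    data.frame(from = w[[1]], to = w[[2]], weight = as.numeric(w[[3]]),
               stringsAsFactors = FALSE)))
  if (is.null(e)) e <- data.frame(from = character(), to = character(),
                                  weight = numeric())
  g <- igraph::graph_from_data_frame(e, directed = FALSE, vertices = labels)
  new("FunctionalNetwork", labels = labels, edges = e,
      metric = metricSpec("pearson"), rule = "node-max",
      nComponents = as.integer(igraph::components(g)$no))
}

test_that("clique synchronization accepts strong cliques, isolates rest", {
  net <- mkNet(c("a", "b", "c", "d"),
               list("a", "b", 0.9), list("a", "c", 0.9),
               list("b", "c", 0.9), list("a", "d", 0.2))
  p <- cliqueSynchronization(net)
  cl <- lapply(clusters(p), sort)
  expect_true(any(vapply(cl, identical, logical(1), c("a", "b", "c"))))
  expect_true(any(vapply(cl, identical, logical(1), "d")))
  ## an isolated node is its own singleton
  net2 <- mkNet(c("a", "b", "z"), list("a", "b", 0.5))
  expect_true(any(vapply(clusters(cliqueSynchronization(net2)),
                         identical, logical(1), "z")))
})

test_that("a dominant external edge rejects the clique", {
  net <- mkNet(c("a", "b", "c", "d"),
               list("a", "b", 0.9), list("a", "c", 0.9),
               list("b", "c", 0.9), list("a", "d", 1.0))
  p <- cliqueSynchronization(net)
  cl <- lapply(clusters(p), sort)
  expect_false(any(vapply(cl, identical, logical(1), c("a", "b", "c"))))
})

test_that("every emitted clique satisfies the synchrony certificate", {
  set.seed(31)
  for (rep in 1:20) {
    labs <- letters[1:7]
    pool <- t(combn(labs, 2))
    keep <- runif(nrow(pool)) < 0.5
    if (!any(keep)) next
    args <- lapply(which(keep), function(k)
      list(pool[k, 1], pool[k, 2], runif(1, 0.1, 1)))
    net <- do.call(mkNet, c(list(labs), args))
    p <- cliqueSynchronization(net)
    W <- matrix(0, 7, 7, dimnames = list(labs, labs))
    for (a in args) {
      W[a[[1]], a[[2]]] <- W[a[[2]], a[[1]]] <- a[[3]]
    }
    for (cl in clusters(p)) {
      N <- length(cl)
      if (N < 2) next
      expect_true(all(W[cl, cl][upper.tri(W[cl, cl])] > 0))  # clique
      internal <- sum(W[cl, cl]) / 2
      for (k in cl) {
        outs <- setdiff(names(which(W[k, ] > 0)), cl)
        for (k2 in outs)
          expect_gte(internal, N * (N - 1) / 2 * W[k, k2] - 1e-9)
      }
    }
    ## partitions are disjoint and exhaustive
    expect_setequal(unlist(clusters(p)), labs)
  }
})

test_that("louvain finds the two-triangle split with Q = 1/2", {
  net <- mkNet(letters[1:6],
               list("a", "b", 1), list("a", "c", 1), list("b", "c", 1),
               list("d", "e", 1), list("d", "f", 1), list("e", "f", 1))
  p <- louvainPartition(net, nRuns = 20, seed = 3)
  cl <- lapply(clusters(p), sort)
  expect_setequal(cl, list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(evalModularity(net, p), 0.5, tolerance = 1e-12)
  ## one triangle: single community, Q identically 0
  net1 <- mkNet(c("a", "b", "c"),
                list("a", "b", 1), list("a", "c", 1), list("b", "c", 1))
  p1 <- louvainPartition(net1, nRuns = 5, seed = 3)
  expect_identical(nClusters(p1), 1L)
  expect_equal(evalModularity(net1, p1), 0, tolerance = 1e-12)
})

test_that("reported modularity equals igraph's weighted modularity", {
  set.seed(9)
  pg <- smallPlanted()
  tr <- simulateDynamics(pg, simulationConfig(noiseSd = 0.05,
                                              duration = 10, dt = 0.1,
                                              seed = 3))
  net <- thresholdMatrix(cohortAverage(list(
    computeMetric(tr, metricSpec("los", 0.1)))))
  p <- louvainPartition(net, nRuns = 25, seed = 5)
  g <- igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                     vertices = net@labels)
  mem <- membershipVector(p)[igraph::V(g)$name]
  expect_equal(evalModularity(net, p),
               igraph::modularity(g, as.integer(factor(mem)),
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("louvain is deterministic under a fixed seed", {
  net <- mkNet(letters[1:5], list("a", "b", 1), list("b", "c", 0.5),
               list("c", "d", 1), list("d", "e", 0.4), list("e", "a", 0.8))
  p1 <- louvainPartition(net, nRuns = 50, seed = 7)
  p2 <- louvainPartition(net, nRuns = 50, seed = 7)
  expect_true(samePartition(p1, p2))
})

test_that("deduplication treats partitions as unordered set partitions", {
  p1 <- syncPartition(list(c("a", "b"), "c"), provenance = "m1")
  p2 <- syncPartition(list("c", c("b", "a")), provenance = "m2")
  p3 <- syncPartition(list(c("a", "c"), "b"), provenance = "m3")
  out <- dedupPartitions(list(p1, p2, p3))
  expect_identical(length(out), 2L)
  expect_setequal(out[[1]]@provenance, c("m1", "m2"))
  expect_identical(dedupPartitions(list()), list())
})
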