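test_that("connectome CSV I/O round-trips and rejects malformed input", {
  g <- connectome(c("u", "v", "w"),
                  data.frame(source = c("u", "w"), target = c("v", "v"),
                             weight = c(1, 2)))
  path <- tempfile(fileext = ".csv")
  writeConnectome(g, path)
  back <- readConnectome(path)
  expect_setequal(nodeLabels(back), nodeLabels(g))
  eo <- g@edges[order(g@edges$source), ]
  eb <- back@edges[order(back@edges$source), ]
  expect_equal(unname(as.matrix(eo[1:3])), unname(as.matrix(eb[1:3])))
  ## a 2-line file makes 3 nodes / 2 edges
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("source,target,weight", "u,v,1", "w,v,1"), p2)
  g2 <- readConnectome(p2)
  expect_identical(nrow(g2@nodes), 3L)
  expect_identical(nrow(g2@edges), 2L)
  ## duplicate pair and negative weight are named errors
  pd <- tempfile(fileext = ".csv")
  writeLines(c("source,target,weight", "u,v,1", "u,v,2"), pd)
  expect_error(readConnectome(pd), "duplicate edge \\(u -> v\\)")
  pn <- tempfile(fileext = ".csv")
  writeLines(c("source,target,weight", "u,v,-1"), pn)
  expect_error(readConnectome(pn), "negative weight")
  ## larger round trip
  pg <- generateFiberedGraph(4, c(2, 3, 2, 3), baseDensity = 0.6, seed = 9)
  p3 <- tempfile(fileext = ".csv")
  writeConnectome(pg@graph, p3)
  expect_true(samePartition(
    minimalBalancedColoring(readConnectome(p3))@partition, pg@planted))
})

test_that("bilateral collapsing ORs topology and sums pre-weights", {
  g <- connectome(
    data.frame(label = c("AVAL", "AVAR", "VA1", "VA2"),
               role = c("interneuron", "interneuron", "motorneuron",
                        "motorneuron")),
    data.frame(source = c("AVAL", "AVAR", "AVAL"),
               target = c("VA1", "VA1", "VA2"),
               weight = c(2, 3, 4)))
  cg <- collapseBilateral(g, list(AVA = c("AVAL", "AVAR")))
  expect_true(cg@collapsed)
  e <- cg@edges
  both <- e[e$source == "AVA" & e$target == "VA1", ]
  expect_identical(both$weight, 1)          # binarised
  expect_identical(both$preWeight, 5)       # 2 + 3
  one <- e[e$source == "AVA" & e$target == "VA2", ]
  expect_identical(one$weight, 1)
  expect_identical(one$preWeight, 4)
  expect_identical(nrow(e), 2L)             # absent edges stay absent
  expect_identical(cg@nodes$role[cg@nodes$label == "AVA"], "interneuron")
  ## within-pair edges would self-loop: dropped with a warning
  g2 <- connectome(c("AVAL", "AVAR", "VA1"),
                   data.frame(source = c("AVAL", "AVAL"),
                              target = c("AVAR", "VA1"), weight = 1))
  expect_warning(cg2 <- collapseBilateral(g2, list(AVA = c("AVAL", "AVAR"))),
                 "self-loop")
  expect_identical(nrow(cg2@edges), 1L)
  ## overlapping pairs are rejected
  expect_error(collapseBilateral(g, list(AVA = c("AVAL", "AVAR"),
                                         AVB = c("AVAR", "VA1"))),
               "overlapping")
})

test_that("balance verification matches hand-checked cases", {
  ## two-colour pattern: each red gets one red input, each green two red
  g <- connectome(c("r1", "r2", "g1", "g2"),
                  data.frame(source = c("r1", "r2", "r1", "r2", "r1", "r2"),
                             target = c("r2", "r1", "g1", "g1", "g2", "g2"),
                             weight = 1))
  col <- syncPartition(list(c("r1", "r2"), c("g1", "g2")))
  expect_true(isBalanced(g, col))
  ## directed 3-cycle, one colour
  cyc <- connectome(c("a", "b", "c"),
                    data.frame(source = c("a", "b", "c"),
                               target = c("b", "c", "a"), weight = 1))
  expect_true(isBalanced(cyc, syncPartition(list(c("a", "b", "c")))))
  ## a->b, a->c, d->b with {b, c} shared is unbalanced; the report names
  ## both members and their counts from the cluster containing d
  g3 <- connectome(c("a", "b", "c", "d"),
                   data.frame(source = c("a", "a", "d"),
                              target = c("b", "c", "b"), weight = 1))
  col3 <- syncPartition(list("a", c("b", "c"), "d"))
  ok <- isBalanced(g3, col3)
  expect_false(ok)
  v <- attr(ok, "violations")
  expect_setequal(v$node, c("b", "c"))
  expect_setequal(v$observed, c(1, 0))
})

test_that("weight mode reads integer weights as multiplicities", {
  g <- connectome(c("s", "x", "y"),
                  data.frame(source = c("s", "s"), target = c("x", "y"),
                             weight = c(2, 1)))
  col <- syncPartition(list("s", c("x", "y")))
  expect_false(isBalanced(g, col, mode = "weight"))
  expect_true(isBalanced(g, col, mode = "binary"))
})

test_that("coarsest refinement matches canonical small cases", {
  cyc <- connectome(letters[1:5],
                    data.frame(source = letters[1:5],
                               target = letters[c(2:5, 1)], weight = 1))
  expect_identical(nClusters(minimalBalancedColoring(cyc)), 1L)
  star <- connectome(c("hub", "l1", "l2", "l3"),
                     data.frame(source = c("l1", "l2", "l3"),
                                target = "hub", weight = 1))
  mbc <- minimalBalancedColoring(star)
  expect_true(samePartition(mbc@partition,
                            syncPartition(list("hub", c("l1", "l2", "l3")))))
})

test_that("refinement equals the naive oracle on random digraphs", {
  for (seed in 1:30) {
    set.seed(seed + 1000)
    n <- sample(3:8, 1)
    nodes <- letters[seq_len(n)]
    pool <- expand.grid(source = nodes, target = nodes,
                        stringsAsFactors = FALSE)
    pool <- pool[pool$source != pool$target, ]
    edges <- pool[runif(nrow(pool)) < 0.3, , drop = FALSE]
    g <- connectome(nodes, edges)
    mbc <- minimalBalancedColoring(g)
    expect_true(isBalanced(g, mbc))
    A <- oracleAdjacency(nodes, g@edges)
    expect_true(oracleSamePartition(oracleRefine(A),
                                    unname(clusters(mbc))))
    ## minimality: no two fibers share an input-count profile
    M <- fibrationRepair:::.inCountMatrix(g, clusters(mbc))
    reps <- vapply(clusters(mbc), `[`, character(1), 1L)
    prof <- apply(M[reps, , drop = FALSE], 1L, paste, collapse = ",")
    expect_false(anyDuplicated(prof) > 0)
    ## fibers coincide with input-tree isomorphism classes at depth |V|
    sig <- inputTreeSignatures(g, depth = n)
    expect_true(oracleSamePartition(unname(split(names(sig), sig)),
                                    unname(clusters(mbc))))
  }
})

test_that("refinement is equivariant under node relabeling", {
  set.seed(77)
  pg <- generateFiberedGraph(3, c(2, 2, 3), baseDensity = 0.7, seed = 15)
  g <- pg@graph
  perm <- sample(nodeLabels(g))
  names(perm) <- nodeLabels(g)
  e <- g@edges
  g2 <- connectome(unname(perm),
                   data.frame(source = unname(perm[e$source]),
                              target = unname(perm[e$target]),
                              weight = e$weight))
  m1 <- clusters(minimalBalancedColoring(g))
  m2 <- clusters(minimalBalancedColoring(g2))
  relabeled <- lapply(m1, function(cl) sort(unname(perm[cl])))
  expect_true(oracleSamePartition(unname(relabeled), unname(m2)))
})

test_that("refinement respects a seed partition and rigid pre-splits", {
  cyc <- connectome(c("a", "b", "c", "d"),
                    data.frame(source = c("a", "b", "c", "d"),
                               target = c("b", "c", "d", "a"), weight = 1))
  seeded <- minimalBalancedColoring(
    cyc, seed = syncPartition(list("a", c("b", "c", "d"))))
  ## splitting a 4-cycle at one node forces alternating refinement
  expect_gte(nClusters(seeded), 2L)
  expect_true(isBalanced(cyc, seeded))
})

test_that("input trees behave as layered in-neighbourhoods", {
  g <- connectome(c("a", "b", "c", "d"),
                  data.frame(source = c("a", "a", "b", "c"),
                             target = c("b", "c", "d", "d"), weight = 1))
  t1 <- inputTree(g, "d", 1)
  expect_setequal(vapply(t1$inputs, `[[`, character(1), "node"),
                  c("b", "c"))
  t2 <- inputTree(g, "d", 2)
  expect_setequal(
    unlist(lapply(t2$inputs, function(x)
      vapply(x$inputs, `[[`, character(1), "node"))),
    c("a", "a"))
  ## different in-degrees: non-isomorphic at depth 1
  expect_false(inputTreesIsomorphic(g, "a", "d", depth = 1))
  ## same planted fiber: isomorphic at depth |V|
  pg <- smallPlanted()
  f <- clusters(pg@planted)[[2]]
  expect_true(inputTreesIsomorphic(pg@graph, f[1], f[2],
                                   depth = length(nodeLabels(pg))))
})

test_that("base graphs satisfy the lifting property and round-trip", {
  ## two-colour example collapses to a 2-node base
  g <- connectome(c("r1", "r2", "g1", "g2"),
                  data.frame(source = c("r1", "r2", "r1", "r2", "r1", "r2"),
                             target = c("r2", "r1", "g1", "g1", "g2", "g2"),
                             weight = 1))
  col <- syncPartition(list(c("r1", "r2"), c("g1", "g2")))
  bg <- buildBase(g, col)
  expect_identical(length(unique(fiberMap(bg))), 2L)
  expect_identical(sum(bg@edges$multiplicity), 3)   # 1 red->red, 2 red->green
  ## all-singleton coloring: base isomorphic to the graph
  singl <- syncPartition(as.list(nodeLabels(g)))
  bgs <- buildBase(g, singl)
  expect_identical(nrow(bgs@edges), nrow(g@edges))
  expect_true(all(bgs@edges$multiplicity == 1))
  ## generated lift: buildBase recovers the generating base
  pg <- generateFiberedGraph(4, c(2, 1, 3, 2), baseDensity = 0.6, seed = 21)
  bgl <- buildBase(pg@graph, pg@planted)
  expect_equal(bgl@edges[c("source", "target", "multiplicity")],
               pg@baseEdges[c("source", "target", "multiplicity")])
  ## unbalanced coloring is refused with the violation report
  bad <- syncPartition(list(c("r1", "g1"), c("r2", "g2")))
  expect_error(buildBase(g, bad), "not balanced")
})
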