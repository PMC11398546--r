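## The 3-node instance used throughout: one edge u -> v, target {u}, {v, w}.
threeNode <- function(mode = "strict") {
  g <- connectome(c("u", "v", "w"),
                  data.frame(source = "u", target = "v", weight = 1))
  repairProblem(g, syncPartition(list("u", c("v", "w"))),
                unbalancingMode = mode)
}

test_that("model dimensions match the hand enumeration on 3 nodes", {
  ## n = 3, |E| = 1 (1 r-variable), |E^C| = 5 (a-variables);
  ## 2 clusters -> 1 representative pair x 2 clusters x 2 directions = 4 s
  mNone <- buildRepairModel(threeNode(), mode = "none")
  expect_identical(nrow(mNone$vars), 6L)          # 1 r + 5 a
  expect_identical(sum(mNone$vars$kind == "s"), 0L)
  ## balance: cluster {v, w} chained once against each of 2 clusters
  expect_identical(mNone$meta$nCons, 2L)
  mRel <- buildRepairModel(threeNode(), mode = "relaxed")
  expect_identical(nrow(mRel$vars), 10L)          # + 4 s
  ## + per cluster R: Eq17, Eq18, Eq19 (2 x 3) and one relaxed Eq20a
  expect_identical(mRel$meta$nCons, 9L)
  mStr <- buildRepairModel(threeNode(), mode = "strict")
  expect_identical(nrow(mStr$vars), 10L)
  expect_identical(mStr$meta$nCons, 10L)          # Eq20b in both directions
  ## objective prices r with alpha and a with beta, s free
  expect_identical(mRel$obj, c(1, rep(1, 5), rep(0, 4)))
})

test_that("an already-balanced target solves at objective zero", {
  g <- connectome(c("a", "b", "c"),
                  data.frame(source = c("a", "a"), target = c("b", "c"),
                             weight = 1))
  pr <- repairProblem(g, syncPartition(list("a", c("b", "c"))),
                      unbalancingMode = "none")
  s <- solveRepair(pr)
  expect_identical(s@status, "optimal")
  expect_identical(s@objective, 0)
  expect_identical(nrow(s@removed) + nrow(s@added), 0L)
  expect_true(s@verification$balanced)
})

test_that("the 3-node strict repair adds u -> w at objective one", {
  ## removing u -> v would also balance, but the refinement then collapses
  ## {u} with {v, w}; minimality forces the addition
  s <- solveRepair(threeNode("strict"))
  expect_identical(s@status, "optimal")
  expect_identical(s@objective, 1)
  expect_identical(nrow(s@removed), 0L)
  expect_identical(paste(s@added$source, s@added$target), "u w")
  expect_true(s@verification$balanced)
  expect_true(s@verification$minimal)
  ## oracle agreement
  expect_identical(
    oracleRepair(c("u", "v", "w"),
                 data.frame(source = "u", target = "v"),
                 list("u", c("v", "w")), mode = "strict"), 1)
})

test_that("penalty weights steer the optimum between add and remove", {
  ## gap-2 block: c receives two edges from {a, b}, d none. Balance needs
  ## 2 additions, 2 removals, or a 1+1 mix; oracle-verified optima:
  nodes <- c("a", "b", "c", "d")
  edges <- data.frame(source = c("a", "b"), target = c("c", "c"))
  target <- list(c("a", "b"), c("c", "d"))
  g <- connectome(nodes, data.frame(edges, weight = 1))
  expect_identical(oracleRepair(nodes, edges, target, 1, 1, "none"), 2)
  expect_identical(oracleRepair(nodes, edges, target, 1, 3, "none"), 2)
  pr11 <- repairProblem(g, syncPartition(target), alpha = 1, beta = 1,
                        unbalancingMode = "none")
  s11 <- solveRepair(pr11)
  expect_identical(s11@objective, 2)
  pr13 <- repairProblem(g, syncPartition(target), alpha = 1, beta = 3,
                        unbalancingMode = "none")
  s13 <- solveRepair(pr13)
  expect_identical(s13@objective, 2)
  expect_identical(nrow(s13@removed), 2L)   # only pure removal costs 2
  expect_identical(nrow(s13@added), 0L)
  pr31 <- repairProblem(g, syncPartition(target), alpha = 3, beta = 1,
                        unbalancingMode = "none")
  s31 <- solveRepair(pr31)
  expect_identical(s31@objective, 2)
  expect_identical(nrow(s31@added), 2L)     # and only pure addition
})

test_that("objectives agree with the exhaustive oracle on a battery", {
  ## the full 200-instance battery runs in the acceptance suite; this is a
  ## fast sentinel of the same property
  for (seed in 1:25) {
    inst <- randomRepairInstance(seed)
    g <- connectome(inst$nodes, data.frame(inst$edges, weight = 1))
    target <- syncPartition(inst$clusterList)
    for (mode in c("none", "strict")) {
      s <- solveRepair(repairProblem(g, target, unbalancingMode = mode))
      o <- oracleRepair(inst$nodes, inst$edges, inst$clusterList,
                        mode = mode, cap = 6L)
      if (is.finite(o)) {
        expect_identical(s@status, "optimal")
        expect_equal(s@objective, o,
                     info = sprintf("seed %d mode %s", seed, mode))
        if (mode == "strict") expect_true(s@verification$minimal)
      } else {
        expect_true(s@status != "optimal" || s@objective > 6)
      }
    }
  }
})

test_that("direct and staged strict solves agree", {
  for (seed in c(3, 11, 19)) {
    inst <- randomRepairInstance(seed)
    g <- connectome(inst$nodes, data.frame(inst$edges, weight = 1))
    pr <- repairProblem(g, syncPartition(inst$clusterList),
                        unbalancingMode = "strict")
    a <- solveRepairBatch(list(pr))[[1]]
    b <- solveRepairBatch(list(pr), directStrict = TRUE)[[1]]
    expect_identical(a@status, b@status)
    if (a@status == "optimal") expect_equal(a@objective, b@objective)
  }
})

test_that("solutions are verified independently of the solver", {
  pr <- threeNode("strict")
  s <- solveRepair(pr)
  v <- verifySolution(pr, s)
  expect_true(v$balanced)
  expect_true(v$minimal)
  ## hand-built alternative: removing u -> v balances but is not minimal
  alt <- new("RepairSolution",
             removed = data.frame(source = "u", target = "v"),
             added = data.frame(source = character(), target = character()),
             imbalance = data.frame(p = character(), q = character(),
                                    R = character()),
             objective = 1, status = "optimal",
             verification = list(balanced = NA, minimal = NA),
             modeUsed = "strict", nSolves = 0L)
  vAlt <- verifySolution(pr, alt)
  expect_true(vAlt$balanced)
  expect_false(vAlt$minimal)
  ## a solution that breaks balance is reported with violations
  bad <- new("RepairSolution",
             removed = data.frame(source = character(), target = character()),
             added = data.frame(source = "v", target = "w"),
             imbalance = data.frame(p = character(), q = character(),
                                    R = character()),
             objective = 1, status = "optimal",
             verification = list(balanced = NA, minimal = NA),
             modeUsed = "strict", nSolves = 0L)
  vBad <- verifySolution(pr, bad)
  expect_false(vBad$balanced)
  expect_gt(nrow(vBad$violations), 0)
})

test_that("objective is monotone in the penalties", {
  inst <- randomRepairInstance(8)
  g <- connectome(inst$nodes, data.frame(inst$edges, weight = 1))
  target <- syncPartition(inst$clusterList)
  objs <- vapply(1:4, function(b) {
    solveRepair(repairProblem(g, target, alpha = 1, beta = b,
                              unbalancingMode = "none"))@objective
  }, numeric(1))
  expect_true(all(diff(objs) >= -1e-9))
})

test_that("penalty sweeps report counts and percentages", {
  pr <- threeNode("strict")
  tab <- penaltySweep(pr, betas = 1:3)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$status == "optimal"))
  expect_true(all(diff(tab$objective) >= -1e-9))
  expect_true(all(diff(tab$nAdded) <= 0))   # additions never increase
  expect_equal(tab$modificationPct,
               100 * tab$nModifications / nrow(pr@connectome@edges))
  ## balanced instance: a sweep of zeros
  g <- connectome(c("a", "b"), data.frame(source = "a", target = "b",
                                          weight = 1))
  pr0 <- repairProblem(g, syncPartition(list("a", "b")),
                       unbalancingMode = "none")
  tab0 <- penaltySweep(pr0, betas = 1:3)
  expect_true(all(tab0$objective == 0))
})

test_that("weighted modification costs use pre-binarisation weights", {
  g <- connectome(
    data.frame(label = c("AVAL", "AVAR", "x", "y"),
               role = c("interneuron", "interneuron", "motorneuron",
                        "motorneuron")),
    data.frame(source = c("AVAL", "AVAR", "AVAL"),
               target = c("x", "x", "y"), weight = c(2, 3, 1)))
  cg <- collapseBilateral(g, list(AVA = c("AVAL", "AVAR")))
  pr <- repairProblem(cg, syncPartition(list("AVA", c("x", "y"))),
                      unbalancingMode = "none")
  s <- solveRepair(pr)
  expect_identical(s@objective, 0)    # already balanced after collapse
  ## force a removal of the heavy collapsed edge to compare cost modes
  rem <- new("RepairSolution",
             removed = data.frame(source = "AVA", target = "x"),
             added = data.frame(source = character(), target = character()),
             imbalance = data.frame(p = character(), q = character(),
                                    R = character()),
             objective = 1, status = "optimal",
             verification = list(balanced = NA, minimal = NA),
             modeUsed = "none", nSolves = 0L)
  expect_equal(modificationPercent(pr, rem), 100 * 1 / 2)
  expect_equal(modificationPercent(pr, rem, weighted = TRUE),
               100 * 5 / 2)
})

test_that("forbidden removals and candidate restrictions are honoured", {
  g <- connectome(c("a", "b", "c"),
                  data.frame(source = c("a", "a"), target = c("b", "c"),
                             weight = 1))
  target <- syncPartition(list(c("a", "b"), "c"))
  full <- repairProblem(g, target, unbalancingMode = "none")
  sFull <- solveRepair(full)
  ## forbid touching a -> b: the solver must work around it
  frozen <- repairProblem(g, target,
                          forbiddenRemovals = data.frame(source = "a",
                                                         target = "b"),
                          unbalancingMode = "none")
  sFrozen <- solveRepair(frozen)
  expect_identical(sFrozen@status, "optimal")
  expect_false("a b" %in% paste(sFrozen@removed$source,
                                sFrozen@removed$target))
  expect_true(sFrozen@verification$balanced)
  expect_gte(sFrozen@objective, sFull@objective)
})
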