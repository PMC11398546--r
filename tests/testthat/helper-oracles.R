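## Independent oracles used to check the package's machinery. Everything in
## here is deliberately written against raw adjacency matrices, not the
## package's internal representations.

## Adjacency matrix (target row, source column) of a connectome-like edge
## data.frame, binary.
oracleAdjacency <- function(nodes, edges) {
  A <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  if (nrow(edges))
    for (k in seq_len(nrow(edges)))
      A[edges$target[k], edges$source[k]] <- 1L
  A
}

## Balance check on an adjacency matrix: every cluster member must have the
## same column-cluster in-count.
oracleBalanced <- function(A, clusterList) {
  nodes <- rownames(A)
  ind <- vapply(clusterList, function(cl) as.numeric(nodes %in% cl),
                numeric(length(nodes)))
  M <- A %*% ind
  all(vapply(clusterList, function(cl) {
    if (length(cl) < 2L) return(TRUE)
    all(apply(M[cl, , drop = FALSE], 2L,
              function(x) length(unique(x)) == 1L))
  }, logical(1)))
}

## Naive coarsest balanced coloring: repeated split of every class by the
## vector of in-counts from every current class, from a one-colour start.
oracleRefine <- function(A, seedClusters = NULL) {
  nodes <- rownames(A)
  cls <- if (is.null(seedClusters)) list(nodes) else seedClusters
  repeat {
    ind <- vapply(cls, function(cl) as.numeric(nodes %in% cl),
                  numeric(length(nodes)))
    M <- A %*% ind
    sig <- apply(M, 1L, paste, collapse = ",")
    nxt <- list()
    for (g in cls) {
      sp <- split(g, sig[match(g, nodes)])
      nxt <- c(nxt, unname(sp))
    }
    if (length(nxt) == length(cls)) return(cls)
    cls <- nxt
  }
}

oracleSamePartition <- function(a, b) {
  key <- function(x) sort(vapply(lapply(x, sort), paste, character(1),
                                 collapse = ","))
  identical(key(a), key(b))
}

## Exhaustive minimum-cost repair by enumeration over modification subsets
## in increasing modification count. mode "none": balanced only; "strict":
## balanced and the coarsest balanced coloring (one-colour seed) equals the
## target. Returns Inf if nothing is found within `cap` modifications.
oracleRepair <- function(nodes, edges, clusterList, alpha = 1, beta = 1,
                         mode = c("none", "strict"), cap = 6L) {
  mode <- match.arg(mode)
  A <- oracleAdjacency(nodes, edges)
  exist <- which(A == 1L, arr.ind = TRUE)
  nonedge <- which(A == 0L & row(A) != col(A), arr.ind = TRUE)
  toggles <- rbind(exist, nonedge)
  isAdd <- c(rep(FALSE, nrow(exist)), rep(TRUE, nrow(nonedge)))
  tcost <- ifelse(isAdd, beta, alpha)
  best <- Inf
  feasible <- function(B) {
    if (!oracleBalanced(B, clusterList)) return(FALSE)
    if (mode == "strict" &&
        !oracleSamePartition(oracleRefine(B), clusterList)) return(FALSE)
    TRUE
  }
  if (feasible(A)) return(0)
  for (m in seq_len(min(nrow(toggles), cap))) {
    cmb <- utils::combn(nrow(toggles), m)
    for (ci in seq_len(ncol(cmb))) {
      sel <- cmb[, ci]
      cost <- sum(tcost[sel])
      if (cost >= best) next
      B <- A
      B[toggles[sel, , drop = FALSE]] <- 1L - B[toggles[sel, , drop = FALSE]]
      if (feasible(B)) best <- cost
    }
    ## subsets are enumerated by count, not cost; with unequal alpha/beta a
    ## cheaper optimum may still hide at a larger count, so only stop once
    ## no larger count could beat the incumbent
    if (is.finite(best) && best <= (m + 1L) * min(alpha, beta)) break
  }
  best
}

## Random digraph + random target coloring battery used by the acceptance
## suite and the unit tests.
randomRepairInstance <- function(seed, maxNodes = 5L) {
  set.seed(seed)
  n <- sample(3:maxNodes, 1L)
  nodes <- letters[seq_len(n)]
  pool <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  pool <- pool[pool$source != pool$target, , drop = FALSE]
  ne <- sample.int(nrow(pool), 1L)
  edges <- pool[sample.int(nrow(pool), ne), , drop = FALSE]
  k <- sample(2:min(3L, n), 1L)
  mem <- sample(rep_len(seq_len(k), n))
  clusterList <- unname(split(nodes, mem))
  list(nodes = nodes, edges = edges, clusterList = clusterList)
}

## Shared small planted fixture for simulator tests.
smallPlanted <- function(seed = 11L) {
  generateFiberedGraph(3L, c(2L, 3L, 2L), baseDensity = 0.7, seed = seed)
}
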