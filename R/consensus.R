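## Consensus across (metric x method) partitions: co-occurrence fusion and
## Ward hierarchical clustering of the consensus matrix.

#' Co-occurrence matrix of one partition
#'
#' @param p a [SyncPartition-class] covering a subset of `labels`.
#' @param labels label universe of the output matrix.
#' @return binary matrix over `labels`: entry (i, j) is 1 iff i and j share
#'   a cluster in `p`; the diagonal is 1 for covered labels, 0 otherwise.
#' @export
coOccurrence <- function(p, labels) {
  M <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (cl in p@clusters) {
    cl <- intersect(cl, labels)
    M[cl, cl] <- 1L
  }
  M
}

#' Consensus matrix across many partitions
#'
#' Entry (i, j) is the fraction of partitions, among those containing both
#' labels, that co-assign i and j; the per-pair denominator mirrors the
#' cohort-averaging rule used upstream for matrices with missing neurons.
#'
#' @param partitions non-empty list of [SyncPartition-class].
#' @return a [ConsensusMatrix-class] over the union of all labels.
#' @export
consensusMatrix <- function(partitions) {
  if (length(partitions) == 0L) stop("invalid argument: no partitions")
  labs <- sort(unique(unlist(lapply(partitions, neuronLabels))))
  acc <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  cnt <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (p in partitions) {
    l <- neuronLabels(p)
    acc[l, l] <- acc[l, l] + coOccurrence(p, l)
    cnt[l, l] <- cnt[l, l] + 1L
  }
  X <- acc / cnt
  X[cnt == 0L] <- NA_real_
  new("ConsensusMatrix", values = X, counts = cnt,
      nPartitions = length(partitions))
}

#' Ward linkage of a consensus matrix
#'
#' Agglomerative clustering with the Lance-Williams Ward update applied to
#' the dissimilarity `1 - X` directly (no embedding step), with leaves
#' arranged by exact optimal leaf ordering for display. Pairs with no
#' defined consensus (never co-observed) are treated as fully dissimilar.
#'
#' @param X a [ConsensusMatrix-class].
#' @return an `hclust` object whose `$order` is optimal-leaf-ordered.
#' @export
wardLinkage <- function(X) {
  D <- 1 - X@values
  if (anyNA(D)) {
    warning("undefined consensus pairs treated as dissimilarity 1")
    D[is.na(D)] <- 1
  }
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D")
  hc$order <- .optimalLeafOrder(hc, D)
  hc
}

## Exact optimal leaf ordering (Bar-Joseph style dynamic programme): among
## the 2^(n-1) orderings consistent with the tree, minimise the summed
## dissimilarity between adjacent leaves. Sizes here are small (tens of
## neurons), so the O(n^3)-ish DP is immediate.
.optimalLeafOrder <- function(hc, D) {
  n <- length(hc$order)
  ## per internal node: list(leaves, M[i, j] = best cost of arrangements
  ## with leftmost leaf i and rightmost leaf j, plus backtracking info)
  nodes <- vector("list", n - 1L)
  leafInfo <- function(v) {
    if (v < 0) {
      i <- -v
      list(leaves = i, M = matrix(0, 1, 1, dimnames = list(i, i)))
    } else nodes[[v]]
  }
  for (k in seq_len(n - 1L)) {
    L <- leafInfo(hc$merge[k, 1L]); R <- leafInfo(hc$merge[k, 2L])
    ll <- L$leaves; rl <- R$leaves
    ## best cost from leaf u (boundary of L) to leaf w (boundary of R):
    ## min over adjacent pair (k in L, l in R)
    bridge <- D[ll, rl, drop = FALSE]
    ## costLR[u, w] = min_{kk, llv} L$M[u, kk] + D[kk, llv] + R$M[llv, w]
    A <- L$M; B <- R$M
    costLR <- matrix(Inf, length(ll), length(rl), dimnames = list(ll, rl))
    for (u in seq_along(ll)) for (w in seq_along(rl))
      costLR[u, w] <- min(outer(A[u, ], B[, w], "+") + bridge)
    leaves <- c(ll, rl)
    M <- matrix(Inf, length(leaves), length(leaves),
                dimnames = list(leaves, leaves))
    M[seq_along(ll), length(ll) + seq_along(rl)] <- costLR
    M[length(ll) + seq_along(rl), seq_along(ll)] <- t(costLR)
    nodes[[k]] <- list(leaves = leaves, M = M)
  }
  root <- nodes[[n - 1L]]
  ends <- which(root$M == min(root$M), arr.ind = TRUE)[1L, ]
  ## reconstruct an ordering achieving the optimum by greedy re-derivation
  order_node <- function(v, i, j) {   # order leaves of v from leaf i to j
    if (v < 0) return(-v)
    L <- leafInfo(hc$merge[v, 1L]); R <- leafInfo(hc$merge[v, 2L])
    swap <- FALSE
    if (i %in% R$leaves) { tmp <- L; L <- R; R <- tmp; swap <- TRUE }
    ## choose the optimal junction (kk in L adjacent to llv in R)
    best <- c(NA, NA); bc <- Inf
    for (kk in L$leaves) for (llv in R$leaves) {
      cc <- L$M[as.character(i), as.character(kk)] + D[kk, llv] +
        R$M[as.character(llv), as.character(j)]
      if (cc < bc - 1e-12) { bc <- cc; best <- c(kk, llv) }
    }
    ml <- hc$merge[v, if (swap) 2L else 1L]
    mr <- hc$merge[v, if (swap) 1L else 2L]
    c(order_node(ml, i, best[1L]), order_node(mr, best[2L], j))
  }
  li <- as.integer(rownames(root$M)[ends[1L]])
  lj <- as.integer(colnames(root$M)[ends[2L]])
  order_node(n - 1L, li, lj)
}

#' Cut the consensus dendrogram at a height
#'
#' Cutting at `h` keeps every merge of Ward height `<= h`; lowering the
#' cutoff only refines the partition (never merges clusters).
#'
#' @param X a [ConsensusMatrix-class] or an `hclust` from [wardLinkage()].
#' @param cutoff non-negative cut height.
#' @return a [SyncPartition-class].
#' @examples
#' ps <- list(syncPartition(list(c("a", "b"), c("c", "d"))),
#'            syncPartition(list(c("a", "b"), c("c", "d"))))
#' wardCut(consensusMatrix(ps), 0.5)
#' @export
wardCut <- function(X, cutoff) {
  stopifnot(cutoff >= 0)
  hc <- if (inherits(X, "hclust")) X else wardLinkage(X)
  mem <- stats::cutree(hc, h = cutoff)
  partitionFromMembership(mem,
    provenance = sprintf("consensus|cutoff=%g", cutoff))
}
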