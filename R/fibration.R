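## Directed-graph fibration machinery: balanced colorings, coarsest
## equitable refinement, input trees, base graphs.

#' Construct a connectome
#'
#' @param nodes character vector of labels, or data.frame with columns
#'   `label` and `role`.
#' @param edges data.frame with columns `source`, `target`, `weight`
#'   (optionally `preWeight`). Missing `weight` defaults to 1.
#' @param collapsed logical(1).
#' @return a [Connectome-class].
#' @examples
#' connectome(c("u", "v", "w"),
#'            data.frame(source = "u", target = c("v", "w"), weight = 1))
#' @export
connectome <- function(nodes, edges = NULL, collapsed = FALSE) {
  if (is.character(nodes))
    nodes <- data.frame(label = nodes, role = "generic",
                        stringsAsFactors = FALSE)
  if (!"role" %in% names(nodes)) nodes$role <- "generic"
  if (is.null(edges) || nrow(edges) == 0L)
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), preWeight = numeric())
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (!"preWeight" %in% names(edges)) edges$preWeight <- edges$weight
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  rownames(edges) <- NULL
  new("Connectome",
      nodes = data.frame(label = as.character(nodes$label),
                         role = as.character(nodes$role),
                         stringsAsFactors = FALSE),
      edges = edges[c("source", "target", "weight", "preWeight")],
      collapsed = isTRUE(collapsed))
}

#' Convert a connectome to an igraph object
#'
#' @param x a [Connectome-class].
#' @return a directed `igraph` graph with a `weight` edge attribute.
#' @export
asIgraph <- function(x) {
  stopifnot(is(x, "Connectome"))
  igraph::graph_from_data_frame(
    x@edges[c("source", "target", "weight")],
    directed = TRUE, vertices = x@nodes$label)
}

## Node x cluster matrix of in-edge counts. mode "weight" reads integer edge
## weights as parallel-edge multiplicities; "binary" counts presence only.
.inCountMatrix <- function(conn, clusterList, mode = "weight") {
  labs <- conn@nodes$label
  K <- length(clusterList)
  cl_of <- rep(names(clusterList), vapply(clusterList, length, integer(1)))
  names(cl_of) <- unlist(clusterList, use.names = FALSE)
  M <- matrix(0, nrow = length(labs), ncol = K,
              dimnames = list(labs, names(clusterList)))
  e <- conn@edges
  if (nrow(e)) {
    w <- if (mode == "binary") rep(1, nrow(e)) else e$weight
    src_cl <- cl_of[e$source]
    for (k in seq_len(nrow(e)))
      M[e$target[k], src_cl[k]] <- M[e$target[k], src_cl[k]] + w[k]
  }
  M
}

#' Test whether a coloring is balanced
#'
#' A coloring is balanced (an equitable partition) when, for every ordered
#' cluster pair, all members of the receiving cluster get the same number of
#' in-edges from the source cluster. Returns `TRUE`/`FALSE` with a
#' `"violations"` attribute listing every offending (node, source-cluster)
#' pair with the observed counts.
#'
#' @param conn a [Connectome-class].
#' @param col a [Coloring-class] or [SyncPartition-class] covering all nodes.
#' @param mode `"weight"` to read integer edge weights as parallel-edge
#'   multiplicities, `"binary"` to count edge presence only.
#' @return logical(1) with attribute `violations` (a data.frame).
#' @examples
#' g <- connectome(c("a", "b", "c", "d"),
#'                 data.frame(source = c("a", "a", "d"),
#'                            target = c("b", "c", "b")))
#' isBalanced(g, syncPartition(list(c("b", "c"), "a", "d")))
#' @export
isBalanced <- function(conn, col, mode = c("weight", "binary")) {
  mode <- match.arg(mode)
  p <- if (is(col, "Coloring")) col@partition else col
  stopifnot(is(p, "SyncPartition"))
  if (!setequal(neuronLabels(p), conn@nodes$label))
    stop("coloring must cover exactly the connectome nodes")
  M <- .inCountMatrix(conn, p@clusters, mode)
  viol <- list()
  for (cn in names(p@clusters)) {
    members <- p@clusters[[cn]]
    if (length(members) < 2L) next
    sub <- M[members, , drop = FALSE]
    for (src in colnames(sub)) {
      cnt <- sub[, src]
      if (length(unique(cnt)) > 1L)
        viol[[length(viol) + 1L]] <- data.frame(
          cluster = cn, node = members, sourceCluster = src,
          observed = unname(cnt), stringsAsFactors = FALSE)
    }
  }
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(cluster = character(), node = character(),
               sourceCluster = character(), observed = numeric(),
               stringsAsFactors = FALSE)
  structure(nrow(viol) == 0L, violations = viol)
}

#' Coarsest balanced coloring (minimal fibration partition)
#'
#' Iterative split-by-input-profile refinement: starting from a seed
#' partition (one colour by default, rigid clusters pre-split if the seed is
#' a [Coloring-class]), clusters are repeatedly split by their members'
#' vectors of in-counts from each current cluster until a fixed point. The
#' fixed point is the coarsest balanced coloring refining the seed: it is
#' balanced and no two clusters share an identical input-count profile.
#'
#' @inheritParams isBalanced
#' @param seed optional seed partition ([Coloring-class] or
#'   [SyncPartition-class]); default one colour.
#' @return a [Coloring-class]; clusters are the fibers, named `f1`, `f2`,
#'   ... in order of their smallest member label.
#' @examples
#' star <- connectome(c("hub", "l1", "l2", "l3"),
#'                    data.frame(source = c("l1", "l2", "l3"),
#'                               target = "hub"))
#' minimalBalancedColoring(star)
#' @export
minimalBalancedColoring <- function(conn, seed = NULL,
                                    mode = c("weight", "binary")) {
  mode <- match.arg(mode)
  labs <- conn@nodes$label
  cl <- if (is.null(seed)) list(labs)
        else if (is(seed, "Coloring")) unname(seed@partition@clusters)
        else unname(seed@clusters)
  if (!setequal(unlist(cl), labs))
    stop("seed partition must cover exactly the connectome nodes")
  cl <- lapply(cl, sort)
  repeat {
    names(cl) <- paste0("k", seq_along(cl))
    M <- .inCountMatrix(conn, cl, mode)
    nxt <- list()
    for (g in cl) {
      prof <- apply(M[g, , drop = FALSE], 1L, paste, collapse = ",")
      pieces <- split(g, prof)
      pieces <- pieces[order(vapply(pieces, `[`, character(1), 1L))]
      nxt <- c(nxt, unname(pieces))
    }
    if (length(nxt) == length(cl)) { cl <- nxt; break }
    cl <- nxt
  }
  cl <- cl[order(vapply(cl, `[`, character(1), 1L))]
  names(cl) <- paste0("f", seq_along(cl))
  coloring(syncPartition(cl, provenance = "minimalBalancedColoring"))
}

## In-neighbour list with multiplicities (weight mode expands integer
## weights into repeated parents).
.inNeighbours <- function(conn, mode = "weight") {
  labs <- conn@nodes$label
  out <- stats::setNames(vector("list", length(labs)), labs)
  for (v in labs) out[[v]] <- character()
  e <- conn@edges
  if (nrow(e)) {
    reps <- if (mode == "binary") rep(1L, nrow(e)) else
      as.integer(round(e$weight))
    for (k in seq_len(nrow(e)))
      out[[e$target[k]]] <- c(out[[e$target[k]]],
                              rep(e$source[k], max(reps[k], 0L)))
  }
  out
}

#' Input tree of a node
#'
#' The rooted, layered tree of a node's iterated in-neighbourhoods: layer 1
#' is the node's input set, layer k+1 the input sets of layer k. Grows
#' exponentially with depth on dense graphs; intended for small graphs and
#' inspection. Isomorphism testing should use [inputTreeSignatures()].
#'
#' @inheritParams isBalanced
#' @param v node label.
#' @param depth positive integer number of layers.
#' @return nested list: `list(node = v, inputs = list(...))`.
#' @export
inputTree <- function(conn, v, depth, mode = c("weight", "binary")) {
  mode <- match.arg(mode)
  stopifnot(depth >= 1, v %in% conn@nodes$label)
  preds <- .inNeighbours(conn, mode)
  build <- function(u, d) {
    if (d == 0L) return(list(node = u, inputs = list()))
    list(node = u, inputs = lapply(preds[[u]], build, d = d - 1L))
  }
  build(v, depth)
}

#' Canonical input-tree signatures at a given depth
#'
#' Level-wise canonical encoding of every node's input tree: two nodes have
#' identical signatures at depth `d` iff their input trees agree down to `d`
#' layers. Equivalent to iterated multiset refinement, so it avoids the
#' exponential blow-up of the explicit trees.
#'
#' @inheritParams isBalanced
#' @param depth number of layers (defaults to the node count, which is
#'   enough to separate all separable nodes).
#' @return named character vector of signatures, one per node.
#' @export
inputTreeSignatures <- function(conn, depth = nrow(conn@nodes),
                                mode = c("weight", "binary")) {
  mode <- match.arg(mode)
  preds <- .inNeighbours(conn, mode)
  labs <- conn@nodes$label
  sig <- stats::setNames(rep("0", length(labs)), labs)
  for (d in seq_len(depth)) {
    raw <- vapply(labs, function(v)
      paste0("(", paste(sort(sig[preds[[v]]]), collapse = "|"), ")"),
      character(1))
    ## compress to ids so strings stay short across layers
    sig <- stats::setNames(as.character(match(raw, sort(unique(raw)))), labs)
    sig <- stats::setNames(paste0("d", d, ".", sig), labs)
  }
  sig
}

#' Test input-tree isomorphism between two nodes
#'
#' @inheritParams inputTreeSignatures
#' @param u,v node labels.
#' @return logical(1).
#' @export
inputTreesIsomorphic <- function(conn, u, v, depth = nrow(conn@nodes),
                                 mode = c("weight", "binary")) {
  mode <- match.arg(mode)
  s <- inputTreeSignatures(conn, depth, mode)
  unname(s[u] == s[v])
}

#' Build the base graph (quotient) of a balanced coloring
#'
#' One base node per fiber; the multiplicity of base edge `j -> i` is the
#' number of in-edges any member of fiber i receives from fiber j (well
#' defined because the coloring is balanced, which is checked first). The
#' lifting property is verified on the result.
#'
#' @inheritParams isBalanced
#' @return a [BaseGraph-class].
#' @export
buildBase <- function(conn, col, mode = c("weight", "binary")) {
  mode <- match.arg(mode)
  p <- if (is(col, "Coloring")) col@partition else col
  ok <- isBalanced(conn, p, mode)
  if (!ok) {
    v <- attr(ok, "violations")
    stop("coloring is not balanced; ", nrow(v),
         " violation rows (see isBalanced report)")
  }
  M <- .inCountMatrix(conn, p@clusters, mode)
  reps <- vapply(p@clusters, `[`, character(1), 1L)   # one member per fiber
  B <- M[reps, , drop = FALSE]                        # fiber x fiber counts
  rownames(B) <- names(p@clusters)
  idx <- which(B > 0, arr.ind = TRUE)
  edges <- data.frame(
    source = colnames(B)[idx[, "col"]],
    target = rownames(B)[idx[, "row"]],
    multiplicity = B[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  fmap <- rep(names(p@clusters), vapply(p@clusters, length, integer(1)))
  names(fmap) <- unlist(p@clusters, use.names = FALSE)
  new("BaseGraph", edges = edges, fiberMap = fmap[conn@nodes$label])
}
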