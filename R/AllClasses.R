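#' @import methods
NULL

## Central S4 containers. Validity methods enforce the structural invariants
## that every downstream stage relies on (finite traces, symmetric matrices,
## disjoint exhaustive partitions, non-negative edge weights).

#' MetricSpec: a pairwise synchrony measure
#'
#' Identifies one member of the metric bank: either the Level of
#' Synchronicity (LoS) at a given Gaussian bandwidth `sigma`, or one of the
#' five correlation-family measures (Pearson, Spearman, Kendall tau-b,
#' distance correlation, covariance).
#'
#' @slot family character, one of `"los"`, `"pearson"`, `"spearman"`,
#'   `"kendall"`, `"distance-correlation"`, `"covariance"`.
#' @slot sigma numeric(1) Gaussian bandwidth; only meaningful (and required)
#'   for `family = "los"`, `NA` otherwise.
#' @exportClass MetricSpec
setClass("MetricSpec",
  slots = c(family = "character", sigma = "numeric"))

.metricFamilies <- c("los", "pearson", "spearman", "kendall",
                     "distance-correlation", "covariance")

setValidity("MetricSpec", function(object) {
  if (length(object@family) != 1L || !object@family %in% .metricFamilies)
    return(sprintf("family must be one of: %s",
                   paste(.metricFamilies, collapse = ", ")))
  if (object@family == "los") {
    if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
        object@sigma <= 0)
      return("LoS requires a single positive finite sigma")
  }
  TRUE
})

#' TraceMatrix: one animal's neuron-by-time activity record
#'
#' Rows are neurons (rownames are the neuron labels), columns are time
#' samples. Values are dimensionless activity (DF/F0-style).
#'
#' @slot values numeric matrix, neurons x time, all finite, unique rownames.
#' @slot animalId character(1) identifier of the recording/animal.
#' @slot dt numeric(1) positive time step (arbitrary units).
#' @exportClass TraceMatrix
setClass("TraceMatrix",
  slots = c(values = "matrix", animalId = "character", dt = "numeric"))

setValidity("TraceMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be a numeric matrix")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("values must carry unique neuron labels as rownames")
  if (!all(is.finite(v))) return("all trace values must be finite")
  if (length(object@animalId) != 1L) return("animalId must be length 1")
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    return("dt must be a single positive number")
  TRUE
})

#' SynchronyMatrix: pairwise metric values for one animal
#'
#' @slot values symmetric numeric matrix over the animal's neuron labels.
#' @slot metric [MetricSpec-class] that produced it.
#' @slot animalId character(1).
#' @exportClass SynchronyMatrix
setClass("SynchronyMatrix",
  slots = c(values = "matrix", metric = "MetricSpec", animalId = "character"))

setValidity("SynchronyMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must be square with identical row/col labels")
  if (anyDuplicated(rownames(v))) return("duplicate neuron labels")
  if (!isSymmetric(unname(v), tol = 1e-10)) return("values must be symmetric")
  TRUE
})

#' AveragedMatrix: cohort-averaged synchrony with co-occurrence counts
#'
#' Entry (i, j) is the mean of the per-animal metric values over the animals
#' in which neurons i and j were both observed; `counts` records how many
#' animals that was. Entries with count 0 are `NA`.
#'
#' @slot values numeric matrix over the cohort's label union.
#' @slot counts integer matrix of pairwise co-occurrence counts.
#' @slot metric [MetricSpec-class].
#' @slot nAnimals integer(1) cohort size.
#' @exportClass AveragedMatrix
setClass("AveragedMatrix",
  slots = c(values = "matrix", counts = "matrix", metric = "MetricSpec",
            nAnimals = "integer"))

setValidity("AveragedMatrix", function(object) {
  v <- object@values; k <- object@counts
  if (!identical(dim(v), dim(k))) return("values/counts dimension mismatch")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must be square with identical row/col labels")
  if (!identical(rownames(v), rownames(k)))
    return("counts labels must match values labels")
  if (any(k < 0)) return("counts must be non-negative")
  if (!isSymmetric(unname(k))) return("counts must be symmetric")
  bad <- k == 0 & !is.na(v)
  if (any(bad)) return("entries with count 0 must be NA")
  TRUE
})

#' SyncPartition: a partition of neuron labels into synchrony clusters
#'
#' Clusters are disjoint, non-empty, and jointly cover the partition's label
#' set. Comparison and deduplication treat a partition as an unordered set of
#' label sets (cluster names are decorative).
#'
#' @slot clusters named list of character vectors.
#' @slot provenance character vector of free-form `(metric, method)` tags.
#' @exportClass SyncPartition
setClass("SyncPartition",
  slots = c(clusters = "list", provenance = "character"))

setValidity("SyncPartition", function(object) {
  cl <- object@clusters
  if (length(cl) == 0L) return("partition must contain at least one cluster")
  if (!all(vapply(cl, is.character, logical(1))))
    return("clusters must be character vectors")
  if (any(vapply(cl, length, integer(1)) == 0L)) return("empty cluster")
  all_labels <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(all_labels)) return("clusters must be disjoint")
  TRUE
})

#' FunctionalNetwork: thresholded undirected synchrony graph
#'
#' @slot labels character vector of node labels.
#' @slot edges data.frame with columns `from`, `to`, `weight`.
#' @slot metric [MetricSpec-class] the averaged matrix came from.
#' @slot rule character(1) thresholding rule used (`"node-max"` or
#'   `"percolation"`), kept as provenance because the two readings of the
#'   thresholding step can differ.
#' @slot nComponents integer(1) connected-component count after thresholding.
#' @exportClass FunctionalNetwork
setClass("FunctionalNetwork",
  slots = c(labels = "character", edges = "data.frame", metric = "MetricSpec",
            rule = "character", nComponents = "integer"))

setValidity("FunctionalNetwork", function(object) {
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges needs columns from, to, weight")
  if (nrow(e)) {
    if (any(e$from == e$to)) return("self-edges are not allowed")
    if (!all(c(e$from, e$to) %in% object@labels))
      return("edge endpoints must be listed labels")
  }
  TRUE
})

#' ConsensusMatrix: co-assignment frequencies across partitions
#'
#' @slot values numeric matrix in `[0, 1]`; entry (i, j) is the fraction of
#'   partitions containing both i and j that co-assign them.
#' @slot counts integer matrix; number of partitions containing both labels.
#' @slot nPartitions integer(1).
#' @exportClass ConsensusMatrix
setClass("ConsensusMatrix",
  slots = c(values = "matrix", counts = "matrix", nPartitions = "integer"))

setValidity("ConsensusMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values must be square and labelled")
  ok <- is.na(v) | (v >= -1e-12 & v <= 1 + 1e-12)
  if (!all(ok)) return("consensus values must lie in [0, 1]")
  if (!isSymmetric(unname(v))) return("values must be symmetric")
  TRUE
})

#' Connectome: a directed, weighted graph of labelled neurons
#'
#' Edge weights are non-negative; integer weights are read as parallel-edge
#' multiplicities by the balance machinery when `mode = "weight"`. After
#' bilateral collapsing, `weight` is the binarised (OR) topology and
#' `preWeight` retains the summed pre-binarisation weight used by the
#' weighted modification-cost mode.
#'
#' @slot nodes data.frame with columns `label` and `role`
#'   (`"interneuron"`, `"motorneuron"` or `"generic"`).
#' @slot edges data.frame with columns `source`, `target`, `weight`,
#'   `preWeight`.
#' @slot collapsed logical(1), whether bilateral collapsing was applied.
#' @exportClass Connectome
setClass("Connectome",
  slots = c(nodes = "data.frame", edges = "data.frame", collapsed = "logical"))

setValidity("Connectome", function(object) {
  nd <- object@nodes; e <- object@edges
  if (!all(c("label", "role") %in% names(nd)))
    return("nodes needs columns label, role")
  if (anyDuplicated(nd$label)) return("duplicate node labels")
  if (!all(nd$role %in% c("interneuron", "motorneuron", "generic")))
    return("roles must be interneuron, motorneuron or generic")
  if (!all(c("source", "target", "weight", "preWeight") %in% names(e)))
    return("edges needs columns source, target, weight, preWeight")
  if (nrow(e)) {
    if (!all(c(e$source, e$target) %in% nd$label))
      return("edge endpoints must be declared nodes")
    if (anyDuplicated(paste(e$source, e$target, sep = "\r")))
      return("duplicate (source, target) pairs")
    if (any(e$weight < 0)) return("negative edge weight")
  }
  TRUE
})

#' Coloring: a target partition over connectome nodes, with rigid clusters
#'
#' @slot partition [SyncPartition-class] over all connectome nodes.
#' @slot rigid character vector of cluster names whose membership must not be
#'   permuted (the interneuron convention: each interneuron pair is its own
#'   singleton cluster).
#' @exportClass Coloring
setClass("Coloring",
  slots = c(partition = "SyncPartition", rigid = "character"))

setValidity("Coloring", function(object) {
  if (!all(object@rigid %in% names(object@partition@clusters)))
    return("rigid must name clusters of the partition")
  TRUE
})

#' BaseGraph: quotient of a connectome under a balanced coloring
#'
#' One node per fiber; edge multiplicities are the per-member in-counts,
#' well defined by balance. Satisfies the lifting property with respect to
#' the graph it was built from.
#'
#' @slot edges data.frame with columns `source`, `target`, `multiplicity`.
#' @slot fiberMap named character vector, node label -> base node name.
#' @exportClass BaseGraph
setClass("BaseGraph",
  slots = c(edges = "data.frame", fiberMap = "character"))

#' PlantedGraph: a generated fibration-symmetric graph with known fibers
#'
#' @slot graph [Connectome-class] the lifted graph.
#' @slot planted [SyncPartition-class] the planted fibers.
#' @slot baseEdges data.frame the generating base multigraph
#'   (`source`, `target`, `multiplicity`, names are fiber names).
#' @slot drive list per-fiber square-wave drive parameters
#'   (`period`, `amplitude`, `phase`) used by the simulator.
#' @exportClass PlantedGraph
setClass("PlantedGraph",
  slots = c(graph = "Connectome", planted = "SyncPartition",
            baseEdges = "data.frame", drive = "list"))

#' RepairProblem: inputs of the symmetry-driven repair MILP
#'
#' @slot connectome [Connectome-class] the graph to repair.
#' @slot target [Coloring-class] the prescribed synchrony coloring.
#' @slot alpha,beta numeric(1) penalty weights for removal/addition.
#' @slot candidateEdges data.frame (`source`, `target`) of addable non-edges.
#' @slot forbiddenRemovals data.frame edges that must stay.
#' @slot enforceMinIndegree logical(1), optional in-degree >= 1 constraint.
#' @slot unbalancingMode character(1): `"none"` (balance only), `"relaxed"`
#'   or `"strict"` (minimality-seeking unbalancing constraints).
#' @exportClass RepairProblem
setClass("RepairProblem",
  slots = c(connectome = "Connectome", target = "Coloring",
            alpha = "numeric", beta = "numeric",
            candidateEdges = "data.frame", forbiddenRemovals = "data.frame",
            enforceMinIndegree = "logical", unbalancingMode = "character"))

setValidity("RepairProblem", function(object) {
  if (!object@unbalancingMode %in% c("none", "relaxed", "strict"))
    return("unbalancingMode must be none, relaxed or strict")
  if (object@alpha < 0 || object@beta < 0)
    return("alpha and beta must be non-negative")
  labs <- sort(object@connectome@nodes$label)
  covered <- sort(unlist(object@target@partition@clusters, use.names = FALSE))
  if (!identical(labs, covered))
    return("target coloring must cover exactly the connectome nodes")
  ce <- object@candidateEdges
  if (nrow(ce)) {
    if (any(ce$source == ce$target)) return("candidate self-loops not allowed")
    ek <- paste(object@connectome@edges$source,
                object@connectome@edges$target, sep = "\r")
    if (any(paste(ce$source, ce$target, sep = "\r") %in% ek))
      return("candidate edges must not already exist")
  }
  TRUE
})

#' RepairSolution: output of the symmetry-driven repair MILP
#'
#' @slot removed data.frame (`source`, `target`) edges removed.
#' @slot added data.frame (`source`, `target`) edges added.
#' @slot imbalance data.frame the active imbalance indicators
#'   (`p`, `q`, `R`) from the unbalancing constraints, if any.
#' @slot objective numeric(1) alpha * |removed| + beta * |added|.
#' @slot status character(1): `"optimal"`, `"infeasible"` or `"suboptimal"`.
#' @slot verification list with logicals `balanced`, `minimal` recomputed
#'   independently of the solver, plus `coarsest`, the coarsest balanced
#'   coloring of the repaired graph (a [SyncPartition-class], `NULL` when
#'   the solution is not balanced).
#' @slot modeUsed character(1) which unbalancing variant produced the
#'   returned solution (records the strict-to-relaxed fallback).
#' @slot nSolves integer(1) MILP solves consumed (cut loop included).
#' @exportClass RepairSolution
setClass("RepairSolution",
  slots = c(removed = "data.frame", added = "data.frame",
            imbalance = "data.frame", objective = "numeric",
            status = "character", verification = "list",
            modeUsed = "character", nSolves = "integer"))

#' PermutationResult: permutation test of a repair cost
#'
#' @slot nPermutations,nValid,nAsGood integer(1) counts.
#' @slot pValue numeric(1).
#' @slot observed numeric(1) the observed modification count.
#' @slot objectives numeric per-permutation optimal modification counts
#'   (`NA` for invalid permutations).
#' @slot denominator character(1): `"fixed-n"` or `"valid-only"`.
#' @slot seed integer(1).
#' @exportClass PermutationResult
setClass("PermutationResult",
  slots = c(nPermutations = "integer", nValid = "integer",
            nAsGood = "integer", pValue = "numeric", observed = "numeric",
            objectives = "numeric", denominator = "character",
            seed = "integer"))

setValidity("PermutationResult", function(object) {
  if (object@nAsGood > object@nValid ||
      object@nValid > object@nPermutations)
    return("need nAsGood <= nValid <= nPermutations")
  if (object@pValue < 0 || object@pValue > 1)
    return("pValue must lie in [0, 1]")
  TRUE
})
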