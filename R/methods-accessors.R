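## Accessors and show() methods.

#' @rdname accessors
setMethod("neuronLabels", "TraceMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("neuronLabels", "SynchronyMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("neuronLabels", "AveragedMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("neuronLabels", "ConsensusMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("neuronLabels", "SyncPartition",
          function(x) sort(unlist(x@clusters, use.names = FALSE)))
#' @rdname accessors
setMethod("neuronLabels", "FunctionalNetwork", function(x) x@labels)

#' @rdname accessors
setMethod("values", "TraceMatrix", function(x) x@values)
#' @rdname accessors
setMethod("values", "SynchronyMatrix", function(x) x@values)
#' @rdname accessors
setMethod("values", "AveragedMatrix", function(x) x@values)
#' @rdname accessors
setMethod("values", "ConsensusMatrix", function(x) x@values)

#' @rdname accessors
setMethod("counts", "AveragedMatrix", function(x) x@counts)
#' @rdname accessors
setMethod("counts", "ConsensusMatrix", function(x) x@counts)

#' @rdname accessors
setMethod("metricOf", "SynchronyMatrix", function(x) x@metric)
#' @rdname accessors
setMethod("metricOf", "AveragedMatrix", function(x) x@metric)
#' @rdname accessors
setMethod("metricOf", "FunctionalNetwork", function(x) x@metric)

#' @rdname accessors
setMethod("animalId", "TraceMatrix", function(x) x@animalId)
#' @rdname accessors
setMethod("animalId", "SynchronyMatrix", function(x) x@animalId)

#' @rdname accessors
setMethod("timeStep", "TraceMatrix", function(x) x@dt)

#' @rdname accessors
setMethod("clusters", "SyncPartition", function(x) x@clusters)
#' @rdname accessors
setMethod("clusters", "Coloring", function(x) x@partition@clusters)
#' @rdname accessors
setMethod("nClusters", "SyncPartition", function(x) length(x@clusters))
#' @rdname accessors
setMethod("nClusters", "Coloring", function(x) length(x@partition@clusters))
#' @rdname accessors
setMethod("provenance", "SyncPartition", function(x) x@provenance)

#' @rdname accessors
setMethod("nodeLabels", "Connectome", function(x) x@nodes$label)
#' @rdname accessors
setMethod("nodeLabels", "PlantedGraph", function(x) x@graph@nodes$label)
#' @rdname accessors
setMethod("edgeTable", "Connectome", function(x) x@edges)
#' @rdname accessors
setMethod("edgeTable", "PlantedGraph", function(x) x@graph@edges)
#' @rdname accessors
setMethod("edgeTable", "BaseGraph", function(x) x@edges)

#' @rdname accessors
setMethod("membershipVector", "SyncPartition", function(x) {
  m <- rep(names(x@clusters), vapply(x@clusters, length, integer(1)))
  names(m) <- unlist(x@clusters, use.names = FALSE)
  m[order(names(m))]
})
#' @rdname accessors
setMethod("membershipVector", "Coloring",
          function(x) membershipVector(x@partition))

#' @rdname accessors
setMethod("fiberMap", "BaseGraph", function(x) x@fiberMap)

#' @rdname accessors
setMethod("objectiveValue", "RepairSolution", function(x) x@objective)
#' @rdname accessors
setMethod("solutionStatus", "RepairSolution", function(x) x@status)

#' @rdname accessors
setMethod("pValue", "PermutationResult", function(x) x@pValue)

setMethod("show", "MetricSpec", function(object) {
  if (object@family == "los")
    cat(sprintf("LoS metric (sigma = %g)\n", object@sigma))
  else cat(sprintf("%s metric\n", object@family))
})

setMethod("show", "TraceMatrix", function(object) {
  cat(sprintf("TraceMatrix '%s': %d neurons x %d time points (dt = %g)\n",
              object@animalId, nrow(object@values), ncol(object@values),
              object@dt))
})

setMethod("show", "SynchronyMatrix", function(object) {
  cat(sprintf("SynchronyMatrix '%s' [%s]: %d neurons\n", object@animalId,
              .metricTag(object@metric), nrow(object@values)))
})

setMethod("show", "AveragedMatrix", function(object) {
  cat(sprintf(
    "AveragedMatrix [%s]: %d neurons, %d animals, %d undefined pairs\n",
    .metricTag(object@metric), nrow(object@values), object@nAnimals,
    sum(is.na(object@values[upper.tri(object@values)]))))
})

setMethod("show", "SyncPartition", function(object) {
  sizes <- vapply(object@clusters, length, integer(1))
  cat(sprintf("SyncPartition: %d clusters over %d labels (sizes: %s)\n",
              length(sizes), sum(sizes),
              paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
  if (length(object@provenance))
    cat("  provenance:", paste(object@provenance, collapse = "; "), "\n")
})

setMethod("show", "FunctionalNetwork", function(object) {
  cat(sprintf(
    "FunctionalNetwork [%s, rule = %s]: %d nodes, %d edges, %d component(s)\n",
    .metricTag(object@metric), length(object@labels), nrow(object@edges),
    object@nComponents))
})

setMethod("show", "ConsensusMatrix", function(object) {
  cat(sprintf("ConsensusMatrix: %d labels, %d partitions\n",
              nrow(object@values), object@nPartitions))
})

setMethod("show", "Connectome", function(object) {
  cat(sprintf("Connectome%s: %d nodes, %d directed edges\n",
              if (object@collapsed) " (bilaterally collapsed)" else "",
              nrow(object@nodes), nrow(object@edges)))
  tab <- table(object@nodes$role)
  cat("  roles:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
})

setMethod("show", "Coloring", function(object) {
  cat(sprintf("Coloring: %d clusters (%d rigid) over %d nodes\n",
              nClusters(object), length(object@rigid),
              length(neuronLabels(object@partition))))
})

setMethod("show", "BaseGraph", function(object) {
  cat(sprintf("BaseGraph: %d fibers, %d multi-edges\n",
              length(unique(object@fiberMap)), nrow(object@edges)))
})

setMethod("show", "PlantedGraph", function(object) {
  cat(sprintf("PlantedGraph: %d nodes in %d planted fibers, %d edges\n",
              nrow(object@graph@nodes), length(object@planted@clusters),
              nrow(object@graph@edges)))
})

setMethod("show", "RepairProblem", function(object) {
  cat(sprintf(
    "RepairProblem: %d nodes, %d edges, %d candidate additions\n",
    nrow(object@connectome@nodes), nrow(object@connectome@edges),
    nrow(object@candidateEdges)))
  cat(sprintf("  target: %d clusters; alpha = %g, beta = %g, mode = %s\n",
              nClusters(object@target), object@alpha, object@beta,
              object@unbalancingMode))
})

setMethod("show", "RepairSolution", function(object) {
  cat(sprintf(
    "RepairSolution [%s, mode %s]: objective %g (%d removed, %d added)\n",
    object@status, object@modeUsed, object@objective,
    nrow(object@removed), nrow(object@added)))
  cat(sprintf("  verified: balanced = %s, minimal = %s (%d solver calls)\n",
              object@verification$balanced, object@verification$minimal,
              object@nSolves))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: p = %g (%d/%d as good, %d valid, denominator %s)\n",
    object@pValue, object@nAsGood, object@nPermutations, object@nValid,
    object@denominator))
})
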