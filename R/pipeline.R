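## End-to-end pipeline: traces -> synchrony -> partitions -> consensus ->
## repair -> permutation test, from one config.

#' Derive the target coloring from a synchrony partition
#'
#' Rigid nodes (by convention the interneurons) are pulled out of their
#' synchrony clusters and each becomes its own rigid singleton cluster;
#' the remaining clusters are kept as-is.
#'
#' @param partition a [SyncPartition-class] covering the connectome nodes.
#' @param conn a [Connectome-class].
#' @param rigidNodes labels to force into rigid singletons; defaults to the
#'   connectome's interneuron-role nodes.
#' @return a [Coloring-class].
#' @export
buildTargetColoring <- function(partition, conn, rigidNodes = NULL) {
  if (is.null(rigidNodes))
    rigidNodes <- conn@nodes$label[conn@nodes$role == "interneuron"]
  cl <- lapply(partition@clusters, setdiff, y = rigidNodes)
  cl <- cl[vapply(cl, length, integer(1)) > 0L]
  cl <- unname(cl)
  rigidNames <- character()
  if (length(rigidNodes)) {
    rigidNames <- paste0("rigid.", rigidNodes)
    cl <- c(cl, as.list(rigidNodes))
  }
  part <- syncPartition(cl, provenance = partition@provenance)
  if (length(rigidNodes))
    names(part@clusters)[seq.int(length(cl) - length(rigidNodes) + 1L,
                                 length(cl))] <- rigidNames
  missing <- setdiff(conn@nodes$label, neuronLabels(part))
  if (length(missing))
    stop("partition does not cover connectome nodes: ",
         paste(missing, collapse = ", "))
  coloring(part, rigid = rigidNames)
}

#' Pipeline configuration
#'
#' @param traces directory of per-animal trace CSVs, or an in-memory list
#'   of [TraceMatrix-class].
#' @param conn path to a connectome edge-list CSV, or a
#'   [Connectome-class].
#' @param metrics list of [MetricSpec-class]; default the 44-metric bank.
#' @param thresholdRule passed to [thresholdMatrix()].
#' @param methods clustering methods to apply (`"clique"`, `"louvain"`).
#' @param louvainRuns Louvain restarts per network.
#' @param cutoffs consensus dendrogram cut heights.
#' @param alpha,beta repair penalties.
#' @param unbalancingMode passed to [repairProblem()].
#' @param nPermutations permutations per tested partition.
#' @param denominator p-value denominator mode.
#' @param rigidNodes see [buildTargetColoring()].
#' @param outDir optional output directory for all artifacts.
#' @param seed global seed; all stage seeds are derived from it.
#' @return config list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(traces, conn, metrics = metricBank(),
                           thresholdRule = "node-max",
                           methods = c("clique", "louvain"),
                           louvainRuns = 1000L,
                           cutoffs = c(2.5, 2, 1.5, 1, 0.75, 0.5, 0.25),
                           alpha = 1, beta = 1,
                           unbalancingMode = "strict",
                           nPermutations = 1000L,
                           denominator = "fixed-n",
                           rigidNodes = NULL, outDir = NULL, seed = 1L) {
  if (missing(conn) || is.null(conn))
    stop("config error: connectome is required")
  if (is.character(traces) && !dir.exists(traces))
    stop("config error: trace directory not found: ", traces)
  if (is.character(conn) && !file.exists(conn))
    stop("config error: connectome file not found: ", conn)
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(traces = traces, conn = conn, metrics = metrics,
                 thresholdRule = thresholdRule, methods = methods,
                 louvainRuns = as.integer(louvainRuns), cutoffs = cutoffs,
                 alpha = alpha, beta = beta,
                 unbalancingMode = unbalancingMode,
                 nPermutations = as.integer(nPermutations),
                 denominator = denominator, rigidNodes = rigidNodes,
                 outDir = outDir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pipeline
#'
#' Computes per-animal synchrony matrices for every metric in the bank,
#' cohort-averages them, thresholds each average into a functional network,
#' extracts clique-synchronization and Louvain partitions, fuses all
#' candidate partitions into a consensus matrix, cuts its Ward dendrogram
#' at the configured heights, and for every distinct cut partition solves
#' the symmetry-driven repair of the connectome and scores it with a
#' permutation test. The partition with the lowest p-value (ties broken by
#' the lower modification percentage) is selected as the optimal solution.
#'
#' @param config a [pipelineConfig()].
#' @return a manifest list: counts, the summary table (one row per tested
#'   partition: cutoff, clusters, fibers, modification percentages, p),
#'   the selected solution, all intermediate objects, and (when `outDir`
#'   is set) the written artifact paths with MD5 checksums.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  seeds <- .deriveSeeds(config$seed, 4L)

  cohort <- .stage("load-traces", {
    if (is.character(config$traces)) {
      files <- sort(list.files(config$traces, pattern = "\\.csv$",
                               full.names = TRUE))
      if (length(files) == 0L) stop("no trace CSVs found")
      lapply(files, readTraceCSV)
    } else config$traces
  })
  conn <- .stage("load-connectome", {
    if (is.character(config$conn)) readConnectome(config$conn)
    else config$conn
  })

  averaged <- .stage("synchrony", {
    lapply(config$metrics, function(m)
      cohortAverage(lapply(cohort, computeMetric, metric = m)))
  })

  partitions <- .stage("clustering", {
    louvSeeds <- .deriveSeeds(seeds[1L], length(averaged))
    out <- list()
    for (k in seq_along(averaged)) {
      net <- thresholdMatrix(averaged[[k]], rule = config$thresholdRule)
      if ("clique" %in% config$methods)
        out[[length(out) + 1L]] <- cliqueSynchronization(net)
      if ("louvain" %in% config$methods)
        out[[length(out) + 1L]] <- louvainPartition(
          net, nRuns = config$louvainRuns, seed = louvSeeds[k])
    }
    out
  })
  uniquePartitions <- dedupPartitions(partitions)

  consensus <- .stage("consensus", consensusMatrix(partitions))
  linkage <- .stage("linkage", wardLinkage(consensus))
  cutPartitions <- .stage("cuts", {
    cuts <- lapply(config$cutoffs, function(h) wardCut(linkage, h))
    for (k in seq_along(cuts))
      cuts[[k]]@provenance <- sprintf("consensus|cutoff=%g",
                                      config$cutoffs[k])
    cuts
  })
  testPartitions <- dedupPartitions(cutPartitions)

  repairs <- .stage("repair", {
    permSeeds <- .deriveSeeds(seeds[2L], length(testPartitions))
    lapply(seq_along(testPartitions), function(k) {
      target <- buildTargetColoring(testPartitions[[k]], conn,
                                    config$rigidNodes)
      prob <- repairProblem(conn, target, alpha = config$alpha,
                            beta = config$beta,
                            unbalancingMode = config$unbalancingMode)
      sol <- solveRepair(prob)
      perm <- permutationPValue(prob, n = config$nPermutations,
                                seed = permSeeds[k],
                                denominator = config$denominator)
      list(partition = testPartitions[[k]], target = target,
           problem = prob, solution = sol, permutation = perm)
    })
  })

  summary <- do.call(rbind, lapply(repairs, function(r) {
    data.frame(
      provenance = paste(r$partition@provenance, collapse = ";"),
      clusters = nClusters(r$target),
      fibers = nClusters(r$target) - length(r$target@rigid),
      alpha = config$alpha, beta = config$beta,
      status = r$solution@status,
      objective = r$solution@objective,
      nModifications = nrow(r$solution@removed) + nrow(r$solution@added),
      modificationPct = modificationPercent(r$problem, r$solution),
      modificationPctWeighted =
        modificationPercent(r$problem, r$solution, weighted = TRUE),
      minimal = isTRUE(r$solution@verification$minimal),
      pValue = pValue(r$permutation),
      stringsAsFactors = FALSE)
  }))

  bestIdx <- order(summary$pValue, summary$modificationPct)[1L]

  manifest <- list(
    nAnimals = length(cohort),
    nMetrics = length(config$metrics),
    nAveraged = length(averaged),
    nCandidatePartitions = length(partitions),
    nUniquePartitions = length(uniquePartitions),
    nTestedPartitions = length(testPartitions),
    summary = summary, bestIndex = bestIdx,
    best = repairs[[bestIdx]],
    averaged = averaged, partitions = partitions,
    uniquePartitions = uniquePartitions, consensus = consensus,
    linkage = linkage, cutPartitions = cutPartitions, repairs = repairs,
    config = config)

  if (!is.null(config$outDir))
    manifest$artifacts <- .writeArtifacts(manifest, config$outDir)
  manifest
}

.writeArtifacts <- function(manifest, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wf <- function(fname, writer) {
    path <- file.path(outDir, fname)
    writer(path)
    paths <<- c(paths, path)
    path
  }
  for (k in seq_along(manifest$averaged)) {
    avg <- manifest$averaged[[k]]
    tag <- gsub("[^0-9A-Za-z._-]", "_", .metricTag(avg@metric))
    wf(sprintf("avg_%s.csv", tag), function(p)
      utils::write.csv(avg@values, p))
    wf(sprintf("counts_%s.csv", tag), function(p)
      utils::write.csv(avg@counts, p))
  }
  wf("partitions.json", function(p)
    jsonlite::write_json(lapply(manifest$partitions, function(q)
      list(provenance = q@provenance, clusters = q@clusters)), p,
      auto_unbox = FALSE, pretty = TRUE))
  wf("consensus.csv", function(p)
    utils::write.csv(manifest$consensus@values, p))
  hc <- manifest$linkage
  wf("dendrogram.json", function(p)
    jsonlite::write_json(list(merge = hc$merge, height = hc$height,
                              order = hc$order, labels = hc$labels), p,
                         auto_unbox = FALSE, digits = NA))
  wf("summary.csv", function(p)
    utils::write.csv(manifest$summary, p, row.names = FALSE))
  wf("solutions.json", function(p) {
    jsonlite::write_json(lapply(manifest$repairs, function(r) list(
      provenance = r$partition@provenance,
      target = r$target@partition@clusters,
      rigid = r$target@rigid,
      removed = r$solution@removed, added = r$solution@added,
      objective = r$solution@objective, status = r$solution@status,
      verification = r$solution@verification[c("balanced", "minimal")],
      pValue = pValue(r$permutation),
      permutationObjectives = r$permutation@objectives)), p,
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  cfg <- manifest$config
  cfg$traces <- if (is.character(cfg$traces)) cfg$traces else
    sprintf("<in-memory cohort of %d animals>", manifest$nAnimals)
  cfg$conn <- if (is.character(cfg$conn)) cfg$conn else "<in-memory>"
  cfg$metrics <- vapply(cfg$metrics, .metricTag, character(1))
  cfg$outDir <- NULL    # path-independent artifacts: reruns checksum equal
  wf("config.json", function(p)
    jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA))
  sums <- tools::md5sum(paths)
  wf("manifest.json", function(p)
    jsonlite::write_json(
      list(files = basename(paths), md5 = unname(sums),
           counts = manifest[c("nAnimals", "nMetrics", "nAveraged",
                               "nCandidatePartitions", "nUniquePartitions",
                               "nTestedPartitions")]),
      p, auto_unbox = TRUE, pretty = TRUE))
  data.frame(file = basename(paths), md5 = unname(tools::md5sum(paths)),
             stringsAsFactors = FALSE)
}
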