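## Plain-text I/O for connectomes, partitions and traces, plus bilateral
## collapsing of left/right neuron pairs.

#' Read a connectome from an edge-list CSV
#'
#' Expects a header `source,target,weight`; an optional `role` sidecar is
#' not needed, roles can be assigned afterwards. Node set is the union of
#' endpoints plus any `nodes` given explicitly.
#'
#' @param path CSV file path.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node labels, or data.frame with `label`/`role`.
#' @return a [Connectome-class].
#' @export
readConnectome <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have header source,target,weight: ", path)
  bad <- which(!is.finite(df$weight))
  if (length(bad))
    stop("malformed weight at data line ", bad[1L], " of ", path)
  if (any(df$weight < 0))
    stop("negative weight at data line ", which(df$weight < 0)[1L],
         " of ", path)
  key <- .edgeKey(df$source, df$target)
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate edge (%s -> %s) in %s", d$source, d$target, path))
  }
  labels <- unique(c(df$source, df$target,
                     if (is.data.frame(nodes)) nodes$label else nodes))
  nd <- data.frame(label = labels, role = "generic", stringsAsFactors = FALSE)
  if (is.data.frame(nodes))
    nd$role[match(nodes$label, nd$label)] <- nodes$role
  connectome(nd, df[need])
}

#' Write a connectome to an edge-list CSV
#'
#' Round-trips with [readConnectome()]: `readConnectome(writeConnectome(g))`
#' reproduces `g` up to node ordering (isolated nodes must be re-declared).
#'
#' @param conn a [Connectome-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeConnectome <- function(conn, path) {
  utils::write.csv(conn@edges[c("source", "target", "weight")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a partition as JSON
#'
#' JSON object mapping cluster id to an array of labels; a `"_provenance"`
#' entry, if present, is read back as provenance tags.
#'
#' @param path JSON file path.
#' @return [readPartition()] returns a [SyncPartition-class].
#' @export
readPartition <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- if (!is.null(x[["_provenance"]])) as.character(x[["_provenance"]])
          else character()
  x[["_provenance"]] <- NULL
  syncPartition(lapply(x, as.character), provenance = prov)
}

#' @rdname readPartition
#' @param p a [SyncPartition-class].
#' @export
writePartition <- function(p, path) {
  x <- p@clusters
  if (length(p@provenance)) x[["_provenance"]] <- p@provenance
  jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read / write one animal's trace matrix as CSV
#'
#' First column `neuron` holds labels; remaining columns are time samples
#' (header gives the time index).
#'
#' @param path CSV file path.
#' @param animalId animal identifier; defaults to the file stem.
#' @param dt time step of the stored samples.
#' @return [readTraceCSV()] returns a [TraceMatrix-class].
#' @export
readTraceCSV <- function(path, animalId = NULL, dt = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "neuron")
    stop("trace CSV must have 'neuron' as its first column: ", path)
  m <- as.matrix(df[-1L])
  rownames(m) <- df$neuron
  if (is.null(animalId))
    animalId <- sub("\\.csv$", "", basename(path))
  new("TraceMatrix", values = m, animalId = animalId, dt = dt)
}

#' @rdname readTraceCSV
#' @param traces a [TraceMatrix-class].
#' @export
writeTraceCSV <- function(traces, path) {
  m <- traces@values
  df <- data.frame(neuron = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[-1L] <- as.character(seq_len(ncol(m)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse bilateral neuron pairs into single nodes
#'
#' Each listed left/right pair is replaced by one node carrying the pair
#' name. The collapsed topology is the OR of the two members' edges: the new
#' binary weight is 1 if either member had the edge (in the corresponding
#' direction), and the summed pre-collapse weights are retained in
#' `preWeight` for the weighted modification-cost mode. Edges running inside
#' a pair would become self-loops and are dropped with a warning.
#'
#' @param conn a [Connectome-class].
#' @param pairs named list: pair name -> `c(leftLabel, rightLabel)`.
#' @return a collapsed [Connectome-class] (binary weights).
#' @examples
#' g <- connectome(c("AVAL", "AVAR", "VA1"),
#'                 data.frame(source = c("AVAL", "AVAR"),
#'                            target = c("VA1", "VA1"), weight = c(2, 3)))
#' collapseBilateral(g, list(AVA = c("AVAL", "AVAR")))
#' @export
collapseBilateral <- function(conn, pairs) {
  members <- unlist(pairs, use.names = FALSE)
  if (anyDuplicated(members)) stop("overlapping bilateral pairs")
  if (!all(members %in% conn@nodes$label))
    stop("unknown labels in pairs: ",
         paste(setdiff(members, conn@nodes$label), collapse = ", "))
  alias <- stats::setNames(conn@nodes$label, conn@nodes$label)
  for (pn in names(pairs)) alias[pairs[[pn]]] <- pn
  e <- conn@edges
  src <- unname(alias[e$source]); tgt <- unname(alias[e$target])
  loop <- src == tgt
  if (any(loop)) {
    warning(sum(loop), " within-pair edge(s) dropped (would self-loop)")
    e <- e[!loop, , drop = FALSE]; src <- src[!loop]; tgt <- tgt[!loop]
  }
  if (nrow(e)) {
    agg <- stats::aggregate(e$weight, by = list(source = src, target = tgt),
                            FUN = sum)
    edges <- data.frame(source = agg$source, target = agg$target,
                        weight = 1, preWeight = agg$x,
                        stringsAsFactors = FALSE)
  } else {
    edges <- e
  }
  keep <- conn@nodes[!conn@nodes$label %in% members, , drop = FALSE]
  roles <- vapply(names(pairs), function(pn) {
    r <- unique(conn@nodes$role[conn@nodes$label %in% pairs[[pn]]])
    if (length(r) == 1L) r else "generic"
  }, character(1))
  nd <- rbind(data.frame(label = names(pairs), role = roles,
                         stringsAsFactors = FALSE), keep)
  out <- connectome(nd, edges, collapsed = TRUE)
  out
}
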