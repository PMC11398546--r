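## Internal helpers.

.metricTag <- function(m) {
  if (m@family == "los") sprintf("los@%.3f", m@sigma) else m@family
}

.edgeKey <- function(source, target) paste(source, target, sep = "\r")

## Deterministic child seeds below 2^31, derived from a parent seed. Uses a
## private RNG stream so callers' RNG state is untouched.
.deriveSeeds <- function(seed, n) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

## Run code under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Construct a metric specification
#'
#' @param family one of `"los"`, `"pearson"`, `"spearman"`, `"kendall"`,
#'   `"distance-correlation"`, `"covariance"`.
#' @param sigma Gaussian bandwidth, required iff `family = "los"`.
#' @return a [MetricSpec-class].
#' @examples
#' metricSpec("los", sigma = 0.16)
#' metricSpec("pearson")
#' @export
metricSpec <- function(family, sigma = NA_real_) {
  new("MetricSpec", family = match.arg(family, .metricFamilies),
      sigma = as.numeric(sigma))
}

#' Construct a synchrony partition
#'
#' @param clusters list of character vectors (disjoint, non-empty). Unnamed
#'   lists are given names `c1`, `c2`, ... in order.
#' @param provenance optional character tags recording how it was obtained.
#' @return a [SyncPartition-class].
#' @examples
#' syncPartition(list(c("a", "b"), "c"))
#' @export
syncPartition <- function(clusters, provenance = character()) {
  clusters <- lapply(clusters, as.character)
  if (is.null(names(clusters)) || any(!nzchar(names(clusters))))
    names(clusters) <- paste0("c", seq_along(clusters))
  new("SyncPartition", clusters = clusters,
      provenance = as.character(provenance))
}

#' Build a partition from a membership vector
#'
#' @param membership named vector; names are labels, values cluster ids.
#' @param provenance optional provenance tags.
#' @return a [SyncPartition-class].
#' @export
partitionFromMembership <- function(membership, provenance = character()) {
  stopifnot(!is.null(names(membership)))
  syncPartition(split(names(membership), as.character(membership)),
                provenance = provenance)
}

## Canonical form: sorted clusters of sorted labels; basis for identity.
.canonicalClusters <- function(p) {
  cl <- lapply(p@clusters, sort)
  unname(cl[order(vapply(cl, `[`, character(1), 1L))])
}

#' Compare two partitions as unordered set partitions
#'
#' Cluster names and ordering are ignored.
#'
#' @param a,b [SyncPartition-class] objects.
#' @return logical(1).
#' @export
samePartition <- function(a, b) {
  identical(.canonicalClusters(a), .canonicalClusters(b))
}

#' Construct a coloring (target partition with rigid clusters)
#'
#' @param partition a [SyncPartition-class] covering all connectome nodes.
#' @param rigid character vector of cluster names excluded from permutation
#'   (conventionally the interneuron singletons).
#' @return a [Coloring-class].
#' @export
coloring <- function(partition, rigid = character()) {
  new("Coloring", partition = partition, rigid = as.character(rigid))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index over the labels common to both
#' partitions; used to score planted-partition recovery.
#'
#' @param a,b [SyncPartition-class] objects.
#' @return numeric(1).
#' @export
adjustedRand <- function(a, b) {
  ma <- membershipVector(a); mb <- membershipVector(b)
  common <- intersect(names(ma), names(mb))
  stopifnot(length(common) > 0)
  tab <- table(ma[common], mb[common])
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}
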