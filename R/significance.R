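## Permutation test of a partition's repair cost against label-shuffled
## null partitions.

#' Permute a partition's labels, preserving cluster sizes
#'
#' Labels of the non-rigid clusters are shuffled uniformly among those
#' clusters; the number of clusters and their sizes are untouched, and the
#' rigid clusters keep their exact membership.
#'
#' @param p a [SyncPartition-class] or [Coloring-class].
#' @param rigid cluster names to leave untouched (taken from the object if
#'   `p` is a [Coloring-class]).
#' @param seed integer seed.
#' @return same class as `p`.
#' @export
permutePartition <- function(p, rigid = character(), seed = 1L) {
  isCol <- is(p, "Coloring")
  if (isCol) {
    rigid <- p@rigid
    part <- p@partition
  } else part <- p
  cl <- part@clusters
  free <- setdiff(names(cl), rigid)
  pool <- unlist(cl[free], use.names = FALSE)
  shuffled <- .withSeed(seed, sample(pool))
  sizes <- vapply(cl[free], length, integer(1))
  stops <- cumsum(sizes)
  starts <- stops - sizes + 1L
  for (k in seq_along(free))
    cl[[free[k]]] <- shuffled[starts[k]:stops[k]]
  out <- syncPartition(cl, provenance = part@provenance)
  names(out@clusters) <- names(cl)
  if (isCol) coloring(out, rigid) else out
}

## A label shuffle can only ever reproduce the same set partition when at
## most one non-rigid cluster exists or all non-rigid clusters are
## singletons; such targets have p = 1 by construction.
.permutationInvariant <- function(col) {
  cl <- col@partition@clusters
  free <- setdiff(names(cl), col@rigid)
  sizes <- vapply(cl[free], length, integer(1))
  length(free) <= 1L || all(sizes == 1L)
}

#' Permutation p-value of a repair cost
#'
#' Solves the repair problem for `n` label-shuffled versions of the target
#' coloring and counts how many reach an optimal modification count no
#' larger than the observed one. Degenerate targets (a single non-rigid
#' cluster, or all-singleton non-rigid clusters) are invariant under label
#' shuffles and get p = 1 without solving. The p-value divides by `n`
#' (`"fixed-n"`) or by the number of permutations that produced a valid
#' (optimal, and for strict problems minimally colored) solution
#' (`"valid-only"`). No floor is applied: a zero count reports p = 0.
#'
#' @param problem a [RepairProblem-class]; the observed solution is computed
#'   from it.
#' @param n number of permutations (>= 1); the study default is 1000.
#' @param seed integer seed; permutation seeds are derived from it.
#' @param denominator `"fixed-n"` or `"valid-only"`.
#' @param maxCuts passed to the solver.
#' @return a [PermutationResult-class]; per-permutation modification counts
#'   are kept in `@objectives`.
#' @export
permutationPValue <- function(problem, n = 1000L, seed = 1L,
                              denominator = c("fixed-n", "valid-only"),
                              maxCuts = 100L) {
  denominator <- match.arg(denominator)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  observedSol <- solveRepair(problem, maxCuts = maxCuts)
  if (observedSol@status != "optimal")
    stop("observed problem did not solve to optimality: ",
         observedSol@status)
  observed <- nrow(observedSol@removed) + nrow(observedSol@added)
  if (.permutationInvariant(problem@target)) {
    return(new("PermutationResult", nPermutations = n, nValid = n,
               nAsGood = n, pValue = 1, observed = as.numeric(observed),
               objectives = rep(as.numeric(observed), n),
               denominator = denominator, seed = as.integer(seed)))
  }
  seeds <- .deriveSeeds(seed, n)
  perms <- lapply(seeds, function(s)
    permutePartition(problem@target, seed = s))
  ## identical-to-observed shuffles need no solve
  sameAsObs <- vapply(perms, function(cc)
    samePartition(cc@partition, problem@target@partition), logical(1))
  objectives <- rep(NA_real_, n)
  objectives[sameAsObs] <- observed
  todo <- which(!sameAsObs)
  if (length(todo)) {
    problems <- lapply(perms[todo], function(cc) {
      q <- problem
      q@target <- cc
      q
    })
    if (problem@unbalancingMode == "strict") {
      ## two-phase exact counting: one relaxed solve per permutation gives
      ## a certified lower bound on the strict objective (the relaxed
      ## constraints are necessary for minimality); only permutations whose
      ## bound does not already exceed the observed count need the full
      ## verify-and-cut resolution. Counts of "as good" permutations are
      ## exact; recorded objectives are exact for resolved permutations and
      ## certified lower bounds (> observed) for the rest.
      bounds <- lapply(problems, function(q) {
        q@unbalancingMode <- "relaxed"
        q
      })
      bsols <- solveRepairBatch(bounds, maxCuts = maxCuts)
      bOk <- vapply(bsols, function(s) s@status == "optimal", logical(1))
      bObj <- rep(NA_real_, length(problems))
      bObj[bOk] <- vapply(bsols[bOk], function(s)
        nrow(s@removed) + nrow(s@added), numeric(1))
      resolve <- which(bOk & bObj <= observed)
      objectives[todo[bOk]] <- bObj[bOk]
      if (length(resolve)) {
        esols <- solveRepairBatch(problems[resolve], maxCuts = maxCuts,
                                  directStrict = TRUE)
        eOk <- vapply(esols, function(s) s@status == "optimal" &&
                        isTRUE(s@verification$minimal), logical(1))
        objectives[todo[resolve]] <- NA_real_
        objectives[todo[resolve[eOk]]] <- vapply(esols[eOk], function(s)
          nrow(s@removed) + nrow(s@added), numeric(1))
      }
    } else {
      sols <- solveRepairBatch(problems, maxCuts = maxCuts)
      ok <- vapply(sols, function(s) s@status == "optimal", logical(1))
      objectives[todo[ok]] <- vapply(sols[ok], function(s)
        nrow(s@removed) + nrow(s@added), numeric(1))
    }
  }
  nValid <- sum(!is.na(objectives))
  nAsGood <- sum(objectives <= observed, na.rm = TRUE)
  den <- if (denominator == "fixed-n") n else nValid
  pv <- if (den == 0L) NA_real_ else nAsGood / den
  new("PermutationResult", nPermutations = n, nValid = as.integer(nValid),
      nAsGood = as.integer(nAsGood), pValue = pv,
      observed = as.numeric(observed), objectives = objectives,
      denominator = denominator, seed = as.integer(seed))
}
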