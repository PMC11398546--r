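## Construction of the symmetry-driven repair MILP and the solver bridge.
##
## Decision variables (all binary):
##   r_ij  for removable existing edges      -- 1 iff edge (i, j) is removed
##   a_ij  for candidate non-edges           -- 1 iff edge (i, j) is added
##   s_pq^R per representative cluster pair  -- 1 iff p receives strictly
##          more in-edges from cluster R than q does (big-M coefficient n)
##
## Balance constraints equalise, for every cluster pair (S, T), the post-
## repair in-degree from S across T's members; because they force equality
## within a cluster, the unbalancing constraints are instantiated on one
## representative node per cluster (the smallest label), which is
## equivalent to instantiating them for every node pair.

#' Construct a repair problem
#'
#' @param conn a [Connectome-class] to repair.
#' @param target a [Coloring-class] (or [SyncPartition-class], promoted with
#'   no rigid clusters) covering all nodes.
#' @param alpha,beta non-negative penalties for edge removal / addition.
#' @param candidateEdges data.frame (`source`, `target`) of addable edges;
#'   default: every ordered non-self-loop non-edge.
#' @param forbiddenRemovals data.frame of edges that must not be removed.
#' @param forbiddenAdditions data.frame of non-edges that must not be added
#'   (subtracted from the candidate set).
#' @param excludeRigidTargets drop candidate edges pointing into rigid
#'   singleton clusters (a model-size reduction; off by default).
#' @param enforceMinIndegree require post-repair in-degree >= 1 for every
#'   node (off by default).
#' @param unbalancingMode `"strict"` (default), `"relaxed"` or `"none"`; see
#'   [solveRepair()].
#' @return a [RepairProblem-class].
#' @export
repairProblem <- function(conn, target, alpha = 1, beta = 1,
                          candidateEdges = NULL,
                          forbiddenRemovals = NULL,
                          forbiddenAdditions = NULL,
                          excludeRigidTargets = FALSE,
                          enforceMinIndegree = FALSE,
                          unbalancingMode = c("strict", "relaxed", "none")) {
  unbalancingMode <- match.arg(unbalancingMode)
  if (is(target, "SyncPartition")) target <- coloring(target)
  labs <- conn@nodes$label
  if (is.null(candidateEdges)) {
    all_pairs <- expand.grid(source = labs, target = labs,
                             stringsAsFactors = FALSE,
                             KEEP.OUT.ATTRS = FALSE)
    all_pairs <- all_pairs[all_pairs$source != all_pairs$target, ,
                           drop = FALSE]
    ek <- .edgeKey(conn@edges$source, conn@edges$target)
    candidateEdges <- all_pairs[!.edgeKey(all_pairs$source,
                                          all_pairs$target) %in% ek, ,
                                drop = FALSE]
  }
  candidateEdges <- as.data.frame(candidateEdges, stringsAsFactors = FALSE)
  if (!is.null(forbiddenAdditions) && nrow(forbiddenAdditions))
    candidateEdges <- candidateEdges[
      !.edgeKey(candidateEdges$source, candidateEdges$target) %in%
        .edgeKey(forbiddenAdditions$source, forbiddenAdditions$target), ,
      drop = FALSE]
  if (excludeRigidTargets && length(target@rigid)) {
    rigidNodes <- unlist(target@partition@clusters[target@rigid],
                         use.names = FALSE)
    rigidSingles <- rigidNodes[rigidNodes %in% unlist(
      Filter(function(x) length(x) == 1L,
             target@partition@clusters[target@rigid]))]
    candidateEdges <- candidateEdges[
      !candidateEdges$target %in% rigidSingles, , drop = FALSE]
  }
  if (is.null(forbiddenRemovals))
    forbiddenRemovals <- data.frame(source = character(),
                                    target = character())
  candidateEdges <- candidateEdges[order(candidateEdges$source,
                                         candidateEdges$target), ,
                                   drop = FALSE]
  rownames(candidateEdges) <- NULL
  new("RepairProblem", connectome = conn, target = target,
      alpha = alpha, beta = beta,
      candidateEdges = candidateEdges[c("source", "target")],
      forbiddenRemovals = as.data.frame(forbiddenRemovals),
      enforceMinIndegree = isTRUE(enforceMinIndegree),
      unbalancingMode = unbalancingMode)
}

#' Build the MILP model for a repair problem
#'
#' Produces the variable table and sparse constraint system: the balance
#' equalities, the optional minimum-in-degree constraint, and (for modes
#' other than `"none"`) the big-M unbalancing constraints in their relaxed
#' or strict variant. Mainly useful for inspection and debugging; solving
#' goes through [solveRepair()].
#'
#' @param p a [RepairProblem-class].
#' @param mode override of the problem's unbalancing mode.
#' @param extraCuts list of no-good cuts (integer variable-index vectors at
#'   value 1 paired with 0-valued complements) used by the solve loop.
#' @return list with `vars` (data.frame), `obj`, `cons` (triplets + bounds),
#'   and `meta`.
#' @export
buildRepairModel <- function(p, mode = p@unbalancingMode, extraCuts = list()) {
  conn <- p@connectome
  labs <- conn@nodes$label
  n <- length(labs)
  cl <- lapply(p@target@partition@clusters, sort)
  cl <- cl[order(vapply(cl, `[`, character(1), 1L))]
  K <- length(cl)
  e <- conn@edges
  forb <- .edgeKey(p@forbiddenRemovals$source, p@forbiddenRemovals$target)
  removable <- !(.edgeKey(e$source, e$target) %in% forb)

  vars <- data.frame(
    kind = c(rep("r", sum(removable)), rep("a", nrow(p@candidateEdges))),
    source = c(e$source[removable], p@candidateEdges$source),
    target = c(e$target[removable], p@candidateEdges$target),
    p = NA_character_, q = NA_character_, R = NA_character_,
    stringsAsFactors = FALSE)
  nR <- sum(removable); nA <- nrow(p@candidateEdges)

  ## in-degree expression of node v from cluster S:
  ## const + sum(coef * var); kept as index/coef vectors
  clOf <- rep(names(cl), vapply(cl, length, integer(1)))
  names(clOf) <- unlist(cl, use.names = FALSE)
  rIdxByTarget <- split(seq_len(nR), vars$target[seq_len(nR)])
  aIdxByTarget <- split(nR + seq_len(nA), vars$target[nR + seq_len(nA)])
  fixedIn <- e[!removable, , drop = FALSE]
  exprInDeg <- function(v, S) {
    ri <- rIdxByTarget[[v]]
    ri <- ri[clOf[vars$source[ri]] == S]
    ai <- aIdxByTarget[[v]]
    ai <- ai[clOf[vars$source[ai]] == S]
    const <- length(ri) +
      sum(fixedIn$target == v & clOf[fixedIn$source] == S)
    list(const = const, idx = c(ri, ai),
         coef = c(rep(-1, length(ri)), rep(1, length(ai))))
  }

  ci <- list(); cj <- list(); cv <- list(); lo <- numeric(); hi <- numeric()
  addCon <- function(idx, coef, l, h) {
    k <- length(lo) + 1L
    ci[[k]] <<- rep(k, length(idx)); cj[[k]] <<- idx; cv[[k]] <<- coef
    lo[k] <<- l; hi[k] <<- h
  }

  ## balance equalities (chained within each cluster)
  for (Tcl in names(cl)) {
    mem <- cl[[Tcl]]
    if (length(mem) < 2L) next
    for (S in names(cl)) {
      for (m in seq_len(length(mem) - 1L)) {
        e1 <- exprInDeg(mem[m], S); e2 <- exprInDeg(mem[m + 1L], S)
        rhs <- e2$const - e1$const
        addCon(c(e1$idx, e2$idx), c(e1$coef, -e2$coef), rhs, rhs)
      }
    }
  }

  ## optional in-degree floor
  if (p@enforceMinIndegree) {
    for (v in labs) {
      parts <- lapply(names(cl), function(S) exprInDeg(v, S))
      idx <- unlist(lapply(parts, `[[`, "idx"))
      coef <- unlist(lapply(parts, `[[`, "coef"))
      const <- sum(vapply(parts, `[[`, numeric(1), "const"))
      addCon(idx, coef, 1 - const, Inf)
    }
  }

  ## unbalancing constraints on representative pairs
  sKey <- character(0)
  if (mode != "none" && K >= 2L) {
    reps <- vapply(cl, `[`, character(1), 1L)
    pairIdx <- utils::combn(K, 2L)
    for (cc in seq_len(ncol(pairIdx))) {
      S <- names(cl)[pairIdx[1L, cc]]; Tcl <- names(cl)[pairIdx[2L, cc]]
      for (R in names(cl))
        sKey <- c(sKey, paste(reps[S], reps[Tcl], R, sep = "\r"),
                  paste(reps[Tcl], reps[S], R, sep = "\r"))
    }
    sMap <- stats::setNames(seq_along(sKey) + nR + nA, sKey)
    sVar <- function(pp, qq, RR)
      unname(sMap[[paste(pp, qq, RR, sep = "\r")]])
    sInfo <- do.call(rbind, strsplit(sKey, "\r", fixed = TRUE))
    vars <- rbind(vars, data.frame(
      kind = "s", source = NA_character_, target = NA_character_,
      p = sInfo[, 1L], q = sInfo[, 2L], R = sInfo[, 3L],
      stringsAsFactors = FALSE))
    for (cc in seq_len(ncol(pairIdx))) {
      S <- names(cl)[pairIdx[1L, cc]]; Tcl <- names(cl)[pairIdx[2L, cc]]
      pp <- reps[S]; qq <- reps[Tcl]
      for (R in names(cl)) {
        ep <- exprInDeg(pp, R); eq <- exprInDeg(qq, R)
        spq <- sVar(pp, qq, R); sqp <- sVar(qq, pp, R)
        ## indeg_R(p) - indeg_R(q) >= s_pq^R - n * s_qp^R
        addCon(c(ep$idx, eq$idx, spq, sqp),
               c(ep$coef, -eq$coef, -1, n),
               eq$const - ep$const, Inf)
        ## indeg_R(q) - indeg_R(p) >= s_qp^R - n * s_pq^R
        addCon(c(eq$idx, ep$idx, sqp, spq),
               c(eq$coef, -ep$coef, -1, n),
               ep$const - eq$const, Inf)
        ## s_pq^R + s_qp^R <= 1
        addCon(c(spq, sqp), c(1, 1), -Inf, 1)
      }
      if (mode == "relaxed") {
        idx <- unlist(lapply(names(cl), function(R)
          c(sVar(pp, qq, R), sVar(qq, pp, R))))
        addCon(idx, rep(1, length(idx)), 1, Inf)
      } else {
        outside <- setdiff(names(cl), c(S, Tcl))
        for (orient in list(c(pp, qq), c(qq, pp))) {
          idx <- c(); coef <- c()
          for (O in outside) {
            idx <- c(idx, sVar(orient[1L], orient[2L], O),
                     sVar(orient[2L], orient[1L], O))
            coef <- c(coef, 1, 1)
          }
          for (I in c(S, Tcl)) {
            idx <- c(idx, sVar(orient[1L], orient[2L], I),
                     sVar(orient[2L], orient[1L], I))
            coef <- c(coef, 1, -1)
          }
          addCon(idx, coef, 1, Inf)
        }
      }
    }
  }

  ## cuts from the verify-and-cut loop.
  ##
  ## * collapse cuts (list with $bstar, a named map target-cluster ->
  ##   coarser-group id): every balanced coloring refines the coarsest one,
  ##   so a repair whose coarsest coloring equals the target cannot be
  ##   balanced under the strictly coarser pattern B*; the cut demands that
  ##   some pair of co-merged clusters differ in their summed in-count from
  ##   some B* group (big-M indicators w, forced sum >= 1)
  ## * plain integer vectors: no-good cuts excluding one (r, a) assignment
  bigM <- 2L * n + 2L
  for (cut in extraCuts) {
    if (is.list(cut) && !is.null(cut$bstar)) {
      bstar <- cut$bstar
      groups <- split(names(bstar), bstar)
      reps <- vapply(cl, `[`, character(1), 1L)
      wIdx <- integer()
      for (gMerged in groups) {
        if (length(gMerged) < 2L) next
        pairsM <- utils::combn(sort(gMerged), 2L)
        for (pc in seq_len(ncol(pairsM))) {
          pp <- reps[pairsM[1L, pc]]; qq <- reps[pairsM[2L, pc]]
          for (gAll in groups) {
            dIdx <- integer(); dCoef <- numeric(); dConst <- 0
            for (R in gAll) {
              ep <- exprInDeg(pp, R); eq <- exprInDeg(qq, R)
              dIdx <- c(dIdx, ep$idx, eq$idx)
              dCoef <- c(dCoef, ep$coef, -eq$coef)
              dConst <- dConst + ep$const - eq$const
            }
            wP <- nrow(vars) + 1L; wM <- nrow(vars) + 2L
            vars <- rbind(vars, data.frame(
              kind = "w", source = NA_character_, target = NA_character_,
              p = c(pp, qq), q = c(qq, pp), R = paste(gAll, collapse = "+"),
              stringsAsFactors = FALSE))
            ## d >= 1 - M (1 - wP)  <=>  d - M wP >= 1 - M - dConst shift
            addCon(c(dIdx, wP), c(dCoef, -bigM), 1 - bigM - dConst, Inf)
            ## -d >= 1 - M (1 - wM)
            addCon(c(dIdx, wM), c(-dCoef, -bigM), 1 - bigM + dConst, Inf)
            wIdx <- c(wIdx, wP, wM)
          }
        }
      }
      if (length(wIdx))
        addCon(wIdx, rep(1, length(wIdx)), 1, Inf)
    } else {
      ones <- cut
      zeros <- setdiff(seq_len(nR + nA), ones)
      addCon(c(ones, zeros),
             c(rep(-1, length(ones)), rep(1, length(zeros))),
             1 - length(ones), Inf)
    }
  }

  obj <- c(rep(p@alpha, nR), rep(p@beta, nA),
           rep(0, nrow(vars) - nR - nA))
  list(vars = vars, obj = obj,
       cons = list(i = unlist(ci), j = unlist(cj), v = unlist(cv),
                   lo = lo, hi = hi),
       meta = list(mode = mode, n = n, nR = nR, nA = nA,
                   nS = nrow(vars) - nR - nA, nCons = length(lo)))
}

## ---- solver bridge -------------------------------------------------------

.pythonBin <- function() {
  py <- Sys.getenv("FIBRATIONREPAIR_PYTHON", Sys.which("python"))
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found for the MILP backend")
  py
}

## Solve a batch of 0/1 models in one interpreter call.
.milpSolveBatch <- function(models) {
  if (length(models) == 0L) return(list())
  script <- system.file("python", "milp_solve.py",
                        package = "fibrationRepair", mustWork = TRUE)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  payload <- lapply(models, function(m) list(
    nvar = nrow(m$vars), obj = m$obj,
    cons = list(i = as.integer(m$cons$i), j = as.integer(m$cons$j),
                v = as.numeric(m$cons$v),
                lo = ifelse(is.finite(as.numeric(m$cons$lo)),
                            as.numeric(m$cons$lo), -1e30),
                hi = ifelse(is.finite(as.numeric(m$cons$hi)),
                            as.numeric(m$cons$hi), 1e30))))
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA)
  status <- system2(.pythonBin(), c(script, infile, outfile),
                    stdout = FALSE, stderr = "")
  if (status != 0L || !file.exists(outfile))
    stop("MILP backend failed (exit status ", status, ")")
  jsonlite::read_json(outfile, simplifyVector = FALSE)
}
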