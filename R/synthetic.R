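## Synthetic fibration-symmetric graphs, admissible-ODE dynamics and
## multi-animal trace cohorts.

#' Simulation configuration
#'
#' @param model `"saturating-coupling"` (default): leaky saturating units
#'   `dx_i/dt = -x_i + tanh(sum_j A_ij x_j) + u_f(t)` with a per-fiber slow
#'   square-wave drive `u_f` mimicking command states; or `"kuramoto"`:
#'   phase oscillators with per-fiber frequency offsets.
#' @param noiseSd standard deviation of the additive white noise
#'   (Euler-Maruyama, so each step adds `noiseSd * sqrt(dt) * N(0,1)`).
#' @param duration total simulated time (arbitrary units).
#' @param dt integration/recording time step; must be `< duration`.
#' @param seed integer seed; fixed seeds give bit-identical traces.
#' @param initialConditionMode `"shared-within-fiber"` (one draw per fiber)
#'   or `"random"` (one draw per node).
#' @return a validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(model = c("saturating-coupling", "kuramoto"),
                             noiseSd = 0.05, duration = 60, dt = 0.1,
                             seed = 1L,
                             initialConditionMode = c("shared-within-fiber",
                                                      "random")) {
  model <- match.arg(model)
  initialConditionMode <- match.arg(initialConditionMode)
  stopifnot(is.finite(noiseSd), noiseSd >= 0, duration > 0, dt > 0,
            dt < duration)
  structure(list(model = model, noiseSd = noiseSd, duration = duration,
                 dt = dt, seed = as.integer(seed),
                 initialConditionMode = initialConditionMode),
            class = "SimulationConfig")
}

#' Generate a fibration-symmetric graph with planted fibers
#'
#' Draws a random directed base multigraph on `nFibers` base nodes, repairs
#' it deterministically until its coarsest balanced coloring is discrete
#' (so the planted fibers are exactly the coarsest balanced coloring of the
#' lift), then lifts it: base node i expands into a fiber of
#' `fiberSizes[i]` nodes, and a base edge `u -> v` of multiplicity m gives
#' every node of fiber v exactly m in-edges from m distinct members of
#' fiber u (the lifting property, by construction). Base self-loops lift to
#' in-edges from other members of the same fiber, never to self-loops.
#'
#' @param nFibers number of fibers (>= 1).
#' @param fiberSizes integer vector of fiber sizes (all >= 1).
#' @param baseDensity probability that an ordered base-node pair carries an
#'   edge.
#' @param seed integer seed.
#' @param maxMultiplicity cap on base edge multiplicities (further capped by
#'   the source fiber size).
#' @return a [PlantedGraph-class]. Per-fiber square-wave drive parameters
#'   (distinct periods/amplitudes across fibers) are attached for the
#'   simulator.
#' @examples
#' pg <- generateFiberedGraph(2, c(1, 2), baseDensity = 1, seed = 1)
#' isBalanced(pg@graph, pg@planted)
#' @export
generateFiberedGraph <- function(nFibers, fiberSizes, baseDensity = 0.5,
                                 seed = 1L, maxMultiplicity = 2L) {
  nFibers <- as.integer(nFibers)
  fiberSizes <- as.integer(fiberSizes)
  if (nFibers < 1L) stop("invalid argument: nFibers must be >= 1")
  if (length(fiberSizes) != nFibers)
    stop("invalid argument: need one fiber size per fiber")
  if (any(fiberSizes < 1L)) stop("invalid argument: empty fiber")
  fib <- sprintf("F%02d", seq_len(nFibers))
  .withSeed(seed, {
    cap <- function(i, j) {                  # max feasible multiplicity
      m <- if (i == j) fiberSizes[i] - 1L else fiberSizes[i]
      min(m, maxMultiplicity)
    }
    mult <- matrix(0L, nFibers, nFibers, dimnames = list(fib, fib))
    for (i in seq_len(nFibers)) for (j in seq_len(nFibers)) {
      cm <- cap(i, j)
      if (cm >= 1L && stats::runif(1) < baseDensity)
        mult[j, i] <- sample.int(cm, 1L)     # edge fiber i -> fiber j
    }
    ## deterministic fix-up: force the base's coarsest balanced coloring to
    ## be discrete so that fibers are distinguishable after the lift
    for (iter in seq_len(200L)) {
      bconn <- .baseAsConnectome(fib, mult)
      cls <- minimalBalancedColoring(bconn)@partition@clusters
      if (length(cls) == nFibers) break
      big <- cls[[which(vapply(cls, length, integer(1)) > 1L)[1L]]]
      v <- match(sort(big)[2L], fib)         # perturb second member's inputs
      srcs <- which(vapply(seq_len(nFibers), function(s) cap(s, v) > 0L,
                           logical(1)))
      s <- srcs[1L + (iter %% length(srcs))]
      mult[v, s] <- if (mult[v, s] < cap(s, v)) mult[v, s] + 1L
                    else mult[v, s] - 1L
      if (iter == 200L)
        stop("could not make base fibers distinguishable; ",
             "try different sizes or density")
    }
    ## lift
    nodes <- unlist(lapply(seq_len(nFibers), function(i)
      sprintf("%s.%02d", fib[i], seq_len(fiberSizes[i]))))
    fiber_of <- rep(fib, fiberSizes)
    names(fiber_of) <- nodes
    src_l <- character(); tgt_l <- character()
    for (i in seq_len(nFibers)) for (j in seq_len(nFibers)) {
      m <- mult[j, i]
      if (m == 0L) next
      pool0 <- nodes[fiber_of == fib[i]]
      for (x in nodes[fiber_of == fib[j]]) {
        pool <- setdiff(pool0, x)
        pick <- if (length(pool) == 1L) pool else sample(pool, m)
        src_l <- c(src_l, pick)
        tgt_l <- c(tgt_l, rep(x, m))
      }
    }
    g <- connectome(nodes, data.frame(source = src_l, target = tgt_l,
                                      weight = 1))
    bi <- which(mult > 0, arr.ind = TRUE)
    baseEdges <- data.frame(source = fib[bi[, "col"]],
                            target = fib[bi[, "row"]],
                            multiplicity = mult[bi], stringsAsFactors = FALSE)
    baseEdges <- baseEdges[order(baseEdges$source, baseEdges$target), ,
                           drop = FALSE]
    rownames(baseEdges) <- NULL
    drive <- lapply(seq_len(nFibers), function(i)
      list(period = 8 + 3 * (i - 1L),
           amplitude = 0.4 + 0.1 * (i - 1L),
           phase = (i - 1L) / nFibers))
    names(drive) <- fib
    new("PlantedGraph", graph = g,
        planted = syncPartition(split(nodes, fiber_of),
                                provenance = "planted"),
        baseEdges = baseEdges, drive = drive)
  })
}

.baseAsConnectome <- function(fib, mult) {
  idx <- which(mult > 0, arr.ind = TRUE)
  connectome(fib, data.frame(source = fib[idx[, "col"]],
                             target = fib[idx[, "row"]],
                             weight = mult[idx]))
}

#' The base of a planted graph, as a planted graph of its own
#'
#' Returns the generating base multigraph as a [PlantedGraph-class] with one
#' singleton fiber per base node, same drive: simulating it against the lift
#' with matched initial conditions demonstrates that the quotient preserves
#' the dynamics.
#'
#' @param pg a [PlantedGraph-class].
#' @return a [PlantedGraph-class] over the base nodes.
#' @export
basePlantedGraph <- function(pg) {
  fib <- names(pg@planted@clusters)
  be <- pg@baseEdges
  g <- connectome(fib, data.frame(source = be$source, target = be$target,
                                  weight = be$multiplicity))
  new("PlantedGraph", graph = g,
      planted = syncPartition(stats::setNames(as.list(fib), fib),
                              provenance = "base"),
      baseEdges = be, drive = pg@drive)
}

## Square-wave command drive, in {0, amplitude}.
.driveMatrix <- function(drive, fiber_of, times) {
  m <- matrix(0, length(fiber_of), length(times))
  for (i in seq_along(fiber_of)) {
    d <- drive[[fiber_of[i]]]
    m[i, ] <- d$amplitude * ((floor(times / d$period + d$phase) %% 2) == 0)
  }
  m
}

#' Simulate admissible dynamics on a planted graph
#'
#' Integrates the chosen admissible model with Euler-Maruyama at the
#' configured step. Because the coupling term is dictated by the graph's
#' edges and the drive is constant within each fiber, zero-noise runs with
#' shared-within-fiber initial conditions keep same-fiber trajectories
#' exactly equal at every step.
#'
#' @param pg a [PlantedGraph-class].
#' @param config a [simulationConfig()].
#' @return a [TraceMatrix-class] (neurons x time, `duration/dt` samples).
#' @export
simulateDynamics <- function(pg, config) {
  stopifnot(inherits(config, "SimulationConfig"))
  g <- pg@graph
  labs <- g@nodes$label
  n <- length(labs)
  if (n == 0L) stop("empty graph")
  ## in-neighbour index lists with multiplicity expansion; coupling sums add
  ## their terms in value-sorted order so that equal input multisets give
  ## bit-identical sums (exact within-fiber equality, graph-vs-base too)
  nb <- lapply(.inNeighbours(g, mode = "weight"), match, table = labs)
  nb <- nb[labs]
  couple <- function(z) vapply(nb, function(ix)
    if (length(ix)) sum(sort(z[ix])) else 0, numeric(1))
  fiber_of <- membershipVector(pg@planted)[labs]
  fib <- names(pg@planted@clusters)
  nT <- as.integer(round(config$duration / config$dt))
  times <- seq_len(nT) * config$dt
  U <- .driveMatrix(pg@drive, fiber_of, times)
  .withSeed(config$seed, {
    x0 <- if (config$initialConditionMode == "shared-within-fiber") {
      per_fiber <- stats::setNames(stats::rnorm(length(fib), 0, 0.5), fib)
      unname(per_fiber[fiber_of])
    } else stats::rnorm(n, 0, 0.5)
    out <- matrix(NA_real_, n, nT, dimnames = list(labs, NULL))
    x <- x0
    sdt <- sqrt(config$dt)
    for (t in seq_len(nT)) {
      drift <- switch(config$model,
        "saturating-coupling" = -x + tanh(couple(x)) + U[, t],
        "kuramoto" = {
          ## d theta_i = (1 + u_f) + sum_j A_ij sin(theta_j - theta_i)
          s <- sin(x); cs <- cos(x)
          (1 + U[, t]) + cs * couple(s) - s * couple(cs)
        })
      noise <- if (config$noiseSd > 0)
        stats::rnorm(n, 0, config$noiseSd) * sdt else 0
      x <- x + drift * config$dt + noise
      if (!all(is.finite(x)))
        stop("integration failure: non-finite state at step ", t)
      out[, t] <- x
    }
    new("TraceMatrix", values = out, animalId = "simulated", dt = config$dt)
  })
}

#' Simulate a multi-animal cohort with per-animal missing neurons
#'
#' Each animal is an independent realisation (derived seed: noise and, for
#' `"random"` mode, initial conditions differ), observed on a random subset
#' of neurons: a fraction `missingFraction` of neurons is dropped per
#' animal, re-drawn (deterministically) up to 100 times if some neuron
#' would end up observed in no animal, and an error is raised otherwise.
#'
#' @param pg a [PlantedGraph-class].
#' @param nAnimals number of animals (>= 1).
#' @param missingFraction fraction of neurons missing per animal, in
#'   `[0, 1)`.
#' @param config a [simulationConfig()]; per-animal seeds are derived from
#'   `config$seed`.
#' @return list of [TraceMatrix-class], one per animal.
#' @export
makeCohort <- function(pg, nAnimals, missingFraction = 0, config) {
  stopifnot(nAnimals >= 1, missingFraction >= 0, missingFraction < 1)
  labs <- pg@graph@nodes$label
  n <- length(labs)
  nDrop <- as.integer(round(missingFraction * n))
  seeds <- .deriveSeeds(config$seed, 2L * nAnimals + 100L)
  simSeeds <- seeds[seq_len(nAnimals)]
  dropSeeds <- seeds[nAnimals + seq_len(nAnimals + 100L)]
  keepSets <- NULL
  for (attempt in 0:99) {
    keepSets <- lapply(seq_len(nAnimals), function(a)
      .withSeed(dropSeeds[a + attempt], {
        if (nDrop == 0L) labs else sort(sample(labs, n - nDrop))
      }))
    if (setequal(unique(unlist(keepSets)), labs)) break
    keepSets <- NULL
  }
  if (is.null(keepSets))
    stop("missingFraction leaves some neuron unobserved in every animal")
  lapply(seq_len(nAnimals), function(a) {
    cfg <- config
    cfg$seed <- simSeeds[a]
    tr <- simulateDynamics(pg, cfg)
    new("TraceMatrix", values = tr@values[keepSets[[a]], , drop = FALSE],
        animalId = sprintf("animal%02d", a), dt = tr@dt)
  })
}
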