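## Pairwise synchrony metrics: Level of Synchronicity over a sigma grid and
## the five correlation-family measures, with cohort averaging.

#' Level of Synchronicity between two signals
#'
#' `LoS = (1/T) * sum_t exp(-(x_t - y_t)^2 / (2 sigma^2))`: the
#' time-averaged Gaussian kernel of the instantaneous differences. Always in
#' `(0, 1]`, equal to 1 iff the signals are pointwise identical, and
#' non-decreasing in `sigma`.
#'
#' @param x,y numeric series of equal, positive length.
#' @param sigma positive bandwidth; the closeness scale against which
#'   instantaneous differences are judged.
#' @return numeric(1).
#' @examples
#' computeLoS(rep(0, 10), rep(0.1, 10), sigma = 0.1)  # exp(-1/2)
#' @export
computeLoS <- function(x, y, sigma) {
  if (length(x) == 0L || length(x) != length(y))
    stop("invalid argument: series must be non-empty and of equal length")
  if (!is.finite(sigma) || sigma <= 0)
    stop("invalid argument: sigma must be positive")
  mean(exp(-(x - y)^2 / (2 * sigma^2)))
}

#' The standard sigma grid
#'
#' 39 bandwidths from 0.01 to 0.20 in steps of 0.005, matching the LoS bank
#' used throughout the pipeline.
#'
#' @return numeric vector of length 39.
#' @export
sigmaGrid <- function() seq(0.01, 0.20, by = 0.005)

#' The full metric bank
#'
#' 39 LoS metrics (one per [sigmaGrid()] value) plus the five
#' correlation-family measures: 44 metrics in total.
#'
#' @return list of [MetricSpec-class] objects.
#' @export
metricBank <- function() {
  c(lapply(sigmaGrid(), function(s) metricSpec("los", s)),
    lapply(c("pearson", "spearman", "kendall", "distance-correlation",
             "covariance"), metricSpec))
}

## Biased (Szekely) sample distance correlation for all row pairs of m.
## Row-wise double-centred |xi - xj| matrices are flattened into columns so
## the pairwise means of elementwise products reduce to one crossprod.
.distanceCorrelationMatrix <- function(m) {
  n <- nrow(m); T <- ncol(m)
  flat <- matrix(0, T * T, n)
  for (i in seq_len(n)) {
    D <- abs(outer(m[i, ], m[i, ], "-"))
    D <- D - rowMeans(D)
    D <- sweep(D, 2L, colMeans(D))   # grand mean already removed twice over
    flat[, i] <- as.vector(D)
  }
  V <- crossprod(flat) / (T * T)     # dCov^2 matrix
  d <- sqrt(diag(V))
  R <- V / outer(d, d)
  R[outer(d, d) == 0] <- 0           # zero-variance series: no association
  R <- sqrt(pmax(R, 0))
  dimnames(R) <- list(rownames(m), rownames(m))
  R
}

#' Compute a pairwise synchrony matrix for one animal
#'
#' Applies one metric to every neuron pair of a trace matrix. Correlation
#' families need at least 2 time points; pairs involving a zero-variance
#' series get value 0 (with a warning) rather than NaN, so matrices stay
#' total. Covariance uses the unbiased 1/(T-1) estimator; Kendall is the
#' tie-corrected tau-b; distance correlation is the biased sample estimator
#' on the 1-D series.
#'
#' @param traces a [TraceMatrix-class] with >= 2 neurons.
#' @param metric a [MetricSpec-class].
#' @return a [SynchronyMatrix-class].
#' @export
computeMetric <- function(traces, metric) {
  m <- traces@values
  if (nrow(m) < 2L) stop("need at least 2 neurons")
  fam <- metric@family
  if (fam != "los" && ncol(m) < 2L)
    stop("correlation families need at least 2 time points")
  vals <- switch(fam,
    los = {
      n <- nrow(m)
      V <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
      s2 <- 2 * metric@sigma^2
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        V[i, j] <- V[j, i] <- mean(exp(-(m[i, ] - m[j, ])^2 / s2))
      }
      V
    },
    pearson = .corTotal(m, "pearson"),
    spearman = .corTotal(m, "spearman"),
    kendall = .corTotal(m, "kendall"),
    `distance-correlation` = .distanceCorrelationMatrix(m),
    covariance = stats::cov(t(m)))
  new("SynchronyMatrix", values = vals, metric = metric,
      animalId = traces@animalId)
}

.corTotal <- function(m, method) {
  sds <- apply(m, 1L, stats::sd)
  V <- suppressWarnings(stats::cor(t(m), method = method))
  if (any(sds == 0)) {
    warning("zero-variance series; affected correlations recorded as 0")
    V[sds == 0, ] <- 0
    V[, sds == 0] <- 0
  }
  diag(V) <- 1
  V
}

#' Average synchrony matrices across a cohort
#'
#' Entry (i, j) is the sum of the per-animal values over animals observing
#' both neurons, divided by the number of such animals (the pair's
#' co-occurrence count). Pairs never co-observed are `NA` with count 0.
#'
#' @param matrices list of [SynchronyMatrix-class] sharing one metric.
#' @return an [AveragedMatrix-class].
#' @export
cohortAverage <- function(matrices) {
  if (length(matrices) == 0L) stop("invalid argument: no matrices")
  tags <- vapply(matrices, function(x) .metricTag(x@metric), character(1))
  if (length(unique(tags)) != 1L)
    stop("all matrices must share the same metric")
  labs <- sort(unique(unlist(lapply(matrices, neuronLabels))))
  acc <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  cnt <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (sm in matrices) {
    l <- neuronLabels(sm)
    acc[l, l] <- acc[l, l] + sm@values
    cnt[l, l] <- cnt[l, l] + 1L
  }
  avg <- acc / cnt
  avg[cnt == 0L] <- NA_real_
  new("AveragedMatrix", values = avg, counts = cnt,
      metric = matrices[[1L]]@metric, nAnimals = length(matrices))
}
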