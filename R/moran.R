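#' k-nearest-neighbor weight matrix
#'
#' Row-normalized kNN weights on an embedding: cell `i` gives weight `1/k`
#' to each of its `k` nearest neighbors by Euclidean distance (self
#' excluded), zero elsewhere; the diagonal is zero and every row sums to 1.
#' Distance ties break deterministically by cell index.
#'
#' @param embedding cells x dims numeric matrix of coordinates.
#' @param k number of neighbors (1 <= k < number of cells).
#' @return sparse `dgCMatrix` of weights (cells x cells).
#' @export
knnWeights <- function(embedding, k = 15L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  stopIfNot(all(is.finite(embedding)), "embedding must be finite")
  stopIfNot(k >= 1 && k < n,
    "invalid-argument: k must satisfy 1 <= k < n_cells")
  D <- as.matrix(stats::dist(embedding))
  neighbors <- t(vapply(seq_len(n), function(i) {
    d <- D[i, ]
    d[i] <- Inf
    # order() breaks distance ties by index, giving deterministic graphs
    order(d)[seq_len(k)]
  }, integer(k)))
  if (k == 1) neighbors <- matrix(neighbors, ncol = 1)
  Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k),
    j = as.vector(t(neighbors)),
    x = 1 / k, dims = c(n, n),
    dimnames = list(rownames(embedding), rownames(embedding))
  )
}

#' Moran's I statistic on a weighted neighbor graph
#'
#' Graph autocorrelation of a per-cell value vector:
#' \deqn{I = \frac{N}{W} \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j - \bar
#'   x)}{\sum_i (x_i - \bar x)^2},}
#' with `W` the total weight. Under the permutation null the expectation
#' of `I` is `-1/(N-1)`. With `permutations > 0`, a permutation p-value
#' for positive autocorrelation is computed by shuffling the values over
#' the fixed graph.
#'
#' @param values numeric vector, one value per cell (non-constant).
#' @param weights weight matrix from [knnWeights] (zero diagonal).
#' @param permutations number of permutations for the null (0 = none).
#' @param seed integer seed for the permutations.
#' @return list with `I`, `nCells`, `expectation` (`-1/(N-1)`), and, when
#'   permuted, `pValue` and `permI` (the null draws).
#' @export
moransI <- function(values, weights, permutations = 0L, seed = 1L) {
  values <- as.numeric(values)
  n <- length(values)
  stopIfNot(n == nrow(weights) && n == ncol(weights),
    "values length must match the weight matrix")
  stopIfNot(all(Matrix::diag(weights) == 0), "weights must have zero diagonal")
  xc <- values - mean(values)
  denom <- sum(xc^2)
  if (denom == 0) {
    stop("undefined-statistic: constant values (zero denominator)",
      call. = FALSE)
  }
  W <- sum(weights)
  statistic <- function(v) {
    vc <- v - mean(v)
    (n / W) * sum(vc * as.numeric(weights %*% vc)) / sum(vc^2)
  }
  I <- statistic(values)
  out <- list(I = I, nCells = n, expectation = -1 / (n - 1))
  if (permutations > 0) {
    permI <- withSeed(seed, {
      vapply(seq_len(permutations), function(p) {
        statistic(sample(values))
      }, numeric(1))
    })
    out$permI <- permI
    out$pValue <- (1 + sum(permI >= I)) / (permutations + 1)
  }
  out
}

#' Compare mean expression of two gene sets
#'
#' Reports the mean expression (optionally per cluster) of a driver gene
#' set against a comparison set (e.g., genes selected by trajectory
#' autocorrelation), their difference, and a Wilcoxon rank-sum flag on the
#' per-gene mean expression values. No significance claim beyond that flag
#' is made.
#'
#' @param driverGenes character vector of gene labels (non-empty).
#' @param otherGenes character vector of comparison gene labels
#'   (non-empty).
#' @param x genes x cells expression matrix or `SingleCellExperiment`.
#' @param annotation optional data.frame with a `cluster` column for
#'   per-cluster reporting.
#' @return data.frame with columns `group` (`"overall"` or cluster label),
#'   `meanDriver`, `meanOther`, `difference`, `rankSumP`.
#' @export
compareMeanExpression <- function(driverGenes, otherGenes, x,
                                  annotation = NULL) {
  if (is(x, "SummarizedExperiment")) {
    annotation <- as.data.frame(SummarizedExperiment::colData(x))
    x <- SummarizedExperiment::assay(x, 1)
  }
  stopIfNot(length(driverGenes) >= 1 && length(otherGenes) >= 1,
    "invalid-argument: both gene sets must be non-empty")
  stopIfNot(all(driverGenes %in% rownames(x)),
    "invalid-argument: driver genes missing from the matrix")
  stopIfNot(all(otherGenes %in% rownames(x)),
    "invalid-argument: comparison genes missing from the matrix")
  oneGroup <- function(cols, label) {
    mDrv <- Matrix::rowMeans(x[driverGenes, cols, drop = FALSE])
    mOth <- Matrix::rowMeans(x[otherGenes, cols, drop = FALSE])
    p <- if (identical(sort(driverGenes), sort(otherGenes))) {
      1
    } else {
      suppressWarnings(stats::wilcox.test(mDrv, mOth)$p.value)
    }
    data.frame(
      group = label, meanDriver = mean(mDrv), meanOther = mean(mOth),
      difference = mean(mDrv) - mean(mOth), rankSumP = p
    )
  }
  out <- oneGroup(seq_len(ncol(x)), "overall")
  if (!is.null(annotation) && "cluster" %in% names(annotation)) {
    for (cl in sort(unique(annotation$cluster))) {
      out <- rbind(out, oneGroup(which(annotation$cluster == cl), cl))
    }
  }
  rownames(out) <- NULL
  out
}
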