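#' Simulation configuration
#'
#' Defines the study conditions for the synthetic-data generator: a
#' stage-ordered cell population with a designated marker-positive
#' progenitor cluster whose abundance trends across stages, and gene
#' trajectories generated by the package's own state-space model.
#'
#' Defaults: 3 stages, 3 clusters of 300 cells per stage with the progenitor
#' cluster at abundance fractions (0.1, 0.2, 0.4) across stages (the
#' remainder split evenly), Hurst exponent 0.6, unit innovation sd, and
#' observation noise sd 0.1.
#'
#' @param nGenes number of genes.
#' @param nStages number of ordered stages K (>= 2; default 3).
#' @param nClusters number of clusters (>= 1).
#' @param cellsPerClusterStage clusters x stages integer matrix of cell
#'   counts, or `NULL` to build it from `cellsPerStage` and
#'   `progenitorFractions`.
#' @param cellsPerStage total cells per stage when building counts.
#' @param progenitorFractions length-`nStages` vector of progenitor
#'   abundance fractions per stage (monotone by default).
#' @param progenitorCluster label of the designated progenitor cluster.
#' @param markerGene label of the tumor marker gene.
#' @param markerContaminationRate probability a non-progenitor cell shows
#'   spurious marker expression.
#' @param hurst Hurst exponent, strictly inside (0.5, 1).
#' @param sigmaU innovation sd (>= 0).
#' @param obsNoiseSd observation noise sd for the trajectory observations.
#' @param cellNoiseSd per-cell expression noise sd around the cluster/stage
#'   mean.
#' @param baselineShift minimum positive offset added to all cluster/stage
#'   means; the realized offset is raised to the trajectory range so that
#'   truncation of cell-level expression at zero only affects the noise
#'   tail, never the means.
#' @param arCoef self-autoregression coefficient of the latent recursion.
#' @param couplingEps coupling scale of the interaction term in the latent
#'   recursion.
#' @param seed integer seed.
#' @return a validated `simulationConfig` list object.
#' @export
simulationConfig <- function(nGenes = 30L,
                             nStages = 3L,
                             nClusters = 3L,
                             cellsPerClusterStage = NULL,
                             cellsPerStage = 300L,
                             progenitorFractions = NULL,
                             progenitorCluster = "epithelial",
                             markerGene = "gene1",
                             markerContaminationRate = 0.01,
                             hurst = 0.6,
                             sigmaU = 1,
                             obsNoiseSd = 0.1,
                             cellNoiseSd = 0.25,
                             baselineShift = 5,
                             arCoef = 0.5,
                             couplingEps = 0.1,
                             seed = 1L) {
  stopIfNot(nGenes >= 1, "nGenes must be positive")
  stopIfNot(nStages >= 2, "at least two stages are required")
  stopIfNot(nClusters >= 1, "nClusters must be positive")
  stopIfNot(hurst > 0.5 && hurst < 1,
    "hurst must lie strictly inside (0.5, 1)")
  stopIfNot(sigmaU >= 0, "sigmaU must be non-negative")
  stopIfNot(obsNoiseSd >= 0, "obsNoiseSd must be non-negative")
  stopIfNot(
    markerContaminationRate >= 0 && markerContaminationRate <= 1,
    "markerContaminationRate must be a probability"
  )
  geneLabels <- paste0("gene", seq_len(nGenes))
  stopIfNot(markerGene %in% geneLabels,
    "markerGene must appear in the gene set")
  clusterLabels <- c(
    progenitorCluster,
    paste0("cluster", seq_len(max(nClusters - 1, 0)))
  )[seq_len(nClusters)]
  stopIfNot(progenitorCluster %in% clusterLabels,
    "progenitorCluster must appear in the cluster set")
  if (is.null(cellsPerClusterStage)) {
    if (is.null(progenitorFractions)) {
      # default abundance trend of the designated progenitor across stages
      progenitorFractions <- seq(0.1, 0.4, length.out = nStages)
    }
    stopIfNot(length(progenitorFractions) == nStages,
      "progenitorFractions must have one entry per stage")
    stopIfNot(all(progenitorFractions > 0 & progenitorFractions < 1),
      "progenitorFractions must lie in (0, 1)")
    cellsPerClusterStage <- matrix(0L, nClusters, nStages)
    for (k in seq_len(nStages)) {
      np <- round(cellsPerStage * progenitorFractions[k])
      rest <- cellsPerStage - np
      other <- rep(rest %/% max(nClusters - 1, 1), max(nClusters - 1, 0))
      if (nClusters > 1 && sum(other) < rest) {
        other[1] <- other[1] + rest - sum(other)
      }
      cellsPerClusterStage[, k] <- as.integer(c(np, other))
    }
  }
  stopIfNot(
    is.matrix(cellsPerClusterStage) &&
      all(dim(cellsPerClusterStage) == c(nClusters, nStages)) &&
      all(cellsPerClusterStage >= 0),
    "cellsPerClusterStage must be a non-negative clusters x stages matrix"
  )
  dimnames(cellsPerClusterStage) <- list(
    clusterLabels, paste0("stage", seq_len(nStages))
  )
  structure(
    list(
      nGenes = as.integer(nGenes), nStages = as.integer(nStages),
      nClusters = as.integer(nClusters),
      cellsPerClusterStage = cellsPerClusterStage,
      geneLabels = geneLabels, clusterLabels = clusterLabels,
      stageLabels = paste0("stage", seq_len(nStages)),
      progenitorCluster = progenitorCluster, markerGene = markerGene,
      markerContaminationRate = markerContaminationRate,
      hurst = hurst, sigmaU = sigmaU, obsNoiseSd = obsNoiseSd,
      cellNoiseSd = cellNoiseSd, baselineShift = baselineShift,
      arCoef = arCoef, couplingEps = couplingEps, seed = as.integer(seed)
    ),
    class = "simulationConfig"
  )
}

#' Ground-truth interaction matrix with designated driver genes
#'
#' Generates an `nGenes x nGenes` non-negative interaction matrix in which
#' exactly `nDrivers` rows (the planted drivers) carry gamma-distributed
#' off-diagonal entries scaled by `strength`. The planted structure is a
#' driver module: driver genes interact strongly with one another (the
#' co-amplified regulatory module that marks them as drivers), and each
#' driver additionally pushes its own disjoint set of target genes at a
#' fraction `targetWeight` of the module strength. Each driver row carries
#' `round(sparsity * (nGenes - 1))` non-zero off-diagonal entries in total
#' (at least one), so driver rows always have strictly larger off-diagonal
#' row sums than the all-zero non-driver rows. The diagonal is a common
#' self-precision of 1, which keeps downstream tilted posteriors proper.
#'
#' @param nGenes number of genes.
#' @param nDrivers number of planted driver genes (0..nGenes).
#' @param strength non-negative scale of driver interaction entries; 0
#'   yields an all-zero off-diagonal matrix with drivers still flagged.
#' @param sparsity fraction in `[0, 1]` of a driver's possible off-diagonal
#'   entries that are non-zero.
#' @param seed integer seed.
#' @param entryShape gamma shape (= rate, so unit mean) of the multiplicative
#'   variation on the entries.
#' @param targetWeight relative weight of driver-to-target entries versus
#'   driver-to-driver entries.
#' @param excludeGenes gene indices or labels never flagged as drivers
#'   (e.g., a lineage marker gene whose cell-level expression is
#'   construct-driven rather than dynamic).
#' @return list with `matrix` (the interaction matrix), `driverGenes`
#'   (labels of the flagged rows), `strength`, `sparsity`.
#' @export
generateInteractionMatrix <- function(nGenes, nDrivers, strength = 30,
                                      sparsity = 0.3, seed = 1L,
                                      entryShape = 8, targetWeight = 0.3,
                                      excludeGenes = NULL) {
  stopIfNot(nDrivers >= 0 && nDrivers <= nGenes,
    "nDrivers must lie in 0..nGenes (invalid-argument)")
  stopIfNot(strength >= 0, "strength must be non-negative")
  stopIfNot(sparsity >= 0 && sparsity <= 1, "sparsity must be in [0, 1]")
  geneLabels <- paste0("gene", seq_len(nGenes))
  if (is.character(excludeGenes)) {
    excludeGenes <- match(excludeGenes, geneLabels)
  }
  pool0 <- setdiff(seq_len(nGenes), excludeGenes)
  stopIfNot(nDrivers <= length(pool0),
    "nDrivers exceeds the eligible gene pool (invalid-argument)")
  withSeed(seed, {
    phi <- matrix(0, nGenes, nGenes, dimnames = list(geneLabels, geneLabels))
    driverIdx <- sort(pool0[sample.int(length(pool0), nDrivers)])
    if (strength > 0 && nGenes > 1 && nDrivers > 0) {
      deg <- max(1L, round(sparsity * (nGenes - 1)))
      pool <- sample(setdiff(seq_len(nGenes), driverIdx))
      for (g in driverIdx) {
        others <- setdiff(driverIdx, g)
        phi[g, others] <- strength * rgamma(length(others),
          shape = entryShape, rate = entryShape)
        nt <- min(deg - length(others), length(pool))
        if (nt > 0) {
          take <- pool[seq_len(nt)]
          pool <- setdiff(pool, take)
          phi[g, take] <- targetWeight * strength *
            rgamma(nt, shape = entryShape, rate = entryShape)
        }
        if (sum(phi[g, ] > 0) == 0) {
          # degenerate corner (single driver, no pool): ensure one target
          j <- sample(setdiff(seq_len(nGenes), g), 1)
          phi[g, j] <- targetWeight * strength *
            rgamma(1, shape = entryShape, rate = entryShape)
        }
      }
    }
    diag(phi) <- 1
    list(
      matrix = phi,
      driverGenes = geneLabels[driverIdx],
      strength = strength,
      sparsity = sparsity
    )
  })
}

#' Simulate latent and observed gene trajectories
#'
#' Evolves the latent state by the coupled recursion
#' \deqn{x_k = a_1 x_{k-1} + \epsilon \, \Phi_{off} x_{k-1} + u_k}
#' where `Phi_off` is the symmetrized off-diagonal part of the ground-truth
#' interaction matrix, and `u_k` are fractional-Gaussian-noise innovations
#' with the configured Hurst exponent and sd (correlated over stages,
#' independent across genes). Observations are `z_k = x_k + N(0,
#' obsNoiseSd^2)`. The per-gene ARMA recursion leaves gene coupling to the
#' interaction matrix, so this coupled first-order form is the generator's
#' documented way of injecting the interaction structure the inference must
#' recover.
#'
#' @param interactions result of [generateInteractionMatrix].
#' @param config a [simulationConfig].
#' @return list with `latent` and `observed` (genes x K matrices),
#'   `interactions`, and `config`.
#' @export
simulateTrajectories <- function(interactions, config) {
  stopIfNot(inherits(config, "simulationConfig"),
    "config must come from simulationConfig()")
  stopIfNot(
    is.matrix(interactions$matrix) &&
      all(dim(interactions$matrix) == config$nGenes),
    "interaction matrix must be nGenes x nGenes (invalid-argument)"
  )
  N <- config$nGenes
  K <- config$nStages
  phiOff <- symmetrize(interactions$matrix)
  diag(phiOff) <- 0
  coupling <- config$arCoef * diag(N) + config$couplingEps * phiOff
  withSeed(config$seed, {
    u <- simulateFgn(K, config$hurst, config$sigmaU, nSeries = N)
    latent <- matrix(0, N, K)
    prev <- rep(0, N)
    for (k in seq_len(K)) {
      latent[, k] <- as.vector(coupling %*% prev) + u[, k]
      prev <- latent[, k]
    }
    observed <- latent + matrix(rnorm(N * K, sd = config$obsNoiseSd), N, K)
    dimnames(latent) <- dimnames(observed) <-
      list(config$geneLabels, config$stageLabels)
    list(
      latent = latent, observed = observed,
      interactions = interactions, config = config
    )
  })
}

#' Simulate a stage-ordered cell-level dataset
#'
#' Realizes the trajectory set at the cell level: per-cell expression is
#' drawn around the cluster/stage mean with Gaussian noise, truncated at
#' zero. The designated progenitor cluster follows the generated trajectory
#' (plus a positive baseline shift); other clusters receive fixed
#' cluster-specific offsets. Progenitor cells always express the marker gene
#' at a positive level; other cells express it only with probability
#' `markerContaminationRate`. The progenitor cluster's abundance fraction
#' follows the configured trend across stages exactly (cell counts are fixed
#' by the configuration, not resampled).
#'
#' @param trajectories result of [simulateTrajectories].
#' @param config the same [simulationConfig] used for the trajectories.
#' @return a [SingleCellExperiment::SingleCellExperiment] (genes x cells)
#'   with assay `"expression"`, colData columns `cluster` and `stage`, and
#'   the ground truth in `metadata(.)$truth`.
#' @export
simulateCellDataset <- function(trajectories, config = trajectories$config) {
  stopIfNot(inherits(config, "simulationConfig"),
    "config must come from simulationConfig()")
  stopIfNot(
    identical(dim(trajectories$observed),
      c(config$nGenes, config$nStages)),
    "trajectories inconsistent with config (invalid-argument)"
  )
  N <- config$nGenes
  K <- config$nStages
  counts <- config$cellsPerClusterStage
  total <- sum(counts)
  markerIdx <- match(config$markerGene, config$geneLabels)
  # the baseline offset must cover the trajectory range, otherwise
  # truncation at zero clips the negative excursions of the
  # highest-amplitude genes and distorts their cluster means
  shift <- max(config$baselineShift,
    ceiling(max(abs(trajectories$observed))) + 1)
  withSeed(config$seed + 1L, {
    # fixed cluster offsets; the progenitor follows the trajectory itself
    offsets <- matrix(rnorm(N * config$nClusters, sd = 1), N,
      config$nClusters,
      dimnames = list(config$geneLabels, config$clusterLabels)
    )
    offsets[, config$progenitorCluster] <- 0
    expr <- matrix(0, N, total)
    cluster <- character(total)
    stage <- character(total)
    pos <- 0L
    for (k in seq_len(K)) {
      for (c in seq_len(config$nClusters)) {
        nc <- counts[c, k]
        if (nc == 0) next
        idx <- pos + seq_len(nc)
        mu <- shift + trajectories$observed[, k] + offsets[, c]
        cells <- matrix(rnorm(N * nc, sd = config$cellNoiseSd), N, nc) + mu
        cells <- pmax(cells, 0)
        isProgenitor <-
          config$clusterLabels[c] == config$progenitorCluster
        if (isProgenitor) {
          cells[markerIdx, ] <- runif(nc, 1, 2)
        } else {
          contaminated <- runif(nc) < config$markerContaminationRate
          cells[markerIdx, ] <- ifelse(contaminated, runif(nc, 0.5, 1), 0)
        }
        expr[, idx] <- cells
        cluster[idx] <- config$clusterLabels[c]
        stage[idx] <- config$stageLabels[k]
        pos <- pos + nc
      }
    }
    dimnames(expr) <- list(
      config$geneLabels, paste0("cell", seq_len(total))
    )
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(expression = expr),
      colData = S4Vectors::DataFrame(
        cell_id = colnames(expr), cluster = cluster, stage = stage
      )
    )
    S4Vectors::metadata(sce)$truth <- trajectories
    sce
  })
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the expression matrix in Matrix Market triplet format with sidecar
#' gene and barcode files, the cell annotations as TSV
#' (`cell_id`, `cluster`, `stage`), and the ground-truth interaction and
#' trajectory tables as TSV when present.
#'
#' @param sce a `SingleCellExperiment` as produced by
#'   [simulateCellDataset].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(sce, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- SummarizedExperiment::assay(sce, "expression")
  paths <- list(
    matrix = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    annotations = file.path(dir, "annotations.tsv")
  )
  # Matrix Market convention: genes in rows, cells in columns
  Matrix::writeMM(methods::as(Matrix::Matrix(expr, sparse = TRUE),
    "generalMatrix"), paths$matrix)
  writeLines(rownames(expr), paths$genes)
  writeLines(colnames(expr), paths$barcodes)
  ann <- as.data.frame(SummarizedExperiment::colData(sce))
  utils::write.table(ann[, c("cell_id", "cluster", "stage")],
    paths$annotations,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- S4Vectors::metadata(sce)$truth
  if (!is.null(truth)) {
    paths$truth_interactions <- file.path(dir, "truth_interactions.tsv")
    utils::write.table(truth$interactions$matrix, paths$truth_interactions,
      sep = "\t", quote = FALSE
    )
    paths$truth_trajectories <- file.path(dir, "truth_trajectories.tsv")
    utils::write.table(truth$observed, paths$truth_trajectories,
      sep = "\t", quote = FALSE
    )
  }
  invisible(paths)
}
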