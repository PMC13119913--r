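#' Pipeline run configuration
#'
#' Builds and schema-validates the configuration for [runPipeline].
#' Unknown keys at any level are rejected rather than ignored, so a typo
#' in a config file fails loudly before any computation.
#'
#' @param simulation `NULL`, or a named list of [simulationConfig]
#'   arguments describing a synthetic dataset to generate.
#' @param input `NULL`, or a named list with `matrixPath`,
#'   `annotationPath`, `format`, `orientation` (and optionally
#'   `genesPath`, `barcodesPath`, `log1p`) for [readExpression]. Exactly
#'   one of `simulation` / `input` must be given.
#' @param stages ordered character vector of stage labels (derived
#'   automatically for simulated data).
#' @param markerGene tumor marker gene for progenitor selection (derived
#'   automatically for simulated data).
#' @param inference named list overriding `hurst` (`NULL` to fit by grid
#'   search), `hurstGrid`, `arOrder`, `maOrder`, `a0`, `b0`, `tol`,
#'   `maxIter`, `nSamples`, `mcmcMethod`, `topG` (most-variable-gene cap),
#'   `compareModels` (logical).
#' @param scoring named list overriding `topK`, `hdiMass`, `effect`,
#'   `knownGenes` (character vector) or `knownGenesPath` (file with one
#'   symbol per line).
#' @param moran `NULL`, or a named list with `embeddingPath` (delimited
#'   table `cell_id, dim1, dim2, ...`) or `embedding` (matrix), `k`,
#'   `permutations`.
#' @param seed integer master seed for the whole run.
#' @param outdir output directory for tables and the run manifest.
#' @return a validated `runConfig` object.
#' @export
runConfig <- function(simulation = NULL, input = NULL, stages = NULL,
                      markerGene = NULL, inference = list(),
                      scoring = list(), moran = NULL,
                      seed = 1L, outdir = tempfile("driverDyn_run_")) {
  checkKeys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad) > 0) {
      stop("unknown config key(s) in ", where, ": ",
        paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  stopIfNot(xor(is.null(simulation), is.null(input)),
    "exactly one of 'simulation' or 'input' must be provided")
  if (!is.null(simulation)) {
    checkKeys(simulation, names(formals(simulationConfig)), "simulation")
  }
  if (!is.null(input)) {
    checkKeys(input, c("matrixPath", "annotationPath", "format",
      "orientation", "genesPath", "barcodesPath", "log1p"), "input")
    stopIfNot(all(c("matrixPath", "annotationPath", "format",
      "orientation") %in% names(input)),
      "input requires matrixPath, annotationPath, format, orientation")
    stopIfNot(!is.null(stages), "stages must be declared for file input")
    stopIfNot(!is.null(markerGene),
      "markerGene must be declared for file input")
  }
  infDefaults <- list(
    hurst = NULL, hurstGrid = seq(0.55, 0.95, by = 0.05),
    arOrder = 1L, maOrder = 1L, a0 = 1, b0 = 1,
    tol = 1e-6, maxIter = 500L, nSamples = 2000L,
    mcmcMethod = "direct", topG = 300L, compareModels = TRUE
  )
  checkKeys(inference, names(infDefaults), "inference")
  inference <- utils::modifyList(infDefaults, inference,
    keep.null = TRUE)
  scoreDefaults <- list(
    topK = 30L, hdiMass = 0.95, effect = "state",
    knownGenes = NULL, knownGenesPath = NULL
  )
  checkKeys(scoring, names(scoreDefaults), "scoring")
  scoring <- utils::modifyList(scoreDefaults, scoring, keep.null = TRUE)
  if (!is.null(moran)) {
    checkKeys(moran, c("embeddingPath", "embedding", "k", "permutations"),
      "moran")
    moran <- utils::modifyList(
      list(embeddingPath = NULL, embedding = NULL, k = 15L,
        permutations = 199L), moran, keep.null = TRUE)
  }
  structure(
    list(
      simulation = simulation, input = input, stages = stages,
      markerGene = markerGene, inference = inference, scoring = scoring,
      moran = moran, seed = as.integer(seed), outdir = outdir
    ),
    class = "runConfig"
  )
}

#' Load a run configuration from a YAML file
#'
#' @param path path to a YAML file whose top-level keys are the arguments
#'   of [runConfig].
#' @param seed optional seed overriding the file's value.
#' @param outdir optional output directory overriding the file's value.
#' @return a validated `runConfig`.
#' @export
readRunConfig <- function(path, seed = NULL, outdir = NULL) {
  raw <- yaml::read_yaml(path)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  if (!is.null(outdir)) raw$outdir <- outdir
  do.call(runConfig, raw)
}

writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full driver-prioritization pipeline
#'
#' Executes the four-stage workflow end to end: (1) ingest or simulate the
#' stage-ordered dataset and aggregate it to the cluster-by-stage mean
#' expression tensor; (2) select the progenitor cluster from the
#' stage-abundance trend and marker-positive cancer cell fractions; (3)
#' build the ARMA/fGn state-space covariance structure for the progenitor
#' trajectories (capped at the `topG` most variable genes) and run
#' variational inference, with posterior-predictive fit metrics and the
#' interaction-vs-independence model comparison; (4) draw posterior
#' samples, convert them to per-gene effect distributions and rank genes
#' by driver coefficient. An optional final stage computes Moran's I for
#' the ranked genes on a supplied embedding. All randomness derives from
#' the single config seed, so a run is reproducible bit for bit.
#'
#' Result tables are written as TSV under `config$outdir` together with a
#' JSON run manifest; every output is also returned in the result list.
#'
#' @param config a [runConfig].
#' @return invisibly, a list with elements `driverTable`, `fitMetrics`,
#'   `modelComparison`, `ccf`, `trend`, `progenitor`, `fit`,
#'   `covarianceSet`, `hurst`, `moran`, `manifest`, `sce`.
#' @export
runPipeline <- function(config) {
  stopIfNot(inherits(config, "runConfig"),
    "config must come from runConfig()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "driverDyn",
    version = as.character(utils::packageVersion("driverDyn")),
    seed = config$seed, started = format(Sys.time()), outputs = list(),
    warnings = character(0), complete = FALSE
  )
  inf <- config$inference

  # -- stage 1: data -------------------------------------------------------
  if (!is.null(config$simulation)) {
    simArgs <- utils::modifyList(config$simulation,
      list(seed = config$seed))
    simCfg <- do.call(simulationConfig, simArgs)
    truthPhi <- generateInteractionMatrix(
      nGenes = simCfg$nGenes,
      nDrivers = max(1L, round(simCfg$nGenes / 10)),
      seed = config$seed,
      excludeGenes = simCfg$markerGene
    )
    traj <- simulateTrajectories(truthPhi, simCfg)
    sce <- simulateCellDataset(traj, simCfg)
    stages <- simCfg$stageLabels
    markerGene <- simCfg$markerGene
  } else {
    args <- config$input
    names(args)[names(args) == "matrixPath"] <- "path"
    sce <- do.call(readExpression, args)
    stages <- config$stages
    markerGene <- config$markerGene
  }
  ann <- as.data.frame(SummarizedExperiment::colData(sce))
  tensor <- clusterStageMeans(sce, stages = stages)

  # -- stage 2: progenitor -------------------------------------------------
  ccf <- cancerCellFraction(sce, markerGene = markerGene)
  trend <- stageTrend(ann, stages)
  progenitor <- selectProgenitor(ccf, trend)
  manifest$outputs$ccf <- writeTsv(ccf, file.path(config$outdir, "ccf.tsv"))
  manifest$outputs$trend <-
    writeTsv(trend, file.path(config$outdir, "trend.tsv"))

  # -- stage 3: temporal model + inference ---------------------------------
  z <- clusterTrajectories(tensor, progenitor$cluster)
  topG <- min(inf$topG, nrow(z))
  keep <- order(apply(z, 1, stats::var), decreasing = TRUE)[seq_len(topG)]
  z <- z[sort(keep), , drop = FALSE]
  z <- sweep(z, 1, rowMeans(z)) # model states are zero-mean deviations
  K <- ncol(z)
  spec <- estimateArma(z, m = inf$arOrder, n = inf$maOrder)
  if (is.null(inf$hurst)) {
    hfit <- fitHurst(z, grid = inf$hurstGrid, input = "replicates")
  } else {
    R <- stats::toeplitz(fgnAutocorrelation(0:(K - 1), inf$hurst))
    emp <- crossprod(z) / nrow(z)
    hfit <- list(
      H = inf$hurst,
      sigmaU = sqrt(max(sum(R * emp) / sum(R * R), 1e-6))
    )
  }
  covSet <- buildCovarianceSet(spec, K = K, nGenes = nrow(z),
    H = hfit$H, sigmaU = max(hfit$sigmaU, 1e-3))
  prior <- interactionPrior(inf$a0, inf$b0)
  # observation noise of the stage means: pooled standard error of the
  # progenitor cluster's per-(gene, stage) means
  expr <- SummarizedExperiment::assay(sce, 1)
  progCells <- ann$cluster == progenitor$cluster
  seSq <- vapply(stages, function(st) {
    sel <- progCells & ann$stage == st
    if (sum(sel) < 2) return(NA_real_)
    mean(apply(expr[rownames(z), sel, drop = FALSE], 1, stats::var)) /
      sum(sel)
  }, numeric(1))
  sigmaV <- sqrt(mean(seSq, na.rm = TRUE))
  if (!is.finite(sigmaV) || sigmaV <= 0) sigmaV <- NULL
  vbSettings <- list(tol = inf$tol, maxIter = inf$maxIter, sigmaV = sigmaV)
  fit <- vbFit(z, covSet, prior, vbSettings)
  fitMetrics <- evaluateFit(z, fit, byStage = TRUE)
  manifest$outputs$fit_metrics <-
    writeTsv(fitMetrics, file.path(config$outdir, "fit_metrics.tsv"))
  modelComparison <- NULL
  if (isTRUE(inf$compareModels)) {
    modelComparison <- compareModels(z, covSet, prior, vbSettings)
    manifest$outputs$model_comparison <- writeTsv(
      modelComparison, file.path(config$outdir, "model_comparison.tsv")
    )
  }

  # -- stage 4: sampling + driver scoring ----------------------------------
  samples <- mcmcSample(fit, nSamples = inf$nSamples,
    seed = config$seed + 1L, method = inf$mcmcMethod)
  known <- config$scoring$knownGenes
  if (!is.null(config$scoring$knownGenesPath)) {
    known <- readLines(config$scoring$knownGenesPath)
  }
  effects <- lapply(seq_len(nrow(z)), function(g) {
    geneEffectSamples(fit, g, nDraws = inf$nSamples,
      seed = config$seed + 1L + g, effect = config$scoring$effect,
      stateSamples = samples)
  })
  driverTable <- rankDrivers(effects, hdiMass = config$scoring$hdiMass,
    knownGenes = known)
  manifest$outputs$driver_table <- writeTsv(
    driverTable, file.path(config$outdir, "driver_table.tsv")
  )
  overlap <- NULL
  if (!is.null(known)) {
    overlap <- overlapWithKnown(driverTable, known,
      topK = min(config$scoring$topK, nrow(driverTable)))
    manifest$knownDriverOverlapPercent <- overlap
  }

  # -- optional: Moran's I comparison --------------------------------------
  moran <- NULL
  if (!is.null(config$moran)) {
    emb <- config$moran$embedding
    if (!is.null(config$moran$embeddingPath)) {
      embDf <- utils::read.table(config$moran$embeddingPath,
        header = TRUE, sep = "\t")
      emb <- as.matrix(embDf[, -1, drop = FALSE])
      rownames(emb) <- embDf[[1]]
    }
    w <- knnWeights(emb, k = config$moran$k)
    expr <- SummarizedExperiment::assay(sce, 1)
    topGenes <- utils::head(driverTable$gene, config$scoring$topK)
    moran <- do.call(rbind, lapply(topGenes, function(g) {
      res <- moransI(as.numeric(expr[g, rownames(emb)]), w,
        permutations = config$moran$permutations, seed = config$seed)
      data.frame(gene = g, moranI = res$I, pValue = res$pValue %||% NA)
    }))
    manifest$outputs$moran <-
      writeTsv(moran, file.path(config$outdir, "moran.tsv"))
  }

  manifest$progenitor <- progenitor$cluster
  manifest$hurst <- hfit$H
  manifest$sigmaU <- covSet@sigmaU
  manifest$nGenesModeled <- nrow(z)
  manifest$converged <- fit@converged
  manifest$checksums <- lapply(manifest$outputs, function(p) {
    unname(tools::md5sum(p))
  })
  manifest$complete <- TRUE
  manifest$finished <- format(Sys.time())
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    driverTable = driverTable, fitMetrics = fitMetrics,
    modelComparison = modelComparison, ccf = ccf, trend = trend,
    progenitor = progenitor, fit = fit, covarianceSet = covSet,
    hurst = hfit$H, overlap = overlap, moran = moran,
    manifest = manifest, sce = sce
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
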