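#' Cancer cell fraction per cluster
#'
#' For each cluster, the fraction of cells expressing the designated tumor
#' marker gene above the threshold (default: any non-zero expression). With
#' `byStage = TRUE` the fraction is additionally reported per stage and the
#' cluster summary is the across-stage average rather than the pooled
#' fraction.
#'
#' @param x a `SingleCellExperiment` (genes x cells) with colData `cluster`
#'   and `stage`, or a genes x cells matrix.
#' @param annotation data.frame with `cluster` (and `stage`) per cell when
#'   `x` is a matrix.
#' @param markerGene gene label of the marker.
#' @param threshold expression threshold; a cell is marker-positive when its
#'   marker expression is strictly greater than this (default 0).
#' @param byStage average per-stage fractions instead of pooling cells.
#' @return data.frame with columns `cluster`, `ccf`, `nCells` (and a
#'   `perStage` attribute when `byStage = TRUE`).
#' @export
cancerCellFraction <- function(x, annotation = NULL, markerGene,
                               threshold = 0, byStage = FALSE) {
  if (is(x, "SummarizedExperiment")) {
    annotation <- as.data.frame(SummarizedExperiment::colData(x))
    x <- SummarizedExperiment::assay(x, 1)
  }
  stopIfNot(!is.null(annotation), "annotation is required for matrix input")
  stopIfNot(markerGene %in% rownames(x),
    "invalid-argument: marker gene absent from the matrix")
  marker <- as.numeric(x[markerGene, ])
  positive <- marker > threshold
  clusters <- sort(unique(annotation$cluster))
  if (byStage) {
    stopIfNot("stage" %in% names(annotation),
      "byStage requires a stage column")
    perStage <- do.call(rbind, lapply(clusters, function(cl) {
      sel <- annotation$cluster == cl
      stages <- sort(unique(annotation$stage[sel]))
      data.frame(
        cluster = cl, stage = stages,
        ccf = vapply(stages, function(s) {
          mean(positive[sel & annotation$stage == s])
        }, numeric(1)),
        nCells = vapply(stages, function(s) {
          sum(sel & annotation$stage == s)
        }, numeric(1))
      )
    }))
    out <- data.frame(
      cluster = clusters,
      ccf = vapply(clusters, function(cl) {
        mean(perStage$ccf[perStage$cluster == cl])
      }, numeric(1)),
      nCells = as.vector(table(annotation$cluster)[clusters])
    )
    attr(out, "perStage") <- perStage
  } else {
    out <- data.frame(
      cluster = clusters,
      ccf = vapply(clusters, function(cl) {
        mean(positive[annotation$cluster == cl])
      }, numeric(1)),
      nCells = vapply(clusters, function(cl) {
        sum(annotation$cluster == cl)
      }, numeric(1))
    )
  }
  attr(out, "markerGene") <- markerGene
  attr(out, "rule") <- paste0("marker expression > ", threshold)
  rownames(out) <- NULL
  out
}

#' Stage-abundance trend per cluster
#'
#' For each cluster and stage, computes the cluster's fraction of the cells
#' at that stage, then classifies the sequence across ordered stages.
#' "Consistent stage-dependent trend" is operationalized as non-strict
#' monotonicity with at least one strict change: a constant sequence
#' carries no trend and fails.
#'
#' @param annotation data.frame (or colData) with `cluster` and `stage`.
#' @param stages a [stageMap] or ordered character vector of stage labels.
#' @return data.frame with `cluster`, one `frac_<stage>` column per stage,
#'   `direction` in `increasing`/`decreasing`/`none`, and `pass`.
#' @export
stageTrend <- function(annotation, stages) {
  annotation <- as.data.frame(annotation)
  if (!inherits(stages, "stageMap")) stages <- stageMap(stages)
  stageNames <- names(stages)
  stopIfNot(length(stageNames) >= 2, "at least two stages are required")
  counts <- table(
    factor(annotation$cluster),
    factor(annotation$stage, levels = stageNames)
  )
  if (any(colSums(counts) == 0)) {
    stop("invalid-input: stage(s) with zero cells: ",
      paste(stageNames[colSums(counts) == 0], collapse = ", "),
      call. = FALSE)
  }
  frac <- sweep(counts, 2, colSums(counts), "/")
  classify <- function(xi) {
    d <- diff(xi)
    if (all(d >= 0) && any(d > 0)) {
      "increasing"
    } else if (all(d <= 0) && any(d < 0)) {
      "decreasing"
    } else {
      "none"
    }
  }
  direction <- apply(frac, 1, classify)
  out <- data.frame(cluster = rownames(frac), check.names = FALSE)
  for (s in stageNames) out[[paste0("frac_", s)]] <- as.numeric(frac[, s])
  out$direction <- as.character(direction)
  out$pass <- out$direction != "none"
  rownames(out) <- NULL
  out
}

#' Select the progenitor (cancer-originating) cluster
#'
#' Among clusters passing the stage-trend criterion, selects the one with
#' maximal cancer cell fraction. Ties in CCF break by larger total
#' abundance change across stages, then lexicographically by cluster label,
#' so selection is deterministic and invariant to input order.
#'
#' @param ccfTable output of [cancerCellFraction].
#' @param trendResult output of [stageTrend].
#' @return list with `cluster` (the selection), `ccf`, `direction`, and
#'   `note` documenting any tie-break.
#' @export
selectProgenitor <- function(ccfTable, trendResult) {
  stopIfNot(setequal(ccfTable$cluster, trendResult$cluster),
    "CCF and trend tables must cover the same clusters")
  passing <- trendResult$cluster[trendResult$pass]
  if (length(passing) == 0) {
    stop("no-candidate: no cluster passes the stage-trend criterion; ",
      "directions were: ",
      paste(trendResult$cluster, trendResult$direction,
        sep = "=", collapse = ", "),
      call. = FALSE)
  }
  sub <- ccfTable[ccfTable$cluster %in% passing, , drop = FALSE]
  best <- sub$cluster[sub$ccf == max(sub$ccf)]
  note <- "unique CCF maximum among trend-passing clusters"
  if (length(best) > 1) {
    fracCols <- grep("^frac_", names(trendResult), value = TRUE)
    change <- vapply(best, function(cl) {
      xi <- as.numeric(
        trendResult[trendResult$cluster == cl, fracCols]
      )
      abs(xi[length(xi)] - xi[1])
    }, numeric(1))
    best <- best[change == max(change)]
    note <- "CCF tie broken by total abundance change"
    if (length(best) > 1) {
      best <- sort(best)
      note <- "CCF and abundance-change tie broken lexicographically"
    }
  }
  selected <- best[1]
  list(
    cluster = selected,
    ccf = ccfTable$ccf[ccfTable$cluster == selected],
    direction =
      trendResult$direction[trendResult$cluster == selected],
    note = note
  )
}
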