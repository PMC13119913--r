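#' Ordered stage map
#'
#' Declares the ordered set of biological stages and their model time
#' indices. Stage order is taken as given (it is a property of the study
#' design, e.g., normal < primary tumor < metastasis), never inferred.
#'
#' @param stages character vector of stage labels in progression order.
#' @return a `stageMap` object: named integer vector of time indices.
#' @export
stageMap <- function(stages) {
  stages <- as.character(stages)
  stopIfNot(length(stages) >= 1 && !anyDuplicated(stages),
    "stages must be unique")
  structure(stats::setNames(seq_along(stages), stages), class = "stageMap")
}

#' Read an expression matrix and cell annotations
#'
#' Reads either a Matrix Market triplet file with sidecar `genes.tsv` /
#' `barcodes.tsv` files, or a delimited dense table with a header row, plus
#' an annotation TSV with columns `cell_id`, `cluster`, `stage` (and
#' optionally `patient`). The matrix orientation must be declared
#' explicitly; auto-detection is refused because a silently transposed
#' single-cell matrix is a classic irrecoverable bug.
#'
#' Expression values are used as provided; set `log1p = TRUE` to apply a
#' log(1 + x) transform on load.
#'
#' @param path path to the matrix file (`.mtx` or delimited).
#' @param annotationPath path to the annotation TSV.
#' @param format `"mtx"` or `"delimited"`.
#' @param orientation `"genes_x_cells"` or `"cells_x_genes"`; what the rows
#'   of the file on disk are.
#' @param genesPath,barcodesPath sidecar label files for `mtx` format
#'   (defaults: `genes.tsv` / `barcodes.tsv` next to the matrix).
#' @param sep field separator for delimited format (default tab).
#' @param log1p apply `log1p` to the values on load.
#' @return a `SingleCellExperiment` (genes x cells) with assay
#'   `"expression"` and colData `cell_id`, `cluster`, `stage`
#'   (and `patient` when present).
#' @export
readExpression <- function(path, annotationPath,
                           format = c("mtx", "delimited"),
                           orientation = c("genes_x_cells",
                             "cells_x_genes"),
                           genesPath = NULL, barcodesPath = NULL,
                           sep = "\t", log1p = FALSE) {
  format <- tryCatch(match.arg(format), error = function(e) {
    stop("unsupported-format: format must be 'mtx' or 'delimited'",
      call. = FALSE)
  })
  orientation <- match.arg(orientation)
  stopIfNot(file.exists(path), paste("file not found:", path))
  stopIfNot(file.exists(annotationPath),
    paste("file not found:", annotationPath))
  if (format == "mtx") {
    if (is.null(genesPath)) genesPath <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodesPath)) {
      barcodesPath <- file.path(dirname(path), "barcodes.tsv")
    }
    m <- as.matrix(Matrix::readMM(path))
    rowLab <- readLines(genesPath)
    colLab <- readLines(barcodesPath)
    stopIfNot(length(rowLab) == nrow(m) && length(colLab) == ncol(m),
      "inconsistent-input: sidecar label lengths do not match the matrix")
    dimnames(m) <- list(rowLab, colLab)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
      row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
  }
  if (orientation == "cells_x_genes") m <- t(m)
  # from here on: genes x cells
  stopIfNot(all(m >= 0), "expression values must be non-negative")
  stopIfNot(!anyDuplicated(rownames(m)) && !anyDuplicated(colnames(m)),
    "gene and cell labels must be unique")
  if (log1p) m <- log1p(m)
  ann <- utils::read.table(annotationPath, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE)
  required <- c("cell_id", "cluster", "stage")
  stopIfNot(all(required %in% names(ann)),
    "annotation file must have columns cell_id, cluster, stage")
  missing <- setdiff(ann$cell_id, colnames(m))
  if (length(missing) > 0) {
    stop("inconsistent-input: annotated cells absent from the matrix: ",
      paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- m[, ann$cell_id, drop = FALSE]
  cd <- S4Vectors::DataFrame(
    cell_id = ann$cell_id, cluster = ann$cluster, stage = ann$stage
  )
  if ("patient" %in% names(ann)) cd$patient <- ann$patient
  SingleCellExperiment::SingleCellExperiment(
    assays = list(expression = m), colData = cd
  )
}

#' Cluster-by-stage mean expression tensor
#'
#' Aggregates a genes x cells expression matrix into the genes x stages x
#' clusters array of group means that the temporal model consumes. Each
#' present entry is the arithmetic mean over the contributing cells; a
#' (stage, cluster) group with no cells is masked, never imputed, and a
#' message reports how many groups were empty.
#'
#' @param x a `SingleCellExperiment` with colData `cluster` and `stage`, or
#'   a genes x cells matrix.
#' @param annotation when `x` is a matrix: data.frame with columns
#'   `cell_id`, `cluster`, `stage` covering the columns of `x`.
#' @param stages a [stageMap] (or character vector of ordered stage labels)
#'   covering every stage label in the annotation.
#' @return an [ExpressionTensor].
#' @export
clusterStageMeans <- function(x, annotation = NULL, stages) {
  if (is(x, "SummarizedExperiment")) {
    annotation <- as.data.frame(SummarizedExperiment::colData(x))
    x <- SummarizedExperiment::assay(x, 1)
  }
  stopIfNot(is.matrix(x) || is(x, "Matrix"), "x must be a matrix")
  stopIfNot(!is.null(annotation), "annotation is required for matrix input")
  if (!inherits(stages, "stageMap")) stages <- stageMap(stages)
  stageNames <- names(stages)
  stopIfNot(all(annotation$stage %in% stageNames),
    "annotation contains stage labels missing from the stage map")
  stopIfNot(nrow(annotation) == ncol(x),
    "annotation must cover all cells (one row per column of x)")
  clusters <- sort(unique(annotation$cluster))
  N <- nrow(x)
  K <- length(stageNames)
  C <- length(clusters)
  means <- array(0, dim = c(N, K, C),
    dimnames = list(rownames(x), stageNames, clusters))
  mask <- matrix(FALSE, K, C, dimnames = list(stageNames, clusters))
  for (ci in seq_len(C)) {
    for (ki in seq_len(K)) {
      sel <- annotation$cluster == clusters[ci] &
        annotation$stage == stageNames[ki]
      if (any(sel)) {
        means[, ki, ci] <- Matrix::rowMeans(x[, sel, drop = FALSE])
        mask[ki, ci] <- TRUE
      }
    }
  }
  if (!any(mask)) {
    stop("invalid-input: every (stage, cluster) group is empty",
      call. = FALSE)
  }
  if (any(!mask)) {
    message(sum(!mask), " empty (stage, cluster) group(s) masked")
  }
  new("ExpressionTensor", means = means, mask = mask, stages = stageNames)
}

#' Extract one cluster's gene-by-stage trajectory slice
#'
#' @param tensor an [ExpressionTensor].
#' @param cluster cluster label.
#' @return genes x stages matrix of mean expression for that cluster.
#' @export
clusterTrajectories <- function(tensor, cluster) {
  stopIfNot(is(tensor, "ExpressionTensor"), "tensor must be an ExpressionTensor")
  clusters <- dimnames(tensor@means)[[3]]
  stopIfNot(cluster %in% clusters, paste("unknown cluster:", cluster))
  ci <- match(cluster, clusters)
  stopIfNot(all(tensor@mask[, ci]),
    "cluster has masked (absent) stages; cannot form a full trajectory")
  tensor@means[, , ci]
}
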