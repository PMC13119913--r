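writeToyMtx <- function(dir) {
  # 2 cells x 3 genes with entries (cell 1, gene 1) = 4 and
  # (cell 2, gene 3) = 7, stored genes-in-rows
  writeLines(c(
    "%%MatrixMarket matrix coordinate real general",
    "3 2 2",
    "1 1 4",
    "3 2 7"
  ), file.path(dir, "matrix.mtx"))
  writeLines(paste0("g", 1:3), file.path(dir, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(dir, "barcodes.tsv"))
  write.table(
    data.frame(cell_id = c("c1", "c2"), cluster = "A",
      stage = c("s1", "s2")),
    file.path(dir, "annotations.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  dir
}

test_that("Matrix Market triplets expand to the expected dense matrix", {
  dir <- writeToyMtx(withr::local_tempdir())
  sce <- readExpression(
    file.path(dir, "matrix.mtx"), file.path(dir, "annotations.tsv"),
    format = "mtx"
  )
  m <- SummarizedExperiment::assay(sce, 1)
  # cells x genes view: [[4,0,0],[0,0,7]]
  expect_equal(unname(t(m)), rbind(c(4, 0, 0), c(0, 0, 7)))
  expect_equal(rownames(m), paste0("g", 1:3))
})

test_that("unknown formats and inconsistent labels are rejected", {
  dir <- writeToyMtx(withr::local_tempdir())
  expect_error(
    readExpression(file.path(dir, "matrix.mtx"),
      file.path(dir, "annotations.tsv"), format = "tenx"),
    "unsupported-format"
  )
  ann2 <- file.path(dir, "bad.tsv")
  write.table(
    data.frame(cell_id = c("c1", "cX"), cluster = "A", stage = "s1"),
    ann2, sep = "\t", quote = FALSE, row.names = FALSE
  )
  expect_error(
    readExpression(file.path(dir, "matrix.mtx"), ann2, format = "mtx"),
    "inconsistent-input"
  )
})

test_that("delimited tables honor the declared orientation", {
  dir <- withr::local_tempdir()
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
    dimnames = list(c("c1", "c2"), c("gA", "gB", "gC")))
  path <- file.path(dir, "dense.tsv")
  write.table(m, path, sep = "\t", quote = FALSE)
  annPath <- file.path(dir, "ann.tsv")
  write.table(
    data.frame(cell_id = c("c1", "c2"), cluster = "A", stage = "s1"),
    annPath, sep = "\t", quote = FALSE, row.names = FALSE
  )
  sce <- readExpression(path, annPath, format = "delimited",
    orientation = "cells_x_genes")
  expect_equal(
    SummarizedExperiment::assay(sce, 1)["gB", "c2"], m["c2", "gB"]
  )
})

test_that("cluster-stage means equal a brute-force group-by", {
  # direct mean: one cluster, one stage, values 1, 2, 3
  m <- matrix(c(1, 2, 3), nrow = 1,
    dimnames = list("g1", paste0("c", 1:3)))
  ann <- data.frame(cell_id = paste0("c", 1:3), cluster = "A",
    stage = "s1")
  tens <- clusterStageMeans(m, ann, stages = "s1")
  expect_equal(unname(tensorMeans(tens)[1, 1, 1]), 2)

  # single-cell group equals that cell's value
  tens1 <- clusterStageMeans(m[, 1, drop = FALSE], ann[1, ], stages = "s1")
  expect_equal(unname(tensorMeans(tens1)[1, 1, 1]), 1)

  # random 50-cell fixture against an independent group-by oracle
  set.seed(42)
  nc <- 50
  m <- matrix(rpois(5 * nc, 4), nrow = 5,
    dimnames = list(paste0("g", 1:5), paste0("c", seq_len(nc))))
  ann <- data.frame(
    cell_id = colnames(m),
    cluster = sample(c("A", "B"), nc, replace = TRUE),
    stage = sample(c("s1", "s2", "s3"), nc, replace = TRUE)
  )
  tens <- suppressMessages(
    clusterStageMeans(m, ann, stages = c("s1", "s2", "s3"))
  )
  for (cl in c("A", "B")) {
    for (st in c("s1", "s2", "s3")) {
      sel <- ann$cluster == cl & ann$stage == st
      if (!any(sel)) {
        expect_false(tensorMask(tens)[st, cl])
        next
      }
      oracle <- rowMeans(m[, sel, drop = FALSE])
      expect_equal(tensorMeans(tens)[, st, cl], oracle)
    }
  }

  # permutation invariance in cell order
  perm <- sample(nc)
  tens2 <- suppressMessages(
    clusterStageMeans(m[, perm], ann[perm, ], stages = c("s1", "s2", "s3"))
  )
  expect_equal(tensorMeans(tens2), tensorMeans(tens))

  # conservation: mean times group size reproduces group sums
  for (cl in c("A", "B")) {
    sel <- ann$cluster == cl & ann$stage == "s1"
    if (!any(sel)) next
    expect_equal(
      tensorMeans(tens)[, "s1", cl] * sum(sel),
      rowSums(m[, sel, drop = FALSE])
    )
  }
})

test_that("empty groups are masked and an all-empty tensor errors", {
  m <- matrix(1:4, nrow = 2,
    dimnames = list(c("g1", "g2"), c("c1", "c2")))
  ann <- data.frame(cell_id = c("c1", "c2"), cluster = c("A", "A"),
    stage = c("s1", "s1"))
  tens <- suppressMessages(
    clusterStageMeans(m, ann, stages = c("s1", "s2"))
  )
  expect_true(tensorMask(tens)["s1", "A"])
  expect_false(tensorMask(tens)["s2", "A"])
  expect_error(clusterTrajectories(tens, "A"), "masked")
})
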