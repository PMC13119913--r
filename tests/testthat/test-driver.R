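makeGammaFit <- function(shape, rate, a0 = 1, b0 = 1) {
  N <- nrow(shape)
  new("VbFit",
    statePosterior = new("GaussianPosterior",
      mean = rep(0, N * 3), cov = diag(N * 3),
      nGenes = as.integer(N), K = 3L),
    interactionPosterior = new("GammaPosterior", shape = shape,
      rate = rate),
    elbo = 0, converged = TRUE, iterations = 1L, sigmaV = 1,
    settings = list(a0 = a0, b0 = b0),
    observations = matrix(0, N, 3,
      dimnames = list(paste0("g", seq_len(N)), NULL))
  )
}

test_that("centered effects vanish at the prior and track elevations", {
  N <- 5
  # near-degenerate gammas at the prior mean a0/b0 = 1
  shape <- matrix(1e8, N, N, dimnames = list(paste0("g", 1:N),
    paste0("g", 1:N)))
  fit <- makeGammaFit(shape, shape)
  e <- geneEffectSamples(fit, "g2", nDraws = 400, seed = 1,
    effect = "centered_rowsum")
  expect_lt(max(abs(e$draws)), 1e-2)

  # one entry elevated by c above the prior mean
  rate2 <- shape / 1
  rate2["g2", "g4"] <- shape["g2", "g4"] / 2.5 # mean 2.5, c = 1.5
  fit2 <- makeGammaFit(shape, rate2)
  e2 <- geneEffectSamples(fit2, "g2", nDraws = 400, seed = 1,
    effect = "centered_rowsum")
  expect_lt(max(abs(e2$draws - 1.5)), 1e-2)
  expect_error(geneEffectSamples(fit2, "gX"), "invalid-argument")
})

test_that("effect draws equal an independently coded row sum", {
  set.seed(30)
  N <- 6
  shape <- matrix(runif(N * N, 1, 4), N, N,
    dimnames = list(paste0("g", 1:N), paste0("g", 1:N)))
  rate <- matrix(runif(N * N, 0.5, 3), N, N,
    dimnames = dimnames(shape))
  fit <- makeGammaFit(shape, rate)
  g <- 3
  nDraws <- 200
  e <- geneEffectSamples(fit, g, nDraws = nDraws, seed = 77,
    effect = "rowsum")
  # brute force: same gamma stream, explicit per-entry draw and row sum
  others <- setdiff(seq_len(N), g)
  oracle <- driverDyn:::withSeed(77, {
    phi <- rgamma(nDraws * length(others),
      shape = rep(shape[g, others], each = nDraws),
      rate = rep(rate[g, others], each = nDraws))
    rowSums(matrix(phi, nrow = nDraws))
  })
  expect_equal(e$draws, oracle)
})

test_that("the driver coefficient is a squared signal-to-noise ratio", {
  expect_equal(drCoef(0, 1), 0)
  expect_equal(drCoef(2, 1), 4)
  expect_equal(drCoef(-2, 1), 4)
  expect_equal(drCoef(3, 0.5), 36)
  expect_error(drCoef(1, 0), "degenerate-posterior")
  expect_message(out <- drCoef(0, 0), "convention")
  expect_equal(out, 0)
  # scale invariance: mean and sd scale together
  expect_equal(drCoef(5 * 2, 5 * 1), drCoef(2, 1))
})

test_that("ranking orders the four-gene toy by precision-weighted effect", {
  toy <- list(
    list(gene = "G1", draws = rnorm(100, 3, 0.5), mu = 3, sigma = 0.5),
    list(gene = "G2", draws = rnorm(100, 1, 1), mu = 1, sigma = 1),
    list(gene = "G3", draws = rnorm(100, 1, 0.4), mu = 1, sigma = 0.4),
    list(gene = "G4", draws = rnorm(100, 0, 1), mu = 0, sigma = 1)
  )
  tab <- rankDrivers(toy)
  expect_equal(tab$gene, c("G1", "G3", "G2", "G4"))
  expect_equal(tab$drCoef, c(36, 6.25, 1, 0))
  expect_equal(tab$rank, 1:4)

  # permutation invariance of the ranked table
  tab2 <- rankDrivers(toy[c(3, 1, 4, 2)])
  expect_equal(tab2, tab)

  # single gene gets rank 1
  expect_equal(rankDrivers(toy[2])$rank, 1L)
})

test_that("cross-cell-type score matrices mask absent genes", {
  tabA <- data.frame(gene = c("g1", "g2", "g3"), drCoef = c(9, 4, 1),
    rank = 1:3)
  tabB <- data.frame(gene = c("g2", "g4"), drCoef = c(25, 16), rank = 1:2)
  m <- crossTypeScores(list(typeA = tabA, typeB = tabB),
    geneSubset = c("g1", "g2", "g9"))
  expect_equal(m["g1", "typeA"], 9)
  expect_equal(m["g2", "typeB"], 25)
  expect_true(is.na(m["g1", "typeB"]))
  expect_true(all(is.na(m["g9", ])))

  # single table: the column reproduces that table
  m1 <- crossTypeScores(list(only = tabA), geneSubset = tabA$gene)
  expect_equal(unname(m1[, "only"]), tabA$drCoef)
  expect_warning(
    crossTypeScores(list(only = tabA), geneSubset = "gZ"),
    "empty-result"
  )
})

test_that("known-driver overlap is a percentage of the top ranks", {
  tab <- data.frame(
    gene = paste0("G", 1:30), drCoef = 30:1, rank = 1:30
  )
  known <- paste0("g", 1:19) # case-insensitive match, 19 of top 30
  expect_equal(overlapWithKnown(tab, known, topK = 30), 100 * 19 / 30)
  expect_equal(round(overlapWithKnown(tab, known, topK = 30), 2), 63.33)
  expect_equal(overlapWithKnown(tab, tab$gene, topK = 10), 100)
  expect_warning(out <- overlapWithKnown(tab, character(0)), "empty")
  expect_equal(out, 0)
})

test_that("planted drivers rise to the top of the ranking", {
  hits <- vapply(1:8, function(s) {
    cfg <- simulationConfig(nGenes = 30, seed = s)
    phi <- generateInteractionMatrix(30, 3, seed = s)
    traj <- simulateTrajectories(phi, cfg)
    cs <- makeCovSet(traj$observed)
    fit <- suppressWarnings(vbFit(traj$observed, cs,
      settings = list(sigmaV = 0.05)))
    smp <- mcmcSample(fit, 400, seed = s)
    eff <- lapply(seq_len(30), function(g) {
      geneEffectSamples(fit, g, nDraws = 400, seed = g,
        effect = "state", stateSamples = smp)
    })
    tab <- rankDrivers(eff)
    all(tab$rank[match(phi$driverGenes, tab$gene)] <= 5)
  }, logical(1))
  expect_gte(mean(hits), 6 / 8)
})
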